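#' Smile detection threshold
#'
#' The per-participant threshold is one standard deviation above the mean of
#' the filtered positive-expression score, computed over the entire
#' interaction recording. A constant series yields a threshold equal to the
#' constant (so detection finds no smiles there, which is not an error).
#'
#' @param score Filtered score series for the whole interaction clip.
#' @param sd_method `"sample"` (default) or `"population"`.
#' @return Scalar threshold, in score units.
#' @export
detection_threshold <- function(score, sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  if (length(score) == 0L) {
    rlang::abort("Cannot compute a threshold from an empty score series.",
                 class = "dyadsmile_empty_input_error")
  }
  s <- series_sd(score, sd_method)
  if (!is.finite(s)) s <- 0
  mean(score) + s
}

#' Detect smiles as supra-threshold excursions
#'
#' A smile is a maximal run of consecutive frames whose score is strictly
#' greater than the threshold; each run is reported by its first and last
#' frame above the threshold (1-based inclusive).
#'
#' @param score Filtered score series.
#' @param threshold Detection threshold (typically [detection_threshold()]).
#' @param participant_id Identifier attached to each interval.
#' @return A smile-track tibble: `participant_id`, `start_frame`,
#'   `end_frame`, `source` (`"auto"`). Zero rows when nothing exceeds the
#'   threshold.
#' @export
detect_smiles <- function(score, threshold, participant_id = NA_character_) {
  above <- score > threshold
  if (!any(above)) {
    return(empty_track(participant_id))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(
    participant_id = participant_id,
    start_frame = as.integer(starts[keep]),
    end_frame = as.integer(ends[keep]),
    source = "auto"
  )
}

empty_track <- function(participant_id = NA_character_) {
  tibble::tibble(
    participant_id = character(0),
    start_frame = integer(0), end_frame = integer(0), source = character(0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# frames strictly between two 1-based inclusive intervals
interval_gap_frames <- function(end_first, start_second) {
  start_second - end_first - 1L
}

#' Merge smiles separated by less than a maximum gap
#'
#' When two detected smiles are separated by strictly less than `max_gap_s`
#' seconds (gap measured from the end of the first to the start of the
#' second, in frames between them), they are treated as one smile running
#' from the start of the first to the end of the second. Merging chains
#' left-to-right until no adjacent pair qualifies. A gap of exactly
#' `max_gap_s` is \emph{not} merged.
#'
#' @param smiles Smile-track tibble with sorted, pairwise-disjoint intervals.
#' @param fs Sampling rate, Hz.
#' @param max_gap_s Maximum gap, seconds (default 2).
#' @return Merged smile-track tibble; a merged interval keeps the `source`
#'   of its first member.
#' @export
merge_close_smiles <- function(smiles, fs = 30, max_gap_s = 2) {
  if (nrow(smiles) <= 1L) return(smiles)
  gap_frames <- max_gap_s * fs
  o <- order(smiles$start_frame)
  s <- smiles$start_frame[o]
  e <- smiles$end_frame[o]
  src <- smiles$source[o]
  pid <- smiles$participant_id[o]

  ks <- s[1]; ke <- e[1]; ksrc <- src[1]; kpid <- pid[1]
  out_s <- integer(0); out_e <- integer(0); out_src <- character(0); out_pid <- character(0)
  for (i in seq_along(s)[-1]) {
    if (interval_gap_frames(ke, s[i]) < gap_frames) {
      ke <- max(ke, e[i])
    } else {
      out_s <- c(out_s, ks); out_e <- c(out_e, ke)
      out_src <- c(out_src, ksrc); out_pid <- c(out_pid, kpid)
      ks <- s[i]; ke <- e[i]; ksrc <- src[i]; kpid <- pid[i]
    }
  }
  out_s <- c(out_s, ks); out_e <- c(out_e, ke)
  out_src <- c(out_src, ksrc); out_pid <- c(out_pid, kpid)
  tibble::new_tibble(list(participant_id = out_pid, start_frame = as.integer(out_s),
                          end_frame = as.integer(out_e), source = out_src),
                     nrow = length(out_s))
}

#' Read a manual-edit file
#'
#' Human raters who visually verify the automatic detection record their
#' corrections in a small CSV with columns `action` (`remove` or `add`),
#' `start_frame`, `end_frame`, and optionally `annotator`. A `remove` span
#' deletes every detected smile it overlaps; an `add` span inserts a new
#' manual smile.
#'
#' @param path Edits CSV path.
#' @return A tibble with columns `action`, `start_frame`, `end_frame`,
#'   `annotator`.
#' @export
read_edit_set <- function(path) {
  e <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(e) <- trimws(names(e))
  required <- c("action", "start_frame", "end_frame")
  missing <- setdiff(required, names(e))
  if (length(missing) > 0L) {
    rlang::abort(paste0("Edit file missing column(s): ", paste(missing, collapse = ", ")),
                 class = "dyadsmile_format_error")
  }
  if (!all(e$action %in% c("remove", "add"))) {
    rlang::abort("Edit actions must be 'remove' or 'add'.",
                 class = "dyadsmile_format_error")
  }
  if (!("annotator" %in% names(e))) e$annotator <- NA_character_
  e$start_frame <- as.integer(e$start_frame)
  e$end_frame <- as.integer(e$end_frame)
  tibble::as_tibble(e[, c("action", "start_frame", "end_frame", "annotator")])
}

#' Apply manual edits to a detected smile track
#'
#' Removals are applied first (any detected interval overlapping a removal
#' span is deleted), then additions are inserted in sorted order with
#' `source = "manual"`. An addition that overlaps a retained interval is a
#' validation error naming both spans.
#'
#' @param smiles Smile-track tibble (typically merged auto detections).
#' @param edits Edit tibble from [read_edit_set()], or NULL for no edits.
#' @param n_frames Total frames in the clip; additions must lie within.
#' @return Edited smile-track tibble, sorted by start frame.
#' @export
apply_edits <- function(smiles, edits, n_frames = NULL) {
  if (is.null(edits) || nrow(edits) == 0L) return(smiles)
  stopifnot(all(edits$start_frame <= edits$end_frame))
  if (!is.null(n_frames) &&
      any(edits$start_frame < 1L | edits$end_frame > n_frames)) {
    rlang::abort("Edit spans must lie within [1, n_frames].",
                 class = "dyadsmile_validation_error")
  }
  pid <- if (nrow(smiles) > 0L) smiles$participant_id[1] else NA_character_

  removals <- edits[edits$action == "remove", , drop = FALSE]
  keep <- rep(TRUE, nrow(smiles))
  for (i in seq_len(nrow(removals))) {
    keep <- keep & !(smiles$start_frame <= removals$end_frame[i] &
                       removals$start_frame[i] <= smiles$end_frame)
  }
  out <- smiles[keep, , drop = FALSE]

  additions <- edits[edits$action == "add", , drop = FALSE]
  for (i in seq_len(nrow(additions))) {
    hit <- which(out$start_frame <= additions$end_frame[i] &
                   additions$start_frame[i] <= out$end_frame)
    if (length(hit) > 0L) {
      rlang::abort(sprintf(
        "Added smile [%d, %d] overlaps retained interval [%d, %d].",
        additions$start_frame[i], additions$end_frame[i],
        out$start_frame[hit[1]], out$end_frame[hit[1]]),
        class = "dyadsmile_validation_error")
    }
    out <- dplyr::bind_rows(out, tibble::tibble(
      participant_id = pid,
      start_frame = additions$start_frame[i],
      end_frame = additions$end_frame[i],
      source = "manual"
    ))
  }
  out[order(out$start_frame), , drop = FALSE]
}

#' Fraction of the interaction spent smiling
#'
#' @param smiles Smile-track tibble (disjoint intervals).
#' @param n_frames Total frames in the interaction clip.
#' @return Proportion in `[0, 1]`: summed interval lengths over `n_frames`.
#' @export
smile_ratio <- function(smiles, n_frames) {
  stopifnot(n_frames > 0)
  if (nrow(smiles) == 0L) return(0)
  sum(smiles$end_frame - smiles$start_frame + 1L) / n_frames
}

#' Detect, merge, and edit smiles for one participant
#'
#' Convenience wrapper running [detection_threshold()], [detect_smiles()],
#' [merge_close_smiles()], and [apply_edits()] on a scored signal.
#'
#' @param sig An `expression_signal` tibble from [score_expression()].
#' @param edits Optional edit tibble ([read_edit_set()]).
#' @param fs Sampling rate; defaults to the signal's.
#' @param max_gap_s Merge gap, seconds.
#' @param sd_method SD convention for the threshold.
#' @return Smile-track tibble with attributes `threshold`, `n_frames`, `fs`.
#' @export
extract_smile_track <- function(sig, edits = NULL, fs = NULL, max_gap_s = 2,
                                sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  fs <- fs %||% sampling_rate(sig)
  thr <- detection_threshold(sig$score, sd_method)
  track <- detect_smiles(sig$score, thr, participant_id = sig$participant_id[1])
  track <- merge_close_smiles(track, fs = fs, max_gap_s = max_gap_s)
  track <- apply_edits(track, edits, n_frames = nrow(sig))
  attr(track, "threshold") <- thr
  attr(track, "n_frames") <- nrow(sig)
  attr(track, "fs") <- fs
  track
}

#' Export a smile track
#'
#' @param track Smile-track tibble.
#' @param path Output path (tab-separated: participant_id, start_frame,
#'   end_frame, source).
#' @return `path`, invisibly.
#' @export
write_smile_track <- function(track, path) {
  readr::write_tsv(track[, c("participant_id", "start_frame", "end_frame", "source")],
                   path, progress = FALSE)
  invisible(path)
}
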