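#' Flag shared smiles across the two members of a dyad
#'
#' A smile of one participant is *shared* when at least one smile of the
#' partner occurs within `window_s` seconds of it. Under the default
#' `"interval_gap"` predicate the temporal distance between two smiles is 0
#' when their intervals overlap and otherwise the number of frames strictly
#' between their nearer endpoints; a distance of exactly `window_s` counts
#' as shared. Flags are computed independently for each track, so the two
#' participants can have different shared counts (two smiles of one may
#' overlap a single smile of the other).
#'
#' An `"onset_latency"` predicate (distance between smile onsets) is
#' available for sensitivity analysis.
#'
#' @param track_a,track_b Smile-track tibbles (sorted, disjoint), one per
#'   participant.
#' @param fs Sampling rate, Hz (must be shared).
#' @param window_s Matching window, seconds (default 2).
#' @param predicate `"interval_gap"` (default) or `"onset_latency"`.
#' @return One tibble: both tracks row-bound, with a logical `shared`
#'   column added.
#' @export
flag_shared_smiles <- function(track_a, track_b, fs = 30, window_s = 2,
                               predicate = c("interval_gap", "onset_latency")) {
  predicate <- match.arg(predicate)
  fs_a <- attr(track_a, "fs", exact = TRUE)
  fs_b <- attr(track_b, "fs", exact = TRUE)
  if (!is.null(fs_a) && !is.null(fs_b) && fs_a != fs_b) {
    rlang::abort("The two tracks were sampled at different rates.",
                 class = "dyadsmile_fs_mismatch_error")
  }
  window_frames <- window_s * fs
  track_a$shared <- shared_flags(track_a, track_b, window_frames, predicate)
  track_b$shared <- shared_flags(track_b, track_a, window_frames, predicate)
  dplyr::bind_rows(track_a, track_b)
}

shared_flags <- function(own, other, window_frames, predicate) {
  if (nrow(own) == 0L) return(logical(0))
  if (nrow(other) == 0L) return(rep(FALSE, nrow(own)))
  if (predicate == "onset_latency") {
    d <- abs(outer(own$start_frame, other$start_frame, "-"))
  } else {
    # gap between nearer endpoints; 0 when the intervals overlap
    gap_ab <- outer(other$start_frame, own$end_frame, "-") - 1L   # other after own
    gap_ba <- outer(own$start_frame, other$end_frame, "-") - 1L   # own after other
    d <- pmax(t(gap_ab), gap_ba, 0L)
  }
  apply(d <= window_frames, 1L, any)
}

#' Mimicry score
#'
#' The mimicry score of a participant is the number of the *partner's*
#' smiles that were shared, divided by the partner's total smile count: the
#' proportion of the partner's smiles the participant joined within the
#' matching window. When the partner never smiled the score is undefined
#' and returned as `NA` (never 0: no opportunity to mimic is not the same
#' as no mimicry).
#'
#' @param partner_n_shared Number of the partner's smiles flagged shared.
#' @param partner_n_smiles The partner's total smile count.
#' @return Proportion in `[0, 1]`, or `NA_real_` when undefined. Vectorized.
#' @export
mimicry_score <- function(partner_n_shared, partner_n_smiles) {
  stopifnot(all(partner_n_shared >= 0), all(partner_n_shared <= partner_n_smiles))
  ifelse(partner_n_smiles > 0, partner_n_shared / partner_n_smiles, NA_real_)
}

#' Summarize a flagged dyad into per-participant outcomes
#'
#' @param flagged Output of [flag_shared_smiles()] (both tracks with
#'   `shared` flags).
#' @param n_frames Total interaction frames (scalar, or named by
#'   participant).
#' @param dyad_id Identifier copied into the result.
#' @param participant_ids Optional explicit pair of ids (needed when one
#'   participant has zero smiles and so contributes no rows to `flagged`).
#' @return A `dyad_result` tibble, one row per participant: `dyad_id`,
#'   `participant_id`, `n_smiles`, `n_shared`, `smile_ratio`,
#'   `mimicry_score`.
#' @export
summarize_dyad <- function(flagged, n_frames, dyad_id = NA_character_,
                           participant_ids = NULL) {
  ids <- participant_ids %||% unique(flagged$participant_id)
  stopifnot(length(ids) == 2L)
  n_smiles <- integer(2); n_shared <- integer(2); ratio <- numeric(2)
  for (j in 1:2) {
    own_idx <- flagged$participant_id == ids[j]
    nf <- if (length(n_frames) > 1L) n_frames[[ids[j]]] else n_frames
    n_smiles[j] <- sum(own_idx)
    n_shared[j] <- sum(flagged$shared[own_idx])
    ratio[j] <- if (n_smiles[j] == 0L) 0 else
      sum(flagged$end_frame[own_idx] - flagged$start_frame[own_idx] + 1L) / nf
  }
  out <- tibble::new_tibble(list(
    dyad_id = rep(dyad_id, 2L),
    participant_id = ids,
    n_smiles = n_smiles,
    n_shared = n_shared,
    smile_ratio = ratio,
    # score of X = partner's shared / partner's total
    mimicry_score = mimicry_score(rev(n_shared), rev(n_smiles))
  ), nrow = 2L)
  class(out) <- c("dyad_result", class(out))
  out
}

#' Analyze one dyad end to end
#'
#' Runs the full pipeline for both participants of a dyad: read and clean
#' the four clips (baseline + interaction each), score and filter the
#' positive-expression signal, detect/merge/edit smiles, flag shared
#' smiles, and compute mimicry scores and smile ratios.
#'
#' @param manifest A two-row manifest tibble ([read_dyad_manifest()]), or a
#'   path to a manifest CSV.
#' @param config A [dyad_config()] list of stage parameters.
#' @param keep_intermediates Attach signals and tracks as attributes
#'   `signals`, `tracks` of the result.
#' @return A `dyad_result` tibble (two rows) with a `group` column.
#' @export
analyze_dyad <- function(manifest, config = dyad_config(),
                         keep_intermediates = FALSE) {
  if (is.character(manifest)) manifest <- read_dyad_manifest(manifest)
  stopifnot(nrow(manifest) == 2L)
  one <- function(i) {
    row <- manifest[i, ]
    ctx <- sprintf("dyad %s, participant %s", row$dyad_id, row$participant_id)
    withCallingHandlers(
      {
        base <- read_au_table(row$baseline_path, row$participant_id, "baseline",
                              fs = config$fs)
        inter <- read_au_table(row$interaction_path, row$participant_id,
                               "interaction", fs = config$fs)
        base <- clean_frames(base, config$min_confidence, config$interpolate)
        inter <- clean_frames(inter, config$min_confidence, config$interpolate)
        sig <- score_expression(inter, base, sd_method = config$sd_method,
                                order = config$filter_order,
                                cutoff = config$filter_cutoff,
                                cutoff_units = config$filter_cutoff_units,
                                epsilon = config$epsilon)
        edits <- if (!is.na(row$edits_path %||% NA) && nzchar(row$edits_path %||% "")) {
          read_edit_set(row$edits_path)
        } else NULL
        track <- extract_smile_track(sig, edits = edits, fs = config$fs,
                                     max_gap_s = config$merge_gap_s,
                                     sd_method = config$sd_method)
        list(sig = sig, track = track)
      },
      error = function(e) {
        rlang::abort(paste0("While analyzing ", ctx, ": ", conditionMessage(e)),
                     parent = e)
      }
    )
  }
  a <- one(1); b <- one(2)
  flagged <- flag_shared_smiles(a$track, b$track, fs = config$fs,
                                window_s = config$shared_window_s,
                                predicate = config$shared_predicate)
  n_frames <- stats::setNames(c(nrow(a$sig), nrow(b$sig)), manifest$participant_id)
  res <- summarize_dyad(flagged, n_frames, dyad_id = manifest$dyad_id[1],
                        participant_ids = manifest$participant_id)
  res$group <- manifest$group[match(res$participant_id, manifest$participant_id)]
  if (keep_intermediates) {
    attr(res, "signals") <- list(a$sig, b$sig)
    attr(res, "tracks") <- list(a$track, b$track)
  }
  res
}

#' Pipeline run configuration
#'
#' Bundles every tunable stage parameter with its default: confidence
#' cutoff for frame cleaning, SD convention, filter order/cutoff/units,
#' merge gap, shared-smile window and predicate, and sampling rate. The
#' defaults mirror the method's stated values (second-order filter, cutoff
#' 0.05, 2 s merge gap, 2 s shared window, 30 Hz).
#'
#' @param fs Sampling rate, Hz.
#' @param min_confidence Tracking-confidence cutoff.
#' @param interpolate Interpolate (vs drop) invalid frames.
#' @param sd_method `"sample"` or `"population"` SD convention.
#' @param filter_order,filter_cutoff,filter_cutoff_units Low-pass settings.
#' @param merge_gap_s Smile merge gap, seconds (strict `<`).
#' @param shared_window_s Shared-smile window, seconds (inclusive `<=`).
#' @param shared_predicate `"interval_gap"` or `"onset_latency"`.
#' @param epsilon Degenerate-signal SD fallback (NULL = error).
#' @param seed Seed recorded for simulation runs.
#' @return A named list of class `dyad_config`.
#' @export
dyad_config <- function(fs = 30, min_confidence = 0.75, interpolate = TRUE,
                        sd_method = "sample", filter_order = 2,
                        filter_cutoff = 0.05,
                        filter_cutoff_units = "nyquist_fraction",
                        merge_gap_s = 2, shared_window_s = 2,
                        shared_predicate = "interval_gap",
                        epsilon = NULL, seed = NULL) {
  cfg <- list(fs = fs, min_confidence = min_confidence, interpolate = interpolate,
              sd_method = sd_method, filter_order = filter_order,
              filter_cutoff = filter_cutoff,
              filter_cutoff_units = filter_cutoff_units,
              merge_gap_s = merge_gap_s, shared_window_s = shared_window_s,
              shared_predicate = shared_predicate, epsilon = epsilon, seed = seed)
  class(cfg) <- "dyad_config"
  cfg
}

#' Write / read a run configuration as flat key-value text
#'
#' Every analysis run should echo its effective configuration next to its
#' outputs so the parameter choices that matter (cutoff units, SD
#' conventions, boundary rules) stay auditable. The format is one
#' `key = value` pair per line.
#'
#' @param config A [dyad_config()] list.
#' @param path File path.
#' @return `write_config`: `path` invisibly; `read_config`: a
#'   `dyad_config` list.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.null(v)) "NULL" else as.character(v)
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, fmt, character(1))), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), character(1)))
  defaults <- dyad_config()
  cfg <- defaults
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (!k %in% names(defaults)) next
    if (v == "NULL") {
      cfg[k] <- list(NULL)
    } else {
      cfg[[k]] <- if (v %in% c("TRUE", "FALSE")) as.logical(v)
        else if (grepl("^-?[0-9.eE+]+$", v)) as.numeric(v)
        else v
    }
  }
  class(cfg) <- "dyad_config"
  cfg
}

#' Export dyad results
#'
#' One delimited row per participant — the table consumed by the
#' group-level statistics.
#'
#' @param results A `dyad_result` tibble (possibly several row-bound).
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_dyad_results <- function(results, path) {
  readr::write_tsv(results, path, progress = FALSE)
  invisible(path)
}
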