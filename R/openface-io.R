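#' Read an AU tracker output table
#'
#' Reads one clip's worth of facial action-unit intensities as emitted by an
#' automated AU tracker (OpenFace 2.2 CSV dialect: a header row whose column
#' names may be padded with spaces, then one row per video frame). Only the
#' columns needed downstream are retained: `frame`, `timestamp`,
#' `confidence`, `success`, and the intensity columns `AU04_r`, `AU06_r`,
#' `AU12_r` (brow furrow, cheek raiser, lip corner puller). Extra columns are
#' ignored.
#'
#' @param source Path to a delimited text file, or a connection.
#' @param participant_id Identifier attached to every row of the result.
#' @param clip_kind `"interaction"` or `"baseline"`.
#' @param fs Sampling rate in Hz (the tracker's video frame rate).
#'
#' @return A tibble of class `au_frames` with columns `participant_id`,
#'   `clip_kind`, `frame`, `timestamp`, `confidence`, `success` (logical),
#'   `au04`, `au06`, `au12`, and attribute `fs`.
#'
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("frame, timestamp, confidence, success, AU04_r, AU06_r, AU12_r",
#'              "1, 0.000, 0.98, 1, 0.1, 0.3, 0.5",
#'              "2, 0.033, 0.98, 1, 0.1, 0.4, 0.6"), path)
#' read_au_table(path, "p1", "interaction")
#' @export
read_au_table <- function(source, participant_id,
                          clip_kind = c("interaction", "baseline"),
                          fs = 30) {
  clip_kind <- match.arg(clip_kind)
  raw <- readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  names(raw) <- trimws(names(raw))

  required <- c("frame", "timestamp", "confidence", "success",
                "AU04_r", "AU06_r", "AU12_r")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    rlang::abort(
      paste0("AU table is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "dyadsmile_format_error"
    )
  }
  if (nrow(raw) == 0L) {
    rlang::abort("AU table contains no frames.",
                 class = "dyadsmile_empty_input_error")
  }

  num <- function(col) {
    x <- suppressWarnings(as.numeric(trimws(raw[[col]])))
    bad <- which(is.na(x) & !(is.na(raw[[col]]) | trimws(raw[[col]]) %in% c("", "NA")))
    if (length(bad) > 0L) {
      rlang::abort(
        sprintf("Non-numeric value in column '%s' at data row %d ('%s').",
                col, bad[1], raw[[col]][bad[1]]),
        class = "dyadsmile_parse_error"
      )
    }
    x
  }

  out <- tibble::tibble(
    participant_id = participant_id,
    clip_kind = clip_kind,
    frame = as.integer(num("frame")),
    timestamp = num("timestamp"),
    confidence = num("confidence"),
    success = num("success") != 0,
    au04 = num("AU04_r"),
    au06 = num("AU06_r"),
    au12 = num("AU12_r")
  )
  new_au_frames(out, fs = fs)
}

new_au_frames <- function(x, fs) {
  x <- tibble::as_tibble(x)
  attr(x, "fs") <- fs
  class(x) <- c("au_frames", class(x))
  x
}

#' Sampling rate of an AU frame table or expression signal
#'
#' @param x An object carrying an `fs` attribute (e.g. the result of
#'   [read_au_table()] or [score_expression()]).
#' @param default Value returned when no attribute is present.
#' @return Sampling rate in Hz.
#' @export
sampling_rate <- function(x, default = 30) {
  fs <- attr(x, "fs", exact = TRUE)
  if (is.null(fs)) default else fs
}

#' Clean an AU frame table
#'
#' Handles frames where the tracker lost the face: frames with `success`
#' FALSE or `confidence` below `min_confidence` have their AU intensities
#' replaced by linear interpolation between the nearest valid frames
#' (leading/trailing runs take the nearest valid value), or are dropped when
#' `interpolate = FALSE`. Duplicate frame indices are removed (first kept)
#' and rows are sorted by frame, so the result has strictly increasing frame
#' numbers. The number of affected frames is reported via a message.
#'
#' Cleaning is idempotent: the invalid-frame mask is unchanged by AU
#' replacement, so a second pass reproduces the same table.
#'
#' @param frames An `au_frames` tibble from [read_au_table()].
#' @param min_confidence Tracking-confidence cutoff in `[0, 1]`.
#' @param interpolate Replace invalid frames (TRUE, default: preserves the
#'   fixed frame grid all downstream frame arithmetic assumes) or drop them.
#' @return An `au_frames` tibble of the same shape (same length when
#'   `interpolate = TRUE`).
#' @export
clean_frames <- function(frames, min_confidence = 0.75, interpolate = TRUE) {
  stopifnot(is.numeric(min_confidence), min_confidence >= 0, min_confidence <= 1)
  fs <- sampling_rate(frames)
  frames <- frames[order(frames$frame), , drop = FALSE]
  frames <- frames[!duplicated(frames$frame), , drop = FALSE]

  invalid <- !frames$success | frames$confidence < min_confidence
  if (all(invalid)) {
    rlang::abort("No usable frames: every frame failed tracking or fell below the confidence cutoff.",
                 class = "dyadsmile_unusable_clip_error")
  }
  n_bad <- sum(invalid)
  if (n_bad > 0L) {
    if (interpolate) {
      idx <- seq_len(nrow(frames))
      for (au in c("au04", "au06", "au12")) {
        frames[[au]][invalid] <- stats::approx(
          x = idx[!invalid], y = frames[[au]][!invalid],
          xout = idx[invalid], method = "linear", rule = 2
        )$y
      }
      rlang::inform(sprintf("clean_frames: interpolated AU values on %d of %d frames.",
                            n_bad, nrow(frames)))
    } else {
      frames <- frames[!invalid, , drop = FALSE]
      rlang::inform(sprintf("clean_frames: dropped %d invalid frame(s).", n_bad))
    }
  }
  frames$au04 <- pmax(frames$au04, 0)
  frames$au06 <- pmax(frames$au06, 0)
  frames$au12 <- pmax(frames$au12, 0)
  new_au_frames(frames, fs = fs)
}

#' Write an AU frame table in the tracker's CSV dialect
#'
#' Serializes an `au_frames` tibble back to the comma-plus-space padded CSV
#' format the tracker emits, so simulator output is consumable by any tool
#' expecting tracker files. [read_au_table()] round-trips these files
#' losslessly.
#'
#' @param frames An `au_frames` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_au_table <- function(frames, path) {
  header <- "frame, timestamp, confidence, success, AU04_r, AU06_r, AU12_r"
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  lines <- paste(frames$frame, fmt(frames$timestamp), fmt(frames$confidence),
                 as.integer(frames$success), fmt(frames$au04), fmt(frames$au06),
                 fmt(frames$au12), sep = ", ")
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read a dyad manifest
#'
#' A manifest links the two participants of a recorded dyad to their clip
#' files: a CSV with exactly two rows and columns `dyad_id`,
#' `participant_id`, `group` (one of IP, MAT, SCZ), `baseline_path`,
#' `interaction_path`, and optionally `edits_path`. Relative paths are
#' resolved against the manifest's own directory.
#'
#' @param path Manifest CSV path.
#' @return A two-row tibble.
#' @export
read_dyad_manifest <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(m) <- trimws(names(m))
  required <- c("dyad_id", "participant_id", "group", "baseline_path", "interaction_path")
  missing <- setdiff(required, names(m))
  if (length(missing) > 0L) {
    rlang::abort(paste0("Manifest missing column(s): ", paste(missing, collapse = ", ")),
                 class = "dyadsmile_format_error")
  }
  if (nrow(m) != 2L) {
    rlang::abort("A dyad manifest must describe exactly two participants.",
                 class = "dyadsmile_format_error")
  }
  if (!all(m$group %in% c("IP", "MAT", "SCZ"))) {
    rlang::abort("Manifest group labels must be IP, MAT, or SCZ.",
                 class = "dyadsmile_format_error")
  }
  if (!("edits_path" %in% names(m))) m$edits_path <- NA_character_
  base <- dirname(path)
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^(/|[A-Za-z]:)", p),
                                p, file.path(base, p))
  m$baseline_path <- resolve(m$baseline_path)
  m$interaction_path <- resolve(m$interaction_path)
  m$edits_path <- resolve(m$edits_path)
  for (p in c(m$baseline_path, m$interaction_path)) {
    if (!file.exists(p)) {
      rlang::abort(sprintf("Manifest refers to a missing file: %s", p),
                   class = "dyadsmile_missing_file_error")
    }
  }
  tibble::as_tibble(m)
}
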