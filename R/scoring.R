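#' Per-AU baseline profile
#'
#' Computes, for one participant, the arithmetic mean of each action unit
#' over the neutral baseline clip (nominally ~10 s). These means serve as
#' the "zero point" for within-subject standardization of the interaction
#' clip: deviations from them index relative activation or deactivation of
#' the facial muscles.
#'
#' @param baseline A cleaned `au_frames` tibble for the baseline clip.
#' @return A one-row tibble: `participant_id`, `mean_au04`, `mean_au06`,
#'   `mean_au12`, `n_frames`, `duration_s`.
#' @export
compute_baseline_profile <- function(baseline) {
  if (nrow(baseline) == 0L) {
    rlang::abort("Baseline clip has zero frames.", class = "dyadsmile_empty_input_error")
  }
  fs <- sampling_rate(baseline)
  duration_s <- nrow(baseline) / fs
  if (duration_s < 1) {
    rlang::warn(sprintf(
      "Baseline clip is only %.2f s long; baseline means may be unstable.", duration_s))
  }
  tibble::tibble(
    participant_id = baseline$participant_id[1],
    mean_au04 = mean(baseline$au04),
    mean_au06 = mean(baseline$au06),
    mean_au12 = mean(baseline$au12),
    n_frames = nrow(baseline),
    duration_s = duration_s
  )
}

#' Within-subject z-standardization of an AU series
#'
#' Standardizes an interaction-clip AU intensity series against the
#' participant's own neutral baseline: the numerator subtracts the
#' *baseline-clip* mean, while the denominator is the standard deviation of
#' the *interaction* series itself. Values near zero therefore mean "no
#' change from the participant's neutral face", and positive/negative values
#' mean relative activation/deactivation, on a scale set by how variable the
#' participant's face was during the interaction.
#'
#' @param x Numeric AU intensity series from the interaction clip.
#' @param baseline_mean Mean of the same AU over the baseline clip.
#' @param sd_method `"sample"` (n-1 denominator, default) or `"population"`.
#' @param epsilon Optional fallback: when the interaction series is constant
#'   (SD 0) the SD is replaced by `epsilon` instead of erroring.
#' @param label AU name used in error messages.
#' @return Numeric z-series, same length as `x`.
#' @export
zstandardize_au <- function(x, baseline_mean,
                            sd_method = c("sample", "population"),
                            epsilon = NULL, label = "AU") {
  sd_method <- match.arg(sd_method)
  if (length(x) == 0L) {
    rlang::abort("Interaction series is empty.", class = "dyadsmile_empty_input_error")
  }
  s <- series_sd(x, sd_method)
  if (!is.finite(s) || s == 0) {
    if (is.null(epsilon)) {
      rlang::abort(
        sprintf("Degenerate %s signal: interaction series has zero variance (constant face).", label),
        class = "dyadsmile_degenerate_signal_error"
      )
    }
    s <- epsilon
  }
  (x - baseline_mean) / s
}

series_sd <- function(x, sd_method = c("sample", "population")) {
  sd_method <- match.arg(sd_method)
  n <- length(x)
  if (sd_method == "population") {
    sqrt(sum((x - mean(x))^2) / n)
  } else {
    stats::sd(x)
  }
}

#' Composite positive-expression score
#'
#' Combines the three standardized AU series into one per-frame score of
#' positive facial expression: `((z_au12 + z_au06) / 2) - z_au04`. High
#' values index smiling with eye involvement (lip corner puller + cheek
#' raiser) and reduced frowning (brow furrow), capturing the valence of the
#' expression rather than any single muscle.
#'
#' @param z_au04,z_au06,z_au12 Standardized AU series of equal length.
#' @return Numeric score series.
#' @export
positivity_score <- function(z_au04, z_au06, z_au12) {
  n <- length(z_au04)
  if (length(z_au06) != n || length(z_au12) != n) {
    rlang::abort("AU series must have equal length.", class = "dyadsmile_length_error")
  }
  (z_au12 + z_au06) / 2 - z_au04
}

#' Zero-phase Butterworth low-pass filter
#'
#' Smooths a score series with a second-order Butterworth low-pass filter
#' applied forward and backward (zero phase), so smile onsets and offsets
#' are not delayed — a phase lag would bias downstream temporal matching.
#' Constant signals pass through unchanged (unit DC gain).
#'
#' The cutoff can be given either as a fraction of the Nyquist frequency
#' (default: `cutoff = 0.05` at `fs = 30` means 0.05 x 15 Hz = 0.75 Hz) or
#' literally in Hz via `cutoff_units = "hz"`.
#'
#' @param x Numeric series.
#' @param fs Sampling rate, Hz.
#' @param order Filter order (default 2).
#' @param cutoff Cutoff frequency, in the units of `cutoff_units`.
#' @param cutoff_units `"nyquist_fraction"` (default) or `"hz"`.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, fs = 30, order = 2, cutoff = 0.05,
                           cutoff_units = c("nyquist_fraction", "hz")) {
  cutoff_units <- match.arg(cutoff_units)
  stopifnot(fs > 0, order >= 1, cutoff > 0)
  w <- if (cutoff_units == "hz") cutoff / (fs / 2) else cutoff
  if (w >= 1) {
    rlang::abort(sprintf("Cutoff (%.3g of Nyquist) must be below the Nyquist frequency.", w),
                 class = "dyadsmile_filter_error")
  }
  if (length(x) < 3 * (order + 1)) {
    rlang::warn("Series too short to filter; returning it unchanged.")
    return(x)
  }
  bf <- signal::butter(order, w, type = "low")
  filtfilt_zp(bf$b, bf$a, x)
}

# Zero-phase forward-backward IIR application with odd-reflection padding and
# steady-state initial conditions, so edges are transient-free (a constant
# series maps to itself exactly up to floating point).
filtfilt_zp <- function(b, a, x) {
  n <- length(x)
  nfilt <- max(length(a), length(b))
  b <- c(b, rep(0, nfilt - length(b)))
  a <- c(a, rep(0, nfilt - length(a)))
  pad <- min(n - 1L, 3L * nfilt)

  # odd reflection about the end samples
  pre <- 2 * x[1] - x[seq(pad + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(pre, x, post)

  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, xp, zi * xp[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[seq(pad + 1, pad + n)]
}

# Steady-state state vector of the direct-form-II-transposed filter for a
# unit-step input (the classic lfilter_zi construction).
lfilter_zi <- function(b, a) {
  nfilt <- max(length(a), length(b))
  if (nfilt == 1L) return(numeric(0))
  b <- c(b, rep(0, nfilt - length(b))) / a[1]
  a <- c(a, rep(0, nfilt - length(a))) / a[1]
  m <- nfilt - 1L
  A <- rbind(-a[2:nfilt], cbind(diag(1, m - 1L, m - 1L), rep(0, m - 1L)))
  B <- b[2:nfilt] - a[2:nfilt] * b[1]
  solve(diag(m) - t(A), B)
}

# Direct-form-II-transposed IIR filter with initial state zi.
iir_filter <- function(b, a, x, zi) {
  n <- length(x)
  m <- length(zi)
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (m > 1L) {
      for (k in seq_len(m - 1L)) {
        z[k] <- b[k + 1L] * xi + z[k + 1L] - a[k + 1L] * yi
      }
    }
    z[m] <- b[m + 1L] * xi - a[m + 1L] * yi
    y[i] <- yi
  }
  y
}

#' Baseline-corrected, filtered positive-expression signal
#'
#' Runs the full scoring pipeline for one participant: z-standardize each AU
#' of the interaction clip against the baseline-clip means, combine into the
#' composite positive-expression score, then smooth with the zero-phase
#' low-pass filter. The filter is applied once, to the composite.
#'
#' @param interaction A cleaned `au_frames` tibble for the interaction clip.
#' @param baseline Either a cleaned `au_frames` tibble for the baseline clip
#'   or an existing profile from [compute_baseline_profile()].
#' @param sd_method SD convention for standardization, see [zstandardize_au()].
#' @param order,cutoff,cutoff_units Filter parameters, see [lowpass_filter()].
#' @param epsilon Optional degenerate-signal fallback, see [zstandardize_au()].
#' @return A tibble of class `expression_signal`: `participant_id`, `frame`,
#'   `time_s`, `raw_score`, `score`; attribute `fs`.
#' @export
score_expression <- function(interaction, baseline,
                             sd_method = c("sample", "population"),
                             order = 2, cutoff = 0.05,
                             cutoff_units = c("nyquist_fraction", "hz"),
                             epsilon = NULL) {
  sd_method <- match.arg(sd_method)
  cutoff_units <- match.arg(cutoff_units)
  fs <- sampling_rate(interaction)
  profile <- if (is.data.frame(baseline) && "mean_au12" %in% names(baseline)) {
    baseline
  } else {
    compute_baseline_profile(baseline)
  }
  z04 <- zstandardize_au(interaction$au04, profile$mean_au04, sd_method, epsilon, "AU04")
  z06 <- zstandardize_au(interaction$au06, profile$mean_au06, sd_method, epsilon, "AU06")
  z12 <- zstandardize_au(interaction$au12, profile$mean_au12, sd_method, epsilon, "AU12")
  raw <- positivity_score(z04, z06, z12)
  sc <- lowpass_filter(raw, fs = fs, order = order, cutoff = cutoff,
                       cutoff_units = cutoff_units)
  out <- tibble::tibble(
    participant_id = interaction$participant_id[1],
    frame = interaction$frame,
    time_s = (interaction$frame - 1) / fs,
    raw_score = raw,
    score = sc
  )
  attr(out, "fs") <- fs
  class(out) <- c("expression_signal", class(out))
  out
}

#' Export an expression signal as a two-column table
#'
#' Writes `(time_s, score)` rows for plotting or audit outside R.
#'
#' @param sig An `expression_signal` tibble.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_signal <- function(sig, path) {
  readr::write_tsv(sig[, c("time_s", "score")], path, progress = FALSE)
  invisible(path)
}
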