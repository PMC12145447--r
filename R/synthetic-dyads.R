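#' Simulator configuration for synthetic dyads
#'
#' Parameters of the generative model behind [simulate_dyad()] and
#' [simulate_study()]. Each participant produces spontaneous smiles from a
#' Poisson process; every spontaneous smile of one participant additionally
#' triggers a partner smile with probability `mimic_prob` after a latency
#' drawn uniformly from `mimic_latency_range_s` (a one-step
#' trigger process: triggered smiles do not themselves trigger). Each smile
#' raises AU06/AU12 by a smooth plateau bump with raised-cosine
#' onset/offset ramps and suppresses AU04; AR(1) noise is added to every AU
#' channel. A neutral baseline clip (resting levels + noise only) is
#' generated per participant.
#'
#' @param fs Sampling rate, Hz.
#' @param interaction_s Interaction clip length, seconds.
#' @param baseline_s Baseline clip length, seconds.
#' @param smile_rate_per_min Spontaneous smile rate, events/minute.
#' @param smile_duration_median_s,smile_duration_sigma Lognormal smile
#'   duration: median in seconds and log-scale sigma.
#' @param ramp_s Raised-cosine onset/offset ramp length, seconds.
#' @param mimic_prob Probability a partner smile triggers a mimic event.
#' @param mimic_latency_range_s Uniform latency bounds, seconds (within
#'   `[0, 2]`).
#' @param bump_amp_au06,bump_amp_au12 Smile bump amplitudes (tracker 0-5
#'   intensity units).
#' @param au04_suppression Depth of brow-furrow suppression during a smile.
#' @param au04_rest,au06_rest,au12_rest Resting AU levels.
#' @param ar_coef AR(1) coefficient of the intensity noise.
#' @param noise_sd Innovation SD of the AR(1) noise.
#' @param group_effects Named list of per-group multipliers
#'   `c(rate =, duration =, mimic =)` for labels IP, MAT, SCZ.
#' @return A named list of class `dyad_sim_config`.
#' @export
dyad_sim_config <- function(fs = 30, interaction_s = 360, baseline_s = 10,
                            smile_rate_per_min = 3,
                            smile_duration_median_s = 1.5,
                            smile_duration_sigma = 0.35,
                            ramp_s = 0.2,
                            mimic_prob = 0.5,
                            mimic_latency_range_s = c(0.3, 1.5),
                            bump_amp_au06 = 1.8, bump_amp_au12 = 2.2,
                            au04_suppression = 0.4,
                            au04_rest = 0.5, au06_rest = 0.3, au12_rest = 0.4,
                            ar_coef = 0.9, noise_sd = 0.05,
                            group_effects = list(
                              IP = c(rate = 1, duration = 1, mimic = 1),
                              MAT = c(rate = 1, duration = 1, mimic = 1),
                              SCZ = c(rate = 1, duration = 1, mimic = 1)
                            )) {
  stopifnot(mimic_prob >= 0, mimic_prob <= 1,
            smile_duration_median_s > 0,
            mimic_latency_range_s[1] >= 0, mimic_latency_range_s[2] <= 2,
            abs(fs * interaction_s - round(fs * interaction_s)) < 1e-9)
  cfg <- as.list(environment())
  class(cfg) <- "dyad_sim_config"
  cfg
}

#' Group-effect multipliers matched to a detectable deficit
#'
#' A reduced-smiling, reduced-mimicry profile for the SCZ label (rate and
#' mimic probability scaled to 0.6) against unit multipliers elsewhere —
#' an effect in the large range reported for blunted positive expression,
#' used for power calibration of the group-level model.
#'
#' @return A `group_effects` list for [dyad_sim_config()].
#' @export
power_matched_effects <- function() {
  list(IP = c(rate = 1, duration = 1, mimic = 1),
       MAT = c(rate = 1, duration = 1, mimic = 1),
       SCZ = c(rate = 0.6, duration = 1, mimic = 0.6))
}

group_multipliers <- function(config, group) {
  ge <- config$group_effects[[group]]
  if (is.null(ge)) ge <- c(rate = 1, duration = 1, mimic = 1)
  ge
}

# Spontaneous events for one participant: Poisson-count onsets uniform over
# the clip, lognormal durations. Plain lists on the hot path: the event
# layer runs tens of thousands of times inside Monte-Carlo calibrations.
draw_spontaneous <- function(config, group) {
  mult <- group_multipliers(config, group)
  rate <- config$smile_rate_per_min * mult[["rate"]] / 60
  n <- stats::rpois(1, rate * config$interaction_s)
  list(
    onset_s = sort(stats::runif(n, 0, config$interaction_s)),
    duration_s = stats::rlnorm(n, meanlog = log(config$smile_duration_median_s *
                                                  mult[["duration"]]),
                               sdlog = config$smile_duration_sigma)
  )
}

# Mimic responses of `group` to the partner's spontaneous onsets.
draw_mimics <- function(trigger_onsets, trigger_ids, config, group) {
  mult <- group_multipliers(config, group)
  p <- min(1, config$mimic_prob * mult[["mimic"]])
  fired <- stats::runif(length(trigger_onsets)) < p
  k <- sum(fired)
  lat <- stats::runif(k, config$mimic_latency_range_s[1],
                      config$mimic_latency_range_s[2])
  list(
    onset_s = trigger_onsets[fired] + lat,
    duration_s = stats::rlnorm(k, meanlog = log(config$smile_duration_median_s *
                                                  mult[["duration"]]),
                               sdlog = config$smile_duration_sigma),
    trigger_id = trigger_ids[fired]
  )
}

# Combine, sort, drop events that would overlap an earlier one or run past
# the clip; convert to a frame-aligned event table.
realize_events <- function(spont, spont_ids, mimics, config, participant_id) {
  n_sp <- length(spont$onset_s); n_mi <- length(mimics$onset_s)
  onset_s <- c(spont$onset_s, mimics$onset_s)
  duration_s <- c(spont$duration_s, mimics$duration_s)
  is_mimic <- c(rep(FALSE, n_sp), rep(TRUE, n_mi))
  trigger_id <- c(rep(NA_character_, n_sp), mimics$trigger_id)
  event_id <- c(spont_ids, paste0(participant_id, "_m", seq_len(n_mi)))

  o <- order(onset_s)
  onset_s <- onset_s[o]; duration_s <- duration_s[o]
  is_mimic <- is_mimic[o]; trigger_id <- trigger_id[o]; event_id <- event_id[o]

  min_dur <- max(2 / config$fs, 2 * config$ramp_s)
  ok <- onset_s >= 0 & onset_s <= config$interaction_s - min_dur
  onset_s <- onset_s[ok]; duration_s <- duration_s[ok]
  is_mimic <- is_mimic[ok]; trigger_id <- trigger_id[ok]; event_id <- event_id[ok]
  duration_s <- pmin(duration_s, config$interaction_s - onset_s - 1 / config$fs)

  n <- length(onset_s)
  keep <- logical(n)
  last_end <- -Inf
  for (i in seq_len(n)) {
    if (onset_s[i] >= last_end) {
      keep[i] <- TRUE
      last_end <- onset_s[i] + duration_s[i]
    }
  }
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    rlang::warn(sprintf(
      "simulate_dyad: thinned %d overlapping smile event(s) for %s (rate high for the configured durations).",
      n_dropped, participant_id))
  }
  onset_s <- onset_s[keep]; duration_s <- duration_s[keep]
  is_mimic <- is_mimic[keep]; trigger_id <- trigger_id[keep]; event_id <- event_id[keep]
  n <- length(onset_s)

  n_total <- as.integer(config$fs * config$interaction_s)
  start_frame <- as.integer(pmin(round(onset_s * config$fs), n_total - 1) + 1L)
  end_frame <- as.integer(pmin(start_frame + pmax(2L, round(duration_s * config$fs)) - 1L,
                               n_total))
  tibble::new_tibble(list(
    participant_id = rep(participant_id, n),
    event_id = event_id,
    onset_s = onset_s, duration_s = duration_s,
    start_frame = start_frame, end_frame = end_frame,
    is_mimic = is_mimic, trigger_id = trigger_id
  ), nrow = n)
}

# Plateau bump with raised-cosine onset/offset ramps, evaluated at frame
# centers so every frame of the event carries positive activation.
tukey_bump <- function(n_frames, ramp_frames) {
  u <- (seq_len(n_frames) - 0.5) / n_frames
  a <- min(0.5, ramp_frames / n_frames)
  w <- rep(1, n_frames)
  lo <- u < a
  hi <- u > 1 - a
  w[lo] <- 0.5 * (1 - cos(pi * u[lo] / a))
  w[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / a))
  w
}

ar1_noise <- function(n, coef, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd)
  as.numeric(stats::filter(innov, coef, method = "recursive"))
}

build_au_frames <- function(events, config, participant_id, clip_kind) {
  n <- as.integer(config$fs * if (clip_kind == "baseline") config$baseline_s else config$interaction_s)
  au04 <- rep(config$au04_rest, n)
  au06 <- rep(config$au06_rest, n)
  au12 <- rep(config$au12_rest, n)
  if (clip_kind == "interaction" && nrow(events) > 0L) {
    ramp_frames <- config$ramp_s * config$fs
    for (i in seq_len(nrow(events))) {
      idx <- events$start_frame[i]:events$end_frame[i]
      w <- tukey_bump(length(idx), ramp_frames)
      au06[idx] <- au06[idx] + config$bump_amp_au06 * w
      au12[idx] <- au12[idx] + config$bump_amp_au12 * w
      au04[idx] <- au04[idx] - config$au04_suppression * w
    }
  }
  au04 <- pmax(au04 + ar1_noise(n, config$ar_coef, config$noise_sd), 0)
  au06 <- pmax(au06 + ar1_noise(n, config$ar_coef, config$noise_sd), 0)
  au12 <- pmax(au12 + ar1_noise(n, config$ar_coef, config$noise_sd), 0)
  new_au_frames(tibble::tibble(
    participant_id = participant_id, clip_kind = clip_kind,
    frame = seq_len(n), timestamp = (seq_len(n) - 1) / config$fs,
    confidence = 0.98, success = TRUE,
    au04 = au04, au06 = au06, au12 = au12
  ), fs = config$fs)
}

#' Simulate one dyad of AU recordings with known ground truth
#'
#' Generates, for two participants, a neutral baseline clip and an
#' interaction clip containing spontaneous smiles plus partner-contingent
#' mimic smiles, at the configured sampling rate, and returns the true
#' event structure alongside the AU tables. Deterministic under a fixed
#' seed.
#'
#' @param config A [dyad_sim_config()].
#' @param seed Integer seed (optional; the caller may manage RNG state).
#' @param groups Length-2 character: group labels of participants a and b.
#' @param dyad_id Identifier used in outputs.
#' @param participant_ids Length-2 character ids; default derived from
#'   `dyad_id` and groups.
#' @return A list: `clips` — named list of four `au_frames` tibbles
#'   (`a_baseline`, `a_interaction`, `b_baseline`, `b_interaction`);
#'   `truth` — tibble of realized smile events (`participant_id`,
#'   `event_id`, `onset_s`, `duration_s`, `start_frame`, `end_frame`,
#'   `is_mimic`, `trigger_id`); `groups`, `participant_ids`, `config`.
#' @export
simulate_dyad <- function(config = dyad_sim_config(), seed = NULL,
                          groups = c("IP", "MAT"), dyad_id = "dyad1",
                          participant_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- participant_ids %||% paste0(dyad_id, "_", groups, c("_a", "_b"))

  truth <- simulate_dyad_events(config, groups, ids)
  clips <- list(
    a_baseline = build_au_frames(NULL, config, ids[1], "baseline"),
    a_interaction = build_au_frames(truth[truth$participant_id == ids[1], ],
                                    config, ids[1], "interaction"),
    b_baseline = build_au_frames(NULL, config, ids[2], "baseline"),
    b_interaction = build_au_frames(truth[truth$participant_id == ids[2], ],
                                    config, ids[2], "interaction")
  )
  list(clips = clips, truth = truth, groups = groups,
       participant_ids = ids, config = config)
}

# Event layer only (no AU traces): used by both simulate_dyad and the fast
# study-level Monte Carlo.
simulate_dyad_events <- function(config, groups, ids) {
  spont_a <- draw_spontaneous(config, groups[1])
  spont_b <- draw_spontaneous(config, groups[2])
  sp_ids_a <- paste0(ids[1], "_s", seq_along(spont_a$onset_s))
  sp_ids_b <- paste0(ids[2], "_s", seq_along(spont_b$onset_s))
  mim_b <- draw_mimics(spont_a$onset_s, sp_ids_a, config, groups[2])
  mim_a <- draw_mimics(spont_b$onset_s, sp_ids_b, config, groups[1])
  dplyr::bind_rows(
    realize_events(spont_a, sp_ids_a, mim_a, config, ids[1]),
    realize_events(spont_b, sp_ids_b, mim_b, config, ids[2])
  )
}

#' Write a simulated dyad to tracker-dialect files
#'
#' Serializes the four clips as tracker CSVs, the ground truth as a TSV,
#' and a manifest CSV linking them, so the file-based pipeline entry points
#' can be exercised end to end.
#'
#' @param sim Result of [simulate_dyad()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest CSV, invisibly.
#' @export
write_dyad_clips <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sim$participant_ids
  paths <- list(
    a_baseline = file.path(dir, paste0(ids[1], "_baseline.csv")),
    a_interaction = file.path(dir, paste0(ids[1], "_interaction.csv")),
    b_baseline = file.path(dir, paste0(ids[2], "_baseline.csv")),
    b_interaction = file.path(dir, paste0(ids[2], "_interaction.csv"))
  )
  for (k in names(paths)) write_au_table(sim$clips[[k]], paths[[k]])
  readr::write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"), progress = FALSE)
  manifest <- tibble::tibble(
    dyad_id = sub("_.*$", "", ids[1]),
    participant_id = ids,
    group = sim$groups,
    baseline_path = basename(c(paths$a_baseline, paths$b_baseline)),
    interaction_path = basename(c(paths$a_interaction, paths$b_interaction)),
    edits_path = ""
  )
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath, progress = FALSE)
  invisible(mpath)
}

#' Simulate a full study of dyads
#'
#' Emulates the repeated-measures study design: `n_dyads_per_group`
#' interacting partners (IP), each recorded once with a matched control
#' (MAT) and once with a participant carrying the SCZ label, with the
#' configured group-effect multipliers applied. IP rows are relabeled
#' `IPS` for their SCZ-partner interaction when `relabel_ips` is TRUE.
#'
#' Two fidelity levels are available. `mode = "signal"` synthesizes AU
#' traces for every clip and runs the full scoring/detection pipeline.
#' `mode = "events"` (default) skips trace synthesis and treats the true
#' (merged) event intervals as the smile tracks, then runs the real
#' shared-smile matching and scoring code — orders of magnitude faster,
#' appropriate for Monte-Carlo calibration of the group-level statistics.
#'
#' @param n_dyads_per_group Number of IP-MAT and of IP-SCZ dyads.
#' @param config A [dyad_sim_config()].
#' @param seed Integer seed.
#' @param mode `"events"` or `"signal"`.
#' @param relabel_ips Relabel IP as IPS in SCZ-partner dyads.
#' @param analysis_config [dyad_config()] used by the pipeline stages.
#' @return A list: `outcomes` — participant-level tibble (`dyad_id`,
#'   `participant_id`, `group`, `n_smiles`, `n_shared`, `smile_ratio`,
#'   `mimicry_score`); `truth` — row-bound ground-truth events with a
#'   `dyad_id` column.
#' @export
simulate_study <- function(n_dyads_per_group = 20,
                           config = dyad_sim_config(), seed = NULL,
                           mode = c("events", "signal"),
                           relabel_ips = TRUE,
                           analysis_config = dyad_config(fs = config$fs)) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  n_frames <- as.integer(config$fs * config$interaction_s)

  out <- vector("list", 2L * n_dyads_per_group)
  truths <- vector("list", 2L * n_dyads_per_group)
  k <- 0L
  for (i in seq_len(n_dyads_per_group)) {
    ip_id <- sprintf("IP%02d", i)
    for (partner_group in c("MAT", "SCZ")) {
      k <- k + 1L
      dyad_id <- sprintf("d_%s_%02d", partner_group, i)
      partner_id <- sprintf("%s%02d", partner_group, i)
      ids <- c(ip_id, partner_id)
      groups <- c("IP", partner_group)

      if (mode == "signal") {
        sim <- simulate_dyad(config, seed = NULL, groups = groups,
                             dyad_id = dyad_id, participant_ids = ids)
        tracks <- lapply(1:2, function(j) {
          inter <- sim$clips[[c("a_interaction", "b_interaction")[j]]]
          base <- sim$clips[[c("a_baseline", "b_baseline")[j]]]
          sig <- score_expression(inter, base,
                                  sd_method = analysis_config$sd_method,
                                  order = analysis_config$filter_order,
                                  cutoff = analysis_config$filter_cutoff,
                                  cutoff_units = analysis_config$filter_cutoff_units)
          extract_smile_track(sig, fs = config$fs,
                              max_gap_s = analysis_config$merge_gap_s,
                              sd_method = analysis_config$sd_method)
        })
        truth <- sim$truth
      } else {
        truth <- simulate_dyad_events(config, groups, ids)
        tracks <- lapply(ids, function(id) {
          tr <- truth[truth$participant_id == id,
                      c("participant_id", "start_frame", "end_frame")]
          tr$source <- "auto"
          merge_close_smiles(tr, fs = config$fs,
                             max_gap_s = analysis_config$merge_gap_s)
        })
      }
      flagged <- flag_shared_smiles(tracks[[1]], tracks[[2]], fs = config$fs,
                                    window_s = analysis_config$shared_window_s,
                                    predicate = analysis_config$shared_predicate)
      res <- summarize_dyad(flagged, n_frames, dyad_id = dyad_id,
                            participant_ids = ids)
      res$group <- groups
      if (relabel_ips && partner_group == "SCZ") {
        res$group[res$participant_id == ip_id] <- "IPS"
      }
      out[[k]] <- res
      truth$dyad_id <- dyad_id
      truths[[k]] <- truth
    }
  }
  list(outcomes = dplyr::bind_rows(out), truth = dplyr::bind_rows(truths))
}

#' One-directional mimicry-recovery configuration
#'
#' A simulator configuration in which the first participant (storyteller,
#' IP label) smiles spontaneously but never mimics, and the second (pure
#' responder, MAT label) produces no spontaneous smiles and mimics each
#' storyteller smile with probability `mimic_prob`. In this design the
#' responder's mimicry score is a direct estimator of `mimic_prob`: every
#' responder smile is a mimic, and the storyteller's smiles are shared
#' exactly when they were mimicked (up to chance proximity and detection
#' error). With symmetric mimicry the score would instead estimate an
#' inflated mixture, because mimic smiles also enter the totals.
#'
#' @param mimic_prob Planted mimic probability.
#' @param ... Further arguments passed to [dyad_sim_config()].
#' @return A `dyad_sim_config`.
#' @export
mimic_recovery_config <- function(mimic_prob = 0.8, ...) {
  dyad_sim_config(
    mimic_prob = mimic_prob,
    group_effects = list(IP = c(rate = 1, duration = 1, mimic = 0),
                         MAT = c(rate = 0, duration = 1, mimic = 1),
                         SCZ = c(rate = 1, duration = 1, mimic = 1)),
    ...
  )
}

#' Estimate mimicry-probability recovery through the full pipeline
#'
#' Simulates `n_dyads` storyteller/responder dyads
#' ([mimic_recovery_config()]), runs each through signal scoring, smile
#' detection, and shared-smile matching, and returns the responder's
#' mimicry score per dyad. The mean of these scores estimates the planted
#' `mimic_prob`.
#'
#' @param n_dyads Number of simulated dyads.
#' @param config Simulator configuration (a one-directional design).
#' @param seed Integer seed.
#' @return Tibble: `dyad`, `responder_score`.
#' @export
recover_mimicry <- function(n_dyads = 50, config = mimic_recovery_config(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scores <- numeric(n_dyads)
  for (s in seq_len(n_dyads)) {
    sim <- simulate_dyad(config, seed = NULL)
    tracks <- lapply(1:2, function(j) {
      inter <- sim$clips[[c("a_interaction", "b_interaction")[j]]]
      base <- sim$clips[[c("a_baseline", "b_baseline")[j]]]
      extract_smile_track(score_expression(inter, base), fs = config$fs)
    })
    flagged <- flag_shared_smiles(tracks[[1]], tracks[[2]], fs = config$fs)
    res <- summarize_dyad(flagged, as.integer(config$fs * config$interaction_s),
                          participant_ids = sim$participant_ids)
    scores[s] <- res$mimicry_score[2]
  }
  tibble::tibble(dyad = seq_len(n_dyads), responder_score = scores)
}
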