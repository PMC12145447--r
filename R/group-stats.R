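#' Mixed-model group comparison with Tukey-adjusted contrasts
#'
#' Fits a linear mixed model `outcome ~ group + (1 | id)` on the
#' participant-level outcome table — the random intercept absorbs the
#' repeated-measures structure (an interacting partner contributes one row
#' per interaction) — and extracts all pairwise group contrasts with
#' Tukey-family multiplicity adjustment. When the random-intercept variance
#' is estimated as zero (singular fit) or the mixed fit fails, the model
#' falls back to ordinary least squares with a logged warning; contrasts
#' are computed the same way.
#'
#' Standardized effect sizes use a simple reproducible convention: the
#' contrast estimate divided by the pooled within-group SD of the raw
#' outcome.
#'
#' @param outcomes Participant-level tibble (e.g. from [simulate_study()]
#'   or row-bound [analyze_dyad()] results, joined with covariates).
#' @param outcome_name Name of the outcome column (e.g. `"n_smiles"`,
#'   `"smile_ratio"`, `"mimicry_score"`).
#' @param group Name of the group column.
#' @param id Name of the grouping-unit column for the random intercept
#'   (participant id for individual-level outcomes; a dyad id is equally
#'   accepted for dyad-level analyses).
#' @param df_method Degrees-of-freedom method passed to emmeans for mixed
#'   fits (`"satterthwaite"` default).
#' @return An object of class `mimicry_group_fit`; see [tidy()] and
#'   [glance()] methods, and [autoplot.mimicry_group_fit()].
#' @export
fit_group_model <- function(outcomes, outcome_name, group = "group",
                            id = "participant_id",
                            df_method = "satterthwaite") {
  dat <- as.data.frame(outcomes[, c(outcome_name, group, id)])
  names(dat) <- c(".y", ".group", ".id")
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  dat$.group <- factor(dat$.group)
  counts <- table(dat$.group)
  if (length(counts) < 2L || any(counts < 2L)) {
    rlang::abort("Need at least two groups with at least two observations each.",
                 class = "dyadsmile_stats_error")
  }

  singular <- FALSE
  model <- tryCatch({
    m <- lmerTest::lmer(.y ~ .group + (1 | .id), data = dat,
                        control = lme4::lmerControl(check.conv.singular = "ignore"))
    if (lme4::isSingular(m, tol = 1e-5)) singular <- TRUE
    m
  }, error = function(e) NULL)
  method <- "lmm"
  if (is.null(model) || singular) {
    if (singular) {
      rlang::inform("fit_group_model: random-intercept variance is ~0 (singular fit); falling back to OLS.")
    } else {
      rlang::warn("fit_group_model: mixed fit failed; falling back to OLS.")
    }
    model <- stats::lm(.y ~ .group, data = dat)
    method <- "ols"
  }

  emm <- if (method == "lmm") {
    emmeans::emmeans(model, ".group", lmer.df = df_method)
  } else {
    emmeans::emmeans(model, ".group")
  }
  ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"),
                 infer = c(TRUE, TRUE))

  pooled_sd <- sqrt(sum((counts - 1) * tapply(dat$.y, dat$.group, stats::sd)^2) /
                      sum(counts - 1))
  contrasts <- tibble::tibble(
    contrast = as.character(ctr$contrast),
    estimate = ctr$estimate,
    se = ctr$SE,
    df = ctr$df,
    conf_low = ctr$lower.CL,
    conf_high = ctr$upper.CL,
    p_adjusted = ctr$p.value,
    cohens_d = ctr$estimate / pooled_sd
  )
  # degenerate data (zero residual variance, zero estimate): no evidence of
  # any difference rather than an indeterminate 0/0 statistic
  degenerate <- abs(contrasts$estimate) < 1e-12 & contrasts$se < 1e-12
  contrasts$p_adjusted[degenerate] <- 1
  contrasts$cohens_d[degenerate] <- 0

  structure(
    list(model = model, contrasts = contrasts, outcome = outcome_name,
         method = method, singular = singular, pooled_sd = pooled_sd,
         group_means = tibble::tibble(
           group = levels(dat$.group),
           n = as.integer(counts),
           mean = as.numeric(tapply(dat$.y, dat$.group, mean)),
           sd = as.numeric(tapply(dat$.y, dat$.group, stats::sd))
         ),
         nobs = nrow(dat)),
    class = "mimicry_group_fit"
  )
}

#' @export
#' @method print mimicry_group_fit
print.mimicry_group_fit <- function(x, ...) {
  cat(sprintf("Group comparison of '%s' (%s%s)\n", x$outcome,
              if (x$method == "lmm") "linear mixed model" else "OLS fallback",
              if (x$singular) ", singular random intercept" else ""))
  cat("Group means:\n")
  print(as.data.frame(x$group_means), row.names = FALSE, digits = 3)
  cat("Tukey-adjusted pairwise contrasts:\n")
  print(as.data.frame(x$contrasts), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Tidy a group-comparison fit
#'
#' @param x A `mimicry_group_fit`.
#' @param ... Unused.
#' @return One row per pairwise contrast: estimate, SE, df, 95% CI,
#'   Tukey-adjusted p, Cohen's d.
#' @export
tidy.mimicry_group_fit <- function(x, ...) {
  x$contrasts
}

#' Model-level summary of a group-comparison fit
#'
#' @param x A `mimicry_group_fit`.
#' @param ... Unused.
#' @return One-row tibble: outcome, method, singular flag, nobs, number of
#'   groups, pooled within-group SD.
#' @export
glance.mimicry_group_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, method = x$method, singular = x$singular,
    nobs = x$nobs, n_groups = nrow(x$group_means), pooled_sd = x$pooled_sd
  )
}

#' Willingness-to-interact total score
#'
#' Sums the nine willingness items (each rated 1-5) into a total score in
#' the 9-45 range, keeping the per-item values alongside.
#'
#' @param items A data frame or tibble of item responses: nine numeric
#'   columns (any names), one row per rating occasion; id columns may be
#'   included and are passed through.
#' @param item_cols Names of the nine item columns; default: the nine
#'   numeric columns found.
#' @return The input tibble with a `willingness_total` column appended.
#' @export
willingness_scores <- function(items, item_cols = NULL) {
  items <- tibble::as_tibble(items)
  if (is.null(item_cols)) {
    item_cols <- names(items)[vapply(items, is.numeric, logical(1))]
  }
  if (length(item_cols) != 9L) {
    rlang::abort(sprintf("Expected nine item columns, found %d.", length(item_cols)),
                 class = "dyadsmile_validation_error")
  }
  vals <- as.matrix(items[, item_cols])
  if (any(!(vals %in% 1:5))) {
    rlang::abort("Willingness items must be integers in 1..5.",
                 class = "dyadsmile_validation_error")
  }
  items$willingness_total <- as.integer(rowSums(vals))
  items
}

#' Correlations of mimicry with symptom and medication covariates
#'
#' Pearson correlations between a mimicry (or other outcome) column and a
#' set of clinical covariates, with the Bonferroni-adjusted significance
#' threshold alongside the unadjusted one, so both decisions are explicit.
#' With the default five covariates the adjusted threshold is
#' 0.05 / 5 = 0.01.
#'
#' @param outcomes Tibble containing the outcome and covariate columns.
#' @param outcome_name Outcome column name (default `"mimicry_score"`).
#' @param covariates Character vector of covariate column names.
#' @param alpha Familywise significance level (default 0.05).
#' @return A tibble: covariate, n (complete pairs), r, p,
#'   `sig_unadjusted`, `sig_bonferroni`, `alpha_bonferroni`. Zero-variance
#'   or undersized pairs yield `NA` correlations.
#' @export
symptom_correlations <- function(outcomes, outcome_name = "mimicry_score",
                                 covariates = c("cpz_mg", "panss_positive",
                                                "panss_negative",
                                                "panss_general", "panss_total"),
                                 alpha = 0.05) {
  alpha_b <- alpha / length(covariates)
  y <- outcomes[[outcome_name]]
  purrr::map_dfr(covariates, function(cv) {
    x <- outcomes[[cv]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(covariate = cv, n = n, r = NA_real_, p = NA_real_,
                            sig_unadjusted = NA, sig_bonferroni = NA,
                            alpha_bonferroni = alpha_b))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(covariate = cv, n = n, r = unname(ct$estimate),
                   p = ct$p.value,
                   sig_unadjusted = ct$p.value < alpha,
                   sig_bonferroni = ct$p.value < alpha_b,
                   alpha_bonferroni = alpha_b)
  })
}
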