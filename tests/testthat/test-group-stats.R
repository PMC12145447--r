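test_that("identical outcomes give null contrasts with p near 1", {
  out <- tibble::tibble(
    participant_id = paste0("p", 1:20),
    group = rep(c("MAT", "SCZ"), each = 10),
    n_smiles = rep(12, 20)
  )
  fit <- suppressMessages(fit_group_model(out, "n_smiles"))
  ct <- tidy(fit)
  expect_equal(ct$estimate, 0)
  expect_gt(min(ct$p_adjusted), 0.99)
})

test_that("with no repeated measures the contrast equals the group-mean difference", {
  set.seed(51)
  out <- tibble::tibble(
    participant_id = paste0("p", 1:40),
    group = rep(c("MAT", "SCZ"), each = 20),
    n_smiles = c(rnorm(20, 20, 3), rnorm(20, 14, 3))
  )
  fit <- suppressMessages(fit_group_model(out, "n_smiles"))
  ct <- tidy(fit)
  want <- mean(out$n_smiles[out$group == "MAT"]) -
    mean(out$n_smiles[out$group == "SCZ"])
  expect_equal(ct$estimate[ct$contrast == "MAT - SCZ"], want, tolerance = 1e-8)
  # one row per participant leaves no information for a random intercept
  expect_equal(glance(fit)$method, "ols")
  # Cohen's d convention: estimate / pooled within-group SD
  sds <- tapply(out$n_smiles, out$group, sd)
  pooled <- sqrt(mean(sds^2))
  expect_equal(ct$cohens_d, ct$estimate / pooled, tolerance = 1e-8)
})

test_that("relabeling groups permutes contrasts without changing magnitudes", {
  st <- suppressWarnings(simulate_study(10, dyad_sim_config(), seed = 52, mode = "events"))
  f1 <- suppressMessages(fit_group_model(st$outcomes, "n_smiles"))
  relabeled <- st$outcomes
  map <- c(IP = "g1", IPS = "g2", MAT = "g3", SCZ = "g4")
  relabeled$group <- unname(map[relabeled$group])
  f2 <- suppressMessages(fit_group_model(relabeled, "n_smiles"))
  expect_equal(sort(abs(tidy(f1)$estimate)), sort(abs(tidy(f2)$estimate)),
               tolerance = 1e-8)
})

test_that("repeated-measures outcomes keep the random intercept in the model", {
  set.seed(53)
  n <- 24
  subj <- rnorm(n, 0, 4)
  out <- tibble::tibble(
    participant_id = rep(paste0("ip", 1:n), 2),
    group = rep(c("IP", "IPS"), each = n),
    n_smiles = c(subj + rnorm(n, 20, 1), subj + rnorm(n, 18, 1))
  )
  fit <- suppressMessages(fit_group_model(out, "n_smiles"))
  expect_equal(glance(fit)$method, "lmm")
  expect_false(glance(fit)$singular)
})

test_that("willingness totals sum nine 1-5 items into the 9-45 range", {
  floor_items <- tibble::as_tibble(as.list(setNames(rep(1, 9), paste0("w", 1:9))))
  expect_equal(willingness_scores(floor_items)$willingness_total, 9L)
  ceiling_items <- tibble::as_tibble(as.list(setNames(rep(5, 9), paste0("w", 1:9))))
  expect_equal(willingness_scores(ceiling_items)$willingness_total, 45L)

  set.seed(54)
  m <- matrix(sample(1:5, 90, replace = TRUE), nrow = 10)
  df <- tibble::as_tibble(as.data.frame(m))
  expect_equal(willingness_scores(df)$willingness_total, as.integer(rowSums(m)))

  bad <- floor_items; bad$w3 <- 6
  expect_error(willingness_scores(bad), class = "dyadsmile_validation_error")
  expect_error(willingness_scores(floor_items[, 1:8]),
               class = "dyadsmile_validation_error")
})

test_that("symptom correlations report r, p, and both significance decisions", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  out <- tibble::tibble(mimicry_score = x, cpz_mg = x, panss_positive = -x,
                        panss_negative = x + c(0.1, -0.2, 0.3, 0, -0.1, 0.2, -0.3, 0),
                        panss_general = rep(3, 8), panss_total = x^2)
  res <- symptom_correlations(out)
  expect_equal(res$r[res$covariate == "cpz_mg"], 1)
  expect_equal(res$r[res$covariate == "panss_positive"], -1)
  expect_true(is.na(res$r[res$covariate == "panss_general"]))  # zero variance
  expect_equal(unique(res$alpha_bonferroni), 0.01)
  expect_true(all(res$p[res$sig_bonferroni %in% TRUE] < 0.01))
})

test_that("correlation type-I error is near nominal for independent variables", {
  set.seed(55)
  n_rep <- 500
  n_tests <- 0L; hits <- 0L
  for (r in seq_len(n_rep)) {
    out <- tibble::tibble(mimicry_score = rnorm(20), cpz_mg = rnorm(20),
                          panss_positive = rnorm(20), panss_negative = rnorm(20),
                          panss_general = rnorm(20), panss_total = rnorm(20))
    res <- symptom_correlations(out)
    n_tests <- n_tests + nrow(res)
    hits <- hits + sum(res$sig_unadjusted)
  }
  rate <- hits / n_tests
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
})
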