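test_that("shared-smile flags follow the 2 s interval-gap predicate with an inclusive boundary", {
  a <- make_track(c(1, 200), c(30, 260), "a")
  fl <- flag_shared_smiles(a, dplyr::mutate(a, participant_id = "b"), fs = 30)
  expect_true(all(fl$shared))  # identical tracks self-match

  # gap of 64 frames > 60 -> not shared
  fl2 <- flag_shared_smiles(make_track(1, 30, "a"), make_track(95, 120, "b"), fs = 30)
  expect_false(any(fl2$shared))
  # gap of exactly 60 frames = 2 s -> shared (contrast with the strict merge rule)
  fl3 <- flag_shared_smiles(make_track(1, 30, "a"), make_track(91, 120, "b"), fs = 30)
  expect_true(all(fl3$shared))
})

test_that("shared flags equal the all-pairs brute-force oracle", {
  set.seed(41)
  for (rep in 1:200) {
    a <- random_track(50, 10000, "a")
    b <- random_track(50, 10000, "b")
    w <- sample(c(0L, 30L, 60L, 150L), 1)
    fl <- flag_shared_smiles(a, b, fs = 30, window_s = w / 30)
    expect_equal(fl$shared[fl$participant_id == "a"], shared_oracle(a, b, w))
    expect_equal(fl$shared[fl$participant_id == "b"], shared_oracle(b, a, w))
  }
})

test_that("widening the window never removes shared flags, and sharing is symmetric in existence", {
  set.seed(42)
  for (rep in 1:50) {
    a <- random_track(20, 8000, "a")
    b <- random_track(20, 8000, "b")
    n_shared <- vapply(c(0, 1, 2, 4), function(w) {
      fl <- flag_shared_smiles(a, b, fs = 30, window_s = w)
      sum(fl$shared)
    }, numeric(1))
    expect_true(all(diff(n_shared) >= 0))
    fl <- flag_shared_smiles(a, b, fs = 30, window_s = 2)
    any_a <- any(fl$shared[fl$participant_id == "a"])
    any_b <- any(fl$shared[fl$participant_id == "b"])
    expect_equal(any_a, any_b)
  }
})

test_that("onset-latency predicate is available for sensitivity analysis", {
  # intervals overlap but onsets are 5 s apart
  a <- make_track(1, 400, "a")
  b <- make_track(151, 400, "b")
  expect_true(all(flag_shared_smiles(a, b, fs = 30)$shared))
  expect_false(any(flag_shared_smiles(a, b, fs = 30,
                                      predicate = "onset_latency")$shared))
})

test_that("mimicry score is the partner's shared fraction, undefined when the partner never smiles", {
  expect_equal(round(mimicry_score(16, 18), 2), 0.89)
  expect_equal(round(mimicry_score(20, 27), 2), 0.74)
  expect_equal(mimicry_score(12, 12), 1)
  expect_true(is.na(mimicry_score(0, 0)))
})

test_that("summarize_dyad assigns each participant the partner's ratio", {
  tk <- worked_example_tracks()
  fl <- flag_shared_smiles(tk$a, tk$b, fs = 30)
  res <- summarize_dyad(fl, n_frames = 15000, dyad_id = "d1",
                        participant_ids = c("A", "B"))
  expect_equal(res$n_smiles, c(18L, 27L))
  expect_equal(res$n_shared, c(16L, 20L))
  expect_equal(res$mimicry_score, c(20 / 27, 16 / 18))
  expect_true(all(res$n_shared <= res$n_smiles))

  # a partner with no smiles leaves the other's score undefined
  fl0 <- flag_shared_smiles(tk$a, tk$b[0, ], fs = 30)
  res0 <- summarize_dyad(fl0, 15000, participant_ids = c("A", "B"))
  expect_equal(res0$n_smiles, c(18L, 0L))
  expect_true(is.na(res0$mimicry_score[1]))  # A's score: B never smiled
  expect_equal(res0$mimicry_score[2], 0)     # B joined none of A's smiles
})

test_that("analyze_dyad runs file-to-result and is label-symmetric", {
  dir <- withr::local_tempdir()
  sim <- suppressWarnings(simulate_dyad(dyad_sim_config(interaction_s = 120), seed = 9))
  mpath <- write_dyad_clips(sim, dir)
  res <- suppressMessages(analyze_dyad(mpath))
  expect_s3_class(res, "dyad_result")
  expect_equal(res$participant_id, sim$participant_ids)
  expect_true(all(res$n_shared <= res$n_smiles))
  expect_true(all(res$smile_ratio >= 0 & res$smile_ratio <= 1))

  m <- read_dyad_manifest(mpath)
  res_swapped <- suppressMessages(analyze_dyad(m[2:1, ]))
  expect_equal(res_swapped$n_smiles, rev(res$n_smiles))
  expect_equal(res_swapped$mimicry_score, rev(res$mimicry_score))
})

test_that("run configurations round-trip through the key-value echo format", {
  cfg <- dyad_config(min_confidence = 0.6, filter_cutoff_units = "hz",
                     filter_cutoff = 0.75, shared_window_s = 1.5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back[setdiff(names(back), "seed")],
               cfg[setdiff(names(cfg), "seed")])
})
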