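test_that("threshold is mean + 1 SD over the whole recording", {
  expect_equal(detection_threshold(c(0, 0, 0, 0)), 0)
  expect_equal(detection_threshold(c(-1, 1), sd_method = "population"), 1)
  set.seed(31)
  x <- rnorm(500)
  expect_equal(detection_threshold(x), mean(x) + sd(x))
  expect_equal(detection_threshold(x, "population"),
               mean(x) + sqrt(mean((x - mean(x))^2)))
})

test_that("detection reports maximal strictly-supra-threshold runs, 1-based inclusive", {
  tr <- detect_smiles(c(0, 2, 2, 0, 2, 0), 1, "p")
  expect_equal(tr$start_frame, c(2L, 5L))
  expect_equal(tr$end_frame, c(3L, 5L))
  expect_equal(nrow(detect_smiles(c(0.1, 0.2, 0.1), 1)), 0L)
  # strict inequality at the threshold itself
  expect_equal(nrow(detect_smiles(c(1, 1, 1), 1)), 0L)
})

test_that("detection matches a brute-force run scan on random masks", {
  set.seed(32)
  for (rep in 1:200) {
    mask <- runif(sample(5:120, 1)) < 0.4
    tr <- detect_smiles(as.numeric(mask), 0.5)
    oracle <- detect_oracle(mask)
    expect_equal(tr$start_frame, oracle$starts)
    expect_equal(tr$end_frame, oracle$ends)
  }
})

test_that("degenerate thresholds bracket the detection range and raising the threshold is monotone", {
  set.seed(33)
  x <- rnorm(300)
  all_tr <- detect_smiles(x, -Inf)
  expect_equal(nrow(all_tr), 1L)
  expect_equal(c(all_tr$start_frame, all_tr$end_frame), c(1L, 300L))
  expect_equal(nrow(detect_smiles(x, Inf)), 0L)

  total_frames <- function(tr) sum(tr$end_frame - tr$start_frame + 1L)
  thresholds <- sort(runif(10, -2, 2))
  frames <- vapply(thresholds, function(th) total_frames(detect_smiles(x, th)), numeric(1))
  expect_true(all(diff(frames) <= 0))
})

test_that("merging uses a strict 2 s gap rule and chains left to right", {
  m <- merge_close_smiles(make_track(c(1, 80), c(30, 100)), fs = 30, max_gap_s = 2)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start_frame, m$end_frame), c(1L, 100L))
  # gap of exactly 2 s (60 frames) stays split
  m2 <- merge_close_smiles(make_track(c(1, 91), c(30, 100)), fs = 30, max_gap_s = 2)
  expect_equal(nrow(m2), 2L)
  # chaining: three smiles each within 2 s of the next collapse to one
  m3 <- merge_close_smiles(make_track(c(1, 60, 120), c(30, 90, 150)), fs = 30)
  expect_equal(nrow(m3), 1L)
  expect_equal(c(m3$start_frame, m3$end_frame), c(1L, 150L))
})

test_that("merging equals the dilation-union-contraction oracle and is idempotent", {
  set.seed(34)
  for (rep in 1:200) {
    tr <- random_track(20, 3000)
    gap <- sample(c(15L, 60L, 100L), 1)
    got <- merge_close_smiles(tr, fs = 30, max_gap_s = gap / 30)
    want <- merge_oracle(tr, gap)
    expect_equal(got$start_frame, want$start_frame)
    expect_equal(got$end_frame, want$end_frame)
    expect_equal(merge_close_smiles(got, fs = 30, max_gap_s = gap / 30), got)
    if (nrow(got) > 1L) {
      expect_true(all(got$start_frame[-1] - got$end_frame[-nrow(got)] - 1L >= gap))
    }
  }
})

test_that("manual edits remove overlapped intervals first, then insert additions", {
  tr <- make_track(c(100, 400, 700), c(150, 450, 750))
  expect_equal(apply_edits(tr, NULL), tr)
  edits <- tibble::tibble(action = c("remove", "add"),
                          start_frame = c(420L, 900L), end_frame = c(430L, 930L),
                          annotator = "r1")
  out <- apply_edits(tr, edits, n_frames = 1000)
  expect_equal(nrow(out), 3L)
  expect_equal(sum(out$source == "manual"), 1L)
  expect_false(any(out$start_frame == 400))

  overlap <- tibble::tibble(action = "add", start_frame = 120L, end_frame = 160L,
                            annotator = "r1")
  expect_error(apply_edits(tr, overlap, 1000), "overlaps",
               class = "dyadsmile_validation_error")
  out_of_range <- tibble::tibble(action = "add", start_frame = 990L,
                                 end_frame = 1200L, annotator = "r1")
  expect_error(apply_edits(tr, out_of_range, 1000), class = "dyadsmile_validation_error")
})

test_that("edited interval count is auto - removed + added over random edit sets", {
  set.seed(35)
  for (rep in 1:50) {
    tr <- random_track(15, 5000)
    n_rm <- if (nrow(tr) > 0) sample(0:nrow(tr), 1) else 0
    rm_idx <- if (n_rm > 0) sample(nrow(tr), n_rm) else integer(0)
    rms <- tr[rm_idx, c("start_frame", "end_frame")]
    # additions dropped into guaranteed-free space beyond the track
    n_add <- sample(0:3, 1)
    adds <- tibble::tibble(start_frame = 6000L + 100L * seq_len(n_add),
                           end_frame = 6000L + 100L * seq_len(n_add) + 10L)
    edits <- dplyr::bind_rows(
      if (n_rm > 0) tibble::tibble(action = "remove", rms) else NULL,
      if (n_add > 0) tibble::tibble(action = "add", adds) else NULL
    )
    if (is.null(edits) || nrow(edits) == 0) next
    edits$annotator <- "r"
    out <- apply_edits(tr, edits, n_frames = 10000)
    expect_equal(nrow(out), nrow(tr) - n_rm + n_add)
  }
})

test_that("edit files round-trip through read_edit_set", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("action,start_frame,end_frame,annotator",
               "remove,100,150,r1", "add,200,230,r2"), path)
  e <- read_edit_set(path)
  expect_equal(e$action, c("remove", "add"))
  expect_equal(e$start_frame, c(100L, 200L))
  writeLines(c("action,start_frame,end_frame", "oops,1,2"), path)
  expect_error(read_edit_set(path), class = "dyadsmile_format_error")
})

test_that("smile ratio is the smiling-frame fraction", {
  expect_equal(smile_ratio(make_track(integer(0), integer(0))[0, ], 100), 0)
  expect_equal(smile_ratio(make_track(1, 100), 100), 1)
  set.seed(36)
  for (rep in 1:20) {
    tr <- random_track(10, 1000)
    mask <- rep(FALSE, 1000)
    for (i in seq_len(nrow(tr))) mask[tr$start_frame[i]:tr$end_frame[i]] <- TRUE
    expect_equal(smile_ratio(tr, 1000), mean(mask))
  }
})
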