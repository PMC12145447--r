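# Hand-written tracker-dialect fixture (padded headers, as the tracker emits).
write_openface_fixture <- function(path,
                                   au04 = c(0.1, 0.2, 0.1),
                                   au06 = c(0.5, 1.5, 0.5),
                                   au12 = c(1.0, 2.5, 1.0),
                                   confidence = rep(0.98, length(au04)),
                                   success = rep(1, length(au04)),
                                   drop_cols = character(0)) {
  n <- length(au04)
  cols <- list(frame = seq_len(n),
               timestamp = (seq_len(n) - 1) / 30,
               confidence = confidence,
               success = success,
               AU04_r = au04, AU06_r = au06, AU12_r = au12)
  cols <- cols[setdiff(names(cols), drop_cols)]
  header <- paste(names(cols), collapse = ", ")
  rows <- do.call(paste, c(unname(lapply(cols, as.character)), sep = ", "))
  writeLines(c(header, rows), path)
  path
}

make_track <- function(starts, ends, participant_id = "p", source = "auto") {
  tibble::tibble(participant_id = participant_id,
                 start_frame = as.integer(starts),
                 end_frame = as.integer(ends),
                 source = source)
}

# Dyad geometry reproducing the method's worked example: participant A has
# 18 smiles of which 16 are shared; B has 27 of which 20 are shared (four of
# A's smiles each overlap two B smiles). All placements are >2 s apart
# unless sharing is intended; fs = 30.
worked_example_tracks <- function() {
  slot <- 600L                 # 20 s between A smiles
  a_starts <- 1L + slot * (0:17)
  a <- make_track(a_starts, a_starts + 59L, "A")
  b_starts <- integer(0)
  for (i in 1:16) {
    s <- a_starts[i]
    b_starts <- c(b_starts, s + 30L)                 # overlaps A_i
    if (i >= 13) b_starts <- c(b_starts, s + 100L)   # within 2 s of A_i only
  }
  b_lens <- rep(60L, length(b_starts))
  b_lens[which(b_starts %in% (a_starts[13:16] + 100L))] <- 41L
  far <- 1L + slot * (18:24)                         # 7 isolated B smiles
  b_starts <- c(b_starts, far)
  b_lens <- c(b_lens, rep(60L, 7))
  b <- make_track(b_starts, b_starts + b_lens - 1L, "B")
  list(a = a, b = b)
}
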