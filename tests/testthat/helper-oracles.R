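# Independent brute-force oracles for interval logic. These deliberately use
# different algorithms from the package implementations.

# Maximal runs of TRUE in a boolean mask, by linear scan.
detect_oracle <- function(mask) {
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE
  for (i in seq_along(mask)) {
    if (mask[i] && !in_run) { starts <- c(starts, i); in_run <- TRUE }
    if (!mask[i] && in_run) { ends <- c(ends, i - 1L); in_run <- FALSE }
  }
  if (in_run) ends <- c(ends, length(mask))
  list(starts = starts, ends = ends)
}

# Merge-by-gap oracle: dilate every interval's right edge by `gap` frames,
# union overlapping dilated intervals, then contract. Dilated intervals
# [s, e + gap] intersect iff the original gap (s2 - e1 - 1) is < gap, which
# is exactly the strict merge rule.
merge_oracle <- function(track, gap) {
  if (nrow(track) == 0L) return(track)
  o <- order(track$start_frame)
  s <- track$start_frame[o]
  e <- track$end_frame[o] + gap
  us <- s[1]; ue <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= ue) ue <- max(ue, e[i])
    else { out_s <- c(out_s, us); out_e <- c(out_e, ue); us <- s[i]; ue <- e[i] }
  }
  out_s <- c(out_s, us); out_e <- c(out_e, ue)
  tibble::tibble(participant_id = track$participant_id[1],
                 start_frame = as.integer(out_s),
                 end_frame = as.integer(out_e - gap),
                 source = track$source[1])
}

# All-pairs shared-smile oracle: per-pair scalar distance, double loop.
pair_distance <- function(s1, e1, s2, e2) {
  if (s1 <= e2 && s2 <= e1) return(0L)            # overlap
  if (s2 > e1) s2 - e1 - 1L else s1 - e2 - 1L     # gap between nearer ends
}

shared_oracle <- function(own, other, window_frames) {
  vapply(seq_len(nrow(own)), function(i) {
    any(vapply(seq_len(nrow(other)), function(j) {
      pair_distance(own$start_frame[i], own$end_frame[i],
                    other$start_frame[j], other$end_frame[j]) <= window_frames
    }, logical(1)))
  }, logical(1))
}

# Random sorted disjoint smile track.
random_track <- function(max_intervals = 50, n_frames = 10000,
                         participant_id = "p") {
  n <- sample.int(max_intervals + 1L, 1L) - 1L
  if (n == 0L) {
    return(tibble::tibble(participant_id = character(0), start_frame = integer(0),
                          end_frame = integer(0), source = character(0)))
  }
  pts <- sort(sample.int(n_frames, 2L * n))
  tibble::tibble(participant_id = participant_id,
                 start_frame = pts[seq(1, 2 * n, by = 2)],
                 end_frame = pts[seq(2, 2 * n, by = 2)],
                 source = "auto")
}
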