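# Independent brute-force oracles, deliberately implemented differently from
# the package internals they cross-check.

# Episode segmentation oracle: start with each intake image as its own
# one-interval episode, then repeatedly merge any adjacent pair whose
# non-intake separation is <= merge_gap, until nothing changes; finally drop
# episodes with fewer than min_images intake images. Quadratic-ish and dumb
# on purpose.
oracle_episodes <- function(timestamps, labels, interval, merge_gap, min_images) {
  t_on <- as.numeric(timestamps[labels == 1])
  if (length(t_on) == 0) {
    return(data.frame(start = numeric(0), end = numeric(0), n = integer(0)))
  }
  start <- t_on
  end <- t_on + interval
  n <- rep(1L, length(t_on))
  alive <- rep(TRUE, length(t_on))
  repeat {
    merged <- FALSE
    idx <- which(alive)
    k <- 1
    while (k < length(idx)) {
      i <- idx[k]
      j <- idx[k + 1]
      # non-intake time between adjacent episodes
      if (start[j] - end[i] <= merge_gap) {
        end[i] <- end[j]
        n[i] <- n[i] + n[j]
        alive[j] <- FALSE
        idx <- idx[-(k + 1)]
        merged <- TRUE
      } else {
        k <- k + 1
      }
    }
    if (!merged) break
  }
  keep <- alive & n >= min_images
  data.frame(start = start[keep], end = end[keep], n = n[keep])
}

# Interval-overlap scoring oracle: loops over every (detected, truth) pair.
oracle_detection <- function(truth, detected) {
  n_t <- nrow(truth)
  n_d <- nrow(detected)
  overlap <- function(a1, a2, b1, b2) {
    max(0, min(as.numeric(a2), as.numeric(b2)) - max(as.numeric(a1), as.numeric(b1)))
  }
  tp <- 0
  for (i in seq_len(n_d)) {
    hit <- FALSE
    for (j in seq_len(n_t)) {
      if (overlap(detected$start[i], detected$end[i], truth$start[j], truth$end[j]) > 0) hit <- TRUE
    }
    if (hit) tp <- tp + 1
  }
  rec <- 0
  for (j in seq_len(n_t)) {
    hit <- FALSE
    for (i in seq_len(n_d)) {
      if (overlap(detected$start[i], detected$end[i], truth$start[j], truth$end[j]) > 0) hit <- TRUE
    }
    if (hit) rec <- rec + 1
  }
  precision <- if (n_d == 0) 0 else tp / n_d
  recall <- if (n_t == 0) 1 else rec / n_t
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1)
}
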