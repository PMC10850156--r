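# Independent oracles and small builders shared across test files. Each
# oracle deliberately uses a different algorithm than the implementation it
# checks (explicit loops, enumeration) so agreement is informative.

# O(n*w) rolling mean/sd with centered truncated windows, by direct loops
brute_rolling_zscore <- function(y, rate, window) {
  n <- length(y)
  half <- floor(window * rate / 2)
  z <- numeric(n)
  for (i in seq_len(n)) {
    idx <- max(1, i - half):min(n, i + half)
    z[i] <- (y[i] - mean(y[idx])) / stats::sd(y[idx])
  }
  z
}

# Benjamini-Hochberg step-up, written out longhand
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    val <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- val
    prev <- val
  }
  adj
}

# focused-exploration episode count by enumeration of all contiguous index
# ranges that form valid maximal chains (gap rule checked pairwise)
brute_focused_count <- function(dips, gap = 5) {
  n <- nrow(dips)
  if (n < 2) return(0L)
  valid <- function(i, j)
    all(dips$start[(i + 1):j] - dips$stop[i:(j - 1)] <= gap)
  cnt <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (!valid(i, j)) next
    left_max <- (i == 1) || (dips$start[i] - dips$stop[i - 1] > gap)
    right_max <- (j == n) || (dips$start[j + 1] - dips$stop[j] > gap)
    if (left_max && right_max) cnt <- cnt + 1L
  }
  cnt
}

# PSTH by explicit per-trial loops and hist(), z-scored against pooled
# pre-stimulus bins
brute_psth_z <- function(spikes, events, bin = 0.1, window = c(-1, 1)) {
  edges <- seq(window[1], window[2], by = bin)
  per <- t(sapply(events, function(ev) {
    rel <- spikes - ev
    rel <- rel[rel >= window[1] & rel < window[2]]
    graphics::hist(rel, breaks = edges, plot = FALSE)$counts / bin
  }))
  lags <- edges[-length(edges)]
  pre <- as.numeric(per[, lags < 0])
  colMeans((per - mean(pre)) / stats::sd(pre))
}

# interval Jaccard and the best-match score of each truth bout
interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1))
  inter / (max(a2, b2) - min(a1, b1))
}

best_match_jaccards <- function(truth, detected) {
  vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(detected) == 0) return(0)
    max(vapply(seq_len(nrow(detected)), function(j)
      interval_jaccard(truth$start[i], truth$stop[i],
                       detected$start[j], detected$stop[j]), numeric(1)))
  }, numeric(1))
}

# merge consecutive script rows satisfying a predicate into truth intervals
script_truth_intervals <- function(script, sel) {
  ends <- cumsum(script$duration)
  starts <- c(0, ends[-length(ends)])
  r <- rle(sel)
  re <- cumsum(r$lengths)
  rs <- re - r$lengths + 1
  data.frame(start = starts[rs[r$values]], stop = ends[re[r$values]])
}

# a minimal processed_trace for unit tests that need direct control of z
make_trace <- function(z, rate = 100, t0 = 0) {
  structure(list(time = t0 + (seq_along(z) - 1) / rate, z = z,
                 f0 = rep(0, length(z)), f1 = rep(1, length(z)),
                 rate = rate, steps = list()),
            class = "processed_trace")
}

# a trajectory plus a hand-specified velocity (speed in cm/s per frame);
# x advances consistently with the speed so path lengths are exact
make_traj_with_speed <- function(speed, motion = NULL, frame_rate = 30,
                                 arena = c(50, 50)) {
  n <- length(speed)
  if (is.null(motion)) motion <- rep(5, n)
  x <- cumsum(c(2, speed[-1] / frame_rate))
  y <- rep(2, n)
  traj <- trajectory(seq_len(n) - 1L, (seq_len(n) - 1) / frame_rate,
                     pmin(x, arena[1]), y, motion, frame_rate, arena)
  vel <- list(speed = speed, x = x, y = y)
  list(traj = traj, vel = vel)
}

expect_ek_error <- function(expr, class) {
  expect_error(expr, class = class)
}
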