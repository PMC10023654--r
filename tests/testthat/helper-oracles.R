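# Shared fixtures and independent oracles used across the suite.

# ratio trace from a plain numeric vector at a given frame rate
make_rt <- function(x, fs = 10) {
  ratio_trace(seq(0, by = 1 / fs, length.out = length(x)), x,
              frame_rate_hz = fs)
}

# brute-force sliding-window maximum mean, O(N * W)
max_ratio_oracle <- function(x, w) {
  best <- -Inf
  for (i in seq_len(length(x) - w + 1)) {
    best <- max(best, mean(x[i:(i + w - 1)]))
  }
  best
}

# random 3-D rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# analytic sphere-crossing count for one segment: solutions of
# |a + t (b - a)|^2 = r^2 with t in (0, 1]; a double root (tangency)
# counts once
segment_sphere_crossings <- function(a, b, r) {
  d <- b - a
  A <- sum(d^2)
  if (A == 0) return(0L)
  B <- 2 * sum(a * d)
  C <- sum(a^2) - r^2
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(0L)
  if (disc == 0) {
    t0 <- -B / (2 * A)
    return(as.integer(t0 > 0 && t0 <= 1))
  }
  ts <- (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  sum(ts > 0 & ts <= 1)
}

# independent Sholl oracle: analytic crossings summed over dendrite edges
sholl_oracle <- function(tree, radii) {
  ctr <- c(mean(tree$x[tree$parent == -1]), mean(tree$y[tree$parent == -1]),
           mean(tree$z[tree$parent == -1]))
  child <- tree[tree$parent != -1 & tree$type != 1, , drop = FALSE]
  pidx <- match(child$parent, tree$id)
  vapply(radii, function(r) {
    total <- 0L
    for (i in seq_len(nrow(child))) {
      a <- c(tree$x[pidx[i]], tree$y[pidx[i]], tree$z[pidx[i]]) - ctr
      b <- c(child$x[i], child$y[i], child$z[i]) - ctr
      total <- total + segment_sphere_crossings(a, b, r)
    }
    total
  }, integer(1))
}

# two-valued signal with a known number of level transitions
make_square_wave <- function(n_transitions, lo, hi, run = 25) {
  states <- rep(c(lo, hi), length.out = n_transitions + 1)
  rep(states, each = run)
}

# minimal odor trial built from a ratio vector
make_trial <- function(ratio, fs = 10, onset = 10, dur = 4, baseline = 5) {
  structure(list(t = seq(0, by = 1 / fs, length.out = length(ratio)),
                 ratio = ratio, frame_rate_hz = fs, stim_onset_s = onset,
                 stim_dur_s = dur, baseline_s = baseline,
                 cell_id = "c1", mouse_id = "m1", trial = 1L),
            class = "odor_trial")
}

# minimal two-channel trace with constant channels
make_dual <- function(n = 50, fs = 10, ven = 200, ven_bg = 50, cer = 150,
                      cer_bg = 50) {
  dual_channel_trace(seq(0, by = 1 / fs, length.out = n),
                     rep(ven, n), rep(ven_bg, n), rep(cer, n), rep(cer_bg, n),
                     frame_rate_hz = fs)
}
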