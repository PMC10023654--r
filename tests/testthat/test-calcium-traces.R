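test_that("compute_ratio follows the background-corrected channel formula", {
  tr <- make_dual(ven = 200, ven_bg = 50, cer = 150, cer_bg = 50)
  rt <- compute_ratio(tr)
  expect_equal(rt$ratio, rep(1.5, 50))
  expect_false(rt$filtered)

  # all four channels equal: donor denominator is zero
  bad <- make_dual(ven = 100, ven_bg = 100, cer = 100, cer_bg = 100)
  expect_error(compute_ratio(bad), "sample 1")

  # joint positive rescaling of channels and backgrounds leaves ratio fixed
  tr2 <- tr
  for (f in c("F_ven_soma", "F_ven_bg", "F_cer_soma", "F_cer_bg")) {
    tr2[[f]] <- tr2[[f]] * 3.7
  }
  expect_equal(compute_ratio(tr2)$ratio, rt$ratio)
})

test_that("computed ratio reproduces the generator's ratio exactly", {
  g <- gen_traces(trace_sim_spec(n_cells = 5, seed = 11))
  for (tr in g$traces) {
    expect_equal(compute_ratio(tr)$ratio, attr(tr, "ratio_true"),
                 tolerance = 1e-12)
  }
})

test_that("lowpass filter has unit DC gain and attenuates above cutoff", {
  fs <- 10
  const <- make_rt(rep(1.3, 1200), fs)
  expect_equal(lowpass_filter(const)$ratio, rep(1.3, 1200), tolerance = 1e-9)

  t <- seq(0, 120, by = 1 / fs)
  hi <- make_rt(sin(2 * pi * 3 * t), fs)          # 5x the 0.6 Hz cutoff
  y <- lowpass_filter(hi)$ratio
  mid <- 200:1000
  expect_lt(max(abs(y[mid])), 0.05)

  lo <- make_rt(sin(2 * pi * 0.05 * t), fs)       # deep in the passband
  z <- lowpass_filter(lo)$ratio
  expect_equal(max(abs(z[mid])), max(abs(lo$ratio[mid])), tolerance = 0.02)

  expect_error(lowpass_filter(make_rt(rnorm(100), fs = 1)), "Nyquist")
})

test_that("basal ratio is the mean of the lowest 10% of samples", {
  expect_equal(basal_ratio(make_rt(rep(1.2, 40))), 1.2)
  expect_equal(basal_ratio(make_rt(1:100)), 5.5)
  expect_error(basal_ratio(make_rt(1:9)), "10 samples")

  # noisy flat baseline recovers the baseline within 2 noise SDs
  set.seed(3)
  x <- 1 + rnorm(1000, 0, 0.05)
  expect_lt(abs(basal_ratio(make_rt(x)) - 1), 2 * 0.05)
})

test_that("max ratio equals the brute-force sliding-window maximum", {
  expect_equal(max_ratio(make_rt(rep(2.1, 40))), 2.1)

  # single-sample spike averaged across the 15-sample window at 10 Hz
  x <- rep(1, 100); x[50] <- 1 + 0.6
  expect_equal(max_ratio(make_rt(x, 10)), 1 + 0.6 / 15)

  set.seed(7)
  for (i in 1:20) {
    fs <- runif(1, 7, 10)
    x <- rnorm(round(runif(1, 50, 300)))
    w <- round(1.5 * fs)
    expect_equal(max_ratio(make_rt(x, fs)), max_ratio_oracle(x, w),
                 tolerance = 1e-12)
  }
  expect_error(max_ratio(make_rt(1:5, 10)), "shorter")
})

test_that("AUC per second integrates the baseline-subtracted trace", {
  expect_equal(auc_per_sec(make_rt(rep(0.9, 100)), baseline = 0.9), 0)
  expect_equal(auc_per_sec(make_rt(rep(1.1, 100)), baseline = 0.9), 0.2,
               tolerance = 1e-12)

  # double-exponential event train against the closed-form event integral
  fs <- 10; t <- seq(0, 120, by = 1 / fs)
  tau_r <- 0.5; tau_d <- 2; amp <- 0.5
  w <- function(u) ifelse(u < 0, 0, exp(-u / tau_d) - exp(-u / tau_r))
  t_pk <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  pk <- w(t_pk)
  onsets <- c(10, 40, 75)
  x <- rep(1, length(t))
  for (t0 in onsets) x <- x + amp * w(t - t0) / pk
  analytic <- length(onsets) * amp * (tau_d - tau_r) / pk / (t[length(t)] - t[1])
  expect_equal(auc_per_sec(make_rt(x, fs), baseline = 1), analytic,
               tolerance = 0.01)
})

test_that("mid-reference crossing count matches the state-level oracle", {
  expect_warning(n0 <- count_midcrossings(make_rt(rep(1, 50))), "constant")
  expect_identical(n0, 0L)

  # clean two-valued signals: oracle = transitions of the state sequence
  set.seed(5)
  for (i in 1:25) {
    k <- sample(1:8, 1)
    lo <- runif(1, 0, 1); hi <- lo + runif(1, 0.5, 2)
    x <- make_square_wave(k, lo, hi)
    mid <- (lo + hi) / 2
    s <- x - mid
    oracle <- sum(s[-1] * s[-length(s)] < 0)
    expect_identical(as.integer(count_midcrossings(make_rt(x))),
                     as.integer(oracle))
    expect_identical(oracle, k)
  }

  # a monotone ramp crosses any interior level exactly once
  expect_identical(as.integer(count_midcrossings(make_rt(seq(0, 1, length.out = 200)))), 1L)
})

test_that("crossing count is invariant under positive affine maps", {
  set.seed(9)
  g <- gen_traces(trace_sim_spec(n_cells = 6, seed = 21))
  for (tr in g$traces) {
    rt <- lowpass_filter(compute_ratio(tr))
    n1 <- count_midcrossings(rt)
    rt2 <- rt; rt2$ratio <- 2.3 * rt$ratio + 0.7
    expect_identical(count_midcrossings(rt2), n1)
  }
})

test_that("basal <= mean <= max holds for arbitrary traces", {
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(200, sd = runif(1, 0.1, 2)) + runif(1, -5, 5)
    rt <- make_rt(x)
    expect_lte(basal_ratio(rt), mean(x))
    expect_lte(mean(x), max_ratio(rt) + 1e-12)
  }
})

test_that("feature pipeline separates fluctuating from flat populations", {
  g <- gen_traces(trace_sim_spec(n_cells = 40, seed = 31))
  f <- compute_trace_features(g$traces)
  med_fluct <- median(f$n_crossings[g$truth$fluctuating])
  med_flat <- median(f$n_crossings[!g$truth$fluctuating])
  expect_gt(med_fluct, med_flat)
})
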