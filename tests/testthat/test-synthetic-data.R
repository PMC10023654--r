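test_that("trace generator is deterministic and allocates labels exactly", {
  s <- trace_sim_spec(n_cells = 10, seed = 4)
  g1 <- gen_traces(s); g2 <- gen_traces(s)
  expect_identical(g1$truth, g2$truth)
  expect_identical(g1$traces[[3]]$F_ven_soma, g2$traces[[3]]$F_ven_soma)

  g3 <- gen_traces(trace_sim_spec(n_cells = 10, seed = 5))
  expect_false(identical(g1$traces[[3]]$F_ven_soma, g3$traces[[3]]$F_ven_soma))

  g60 <- gen_traces(trace_sim_spec(n_cells = 60, frac_fluctuating = 0.6,
                                   seed = 1))
  expect_identical(sum(g60$truth$fluctuating), 36L)
})

test_that("degenerate trace spec yields constant traces at baseline", {
  g <- gen_traces(trace_sim_spec(n_cells = 4, frac_fluctuating = 0,
                                 noise_sd = 0, drift_amp = 0,
                                 baseline_ratio = 1.4, seed = 2))
  for (tr in g$traces) {
    expect_equal(compute_ratio(tr)$ratio,
                 rep(1.4, length(tr$t)), tolerance = 1e-12)
  }
})

test_that("fluctuating cells out-cross flat cells in nearly every cell", {
  g <- gen_traces(trace_sim_spec(n_cells = 60, event_amp = 0.5,
                                 noise_sd = 0.01, seed = 8))
  f <- compute_trace_features(g$traces)
  # oracle: the generator's own event bookkeeping identifies event carriers
  frac_sep <- mean(f$n_crossings[g$truth$fluctuating] >
                     median(f$n_crossings[!g$truth$fluctuating]))
  expect_gte(frac_sep, 0.95)
})

test_that("track generator honors degenerate and saturated settings", {
  g0 <- gen_tracks(track_sim_spec(n_cells = 8, frac_migratory = 0,
                                  jitter_um = 0, seed = 1))
  for (tr in g0$tracks) {
    expect_equal(max(abs(diff(as.matrix(tr[, c("x_um", "y_um", "z_um")])))), 0)
  }

  g1 <- gen_tracks(track_sim_spec(n_cells = 8, frac_migratory = 1, p_move = 1,
                                  step_scale_um = 10, jitter_um = 0, seed = 2))
  for (tr in g1$tracks) {
    d <- sqrt(rowSums(diff(as.matrix(tr[, c("x_um", "y_um", "z_um")]))^2))
    expect_equal(d, rep(10, 16), tolerance = 1e-9)
    expect_true(classify_moving(tr)$moving)
  }
})

test_that("localization jitter alone rarely exceeds the 4 um rule", {
  # analytic check: each axis difference is N(0, 2 sigma^2), so
  # P(step > 4) = P(chisq_3 > 16 / (2 sigma^2))
  p_true <- 1 - pchisq(16 / 2, df = 3)
  expect_lt(p_true, 0.05)

  g <- gen_tracks(track_sim_spec(n_cells = 40, frac_migratory = 0,
                                 jitter_um = 1, seed = 3))
  steps <- unlist(lapply(g$tracks, function(tr) {
    sqrt(rowSums(diff(as.matrix(tr[, c("x_um", "y_um", "z_um")]))^2))
  }))
  expect_lt(abs(mean(steps > 4) - p_true), 0.02)
})

test_that("tree generator records exact morphometry ground truth", {
  g0 <- gen_trees(1, depth = 0, seed = 1)
  expect_identical(nrow(g0$trees[[1]]), 1L)
  expect_equal(g0$truth$tdbl_um, 0)
  expect_identical(g0$truth$n_branches, 0L)

  g2 <- gen_trees(1, depth = 2, seg_len_um = 10, seed = 2)
  expect_equal(g2$truth$tdbl_um, 60)
  expect_identical(g2$truth$n_branches, 6L)

  # independent traversal recomputes the stored truth
  gr <- gen_trees(12, depth = 4, seg_len_um = 8, seed = 3, prune_p = 0.3)
  m <- morphometry_table(gr$trees)
  expect_equal(m$tdbl_um, gr$truth$tdbl_um, tolerance = 1e-9)
  expect_identical(m$n_branches, gr$truth$n_branches)
})

test_that("census pairs encode survival ground truth", {
  gA <- gen_census_pair(n_cells = 50, frac_survive = 1, drift_um = 0,
                        newcomer_frac = 0, seed = 1)
  expect_equal(survival_rate(gA$census_a, gA$census_b)$rate, 1)

  gB <- gen_census_pair(n_cells = 100, frac_survive = 0.5, drift_um = 10,
                        seed = 2)
  expect_lt(survival_rate(gB$census_a, gB$census_b)$rate, 0.05)
})

test_that("count generator plants recoverable fold changes", {
  # noise-free limit: CPM identical across samples within each gene
  g0 <- gen_counts(count_sim_spec(n_genes = 200, frac_de = 0, dispersion = 0,
                                  lib_size_range = c(1, 1), seed = 1))
  cpm <- cpm_matrix(g0$counts)
  keep <- rowSums(g0$counts) > 0
  cv <- apply(cpm[keep, ], 1, function(x) sd(x) / mean(x))
  expect_lt(max(cv), 0.01)

  # null matrix: fold-change caller stays quiet
  gn <- gen_counts(count_sim_spec(n_genes = 3000, n_samples_per_group = 5,
                                  frac_de = 0, seed = 2))
  filt <- expression_filter(gn$counts)
  dg <- call_degs(filt, gn$groups)
  expect_lt(mean(dg$is_deg), 0.05)
})
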