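make_samples <- function(counts, mouse = NULL, group = "control") {
  n <- length(counts)
  data.frame(cell_id = sprintf("c%03d", seq_len(n)),
             mouse_id = mouse %||% sprintf("m%02d", rep_len(1:4, n)),
             group = group, n_crossings = counts, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("well-separated bimodal counts recover two components and labels", {
  set.seed(1)
  origin <- rep(c(FALSE, TRUE), each = 100)
  counts <- round(c(pmax(rnorm(100, 1, 0.5), 0), rnorm(100, 20, 2)))
  cl <- fit_crossing_gmm(make_samples(counts), seed = 0)
  expect_identical(cl$k_selected, 2L)
  expect_gte(mean((cl$labels$label == "with") == origin), 0.95)
})

test_that("identical counts degenerate to a single labeled component", {
  expect_warning(cl <- fit_crossing_gmm(make_samples(rep(3, 30))), "identical")
  expect_identical(cl$k_selected, 1L)
  expect_true(all(cl$labels$label == "with"))   # mean 3 > threshold 2

  expect_warning(cl0 <- fit_crossing_gmm(make_samples(rep(1, 30))))
  expect_true(all(cl0$labels$label == "without"))
})

test_that("three well-separated modes keep the two upper components 'with'", {
  set.seed(2)
  counts <- round(c(pmax(rnorm(60, 2, 0.8), 0), rnorm(60, 20, 2),
                    rnorm(60, 40, 2)))
  cl <- fit_crossing_gmm(make_samples(counts), seed = 0)
  expect_identical(cl$k_selected, 3L)
  lab <- cl$labels$label
  expect_true(all(lab[61:180] == "with"))
  expect_true(all(lab[1:60] == "without"))
})

test_that("label assignment ignores input ordering", {
  set.seed(3)
  counts <- round(c(pmax(rnorm(50, 1, 0.5), 0), rnorm(50, 18, 2)))
  s <- make_samples(counts)
  cl1 <- fit_crossing_gmm(s, seed = 0)
  perm <- sample(nrow(s))
  cl2 <- fit_crossing_gmm(s[perm, ], seed = 0)
  lab2 <- cl2$labels$label[match(s$cell_id, cl2$labels$cell_id)]
  expect_identical(cl1$labels$label, lab2)
})

test_that("per-mouse fractions aggregate to the documented group summary", {
  set.seed(6)
  counts <- round(c(1, 2, 1, 25, 26,          # mA: 2 of 5 high
                    2, 24, 25, 26, 24,        # mB: 4 of 5 high
                    pmax(rnorm(6, 1, 0.5), 0), rnorm(6, 25, 1)))  # mC filler
  s <- make_samples(counts, mouse = rep(c("mA", "mB", "mC"),
                                        times = c(5, 5, 12)))
  fr <- fraction_with_fluctuations(fit_crossing_gmm(s, seed = 0))
  pm <- fr$per_mouse
  expect_true(all(pm$fraction >= 0 & pm$fraction <= 1))
  # mA has 2/5 high-count cells, mB 4/5
  expect_equal(pm$fraction[pm$mouse_id == "mA"], 0.4)
  expect_equal(pm$fraction[pm$mouse_id == "mB"], 0.8)
  expect_equal(fr$per_group$mean_fraction,
               mean(pm$fraction))
})

test_that("fraction recovery error shrinks with cohort size", {
  err <- vapply(c(60, 600), function(n) {
    g <- gen_traces(trace_sim_spec(n_cells = n, frac_fluctuating = 0.6,
                                   seed = 17))
    f <- compute_trace_features(g$traces)
    fr <- fraction_with_fluctuations(fit_crossing_gmm(f, seed = 0))
    abs(fr$per_group$mean_fraction - 0.6)
  }, numeric(1))
  expect_lte(err[2], err[1] + 0.02)
  expect_lt(err[2], 0.1)
})

test_that("group comparison routes by Shapiro-Wilk normality", {
  set.seed(4)
  x <- rnorm(20)
  same <- compare_groups(c(x, x), rep(c("a", "b"), each = 20))
  expect_gt(same$p_value, 0.05)

  sep <- compare_groups(c(rnorm(20, 0), rnorm(20, 3)),
                        rep(c("a", "b"), each = 20))
  expect_identical(sep$route, "parametric")
  expect_identical(sep$test, "Student's t-test")
  expect_lt(sep$p_value, 0.001)

  expo <- compare_groups(c(rexp(50), rexp(50)), rep(c("a", "b"), each = 50))
  expect_identical(expo$route, "nonparametric")
  expect_identical(expo$test, "Mann-Whitney U")

  expect_error(compare_groups(c(1, 2, 1, 2, 3), c("a", "a", "b", "b", "b")),
               "n >= 3")
})

test_that("three-group comparisons attach the matching post hoc table", {
  set.seed(6)
  v <- c(rnorm(15, 0), rnorm(15, 0.2), rnorm(15, 3))
  g <- rep(c("a", "b", "c"), each = 15)
  par <- compare_groups(v, g)
  expect_identical(par$test, "one-way ANOVA")
  expect_identical(nrow(par$posthoc), 3L)

  vn <- c(rexp(30), rexp(30), rexp(30) + 2)
  gn <- rep(c("a", "b", "c"), each = 30)
  np <- compare_groups(vn, gn)
  expect_identical(np$test, "Kruskal-Wallis")
  expect_identical(nrow(np$posthoc), 3L)
  expect_true(all(np$posthoc$p_adjusted >= np$posthoc$p_unadjusted - 1e-12))
  # the clearly shifted group drives the significant pairs
  sig <- np$posthoc[np$posthoc$p_adjusted < 0.05, ]
  expect_true(all(sig$group2 == "c" | sig$group1 == "c"))
})
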