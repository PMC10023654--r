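toy_counts <- function() {
  m <- matrix(c(
    #  s1   s2   s3   s4   s5   s6
      500, 500, 500, 500, 500, 500,   # high everywhere
        0,   0,   0,   0,   0,   0,   # zero gene
        1,   1, 800, 800, 800, 800,   # low in exactly 2 samples
        1,   1,   1, 800, 800, 800,   # low in 3 samples
      300,   0, 300, 300, 300, 300,   # low in exactly 1 sample
        2,   2,   2,   2,   2,   2),  # exactly 1 CPM everywhere
    nrow = 6, byrow = TRUE,
    dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:6)))
  # filler gene brings every library to 2e6 so a single count is 0.5 CPM
  rbind(m, filler = 2e6 - colSums(m))
}

test_that("CPM normalizes each sample to one million", {
  m <- matrix(c(1, 999999, 10, 999990), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cpm <- cpm_matrix(m)
  expect_equal(cpm["a", "s1"], 1)
  expect_equal(colSums(cpm), c(s1 = 1e6, s2 = 1e6))

  z <- rbind(a = c(0, 0), b = c(5, 5))
  expect_equal(cpm_matrix(z)["a", ], c(0, 0))

  # duplicating a column changes nothing for either copy
  m3 <- cbind(m, s3 = m[, 2])
  expect_equal(cpm_matrix(m3)[, "s3"], cpm_matrix(m)[, "s2"])

  expect_error(cpm_matrix(rbind(c(0, 1), c(0, 3))), "library")
})

test_that("expression filtering matches hand enumeration under both rules", {
  m <- toy_counts()
  cpm <- cpm_matrix(m)
  # oracle: brute-force evaluation of the two written rules
  drop_low <- rownames(m)[rowSums(cpm < 1) >= 2]
  keep_high <- rownames(m)[rowSums(cpm >= 1) >= 2]

  f1 <- expression_filter(m)
  expect_identical(rownames(f1), setdiff(rownames(m), drop_low))
  f2 <- expression_filter(m, rule = "keep_high")
  expect_identical(rownames(f2), keep_high)

  # the two readings of the rule disagree exactly on the genes that are both
  # low in >= 2 samples and expressed in >= 2 samples
  expect_true("g3" %in% rownames(f2) && !("g3" %in% rownames(f1)))
  expect_true("g6" %in% rownames(f1))   # exactly 1 CPM is not "less than 1"

  # the all-zero gene is dropped and the everywhere-expressed gene kept by both
  expect_false("g2" %in% rownames(f1) || "g2" %in% rownames(f2))
  expect_true("g1" %in% rownames(f1) && "g1" %in% rownames(f2))

  # idempotence
  expect_identical(expression_filter(f1), f1)
  expect_identical(expression_filter(f2, rule = "keep_high"), f2)
})

test_that("DEG calls apply the strict twofold union rule on mean CPM", {
  groups <- rep(c("control", "kv", "kir"), each = 2)
  m <- rbind(
    flat = rep(1000, 6),
    up_kv = c(250, 250, 1000, 1000, 250, 250),
    up_both = c(100, 100, 500, 500, 500, 500),
    down_kir = c(800, 800, 800, 800, 150, 150))
  colnames(m) <- sprintf("s%d", 1:6)
  # equalize library sizes so fold changes act on CPM as written
  m <- rbind(m, filler = 2e5 - colSums(m))

  dg <- call_degs(m, groups)
  expect_false(dg$is_deg[dg$gene == "flat"])
  expect_true(all(dg$is_deg[dg$gene %in% c("up_kv", "up_both", "down_kir")]))

  di <- call_degs(m, groups, combine = "intersection")
  expect_true(di$is_deg[di$gene == "up_both"])
  expect_false(di$is_deg[di$gene == "up_kv"])

  expect_error(call_degs(m, rep(c("kv", "kir"), 3)), "control")

  # permuting samples within groups changes nothing
  perm <- c(2, 1, 4, 3, 6, 5)
  dp <- call_degs(m[, perm], groups[perm])
  expect_equal(dp$is_deg[match(dg$gene, dp$gene)], dg$is_deg)
})

test_that("fold-change boundary is strict at the threshold", {
  groups <- rep(c("control", "kv"), each = 2)
  # library size 1e6 makes CPM equal the entry, so the pseudo-counted
  # fold change is exactly 2
  ctrl <- 99.5; kv <- 2 * (ctrl + 0.5) - 0.5
  m <- rbind(g_at = c(ctrl, ctrl, kv, kv),
             filler = 1e6 - c(ctrl, ctrl, kv, kv))
  colnames(m) <- sprintf("s%d", 1:4)
  dg <- call_degs(m, groups)
  expect_equal(dg$log2fc_kv[dg$gene == "g_at"], 1, tolerance = 1e-9)
  expect_false(dg$is_deg[dg$gene == "g_at"])
})

test_that("planted simulations hit the designed sensitivity and FPR", {
  g <- gen_counts(count_sim_spec(n_genes = 4000, n_samples_per_group = 5,
                                 frac_de = 0.1, log2fc_de = 2,
                                 dispersion = 0.1, seed = 11))
  filt <- expression_filter(g$counts)
  dg <- call_degs(filt, g$groups)
  truth <- g$truth$is_de[match(dg$gene, g$truth$gene)]
  expect_gte(mean(dg$is_deg[truth]), 0.9)
  expect_lt(mean(dg$is_deg[!truth]), 0.05)
})

test_that("module summaries report member-gene log2 CPM by group", {
  g <- gen_counts(count_sim_spec(n_genes = 500, n_samples_per_group = 5,
                                 frac_de = 0.2, log2fc_de = 2, seed = 12))
  cpm <- cpm_matrix(g$counts)
  down <- g$truth$gene[g$truth$direction == -1][1:20]
  null_genes <- g$truth$gene[!g$truth$is_de][1:20]
  modules <- rbind(data.frame(module = "suppressed", gene = down),
                   data.frame(module = "housekeeping", gene = null_genes))
  ms <- module_summary(cpm, modules, g$groups)

  s <- ms$summary
  expect_lt(s$median_log2_cpm[s$module == "suppressed" & s$group == "kv"],
            s$median_log2_cpm[s$module == "suppressed" & s$group == "control"])
  hk <- s[s$module == "housekeeping", ]
  expect_lt(max(hk$median_log2_cpm) - min(hk$median_log2_cpm), 0.3)

  # single-gene module reproduces that gene's values
  one <- module_summary(cpm, data.frame(module = "solo", gene = "g00001"),
                        g$groups)
  expect_equal(one$expression$log2_cpm, unname(log2(cpm["g00001", ] + 0.5)))

  expect_error(module_summary(cpm, data.frame(module = "x", gene = "nope"),
                              g$groups), "missing")
})
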