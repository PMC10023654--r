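#' Cluster mid-crossing counts with a 1-D Gaussian mixture model
#'
#' Fits univariate Gaussian mixtures with 1 to `k_max` components to the
#' pooled per-cell crossing counts and selects the component number by the
#' Bayesian information criterion. The component with the smallest mean is
#' labeled "without" fluctuations; cells assigned to any other component are
#' labeled "with".
#'
#' @param samples Data frame with columns `cell_id`, `mouse_id`, `group`,
#'   `n_crossings` (non-negative counts).
#' @param k_max Largest number of components searched (default 5).
#' @param seed Integer seed (model initialization is deterministic; the seed
#'   is set for reproducibility of any downstream tie-breaking).
#' @param transform `"none"` (default) fits raw counts; `"log1p"` fits
#'   `log(1 + count)`.
#' @param single_mean_threshold If BIC selects one component, all cells are
#'   labeled "without" when the component mean is at or below this crossing
#'   count (default 2), otherwise "with".
#' @param merge_tol Starting from the minimum-mean component, successive
#'   components join the "without" state while the step between adjacent
#'   component means is at most `merge_tol` crossings (default 3, about one
#'   fluctuation event's worth of crossings; EM can describe one cluster
#'   with several nearby components).
#' @return An object of class `cluster_result`: `k_selected`, `means`,
#'   `variances`, `weights`, `labels` (the input table with a `label` column
#'   of "with"/"without"), `bic` (per-k table).
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_crossing_gmm <- function(samples, k_max = 5, seed = 0L,
                             transform = c("none", "log1p"),
                             single_mean_threshold = 2, merge_tol = 3) {
  transform <- match.arg(transform)
  stopifnot(is.data.frame(samples), "n_crossings" %in% names(samples))
  if (any(samples$n_crossings < 0)) stop("crossing counts must be >= 0")
  n <- nrow(samples)
  if (n < 2 * k_max) stop("need at least 2 * k_max samples")
  x <- samples$n_crossings
  if (transform == "log1p") x <- log1p(x)
  set.seed(seed)
  out <- samples
  if (diff(range(x)) == 0) {
    warning("all crossing counts identical: k = 1 degenerate fit")
    mu <- mean(samples$n_crossings)
    out$label <- if (mu <= single_mean_threshold) "without" else "with"
    return(structure(list(k_selected = 1L, means = mu, variances = 0,
                          weights = 1, labels = out, bic = NULL),
                     class = "cluster_result"))
  }
  # search equal- and unequal-variance univariate mixtures jointly: the
  # unequal-variance fit can go singular on tight count clusters, and the
  # equal-variance one keeps those k in the BIC comparison
  fit <- suppressWarnings(
    mclust::Mclust(x, G = 1:k_max, modelNames = c("E", "V"), verbose = FALSE))
  if (is.null(fit)) stop("mixture fit failed for all k")
  k <- fit$G
  means <- as.numeric(fit$parameters$mean)
  vars <- as.numeric(fit$parameters$variance$sigmasq)
  if (length(vars) == 1) vars <- rep(vars, k)
  weights <- as.numeric(fit$parameters$pro)
  if (k == 1) {
    mu_counts <- mean(samples$n_crossings)
    out$label <- if (mu_counts <= single_mean_threshold) "without" else "with"
  } else {
    mu_scale <- if (transform == "log1p") log1p(merge_tol) else merge_tol
    ord <- order(means)
    n_low <- 1L
    while (n_low < k &&
           means[ord[n_low + 1]] - means[ord[n_low]] <= mu_scale) {
      n_low <- n_low + 1L
    }
    low <- ord[seq_len(n_low)]
    out$label <- ifelse(fit$classification %in% low, "without", "with")
  }
  structure(list(k_selected = k, means = means, variances = vars,
                 weights = weights, labels = out,
                 bic = fit$BIC), class = "cluster_result")
}

#' Fraction of cells with calcium fluctuations, per mouse and per group
#'
#' @param result A `cluster_result` from [fit_crossing_gmm()].
#' @return A list with `per_mouse` (data frame `mouse_id`, `group`,
#'   `n_cells`, `n_with`, `fraction`) and `per_group` (data frame `group`,
#'   `mean_fraction`, `sem`, `n_mice`), fractions in \[0, 1\]. Mice with no
#'   cells are excluded with a warning.
#' @export
fraction_with_fluctuations <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  lab <- result$labels
  keys <- unique(lab[, c("mouse_id", "group")])
  per_mouse <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    sel <- lab$mouse_id == keys$mouse_id[i] & lab$group == keys$group[i]
    data.frame(mouse_id = keys$mouse_id[i], group = keys$group[i],
               n_cells = sum(sel), n_with = sum(lab$label[sel] == "with"),
               stringsAsFactors = FALSE)
  }))
  empty <- per_mouse$n_cells == 0
  if (any(empty)) {
    warning("excluding mice with no cells: ",
            paste(per_mouse$mouse_id[empty], collapse = ", "))
    per_mouse <- per_mouse[!empty, ]
  }
  per_mouse$fraction <- per_mouse$n_with / per_mouse$n_cells
  per_group <- do.call(rbind, lapply(split(per_mouse, per_mouse$group),
    function(d) data.frame(group = d$group[1],
                           mean_fraction = mean(d$fraction),
                           sem = sd(d$fraction) / sqrt(nrow(d)),
                           n_mice = nrow(d), stringsAsFactors = FALSE)))
  rownames(per_group) <- NULL
  list(per_mouse = per_mouse, per_group = per_group)
}

#' Dunn's multiple-comparison test
#'
#' Rank-based pairwise post hoc comparisons following a Kruskal-Wallis test:
#' z statistics on mean ranks with tie correction, Bonferroni-adjusted across
#' all pairs (the convention of common statistics packages).
#'
#' @param values Numeric response vector.
#' @param group Group labels, same length.
#' @return Data frame `group1`, `group2`, `z`, `p_unadjusted`, `p_adjusted`.
#' @export
dunn_test <- function(values, group) {
  group <- factor(group)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  levs <- levels(group)
  cmb <- utils::combn(levs, 2)
  res <- apply(cmb, 2, function(pair) {
    i <- group == pair[1]; j <- group == pair[2]
    ni <- sum(i); nj <- sum(j)
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    z <- (mean(r[i]) - mean(r[j])) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  out <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
                    z = res["z", ], p_unadjusted = res["p", ],
                    stringsAsFactors = FALSE)
  out$p_adjusted <- pmin(1, out$p_unadjusted * ncol(cmb))
  rownames(out) <- NULL
  out
}

#' Compare experimental groups with normality-gated test selection
#'
#' Each group's distribution is checked with the Shapiro-Wilk test at
#' `alpha`. If every group is consistent with normality, a parametric route
#' is taken: Student's t-test for two groups, or one-way ANOVA followed by
#' Tukey's multiple-comparison test for three or more. If any group fails the
#' check, the nonparametric route is taken: Mann-Whitney U test for two
#' groups, or Kruskal-Wallis followed by Dunn's multiple comparisons. With
#' `paired = TRUE` the two-group tests become the paired t-test and the
#' Wilcoxon signed-rank test.
#'
#' @param values Numeric response vector.
#' @param group Group labels (>= 2 groups, each with n >= 3).
#' @param paired Use paired two-group tests (default FALSE).
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return An object of class `test_report`: `test`, `route`, `statistic`,
#'   `p_value`, `normality` (per-group Shapiro-Wilk table), `posthoc`
#'   (pairwise table for >= 3 groups, else NULL).
#' @export
compare_groups <- function(values, group, paired = FALSE, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 groups")
  ns <- table(group)
  if (any(ns < 3)) stop("every group needs n >= 3 for the normality check")
  norm_tab <- do.call(rbind, lapply(levels(group), function(g) {
    x <- values[group == g]
    if (diff(range(x)) == 0) {
      # constant group: Shapiro-Wilk undefined; treat as non-normal
      return(data.frame(group = g, W = NA_real_, p = 0, normal = FALSE,
                        stringsAsFactors = FALSE))
    }
    sw <- shapiro.test(x)
    data.frame(group = g, W = unname(sw$statistic), p = sw$p.value,
               normal = sw$p.value >= alpha, stringsAsFactors = FALSE)
  }))
  all_normal <- all(norm_tab$normal)
  route <- if (all_normal) "parametric" else "nonparametric"
  posthoc <- NULL
  if (nlevels(group) == 2) {
    if (all_normal) {
      ht <- t.test(values ~ group, paired = paired, var.equal = TRUE)
      test <- if (paired) "paired t-test" else "Student's t-test"
    } else {
      ht <- suppressWarnings(wilcox.test(values ~ group, paired = paired))
      test <- if (paired) "Wilcoxon signed-rank" else "Mann-Whitney U"
    }
    stat <- unname(ht$statistic); pval <- ht$p.value
  } else {
    if (all_normal) {
      fit <- aov(values ~ group)
      s <- summary(fit)[[1]]
      stat <- s[["F value"]][1]; pval <- s[["Pr(>F)"]][1]
      test <- "one-way ANOVA"
      tk <- TukeyHSD(fit)$group
      posthoc <- data.frame(comparison = rownames(tk),
                            diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
                            stringsAsFactors = FALSE)
      rownames(posthoc) <- NULL
    } else {
      ht <- kruskal.test(values, group)
      stat <- unname(ht$statistic); pval <- ht$p.value
      test <- "Kruskal-Wallis"
      posthoc <- dunn_test(values, group)
    }
  }
  structure(list(test = test, route = route, statistic = stat,
                 p_value = pval, normality = norm_tab, posthoc = posthoc),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("%s (%s route): statistic = %.4g, p = %.4g\n",
              x$test, x$route, x$statistic, x$p_value))
  invisible(x)
}
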