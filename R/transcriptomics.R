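#' Counts-per-million normalization
#'
#' `CPM = count * 1e6 / library size`, with library size the raw column sum
#' (no compositional normalization).
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Matrix of CPM values, same dimensions.
#' @export
cpm_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  libs <- colSums(counts)
  if (any(libs == 0)) {
    stop("zero library size in sample(s): ",
         paste(which(libs == 0), collapse = ", "))
  }
  edgeR::cpm(counts, lib.size = libs)
}

#' Filter low-expressed transcripts by a CPM rule
#'
#' The default (`rule = "exclude_low"`) drops every gene whose CPM is below
#' `cpm_min` in at least `n_samples` samples — the literal reading of
#' "less than 1 count per million in at least two samples were excluded".
#' The alternative (`rule = "keep_high"`) keeps genes with CPM at or above
#' `cpm_min` in at least `n_samples` samples.
#'
#' @param counts Raw count matrix, genes x samples.
#' @param cpm_min CPM threshold (default 1).
#' @param n_samples Sample-count threshold (default 2).
#' @param rule `"exclude_low"` (default) or `"keep_high"`.
#' @return The filtered count matrix (rows subset).
#' @export
expression_filter <- function(counts, cpm_min = 1, n_samples = 2,
                              rule = c("exclude_low", "keep_high")) {
  rule <- match.arg(rule)
  counts <- as.matrix(counts)
  cpm <- cpm_matrix(counts)
  keep <- if (rule == "exclude_low") {
    rowSums(cpm < cpm_min) < n_samples
  } else {
    rowSums(cpm >= cpm_min) >= n_samples
  }
  counts[keep, , drop = FALSE]
}

#' Call differentially expressed genes by fold change of group-mean CPM
#'
#' For each contrast of control against an overexpression group, the log2
#' fold change of pseudo-counted group-mean CPM is computed; a gene is a DEG
#' when its absolute fold change strictly exceeds `fc_threshold` in the
#' control-vs-kv or control-vs-kir contrast (union rule by default).
#'
#' @param counts Filtered count matrix, genes x samples.
#' @param groups Character vector of group labels per sample; must contain
#'   `control_label` and at least one other group.
#' @param fc_threshold Fold-change threshold (default 2, i.e. |log2 FC| > 1,
#'   strict).
#' @param pseudo Pseudo-count added to group-mean CPM (default 0.5).
#' @param combine `"union"` (default): DEG in any contrast; `"intersection"`:
#'   DEG in every contrast.
#' @param control_label Label of the reference group (default "control").
#' @return Data frame with `gene`, one `log2fc_<group>` column per
#'   non-control group, and `is_deg`.
#' @export
call_degs <- function(counts, groups, fc_threshold = 2, pseudo = 0.5,
                      combine = c("union", "intersection"),
                      control_label = "control") {
  combine <- match.arg(combine)
  counts <- as.matrix(counts)
  if (length(groups) != ncol(counts)) stop("one group label per sample required")
  if (!control_label %in% groups) stop("missing group: ", control_label)
  others <- setdiff(unique(groups), control_label)
  if (length(others) == 0) stop("need at least one non-control group")
  cpm <- cpm_matrix(counts)
  ctrl_mean <- rowMeans(cpm[, groups == control_label, drop = FALSE])
  out <- data.frame(gene = rownames(counts), stringsAsFactors = FALSE)
  hits <- matrix(FALSE, nrow(counts), length(others))
  for (k in seq_along(others)) {
    gmean <- rowMeans(cpm[, groups == others[k], drop = FALSE])
    lfc <- log2((gmean + pseudo) / (ctrl_mean + pseudo))
    out[[paste0("log2fc_", others[k])]] <- lfc
    hits[, k] <- abs(lfc) > log2(fc_threshold)
  }
  out$is_deg <- if (combine == "union") rowSums(hits) > 0 else
    rowSums(hits) == length(others)
  out
}

#' Percentage of detected genes called differentially expressed
#'
#' @param n_deg Number of DEGs.
#' @param n_total Number of detected (filter-passing) genes.
#' @return Percentage `100 * n_deg / n_total`.
#' @export
deg_percentage <- function(n_deg, n_total) {
  stopifnot(n_total > 0, n_deg >= 0, n_deg <= n_total)
  100 * n_deg / n_total
}

#' Per-module expression summary
#'
#' Expression of the member genes of each gene module (e.g. the
#' calcium/CaMKII signaling set, or a housekeeping control set), reported as
#' log2 CPM (pseudo-count 0.5) per sample with group labels, plus per-group
#' medians.
#'
#' @param cpm CPM matrix, genes x samples.
#' @param modules Data frame with columns `module`, `gene`.
#' @param groups Character vector of group labels per sample.
#' @return A list with `expression` (long data frame `module`, `gene`,
#'   `sample`, `group`, `log2_cpm`) and `summary` (data frame `module`,
#'   `group`, `median_log2_cpm`, `n_genes`). Errors if a module has no genes
#'   in the matrix, listing the missing genes.
#' @export
module_summary <- function(cpm, modules, groups) {
  cpm <- as.matrix(cpm)
  stopifnot(length(groups) == ncol(cpm),
            all(c("module", "gene") %in% names(modules)))
  samples <- colnames(cpm)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(cpm)))
  expr <- do.call(rbind, lapply(split(modules, modules$module), function(m) {
    present <- m$gene %in% rownames(cpm)
    if (!any(present)) {
      stop("module '", m$module[1], "' has no genes in the matrix; missing: ",
           paste(m$gene, collapse = ", "))
    }
    sub <- log2(cpm[m$gene[present], , drop = FALSE] + 0.5)
    data.frame(module = m$module[1],
               gene = rep(rownames(sub), ncol(sub)),
               sample = rep(samples, each = nrow(sub)),
               group = rep(groups, each = nrow(sub)),
               log2_cpm = as.vector(sub), stringsAsFactors = FALSE)
  }))
  rownames(expr) <- NULL
  summ <- do.call(rbind, lapply(split(expr, expr[c("module", "group")]),
    function(d) data.frame(module = d$module[1], group = d$group[1],
                           median_log2_cpm = median(d$log2_cpm),
                           n_genes = length(unique(d$gene)),
                           stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  list(expression = expr, summary = summ)
}
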