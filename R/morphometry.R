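#' Validate a node table as a neuron reconstruction
#'
#' Checks SWC-style node tables: unique ids, exactly one root
#' (`parent == -1`), all parents present, no cycles.
#'
#' @param nodes Data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @return The validated table with class `neuron_tree`.
#' @export
as_neuron_tree <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    stop("node table must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(nodes$id)) {
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  }
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1) {
    stop(sprintf("expected exactly one root (parent -1), found %d",
                 length(roots)))
  }
  nonroot <- nodes$parent != -1
  missing <- !(nodes$parent[nonroot] %in% nodes$id)
  if (any(missing)) {
    stop("node ", nodes$id[nonroot][missing][1],
         " references a missing parent ", nodes$parent[nonroot][missing][1])
  }
  # cycle check: walk each node to the root
  parent_of <- setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {
    seen <- character(0)
    cur <- as.character(id)
    while (parent_of[[cur]] != -1) {
      if (cur %in% seen) stop("cycle detected at node ", id)
      seen <- c(seen, cur)
      cur <- as.character(parent_of[[cur]])
    }
  }
  class(nodes) <- c("neuron_tree", "data.frame")
  nodes
}

#' Read an SWC reconstruction file
#'
#' Standard 7-column SWC: `id type x y z radius parent`, `#` comments
#' allowed. The soma is the node with parent -1.
#'
#' @param path Path to an SWC file.
#' @return A `neuron_tree` node table.
#' @export
read_swc <- function(path) {
  raw <- read.table(path, comment.char = "#",
                    col.names = c("id", "type", "x", "y", "z", "radius",
                                  "parent"))
  raw$id <- as.integer(raw$id); raw$type <- as.integer(raw$type)
  raw$parent <- as.integer(raw$parent)
  as_neuron_tree(raw)
}

#' Write a neuron reconstruction to SWC
#'
#' @param tree A `neuron_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  writeLines(c("# SWC", sprintf("%d %d %.6f %.6f %.6f %.4f %d", tree$id,
                                tree$type, tree$x, tree$y, tree$z,
                                tree$radius, tree$parent)), path)
  invisible(path)
}

# dendrite edges: parent/child coordinates for every non-root node whose
# type is not soma (type 1)
dendrite_edges <- function(tree) {
  child <- tree[tree$parent != -1 & tree$type != 1, , drop = FALSE]
  pidx <- match(child$parent, tree$id)
  list(p0 = cbind(tree$x[pidx], tree$y[pidx], tree$z[pidx]),
       p1 = cbind(child$x, child$y, child$z), child = child)
}

#' Total dendritic branch length
#'
#' Sum of the Euclidean lengths of all dendrite edges (edges whose child node
#' is soma-typed are excluded).
#'
#' @param tree A `neuron_tree`.
#' @return TDBL in micrometers.
#' @export
tdbl <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  e <- dendrite_edges(tree)
  if (nrow(e$p1) == 0) return(0)
  sum(sqrt(rowSums((e$p1 - e$p0)^2)))
}

#' Number of dendritic branches
#'
#' A branch is a maximal unbranched path between the soma, branch points, and
#' terminal tips: a dendrite edge starts a new branch when its parent node is
#' the soma (or root) or has two or more children; otherwise it continues its
#' parent's branch. The primary stem counts as a branch.
#'
#' @param tree A `neuron_tree`.
#' @return Integer branch count.
#' @export
branch_count <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  e <- dendrite_edges(tree)
  if (nrow(e$child) == 0) return(0L)
  n_children <- table(factor(tree$parent, levels = tree$id))
  root_id <- tree$id[tree$parent == -1]
  starts <- vapply(seq_len(nrow(e$child)), function(i) {
    p <- e$child$parent[i]
    p == root_id || tree$type[match(p, tree$id)] == 1 ||
      n_children[[as.character(p)]] >= 2
  }, logical(1))
  sum(starts)
}

soma_center <- function(tree) {
  soma <- tree[tree$type == 1 | tree$parent == -1, , drop = FALSE]
  c(mean(soma$x), mean(soma$y), mean(soma$z))
}

# crossings of one polyline (radial distances r_i) with a sphere of radius r:
# strict straddles plus on-shell vertices (each counted once; tangency counts
# as a single crossing). Radii within 1e-9 of the shell are snapped onto it
# so that vertices constructed on a shell stay there under rigid motions.
# The first vertex is skipped in the exact-hit count so shared segment
# endpoints are not double counted.
polyline_crossings <- function(rr, r) {
  s <- rr - r
  s[abs(s) < 1e-9] <- 0
  n_straddle <- sum(s[-length(s)] * s[-1] < 0)
  n_exact <- sum(s[-1] == 0)
  n_straddle + n_exact
}

#' Sholl profile: dendrite intersections with concentric spheres
#'
#' Counts the crossings of the piecewise-linear dendritic arbor with
#' concentric spheres centered on the soma at radii `step_um, 2*step_um,
#' ...`. Segments are densely resampled (default 0.1 um pieces) so that a
#' chord dipping through a shell contributes both crossings; a vertex lying
#' exactly on a shell counts as a single crossing.
#'
#' @param tree A `neuron_tree`.
#' @param step_um Radius increment in micrometers (default 10).
#' @param resample_um Resampling resolution in micrometers (default 0.1).
#' @param three_d If FALSE, use circles in the XY plane instead of spheres
#'   (thin-slice variant). Default TRUE.
#' @return Data frame of class `sholl_profile`: `radius_um`,
#'   `intersections`.
#' @export
sholl <- function(tree, step_um = 10, resample_um = 0.1, three_d = TRUE) {
  stopifnot(inherits(tree, "neuron_tree"), step_um > 0, resample_um > 0)
  ctr <- soma_center(tree)
  e <- dendrite_edges(tree)
  dims <- if (three_d) 1:3 else 1:2
  radial <- function(p) sqrt(rowSums((p[, dims, drop = FALSE] -
    matrix(ctr[dims], nrow(p), length(dims), byrow = TRUE))^2))
  if (nrow(e$p1) == 0) {
    out <- data.frame(radius_um = step_um, intersections = 0L)
    class(out) <- c("sholl_profile", "data.frame")
    return(out)
  }
  rmax <- max(radial(e$p0), radial(e$p1))
  radii <- seq(step_um, by = step_um,
               length.out = max(1, floor(rmax / step_um + 1e-9)))
  counts <- integer(length(radii))
  for (i in seq_len(nrow(e$p1))) {
    a <- e$p0[i, ]; b <- e$p1[i, ]
    len <- sqrt(sum((b - a)^2))
    n_sub <- max(1L, ceiling(len / resample_um))
    tt <- seq(0, 1, length.out = n_sub + 1)
    pts <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
                 a[3] + tt * (b[3] - a[3]))
    rr <- radial(pts)
    for (j in seq_along(radii)) {
      if (radii[j] < min(rr) - 1e-9 || radii[j] > max(rr) + 1e-9) next
      counts[j] <- counts[j] + polyline_crossings(rr, radii[j])
    }
  }
  out <- data.frame(radius_um = radii, intersections = counts)
  class(out) <- c("sholl_profile", "data.frame")
  out
}

#' Morphometry summary for a set of reconstructions
#'
#' @param trees List of `neuron_tree` objects.
#' @return Data frame `tree_id`, `tdbl_um`, `n_branches`.
#' @export
morphometry_table <- function(trees) {
  ids <- names(trees)
  if (is.null(ids)) ids <- sprintf("t%03d", seq_along(trees))
  data.frame(tree_id = ids,
             tdbl_um = vapply(trees, tdbl, numeric(1)),
             n_branches = vapply(trees, branch_count, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
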