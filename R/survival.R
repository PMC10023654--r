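#' Field-of-view census of cell positions at one timepoint
#'
#' @param cells Data frame `cell_id`, `x_um`, `y_um`, `z_um` with positions
#'   inside the FOV.
#' @param session Imaging session label (e.g. dpi).
#' @param fov_um FOV extent `c(x, y, z)` in micrometers
#'   (default c(635, 635, 200)).
#' @param margin_um XY safe margin in micrometers (default 100; must be less
#'   than half the FOV extent).
#' @return An object of class `fov_census`.
#' @export
fov_census <- function(cells, session = NA, fov_um = c(635, 635, 200),
                       margin_um = 100) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "x_um", "y_um", "z_um") %in% names(cells)),
            length(fov_um) == 3, margin_um < min(fov_um[1:2]) / 2)
  inside <- cells$x_um >= 0 & cells$x_um <= fov_um[1] &
    cells$y_um >= 0 & cells$y_um <= fov_um[2] &
    cells$z_um >= 0 & cells$z_um <= fov_um[3]
  if (!all(inside)) {
    stop("cell positions outside the FOV: ",
         paste(cells$cell_id[!inside][1:min(3, sum(!inside))], collapse = ", "))
  }
  structure(list(cells = cells, session = session, fov_um = fov_um,
                 margin_um = margin_um, n_excluded_margin = NA_integer_),
            class = "fov_census")
}

#' Exclude cells inside the XY safe margin
#'
#' Retains cells with `margin <= x <= fov_x - margin` and likewise in y
#' (inclusive boundaries); z is unrestricted. Cells in the margin band are
#' dropped and counted.
#'
#' @param census A [fov_census()].
#' @return The census with margin cells removed; the number excluded is
#'   recorded in `n_excluded_margin`.
#' @export
apply_margin <- function(census) {
  stopifnot(inherits(census, "fov_census"))
  m <- census$margin_um
  f <- census$fov_um
  keep <- census$cells$x_um >= m & census$cells$x_um <= f[1] - m &
    census$cells$y_um >= m & census$cells$y_um <= f[2] - m
  out <- census
  out$n_excluded_margin <- sum(!keep)
  out$cells <- census$cells[keep, , drop = FALSE]
  out
}

#' Match surviving cells between two sessions
#'
#' Finds the one-to-one assignment between session-A and session-B cells
#' that maximizes the number of matches and, among those, minimizes the
#' total displacement, considering only pairs within the position tolerance
#' (inclusive: an offset equal to `tol_um` is accepted). A session-A cell
#' with a match is a survivor; the survival rate is survivors divided by the
#' session-A cells analyzed.
#'
#' @param a,b [fov_census()] objects (apply [apply_margin()] first, or use
#'   [survival_rate()]).
#' @param tol_um Position tolerance in micrometers (default 4, the
#'   microscope resolution limit).
#' @param use_z Include the z displacement in the gate distance
#'   (default TRUE); FALSE gates on XY only.
#' @return A list of class `survival_result`: `pairs` (data frame `cell_a`,
#'   `cell_b`, `distance_um`), `survivors` (session-A ids), `rate`, `n_a`,
#'   `n_b`.
#' @export
match_survivors <- function(a, b, tol_um = 4, use_z = TRUE) {
  stopifnot(inherits(a, "fov_census"), inherits(b, "fov_census"))
  ca <- a$cells; cb <- b$cells
  if (nrow(ca) == 0) stop("session-A census is empty")
  pairs <- data.frame(cell_a = character(0), cell_b = character(0),
                      distance_um = numeric(0), stringsAsFactors = FALSE)
  if (nrow(cb) > 0) {
    dims <- if (use_z) c("x_um", "y_um", "z_um") else c("x_um", "y_um")
    pa <- as.matrix(ca[, dims]); pb <- as.matrix(cb[, dims])
    d2 <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
      outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
    dmat <- sqrt(pmax(d2, 0))
    dmat[dmat < 1e-4] <- 0   # cancellation noise on coincident points
    adm <- which(dmat <= tol_um, arr.ind = TRUE)
    if (nrow(adm) > 0) {
      # max-weight bipartite matching; BIG makes cardinality dominate cost
      big <- (nrow(pa) + nrow(pb) + 1) * (tol_um + 1)
      g <- igraph::make_bipartite_graph(
        c(rep(FALSE, nrow(pa)), rep(TRUE, nrow(pb))),
        as.vector(t(cbind(adm[, 1], nrow(pa) + adm[, 2]))))
      igraph::E(g)$weight <- big - dmat[adm]
      mm <- igraph::max_bipartite_match(g)$matching
      ia <- seq_len(nrow(pa))
      matched <- !is.na(mm[ia])
      if (any(matched)) {
        jb <- mm[ia][matched] - nrow(pa)
        pairs <- data.frame(cell_a = ca$cell_id[ia[matched]],
                            cell_b = cb$cell_id[jb],
                            distance_um = dmat[cbind(ia[matched], jb)],
                            stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(pairs = pairs, survivors = pairs$cell_a,
                 rate = nrow(pairs) / nrow(ca),
                 n_a = nrow(ca), n_b = nrow(cb)),
            class = "survival_result")
}

#' Survival rate between two sessions with margin filtering
#'
#' Applies the XY safe margin to both censuses, then matches survivors with
#' the position-tolerance gate.
#'
#' @inheritParams match_survivors
#' @return A `survival_result` (see [match_survivors()]) with added
#'   `n_excluded_margin_a`, `n_excluded_margin_b`.
#' @export
survival_rate <- function(a, b, tol_um = 4, use_z = TRUE) {
  am <- apply_margin(a)
  bm <- apply_margin(b)
  res <- match_survivors(am, bm, tol_um = tol_um, use_z = use_z)
  res$n_excluded_margin_a <- am$n_excluded_margin
  res$n_excluded_margin_b <- bm$n_excluded_margin
  res
}
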