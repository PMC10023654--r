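#' Euclidean step distance between two 3-D soma positions
#'
#' `D = sqrt((X1-X0)^2 + (Y1-Y0)^2 + (Z1-Z0)^2)`, in micrometers.
#'
#' @param p0,p1 Numeric length-3 vectors `(x, y, z)` in micrometers.
#' @return Distance in micrometers.
#' @export
step_distance <- function(p0, p1) {
  stopifnot(length(p0) == 3, length(p1) == 3,
            all(is.finite(p0)), all(is.finite(p1)))
  sqrt(sum((p1 - p0)^2))
}

track_positions <- function(track) {
  stopifnot(is.data.frame(track),
            all(c("t_min", "x_um", "y_um", "z_um") %in% names(track)))
  as.matrix(track[, c("x_um", "y_um", "z_um")])
}

interval_distances <- function(track) {
  p <- track_positions(track)
  sqrt(rowSums(diff(p)^2))
}

#' Classify a cell as moving from its within-session track
#'
#' A cell is moving if the soma translocation between any two consecutive
#' time points is strictly more than `threshold_um` (default 4 um, twice the
#' axial step size of the image stacks).
#'
#' @param track Data frame `t_min`, `x_um`, `y_um`, `z_um` (time-ordered).
#' @param threshold_um Per-interval displacement threshold in micrometers
#'   (default 4).
#' @return A list with `moving` (logical) and `interval_moving` (per-interval
#'   flags).
#' @export
classify_moving <- function(track, threshold_um = 4) {
  if (nrow(track) < 2) stop("track needs at least 2 positions")
  d <- interval_distances(track)
  flags <- d > threshold_um
  list(moving = any(flags), interval_moving = flags)
}

#' Migration speed metrics of one track
#'
#' Speeds are per-interval translocations normalized to a 15-minute interval
#' using the actual timestamps (um per 15 min); the 4-h translocation is the
#' net first-to-last displacement.
#'
#' @param track Data frame `t_min`, `x_um`, `y_um`, `z_um` with strictly
#'   increasing `t_min`.
#' @param threshold_um Moving threshold passed to [classify_moving()].
#' @return A list of class `migration_metrics`: `distances_um`,
#'   `speeds_um_per_15min`, `median_speed`, `max_speed`, `translocation_um`,
#'   `moving`.
#' @export
speed_metrics <- function(track, threshold_um = 4) {
  if (nrow(track) < 2) stop("track needs at least 2 positions")
  if (any(diff(track$t_min) <= 0)) stop("timestamps must be strictly increasing")
  p <- track_positions(track)
  d <- interval_distances(track)
  dt <- diff(track$t_min)
  speeds <- d / dt * 15
  structure(list(
    distances_um = d, speeds_um_per_15min = speeds,
    median_speed = median(speeds), max_speed = max(speeds),
    translocation_um = step_distance(p[1, ], p[nrow(p), ]),
    moving = any(d > threshold_um)), class = "migration_metrics")
}

#' Per-track migration metric table
#'
#' @param tracks List of track data frames (as from [gen_tracks()]).
#' @param threshold_um Moving threshold in micrometers (default 4).
#' @return Data frame with one row per track: `cell_id`, `mouse_id`,
#'   `median_speed`, `max_speed`, `translocation_um`, `moving`.
#' @export
migration_table <- function(tracks, threshold_um = 4) {
  do.call(rbind, lapply(tracks, function(tr) {
    m <- speed_metrics(tr, threshold_um)
    data.frame(cell_id = attr(tr, "cell_id") %||% NA_character_,
               mouse_id = attr(tr, "mouse_id") %||% NA_character_,
               median_speed = m$median_speed, max_speed = m$max_speed,
               translocation_um = m$translocation_um, moving = m$moving,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Long-term motility between two imaging sessions
#'
#' Cells identified in both sessions (shared ids) are flagged as migrated if
#' their displacement exceeds `gate_um` (default 4 um, the within-session
#' rule reused as the position-resolution tolerance).
#'
#' @param cells_a,cells_b Data frames `cell_id`, `x_um`, `y_um`, `z_um` (or
#'   [fov_census()] objects) with shared cell ids across sessions.
#' @param gate_um Displacement gate in micrometers (default 4, strict `>`).
#' @return A list with `cells` (data frame `cell_id`, `displacement_um`,
#'   `migrated`), `fraction_migrated`, `n_unmatched` (cells present in only
#'   one session).
#' @export
longterm_motility <- function(cells_a, cells_b, gate_um = 4) {
  if (inherits(cells_a, "fov_census")) cells_a <- cells_a$cells
  if (inherits(cells_b, "fov_census")) cells_b <- cells_b$cells
  shared <- intersect(cells_a$cell_id, cells_b$cell_id)
  n_unmatched <- length(setdiff(cells_a$cell_id, shared)) +
    length(setdiff(cells_b$cell_id, shared))
  if (length(shared) == 0) stop("no shared cell ids between sessions")
  a <- cells_a[match(shared, cells_a$cell_id), ]
  b <- cells_b[match(shared, cells_b$cell_id), ]
  d <- sqrt((a$x_um - b$x_um)^2 + (a$y_um - b$y_um)^2 + (a$z_um - b$z_um)^2)
  cells <- data.frame(cell_id = shared, displacement_um = d,
                      migrated = d > gate_um, stringsAsFactors = FALSE)
  list(cells = cells, fraction_migrated = mean(cells$migrated),
       n_unmatched = n_unmatched)
}
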