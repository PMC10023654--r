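#' Relative pCREB expression level of adult-born cells
#'
#' Normalizes the background-corrected pCREB fluorescence of each labeled
#' adult-born juxtaglomerular cell to the median background-corrected pCREB
#' fluorescence of the mature NeuN-positive neurons in the same field of
#' view:
#' `(F_abJGC - bg) / median(F_NeuN - bg)`.
#'
#' @param abjgc Numeric vector of adult-born cell pCREB intensities (a.u.).
#' @param neun Numeric vector of NeuN-positive cell pCREB intensities (a.u.),
#'   at least one cell.
#' @param background Scalar background level subtracted from all intensities
#'   (default 0; the median noise of negative-control slices).
#' @return Numeric vector of relative pCREB levels, one per adult-born cell.
#'   Negative background-corrected intensities are clamped to 0 with a
#'   warning.
#' @export
relative_pcreb <- function(abjgc, neun, background = 0) {
  if (length(abjgc) < 1) stop("need at least one adult-born cell intensity")
  if (length(neun) < 1) stop("no NeuN-positive cells in the field of view")
  med <- median(neun - background)
  if (med <= 0) stop("non-positive NeuN median after background correction")
  num <- abjgc - background
  if (any(num < 0)) {
    warning("negative background-corrected intensities clamped to 0")
    num <- pmax(num, 0)
  }
  num / med
}

#' Per-FOV relative pCREB table from an intensity measurement table
#'
#' @param measurements Data frame `fov_id`, `cell_type` ("abJGC" or "NeuN"),
#'   `intensity`, `background` (as produced by [gen_if_measurements()]).
#' @return Data frame `fov_id`, `relative_pcreb` with one row per
#'   adult-born cell.
#' @export
relative_pcreb_table <- function(measurements) {
  do.call(rbind, lapply(split(measurements, measurements$fov_id), function(d) {
    ab <- d[d$cell_type == "abJGC", ]
    nn <- d[d$cell_type == "NeuN", ]
    data.frame(fov_id = d$fov_id[1],
               relative_pcreb = relative_pcreb(ab$intensity, nn$intensity,
                                               d$background[1]),
               stringsAsFactors = FALSE)
  }))
}

#' Relative Kv1.2 expression level
#'
#' Ratio of background-corrected somatic fluorescence to the
#' background-corrected fluorescence of the surrounding neuropil:
#' `(soma - bg) / (neuropil - bg)`.
#'
#' @param soma Somatic fluorescence intensity (a.u.).
#' @param neuropil Surrounding-neuropil fluorescence intensity (a.u.).
#' @param background Scalar background level (default 0).
#' @return The expression ratio (vectorized over cells).
#' @export
kv_expression_ratio <- function(soma, neuropil, background = 0) {
  den <- neuropil - background
  if (any(den <= 0)) stop("non-positive neuropil intensity after background correction")
  (soma - background) / den
}
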