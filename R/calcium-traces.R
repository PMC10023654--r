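#' Two-channel FRET fluorescence trace for one cell
#'
#' Container for the soma and background fluorescence of the donor
#' (mCerulean3) and acceptor (cpVenus-CD) channels of a ratiometric
#' Twitch-2B recording, sampled at a common frame rate.
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param F_ven_soma,F_ven_bg Acceptor-channel soma and background
#'   fluorescence (a.u.), same length as `t`.
#' @param F_cer_soma,F_cer_bg Donor-channel soma and background fluorescence
#'   (a.u.), same length as `t`.
#' @param frame_rate_hz Acquisition frame rate in Hz (1--100). Inferred from
#'   `t` when missing.
#' @param cell_id,mouse_id,group Optional identifiers carried through the
#'   feature pipeline.
#' @return An object of class `dual_channel_trace`.
#' @export
dual_channel_trace <- function(t, F_ven_soma, F_ven_bg, F_cer_soma, F_cer_bg,
                               frame_rate_hz = NULL, cell_id = NA_character_,
                               mouse_id = NA_character_, group = NA_character_) {
  n <- length(t)
  lens <- c(length(F_ven_soma), length(F_ven_bg),
            length(F_cer_soma), length(F_cer_bg))
  if (any(lens != n)) {
    stop("all four channels must have the same length as `t`")
  }
  if (n >= 2 && any(diff(t) <= 0)) {
    stop("`t` must be strictly increasing")
  }
  if (is.null(frame_rate_hz)) {
    frame_rate_hz <- 1 / median(diff(t))
  }
  if (!is.finite(frame_rate_hz) || frame_rate_hz < 1 || frame_rate_hz > 100) {
    stop("`frame_rate_hz` must lie in [1, 100]")
  }
  structure(
    list(t = as.numeric(t),
         F_ven_soma = as.numeric(F_ven_soma), F_ven_bg = as.numeric(F_ven_bg),
         F_cer_soma = as.numeric(F_cer_soma), F_cer_bg = as.numeric(F_cer_bg),
         frame_rate_hz = frame_rate_hz,
         cell_id = cell_id, mouse_id = mouse_id, group = group),
    class = "dual_channel_trace")
}

#' Ratio trace constructor
#'
#' @param t Sample times in seconds.
#' @param ratio Dimensionless FRET ratio values, finite, same length as `t`.
#' @param frame_rate_hz Frame rate in Hz.
#' @param filtered Logical; whether a low-pass filter has been applied.
#' @param cell_id,mouse_id,group Optional identifiers.
#' @return An object of class `ratio_trace`.
#' @export
ratio_trace <- function(t, ratio, frame_rate_hz = NULL, filtered = FALSE,
                        cell_id = NA_character_, mouse_id = NA_character_,
                        group = NA_character_) {
  if (length(ratio) != length(t)) stop("`ratio` and `t` lengths differ")
  if (!all(is.finite(ratio))) stop("ratio values must be finite")
  if (is.null(frame_rate_hz)) frame_rate_hz <- 1 / median(diff(t))
  structure(
    list(t = as.numeric(t), ratio = as.numeric(ratio),
         frame_rate_hz = frame_rate_hz, filtered = isTRUE(filtered),
         cell_id = cell_id, mouse_id = mouse_id, group = group),
    class = "ratio_trace")
}

#' Compute the Twitch-2B FRET ratio from a two-channel trace
#'
#' The ratio is the background-corrected acceptor fluorescence divided by the
#' background-corrected donor fluorescence, sample by sample:
#' `(F_ven_soma - F_ven_bg) / (F_cer_soma - F_cer_bg)`. No filtering is
#' applied here.
#'
#' @param trace A [dual_channel_trace()].
#' @return A [ratio_trace()] with `filtered = FALSE`.
#' @details A non-positive background-corrected donor value at any sample
#'   indicates a bad background ROI and raises an error naming the first
#'   offending sample index.
#' @export
compute_ratio <- function(trace) {
  stopifnot(inherits(trace, "dual_channel_trace"))
  den <- trace$F_cer_soma - trace$F_cer_bg
  bad <- which(den <= 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "non-positive donor denominator at sample %d (check background ROI)",
      bad[1]))
  }
  num <- trace$F_ven_soma - trace$F_ven_bg
  ratio_trace(trace$t, num / den, trace$frame_rate_hz, filtered = FALSE,
              cell_id = trace$cell_id, mouse_id = trace$mouse_id,
              group = trace$group)
}

#' Zero-phase low-pass Butterworth filter for ratio traces
#'
#' Applies an order-`order` Butterworth IIR low-pass filter forward and
#' backward (zero phase, DC gain 1) at the given cutoff frequency.
#'
#' @param rt A [ratio_trace()].
#' @param cutoff_hz Cutoff frequency in Hz; must be below the Nyquist
#'   frequency. Default 0.6 Hz.
#' @param order Filter order (default 4; applied twice by the
#'   forward-backward pass).
#' @return A filtered [ratio_trace()] with `filtered = TRUE`.
#' @export
lowpass_filter <- function(rt, cutoff_hz = 0.6, order = 4) {
  stopifnot(inherits(rt, "ratio_trace"))
  nyq <- rt$frame_rate_hz / 2
  if (cutoff_hz >= nyq) {
    stop(sprintf("cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
                 cutoff_hz, nyq))
  }
  bf <- signal::butter(order, cutoff_hz / nyq, type = "low")
  # odd-reflection padding keeps the forward-backward startup transient out
  # of the recording (the filter's impulse response decays over ~fs/cutoff
  # samples)
  x <- rt$ratio
  n <- length(x)
  p <- min(n - 1, ceiling(12 * rt$frame_rate_hz / cutoff_hz))
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), x, 2 * x[n] - rev(x[(n - p):(n - 1)]))
  y <- signal::filtfilt(bf, xp)[(p + 1):(p + n)]
  out <- rt
  out$ratio <- as.numeric(y)
  out$filtered <- TRUE
  out
}

#' Basal ratio: mean of the lowest 10% of samples
#'
#' The basal level of a trace is estimated as the mean of the lowest
#' `ceiling(0.1 * N)` sample values.
#'
#' @param rt A [ratio_trace()] with at least 10 samples.
#' @return The basal ratio (dimensionless).
#' @export
basal_ratio <- function(rt) {
  stopifnot(inherits(rt, "ratio_trace"))
  n <- length(rt$ratio)
  if (n < 10) stop("basal_ratio needs at least 10 samples")
  k <- ceiling(0.1 * n)
  mean(sort(rt$ratio)[seq_len(k)])
}

#' Maximum sliding-window average of a trace
#'
#' Smooths the trace with a boxcar of `window_s` seconds
#' (`round(window_s * frame_rate)` samples, full windows only, no edge
#' padding) and returns the maximum window mean.
#'
#' @param rt A [ratio_trace()].
#' @param window_s Window length in seconds (default 1.5 s).
#' @return The maximum windowed-average ratio.
#' @export
max_ratio <- function(rt, window_s = 1.5) {
  stopifnot(inherits(rt, "ratio_trace"))
  w <- max(1L, round(window_s * rt$frame_rate_hz))
  n <- length(rt$ratio)
  if (w > n) stop("trace shorter than the averaging window")
  cs <- cumsum(c(0, rt$ratio))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  max(means)
}

#' Area under the curve per second
#'
#' Trapezoidal integral of `(ratio - baseline)` over the recording, divided by
#' the total duration in seconds.
#'
#' @param rt A [ratio_trace()].
#' @param baseline Baseline level to subtract; defaults to the trace's own
#'   [basal_ratio()]. Use 0 for an absolute-area reading.
#' @return AUC per second (ratio units).
#' @export
auc_per_sec <- function(rt, baseline = NULL) {
  stopifnot(inherits(rt, "ratio_trace"))
  if (is.null(baseline)) baseline <- basal_ratio(rt)
  if (!is.finite(baseline)) stop("`baseline` must be finite")
  dur <- rt$t[length(rt$t)] - rt$t[1]
  pracma::trapz(rt$t, rt$ratio - baseline) / dur
}

# State levels by the bimodal-histogram convention: 100 bins over the range,
# low state = modal bin of the lower half, high state = modal bin of the
# upper half. Ties take the first (lowest) maximal bin of each half, the
# behavior of the reference state-level estimator; breaking upper-half ties
# toward the top instead misplaces the high state at the trace maximum
# whenever the upper histogram is sparse.
state_levels <- function(x, n_bins = 100) {
  rng <- range(x)
  if (diff(rng) == 0) return(c(low = rng[1], high = rng[2]))
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  centers <- (breaks[-1] + breaks[-(n_bins + 1)]) / 2
  idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  half <- n_bins %/% 2
  lo_counts <- counts[1:half]
  hi_counts <- counts[(half + 1):n_bins]
  lo_bin <- which(lo_counts == max(lo_counts))[1]
  hi_bin <- half + which(hi_counts == max(hi_counts))[1]
  c(low = centers[lo_bin], high = centers[hi_bin])
}

#' Count mid-reference level crossings of a trace
#'
#' Estimates the low and high state levels of the signal by the
#' bimodal-histogram method, takes the mid-reference level as their midpoint,
#' and counts the sample pairs that strictly straddle it. This is the
#' crossing count used to separate cells with and without spontaneous
#' calcium fluctuations.
#'
#' @param rt A [ratio_trace()] (or numeric vector) with at least 2 samples.
#' @param n_bins Number of histogram bins for state-level estimation
#'   (default 100).
#' @return Integer crossing count. A constant trace returns 0 with a warning.
#' @export
count_midcrossings <- function(rt, n_bins = 100) {
  x <- if (inherits(rt, "ratio_trace")) rt$ratio else as.numeric(rt)
  if (length(x) < 2) stop("count_midcrossings needs at least 2 samples")
  if (diff(range(x)) == 0) {
    warning("constant trace: no state levels, crossing count is 0")
    return(0L)
  }
  lv <- state_levels(x, n_bins)
  mid <- (lv["low"] + lv["high"]) / 2
  s <- x - mid
  sum(s[-length(s)] * s[-1] < 0)
}

#' Per-cell spontaneous-activity features of a ratio trace
#'
#' Runs the full feature pipeline on one two-channel trace: ratio computation,
#' optional zero-phase low-pass filtering, basal and maximum ratio, AUC per
#' second, and the mid-reference crossing count.
#'
#' @param trace A [dual_channel_trace()] or a precomputed [ratio_trace()].
#' @param filter Low-pass filter the ratio before feature extraction
#'   (default TRUE).
#' @param cutoff_hz Filter cutoff in Hz (default 0.6).
#' @param auc_baseline `"basal"` (default) subtracts the trace's basal ratio
#'   before integration; `"zero"` integrates the raw ratio.
#' @return A one-row data frame with columns `cell_id`, `mouse_id`, `group`,
#'   `basal_ratio`, `max_ratio`, `auc_per_sec`, `n_crossings`.
#' @export
trace_features <- function(trace, filter = TRUE, cutoff_hz = 0.6,
                           auc_baseline = c("basal", "zero")) {
  auc_baseline <- match.arg(auc_baseline)
  rt <- if (inherits(trace, "dual_channel_trace")) compute_ratio(trace) else trace
  stopifnot(inherits(rt, "ratio_trace"))
  if (filter) rt <- lowpass_filter(rt, cutoff_hz)
  bas <- basal_ratio(rt)
  data.frame(
    cell_id = rt$cell_id, mouse_id = rt$mouse_id, group = rt$group,
    basal_ratio = bas,
    max_ratio = max_ratio(rt),
    auc_per_sec = auc_per_sec(rt, if (auc_baseline == "basal") bas else 0),
    n_crossings = count_midcrossings(rt),
    stringsAsFactors = FALSE)
}

#' Feature table for a set of traces
#'
#' @param traces List of [dual_channel_trace()] objects.
#' @inheritParams trace_features
#' @return Data frame with one feature row per trace.
#' @export
compute_trace_features <- function(traces, filter = TRUE, cutoff_hz = 0.6,
                                   auc_baseline = c("basal", "zero")) {
  auc_baseline <- match.arg(auc_baseline)
  do.call(rbind, lapply(traces, trace_features, filter = filter,
                        cutoff_hz = cutoff_hz, auc_baseline = auc_baseline))
}
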