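#' Action-potential threshold from a current-clamp trace
#'
#' Computes dV/dt by central differences, estimates its SD over a
#' pre-stimulus baseline window, and returns the membrane voltage at the
#' first sample inside the stimulus window where dV/dt exceeds three
#' baseline SDs and stays above for at least `sustain_ms` (the sustain
#' criterion suppresses single-sample noise crossings at 20 kHz). Returns
#' `NA` if no action potential is found.
#'
#' @param t_ms Time in milliseconds, uniformly sampled.
#' @param v_mv Membrane voltage in millivolts.
#' @param stim_window_ms Length-2 stimulus window `c(start, end)` in ms.
#' @param baseline_ms Baseline window length before stimulus start used for
#'   the SD (default 100 ms; at least 50 ms must be available).
#' @param sd_factor Threshold in baseline SDs (default 3).
#' @param sustain_ms Minimum duration the crossing must persist
#'   (default 0.2 ms).
#' @param method `"sd3"` (default, the SD criterion), `"rate"` (fixed dV/dt
#'   criterion, `dvdt_threshold` in V/s), or `"d3"` (first peak of the third
#'   derivative) as cross-check modes.
#' @param dvdt_threshold dV/dt criterion for `method = "rate"` in V/s
#'   (default 50).
#' @return Threshold voltage in mV, or `NA_real_` if no AP.
#' @export
ap_threshold <- function(t_ms, v_mv, stim_window_ms, baseline_ms = 100,
                         sd_factor = 3, sustain_ms = 0.2,
                         method = c("sd3", "rate", "d3"),
                         dvdt_threshold = 50) {
  method <- match.arg(method)
  if (missing(stim_window_ms) || length(stim_window_ms) != 2) {
    stop("a stimulus window c(start, end) in ms is required")
  }
  dt <- median(diff(t_ms))
  n <- length(v_mv)
  # central-difference dV/dt in mV/ms (= V/s)
  dvdt <- c(NA, (v_mv[3:n] - v_mv[1:(n - 2)]) / (2 * dt), NA)
  base_idx <- which(t_ms >= stim_window_ms[1] - baseline_ms &
                      t_ms < stim_window_ms[1])
  if (length(base_idx) * dt < 50) stop("baseline window shorter than 50 ms")
  win <- which(t_ms >= stim_window_ms[1] & t_ms <= stim_window_ms[2] &
                 !is.na(dvdt))
  if (method == "d3") {
    d3 <- c(NA, diff(dvdt, differences = 2) / dt^2, NA)[seq_len(n)]
    cand <- win[-c(1, length(win))]
    peaks <- cand[!is.na(d3[cand]) & d3[cand] > 0 &
                    d3[cand] >= d3[cand - 1] & d3[cand] >= d3[cand + 1]]
    # require a real spike upstroke nearby to avoid noise peaks
    peaks <- peaks[dvdt[peaks] > 10]
    return(if (length(peaks) == 0) NA_real_ else v_mv[peaks[1]])
  }
  thr <- if (method == "sd3") {
    sd_factor * sd(dvdt[base_idx], na.rm = TRUE)
  } else {
    dvdt_threshold
  }
  above <- dvdt[win] > thr
  sustain_n <- max(1L, ceiling(sustain_ms / dt))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= sustain_n)
  if (length(ok) == 0) return(NA_real_)
  v_mv[win[starts[ok[1]]]]
}

#' Input resistance from hyperpolarizing voltage steps
#'
#' Least-squares slope through the origin of the voltage steps against the
#' steady-state currents (Ohm's law); a single step reduces to `dV / dI`.
#'
#' @param delta_v_mv Voltage-step amplitudes in mV.
#' @param i_ss_pa Steady-state current responses in pA.
#' @return Input resistance in megaohms.
#' @export
input_resistance <- function(delta_v_mv, i_ss_pa) {
  stopifnot(length(delta_v_mv) == length(i_ss_pa), length(i_ss_pa) >= 1)
  if (all(i_ss_pa == 0)) stop("zero current change: resistance undefined")
  r_gohm <- sum(delta_v_mv * i_ss_pa) / sum(i_ss_pa^2)   # mV/pA = GOhm
  r_gohm * 1000
}

#' Resting membrane potential from an I-V table
#'
#' Fits a least-squares line through the holding-potential / holding-current
#' points and returns the voltage at zero current (linear interpolation of
#' the I-V plot).
#'
#' @param v_mv Holding potentials in mV (e.g. -110, -90, -70), distinct,
#'   at least two.
#' @param i_pa Measured holding currents in pA.
#' @return Resting membrane potential in mV.
#' @export
resting_potential <- function(v_mv, i_pa) {
  stopifnot(length(v_mv) == length(i_pa), length(v_mv) >= 2)
  if (anyDuplicated(v_mv)) stop("holding potentials must be distinct")
  if (diff(range(i_pa)) == 0) stop("all currents equal: I-V line undefined")
  fit <- lm(i_pa ~ v_mv)
  b <- coef(fit)
  -unname(b[1]) / unname(b[2])
}
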