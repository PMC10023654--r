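#' Generate synthetic odor-trial recordings with known responder truth
#'
#' Emulates 4-second odor pulses delivered to a cohort of cells, each
#' stimulated in `n_trials` trials. True responders carry a
#' double-exponential calcium transient starting shortly after odor onset in
#' every trial; all ratio traces receive Gaussian noise.
#'
#' @param n_cells Number of cells (default 60).
#' @param frac_responsive Fraction of truly odor-responsive cells
#'   (default 0.615, the control-group condition); exactly
#'   `round(frac_responsive * n_cells)` cells respond.
#' @param n_trials Trials per cell (default 2).
#' @param amp_drr Response amplitude in dR/R units (default 1.0; trial
#'   amplitudes vary log-normally with 20% CV).
#' @param noise_sd Ratio noise SD (default 0.02).
#' @param baseline_ratio Pre-stimulus ratio level (default 1).
#' @param stim_onset_s,stim_dur_s Stimulus onset and duration in seconds
#'   (defaults 10 and 4).
#' @param duration_s Trial length in seconds (default 30).
#' @param baseline_s Pre-onset baseline window in seconds (default 5).
#' @param n_mice Number of mice (default 6).
#' @param seed Integer seed.
#' @return A list with `trials` (list of `odor_trial` objects: `t`, `ratio`,
#'   `frame_rate_hz`, `stim_onset_s`, `stim_dur_s`, `baseline_s`, `cell_id`,
#'   `mouse_id`, `trial`) and `truth` (data frame `cell_id`, `mouse_id`,
#'   `responsive`).
#' @export
gen_odor_trials <- function(n_cells = 60, frac_responsive = 0.615, n_trials = 2,
                            amp_drr = 1.0, noise_sd = 0.02,
                            baseline_ratio = 1, stim_onset_s = 10,
                            stim_dur_s = 4, duration_s = 30, baseline_s = 5,
                            n_mice = 6, seed = 0L) {
  stopifnot(n_cells >= 1, frac_responsive >= 0, frac_responsive <= 1,
            n_trials >= 1, noise_sd >= 0,
            stim_onset_s + stim_dur_s < duration_s,
            baseline_s <= stim_onset_s)
  set.seed(seed)
  n_resp <- round(frac_responsive * n_cells)
  resp <- rep(FALSE, n_cells)
  resp[sample.int(n_cells, n_resp)] <- TRUE
  mouse <- sprintf("m%02d", rep_len(seq_len(n_mice), n_cells))
  trials <- list()
  for (i in seq_len(n_cells)) {
    for (k in seq_len(n_trials)) {
      fr <- runif(1, 7, 10)
      t <- seq(0, duration_s, by = 1 / fr)
      r <- rep(baseline_ratio, length(t))
      if (resp[i]) {
        a <- amp_drr * baseline_ratio * rlnorm(1, 0, 0.2)
        t0 <- stim_onset_s + runif(1, 0.1, 0.5)
        r <- r + a * event_waveform(t - t0, 0.2, 2)
      }
      if (noise_sd > 0) r <- r + rnorm(length(t), 0, noise_sd)
      trial <- structure(
        list(t = t, ratio = r, frame_rate_hz = fr,
             stim_onset_s = stim_onset_s, stim_dur_s = stim_dur_s,
             baseline_s = baseline_s, cell_id = sprintf("c%03d", i),
             mouse_id = mouse[i], trial = k),
        class = "odor_trial")
      trials[[length(trials) + 1]] <- trial
    }
  }
  list(trials = trials,
       truth = data.frame(cell_id = sprintf("c%03d", seq_len(n_cells)),
                          mouse_id = mouse, responsive = resp,
                          stringsAsFactors = FALSE))
}

#' Generate synthetic immunofluorescence measurements with a planted ratio
#'
#' Emulates fields of view containing labeled adult-born cells and mature
#' NeuN-positive neurons: the background-corrected adult-born cell intensity
#' is `true_ratio` times the NeuN median, with log-normal cell-to-cell
#' variability.
#'
#' @param n_fov Number of fields of view (default 10).
#' @param n_abjgc Labeled adult-born cells per FOV (default 5).
#' @param n_neun Mature NeuN-positive cells per FOV (default 40).
#' @param true_ratio Planted relative expression level (default 19.7).
#' @param neun_mean Mean background-corrected NeuN intensity in a.u.
#'   (default 100).
#' @param background Scalar background level added to all intensities
#'   (default 20).
#' @param cv Log-normal coefficient of variation of cell intensities
#'   (default 0.15).
#' @param seed Integer seed.
#' @return A list with `measurements` (data frame `fov_id`, `cell_type`,
#'   `intensity`, `background`) and `truth` (the planted ratio).
#' @export
gen_if_measurements <- function(n_fov = 10, n_abjgc = 5, n_neun = 40,
                                true_ratio = 19.7, neun_mean = 100,
                                background = 20, cv = 0.15, seed = 0L) {
  stopifnot(n_fov >= 1, n_abjgc >= 1, n_neun >= 1, true_ratio > 0, cv >= 0)
  set.seed(seed)
  sdlog <- sqrt(log(1 + cv^2))
  rows <- lapply(seq_len(n_fov), function(f) {
    neun <- neun_mean * rlnorm(n_neun, -sdlog^2 / 2, sdlog)
    ab <- true_ratio * neun_mean * rlnorm(n_abjgc, -sdlog^2 / 2, sdlog)
    rbind(
      data.frame(fov_id = f, cell_type = "abJGC", intensity = ab + background,
                 background = background, stringsAsFactors = FALSE),
      data.frame(fov_id = f, cell_type = "NeuN", intensity = neun + background,
                 background = background, stringsAsFactors = FALSE))
  })
  list(measurements = do.call(rbind, rows), truth = true_ratio)
}

#' Generate a synthetic current-clamp trace with a known AP onset
#'
#' Builds a 20 kHz voltage trace: resting baseline with Gaussian noise, then
#' from `ap_onset_ms` an exponential depolarization toward a spike peak
#' followed by repolarization. The voltage at the analytic onset is the
#' ground-truth threshold reference.
#'
#' @param rest_mv Resting potential in mV (default -60).
#' @param ap_onset_ms Time of depolarization onset in ms (default 150;
#'   `NA` produces a spikeless trace).
#' @param onset_v_mv Membrane voltage at depolarization onset (default -40).
#' @param peak_mv Spike peak in mV (default 30).
#' @param rise_tau_ms Exponential rise time constant in ms (default 0.3).
#' @param duration_ms Trace duration in ms (default 300).
#' @param stim_start_ms Stimulus window start in ms (default 100).
#' @param noise_sd_mv Baseline voltage noise SD in mV (default 0.05).
#' @param sampling_khz Sampling rate in kHz (default 20).
#' @param ramp_mv_per_ms Subthreshold depolarization slope from stimulus
#'   start to AP onset (default computed to reach `onset_v_mv`).
#' @param seed Integer seed.
#' @return A list with `t_ms`, `v_mv`, `stim_window_ms`, and
#'   `onset_v_mv` (ground truth; `NA` if spikeless).
#' @export
gen_ap_trace <- function(rest_mv = -60, ap_onset_ms = 150, onset_v_mv = -40,
                         peak_mv = 30, rise_tau_ms = 0.3, duration_ms = 300,
                         stim_start_ms = 100, noise_sd_mv = 0.05,
                         sampling_khz = 20, ramp_mv_per_ms = NULL,
                         seed = 0L) {
  set.seed(seed)
  t <- seq(0, duration_ms, by = 1 / sampling_khz)
  v <- rep(rest_mv, length(t))
  if (!is.na(ap_onset_ms)) {
    if (is.null(ramp_mv_per_ms)) {
      ramp_mv_per_ms <- (onset_v_mv - rest_mv) / (ap_onset_ms - stim_start_ms)
    }
    ramp_idx <- t >= stim_start_ms & t < ap_onset_ms
    v[ramp_idx] <- rest_mv + ramp_mv_per_ms * (t[ramp_idx] - stim_start_ms)
    sp <- t >= ap_onset_ms & t < ap_onset_ms + 2
    v[sp] <- peak_mv - (peak_mv - onset_v_mv) *
      exp(-(t[sp] - ap_onset_ms) / rise_tau_ms)
    post <- t >= ap_onset_ms + 2
    v[post] <- rest_mv + (v[max(which(sp))] - rest_mv) *
      exp(-(t[post] - (ap_onset_ms + 2)) / 5)
  }
  if (noise_sd_mv > 0) v <- v + rnorm(length(t), 0, noise_sd_mv)
  list(t_ms = t, v_mv = v,
       stim_window_ms = c(stim_start_ms, duration_ms),
       onset_v_mv = if (is.na(ap_onset_ms)) NA_real_ else onset_v_mv)
}
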