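#' Relative ratio change from a pre-stimulus baseline
#'
#' Computes dR/R = (R - R0) / R0, with R0 the mean ratio over the
#' `baseline_s` seconds preceding stimulus onset.
#'
#' @param trial An `odor_trial` (see [gen_odor_trials()]): list with `t`,
#'   `ratio`, `frame_rate_hz`, `stim_onset_s`, `stim_dur_s`, `baseline_s`.
#' @return The trial with a `drr` element added (same length as `t`) and the
#'   baseline `r0`.
#' @export
delta_r_over_r <- function(trial) {
  stopifnot(inherits(trial, "odor_trial"))
  idx <- trial$t >= trial$stim_onset_s - trial$baseline_s &
    trial$t < trial$stim_onset_s
  if (!any(idx)) stop("empty baseline window")
  r0 <- mean(trial$ratio[idx])
  if (r0 <= 0) stop("non-positive baseline ratio R0")
  trial$drr <- (trial$ratio - r0) / r0
  trial$r0 <- r0
  trial
}

#' Binomial (Pascal-kernel) smoothing of a trace
#'
#' Convolution with a normalized binomial kernel spanning `window_s` seconds
#' (`round(window_s * frame_rate)` samples, forced odd), with reflective
#' boundary handling. The kernel has DC gain 1.
#'
#' @param x Numeric trace.
#' @param frame_rate_hz Sampling rate in Hz.
#' @param window_s Kernel span in seconds (default 0.3).
#' @return Smoothed trace, same length as `x`.
#' @export
binomial_smooth <- function(x, frame_rate_hz, window_s = 0.3) {
  klen <- max(1L, round(window_s * frame_rate_hz))
  if (klen %% 2 == 0) klen <- klen + 1L
  if (klen > length(x)) stop("kernel longer than the trace")
  if (klen == 1L) return(x)
  kern <- choose(klen - 1, 0:(klen - 1))
  kern <- kern / sum(kern)
  pad <- (klen - 1) %/% 2
  n <- length(x)
  xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
  as.numeric(stats::filter(xp, kern, sides = 2))[(pad + 1):(pad + n)]
}

# Sharp-rise template: difference of exponentials resampled to the trial's
# frame rate, unit peak.
response_template <- function(frame_rate_hz, rise_s = 0.2, decay_s = 2) {
  tt <- seq(0, 4 * decay_s, by = 1 / frame_rate_hz)
  event_waveform(tt, rise_s, decay_s)
}

#' Detect an odor-evoked transient in one trial
#'
#' The dR/R trace is smoothed with a 0.3 s binomial filter; the baseline
#' noise is the raw-minus-smoothed residual over the pre-stimulus window.
#' Candidate transients are located by normalized cross-correlation of the
#' smoothed trace with a sharp-rise (difference-of-exponentials) template
#' within the stimulus window plus a response margin. The best candidate is
#' accepted as an odor-evoked transient if its waveform actually matches the
#' template (correlation at least `cc_min`; this is what makes the step
#' template matching rather than peak picking) and its amplitude is strictly
#' more than three times the baseline noise SD.
#'
#' @param trial An `odor_trial`.
#' @param response_margin_s Seconds past stimulus offset searched for the
#'   response peak (default 2; indicator decay outlasts the pulse).
#' @param template_rise_s,template_decay_s Template time constants in
#'   seconds (defaults 0.2 and 2).
#' @param sd_factor Detection threshold in baseline-noise SDs (default 3).
#' @param cc_min Minimum normalized cross-correlation between the smoothed
#'   candidate waveform and the template (default 0.5).
#' @param strict Use strict `>` at the threshold (default TRUE, per the
#'   detection rule); `FALSE` accepts equality.
#' @param noise_sd Optional override of the estimated baseline noise SD
#'   (e.g. a known noise level).
#' @return A list of class `trial_result`: `drr`, `smoothed`, `noise_sd`,
#'   `responded`, `amplitude` (dR/R, `NA` unless responded), `auc`
#'   (dR/R * s, `NA` unless responded), `peak_time_s`, plus trial ids.
#' @export
detect_response <- function(trial, response_margin_s = 2,
                            template_rise_s = 0.2, template_decay_s = 2,
                            sd_factor = 3, cc_min = 0.5, strict = TRUE,
                            noise_sd = NULL) {
  if (is.null(trial$drr)) trial <- delta_r_over_r(trial)
  fr <- trial$frame_rate_hz
  sm <- binomial_smooth(trial$drr, fr)
  base_idx <- trial$t >= trial$stim_onset_s - trial$baseline_s &
    trial$t < trial$stim_onset_s
  est_sd <- sd(trial$drr[base_idx] - sm[base_idx])
  if (is.null(noise_sd)) noise_sd <- est_sd
  win <- trial$t >= trial$stim_onset_s &
    trial$t <= trial$stim_onset_s + trial$stim_dur_s + response_margin_s
  widx <- which(win)
  tmpl <- response_template(fr, template_rise_s, template_decay_s)
  # sharp-rise check: dR/R must climb from candidate onset to the peak at a
# template-like rate; quantified as normalized cross-correlation
  best <- widx[1]; best_cc <- -Inf
  for (i0 in widx) {
    seg <- sm[i0:min(length(sm), i0 + length(tmpl) - 1)]
    k <- tmpl[seq_along(seg)]
    if (sd(seg) == 0 || sd(k) == 0) next
    cc <- suppressWarnings(stats::cor(seg, k))
    if (is.finite(cc) && cc > best_cc) { best_cc <- cc; best <- i0 }
  }
  ext <- best:min(length(sm), best + length(tmpl) - 1)
  ext <- ext[ext <= max(widx) + length(tmpl)]
  amp <- max(sm[ext])
  peak_i <- ext[which.max(sm[ext])]
  shape_ok <- best_cc >= cc_min
  if (noise_sd == 0) {
    warning("zero baseline noise SD: response decided by amplitude > 0")
    responded <- shape_ok && amp > 0
  } else {
    responded <- shape_ok && if (strict) amp > sd_factor * noise_sd else
      amp >= sd_factor * noise_sd
  }
  auc <- if (responded) pracma::trapz(trial$t[ext], sm[ext]) else NA_real_
  structure(list(drr = trial$drr, smoothed = sm, noise_sd = noise_sd,
                 responded = responded,
                 amplitude = if (responded) amp else NA_real_,
                 auc = auc, peak_time_s = trial$t[peak_i],
                 cell_id = trial$cell_id, mouse_id = trial$mouse_id,
                 trial = trial$trial),
            class = "trial_result")
}

#' Summarize odor responsiveness of one cell across trials
#'
#' @param results List of `trial_result` objects for one cell (each cell is
#'   stimulated at least twice in practice).
#' @param rule Minimum fraction of trials with a detected response for the
#'   cell to count as responsive (default 0.5; `>=` comparison, so 1 of 2
#'   trials qualifies).
#' @return A one-row data frame: `cell_id`, `mouse_id`, `n_trials`,
#'   `n_responded`, `responsive`, `median_amplitude`, `median_auc` (medians
#'   over responding trials; `NA` if none).
#' @export
summarize_cell <- function(results, rule = 0.5) {
  stopifnot(length(results) >= 1)
  responded <- vapply(results, function(r) r$responded, logical(1))
  amps <- vapply(results, function(r) r$amplitude, numeric(1))
  aucs <- vapply(results, function(r) r$auc, numeric(1))
  data.frame(
    cell_id = results[[1]]$cell_id, mouse_id = results[[1]]$mouse_id,
    n_trials = length(results), n_responded = sum(responded),
    responsive = mean(responded) >= rule,
    median_amplitude = if (any(responded)) median(amps[responded]) else NA_real_,
    median_auc = if (any(responded)) median(aucs[responded]) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Cohort-level odor-response summary
#'
#' Runs detection on every trial, summarizes each cell, and computes the
#' per-mouse fraction of odor-responsive cells.
#'
#' @param trials List of `odor_trial` objects (multiple trials per cell).
#' @param rule Cell-level responsiveness rule passed to [summarize_cell()].
#' @param ... Passed to [detect_response()].
#' @return A list with `cells` (per-cell summary table) and `per_mouse`
#'   (data frame `mouse_id`, `n_cells`, `fraction_responsive`).
#' @export
summarize_odor_cohort <- function(trials, rule = 0.5, ...) {
  res <- lapply(trials, detect_response, ...)
  ids <- vapply(res, function(r) r$cell_id, character(1))
  cells <- do.call(rbind, lapply(split(res, ids), summarize_cell, rule = rule))
  rownames(cells) <- NULL
  per_mouse <- do.call(rbind, lapply(split(cells, cells$mouse_id),
    function(d) data.frame(mouse_id = d$mouse_id[1], n_cells = nrow(d),
                           fraction_responsive = mean(d$responsive),
                           stringsAsFactors = FALSE)))
  rownames(per_mouse) <- NULL
  list(cells = cells, per_mouse = per_mouse)
}
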