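#' Simulation settings for spontaneous-activity trace cohorts
#'
#' Defines a synthetic cohort of ratiometric calcium recordings emulating
#' 2-minute awake recordings at 7--10 Hz: a fraction of cells shows
#' spontaneous calcium fluctuations (double-exponential ratio events), the
#' rest stay at baseline; every trace carries slow baseline wander
#' (physiological drift and slow imaging instabilities) plus Gaussian noise
#' on the ratio.
#'
#' @param n_cells Number of cells (default 60, assigned round-robin to
#'   `n_mice` mice).
#' @param frac_fluctuating Fraction of cells carrying fluctuation events, in
#'   \[0, 1\] (default 0.6). Exactly `round(frac_fluctuating * n_cells)` cells
#'   are labeled fluctuating.
#' @param frame_rate_range Per-cell frame rate drawn uniformly from this
#'   range in Hz (default c(7, 10)).
#' @param duration_s Recording duration in seconds (default 120).
#' @param baseline_ratio Baseline FRET ratio (default 1).
#' @param event_rate_hz Mean event rate of fluctuating cells in Hz
#'   (default 0.12, i.e. about 14 events per 2-minute trace).
#' @param event_amp Event peak amplitude in ratio units (default 0.5).
#' @param event_tau_rise_s,event_tau_decay_s Event rise and decay time
#'   constants in seconds (defaults 0.5 and 2).
#' @param noise_sd Gaussian noise SD on the ratio (default 0.01).
#' @param drift_amp Peak amplitude of the slow (0.005--0.03 Hz) baseline
#'   wander in ratio units (default 0.1; 0 disables drift).
#' @param n_mice Number of mice the cells are split across (default 8).
#' @param seed Integer seed; fixed seed gives identical output.
#' @return A list of class `trace_sim_spec`.
#' @export
trace_sim_spec <- function(n_cells = 60, frac_fluctuating = 0.6,
                           frame_rate_range = c(7, 10), duration_s = 120,
                           baseline_ratio = 1, event_rate_hz = 0.12,
                           event_amp = 0.5, event_tau_rise_s = 0.5,
                           event_tau_decay_s = 2, noise_sd = 0.01,
                           drift_amp = 0.1, n_mice = 8, seed = 0L) {
  stopifnot(n_cells >= 1, frac_fluctuating >= 0, frac_fluctuating <= 1,
            duration_s > 0, noise_sd >= 0, drift_amp >= 0,
            event_tau_rise_s > 0,
            event_tau_decay_s > event_tau_rise_s, n_mice >= 1)
  if (any(frame_rate_range <= 0)) stop("frame rates must be positive")
  structure(as.list(environment()), class = "trace_sim_spec")
}

# Double-exponential event waveform, normalized to unit peak.
event_waveform <- function(t, tau_rise, tau_decay) {
  w <- exp(-t / tau_decay) - exp(-t / tau_rise)
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  peak <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  ifelse(t < 0, 0, w / peak)
}

#' Generate a synthetic cohort of two-channel FRET traces
#'
#' Builds the ratio signal first (baseline + events + noise) and derives the
#' two channels so that the event appears with opposite sign in the donor and
#' acceptor, as in a FRET sensor: donor `= bg + D0 * u^-0.5`, acceptor
#' `= bg + R * D0 * u^-0.5` with `u = R / baseline`. The computed ratio of
#' the emitted channels therefore reproduces the generated ratio exactly.
#'
#' @param spec A [trace_sim_spec()].
#' @return A list with `traces` (list of [dual_channel_trace()], each
#'   carrying its generated ratio in `attr(, "ratio_true")` and event count in
#'   `attr(, "n_events")`) and `truth` (data frame `cell_id`, `mouse_id`,
#'   `group`, `fluctuating`, `n_events`, `frame_rate_hz`).
#' @export
gen_traces <- function(spec) {
  stopifnot(inherits(spec, "trace_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  n_fluct <- round(spec$frac_fluctuating * n)
  fluct <- rep(FALSE, n)
  fluct[sample.int(n, n_fluct)] <- TRUE
  mouse <- sprintf("m%02d", rep_len(seq_len(spec$n_mice), n))
  traces <- vector("list", n)
  truth <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      mouse_id = mouse, group = "control",
                      fluctuating = fluct, n_events = 0L,
                      frame_rate_hz = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    fr <- runif(1, spec$frame_rate_range[1], spec$frame_rate_range[2])
    t <- seq(0, spec$duration_s, by = 1 / fr)
    r <- rep(spec$baseline_ratio, length(t))
    if (spec$drift_amp > 0) {
      # cell-specific baseline wander: one dominant slow sinusoid plus two
      # weaker harmonics (random frequencies, phases, amplitudes); the
      # dominant component keeps the trace away from its mid-level most of
      # the time, as slow wander does in real recordings
      amp_i <- spec$drift_amp * rlnorm(1, 0, 0.3)
      w <- c(1, 0.25 * runif(1), 0.1 * runif(1))
      w <- w / sum(w)
      for (h in 1:3) {
        fh <- runif(1, 0.004, 0.02)
        r <- r + amp_i * w[h] * sin(2 * pi * fh * t + runif(1, 0, 2 * pi))
      }
    }
    n_ev <- 0L
    if (fluct[i]) {
      n_ev <- rpois(1, spec$event_rate_hz * spec$duration_s)
      if (n_ev == 0L) n_ev <- 1L   # a fluctuating cell carries >=1 event
      onsets <- sort(runif(n_ev, 0, spec$duration_s - 4 * spec$event_tau_decay_s))
      for (t0 in onsets) {
        r <- r + spec$event_amp *
          event_waveform(t - t0, spec$event_tau_rise_s, spec$event_tau_decay_s)
      }
    }
    if (spec$noise_sd > 0) r <- r + rnorm(length(t), 0, spec$noise_sd)
    r <- pmax(r, 0.05)   # guard: ratio stays positive
    u <- r / spec$baseline_ratio
    d0 <- 400
    bg_c <- 80; bg_v <- 100
    cer <- bg_c + d0 * u^(-0.5)
    ven <- bg_v + r * d0 * u^(-0.5)
    tr <- dual_channel_trace(t, ven, rep(bg_v, length(t)), cer,
                             rep(bg_c, length(t)), frame_rate_hz = fr,
                             cell_id = truth$cell_id[i], mouse_id = mouse[i],
                             group = "control")
    attr(tr, "ratio_true") <- r
    attr(tr, "n_events") <- n_ev
    traces[[i]] <- tr
    truth$n_events[i] <- n_ev
    truth$frame_rate_hz[i] <- fr
  }
  list(traces = traces, truth = truth)
}

#' Simulation settings for saltatory 3-D migration tracks
#'
#' Emulates soma positions monitored every 15 minutes for 4 hours: migratory
#' cells alternate pauses and moves (a move occurs per interval with
#' probability `p_move`, with a displacement of `step_scale_um` in a random
#' 3-D direction); all recorded positions carry isotropic Gaussian
#' localization jitter.
#'
#' @param n_cells Number of cells (default 30).
#' @param frac_migratory Fraction of truly migratory cells (default 0.33,
#'   the per-mouse fraction observed in control recordings).
#' @param p_move Per-interval move probability for migratory cells
#'   (default 0.4, a saltatory pause/move mix).
#' @param step_scale_um Displacement of a moving interval in micrometers
#'   (default 10).
#' @param jitter_um Localization noise SD per axis in micrometers
#'   (default 0.5).
#' @param n_intervals Number of 15-minute intervals (default 16, i.e. 17
#'   stacks over 4 h).
#' @param seed Integer seed.
#' @return A list of class `track_sim_spec`.
#' @export
track_sim_spec <- function(n_cells = 30, frac_migratory = 0.33, p_move = 0.4,
                           step_scale_um = 10, jitter_um = 0.5,
                           n_intervals = 16, seed = 0L) {
  stopifnot(n_cells >= 1, frac_migratory >= 0, frac_migratory <= 1,
            p_move >= 0, p_move <= 1, jitter_um >= 0, n_intervals >= 1)
  structure(as.list(environment()), class = "track_sim_spec")
}

rand_unit_vec <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate synthetic cell tracks with known migratory ground truth
#'
#' @param spec A [track_sim_spec()].
#' @return A list with `tracks` (list of data frames `t_min`, `x_um`, `y_um`,
#'   `z_um` of class `cell_track`, with `cell_id`, `mouse_id`, `session`
#'   attributes) and `truth` (data frame `cell_id`, `migratory`,
#'   `n_move_intervals`).
#' @export
gen_tracks <- function(spec) {
  stopifnot(inherits(spec, "track_sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells
  n_mig <- round(spec$frac_migratory * n)
  mig <- rep(FALSE, n)
  mig[sample.int(n, n_mig)] <- TRUE
  tracks <- vector("list", n)
  truth <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                      migratory = mig, n_move_intervals = 0L,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pos <- matrix(NA_real_, spec$n_intervals + 1, 3)
    pos[1, ] <- runif(3, 50, 500)
    n_moves <- 0L
    for (k in seq_len(spec$n_intervals)) {
      step <- c(0, 0, 0)
      if (mig[i] && runif(1) < spec$p_move) {
        step <- rand_unit_vec() * spec$step_scale_um
        n_moves <- n_moves + 1L
      }
      pos[k + 1, ] <- pos[k, ] + step
    }
    obs <- pos
    if (spec$jitter_um > 0) {
      obs <- pos + matrix(rnorm(length(pos), 0, spec$jitter_um), ncol = 3)
    }
    tr <- data.frame(t_min = 15 * (0:spec$n_intervals),
                     x_um = obs[, 1], y_um = obs[, 2], z_um = obs[, 3])
    class(tr) <- c("cell_track", "data.frame")
    attr(tr, "cell_id") <- truth$cell_id[i]
    attr(tr, "mouse_id") <- sprintf("m%02d", (i - 1) %% 5 + 1)
    attr(tr, "session") <- 8
    tracks[[i]] <- tr
    truth$n_move_intervals[i] <- n_moves
  }
  list(tracks = tracks, truth = truth)
}

#' Generate random binary dendritic trees with known morphometry
#'
#' Builds rooted trees: a soma node at the origin and, down to `depth`
#' levels, up to two daughter segments per node, each of exact length
#' `seg_len_um` in a random direction. With `prune_p > 0` daughters are
#' randomly dropped, producing pass-through nodes and variable branch
#' structure. Exact total dendritic branch length (TDBL) and branch counts
#' are recorded as ground truth.
#'
#' @param n Number of trees.
#' @param depth Tree depth (0 = soma only).
#' @param seg_len_um Segment length in micrometers.
#' @param seed Integer seed.
#' @param prune_p Probability of dropping each daughter below level 1
#'   (default 0 = full binary tree).
#' @return A list with `trees` (list of `neuron_tree` node tables) and
#'   `truth` (data frame `tree_id`, `tdbl_um`, `n_branches`).
#' @export
gen_trees <- function(n, depth, seg_len_um = 10, seed = 0L, prune_p = 0) {
  stopifnot(n >= 1, depth >= 0, seg_len_um > 0, prune_p >= 0, prune_p < 1)
  set.seed(seed)
  trees <- vector("list", n)
  truth <- data.frame(tree_id = sprintf("t%03d", seq_len(n)),
                      tdbl_um = 0, n_branches = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    nodes <- data.frame(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                        radius = 2, parent = -1L)
    # frontier: node ids of the current level
    frontier <- if (depth >= 1) 1L else integer(0)
    lvl <- 0L
    while (lvl < depth && length(frontier) > 0) {
      nxt <- integer(0)
      for (p in frontier) {
        keep <- if (lvl == 0) c(TRUE, TRUE) else runif(2) >= prune_p
        for (d in which(keep)) {
          dir <- rand_unit_vec()
          new_id <- nrow(nodes) + 1L
          prow <- nodes[nodes$id == p, ]
          nodes <- rbind(nodes, data.frame(
            id = new_id, type = 3L,
            x = prow$x + dir[1] * seg_len_um,
            y = prow$y + dir[2] * seg_len_um,
            z = prow$z + dir[3] * seg_len_um,
            radius = 0.5, parent = p))
          nxt <- c(nxt, new_id)
        }
      }
      frontier <- nxt
      lvl <- lvl + 1L
    }
    tree <- as_neuron_tree(nodes)
    trees[[i]] <- tree
    n_edges <- sum(nodes$parent > 0)
    # branch bookkeeping: a dendrite edge starts a branch when its parent is
    # the soma or carries >= 2 children
    n_children <- table(factor(nodes$parent, levels = nodes$id))
    starts <- vapply(which(nodes$parent > 0), function(j) {
      p <- nodes$parent[j]
      p == 1L || n_children[[as.character(p)]] >= 2
    }, logical(1))
    truth$tdbl_um[i] <- n_edges * seg_len_um
    truth$n_branches[i] <- sum(starts)
  }
  list(trees = trees, truth = truth)
}

#' Generate a pair of field-of-view censuses with known survival truth
#'
#' Places cells uniformly in the margin-safe analysis region of a
#' 635 x 635 x 200 um field of view (the margin band is exercised by
#' [apply_margin()] on its own); a chosen fraction survives to the second
#' session, reappearing displaced by exactly `drift_um` in a random 3-D
#' direction. Non-survivors are removed and newcomer cells (continuing
#' arrival) are added by default.
#'
#' @param n_cells Number of session-A cells (default 100).
#' @param frac_survive Fraction surviving to session B (default 0.66, the
#'   control-group survival between the two sessions).
#' @param drift_um Displacement magnitude of survivors in micrometers.
#' @param fov_um FOV extent `c(x, y, z)` in micrometers
#'   (default c(635, 635, 200)).
#' @param margin_um XY safe margin in micrometers (default 100).
#' @param newcomer_frac Newcomers added to session B as a fraction of
#'   `n_cells` (default 0.2; set 0 to disable).
#' @param seed Integer seed.
#' @return A list with `census_a`, `census_b` ([fov_census()] objects) and
#'   `truth` (data frame `cell_id`, `survived`).
#' @export
gen_census_pair <- function(n_cells = 100, frac_survive = 0.66, drift_um = 2,
                            fov_um = c(635, 635, 200), margin_um = 100,
                            newcomer_frac = 0.2, seed = 0L) {
  stopifnot(n_cells >= 1, frac_survive >= 0, frac_survive <= 1,
            drift_um >= 0, newcomer_frac >= 0)
  set.seed(seed)
  pos <- cbind(runif(n_cells, margin_um, fov_um[1] - margin_um),
               runif(n_cells, margin_um, fov_um[2] - margin_um),
               runif(n_cells, 0, fov_um[3]))
  ids <- sprintf("c%04d", seq_len(n_cells))
  n_surv <- round(frac_survive * n_cells)
  survived <- rep(FALSE, n_cells)
  survived[sample.int(n_cells, n_surv)] <- TRUE
  cells_a <- data.frame(cell_id = ids, x_um = pos[, 1], y_um = pos[, 2],
                        z_um = pos[, 3], stringsAsFactors = FALSE)
  pos_b <- pos[survived, , drop = FALSE]
  if (drift_um > 0 && nrow(pos_b) > 0) {
    # drift of exact magnitude in a random direction that stays in the FOV
    for (i in seq_len(nrow(pos_b))) {
      for (try in 1:1000) {
        cand <- pos_b[i, ] + rand_unit_vec() * drift_um
        if (all(cand >= 0) && all(cand <= fov_um)) break
      }
      pos_b[i, ] <- cand
    }
  }
  cells_b <- data.frame(cell_id = sprintf("s%04d", seq_len(nrow(pos_b))),
                        x_um = pos_b[, 1], y_um = pos_b[, 2],
                        z_um = pos_b[, 3], stringsAsFactors = FALSE)
  n_new <- round(newcomer_frac * n_cells)
  if (n_new > 0) {
    cells_b <- rbind(cells_b, data.frame(
      cell_id = sprintf("n%04d", seq_len(n_new)),
      x_um = runif(n_new, 0, fov_um[1]), y_um = runif(n_new, 0, fov_um[2]),
      z_um = runif(n_new, 0, fov_um[3]), stringsAsFactors = FALSE))
  }
  list(census_a = fov_census(cells_a, session = 14, fov_um = fov_um,
                             margin_um = margin_um),
       census_b = fov_census(cells_b, session = 25, fov_um = fov_um,
                             margin_um = margin_um),
       truth = data.frame(cell_id = ids, survived = survived,
                          stringsAsFactors = FALSE))
}

#' Simulation settings for negative-binomial count matrices
#'
#' @param n_genes Number of genes (default 5000).
#' @param n_samples_per_group Samples per group (default 2, the study's
#'   sequencing design).
#' @param groups Group labels (default control, kv, kir).
#' @param frac_de Fraction of genes planted as differentially expressed
#'   between control and both kv and kir (default 0.1).
#' @param log2fc_de Planted absolute log2 fold change (default 2).
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param lib_size_range Library-size scale factors drawn uniformly from this
#'   range (default c(0.8, 1.2), relative to a nominal library).
#' @param seed Integer seed.
#' @return A list of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 5000, n_samples_per_group = 2,
                           groups = c("control", "kv", "kir"), frac_de = 0.1,
                           log2fc_de = 2, dispersion = 0.1,
                           lib_size_range = c(0.8, 1.2), seed = 0L) {
  stopifnot(n_genes >= 1, n_samples_per_group >= 1, frac_de >= 0,
            frac_de <= 1, log2fc_de >= 0, dispersion >= 0)
  structure(as.list(environment()), class = "count_sim_spec")
}

#' Generate a raw count matrix with planted differentially expressed genes
#'
#' Baseline per-gene means are log-normal; planted DE genes are shifted by
#' `log2fc_de` (half up, half down) in every non-control group. Counts are
#' negative-binomial with the given dispersion; `dispersion = 0` yields
#' noise-free counts (the rounded expected counts).
#'
#' @param spec A [count_sim_spec()].
#' @return A list with `counts` (integer matrix genes x samples), `groups`
#'   (character vector per sample), and `truth` (data frame `gene`, `is_de`,
#'   `direction`).
#' @export
gen_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  set.seed(spec$seed)
  g <- spec$n_genes
  base_mu <- rlnorm(g, meanlog = 4, sdlog = 1.5)
  n_de <- round(spec$frac_de * g)
  is_de <- rep(FALSE, g)
  is_de[sample.int(g, n_de)] <- TRUE
  dir <- rep(0L, g)
  dir[is_de] <- sample(c(-1L, 1L), n_de, replace = TRUE)
  samples <- rep(spec$groups, each = spec$n_samples_per_group)
  n_s <- length(samples)
  libfac <- runif(n_s, spec$lib_size_range[1], spec$lib_size_range[2])
  counts <- matrix(0L, g, n_s)
  for (j in seq_len(n_s)) {
    fc <- if (samples[j] == spec$groups[1]) rep(1, g) else 2^(dir * spec$log2fc_de)
    mu <- base_mu * fc * libfac[j]
    counts[, j] <- if (spec$dispersion > 0) {
      rnbinom(g, mu = mu, size = 1 / spec$dispersion)
    } else {
      round(mu)
    }
  }
  rownames(counts) <- sprintf("g%05d", seq_len(g))
  colnames(counts) <- sprintf("%s_%d", samples,
                              sequence(rle(samples)$lengths))
  list(counts = counts, groups = samples,
       truth = data.frame(gene = rownames(counts), is_de = is_de,
                          direction = dir, stringsAsFactors = FALSE))
}
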