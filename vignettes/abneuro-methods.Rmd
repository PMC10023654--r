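---
title: "Quantifying adult-born juxtaglomerular neuron dynamics with abneuro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying adult-born juxtaglomerular neuron dynamics with abneuro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abneuro)
```

Adult-born juxtaglomerular cells (abJGCs) arrive in the olfactory-bulb
glomerular layer from adult neurogenesis and, over roughly six weeks, migrate
laterally, grow a dendritic arbor, and either integrate into the circuit or
die. abneuro implements the quantitative layer of a longitudinal in vivo
study of this process: every measurement that turns raw recordings into the
numbers on which the biology is argued — calcium-trace features and
fluctuation classification, odor-response detection, 3-D migration metrics,
morphometry, survival scoring, immunofluorescence normalization, patch-clamp
estimators, and transcript filtering — together with a synthetic-data
generator that makes each stage verifiable against known ground truth.

## Ratiometric calcium traces

Activity is read with Twitch-2B, a FRET sensor whose donor (mCerulean3) and
acceptor (cpVenus-CD) fluorescence move in opposite directions when calcium
binds. For each cell the somatic and background fluorescence of both
channels give the ratio

$$\mathrm{Ratio} = \frac{F_{\mathrm{ven}}^{\mathrm{soma}} -
F_{\mathrm{ven}}^{\mathrm{bg}}}{F_{\mathrm{cer}}^{\mathrm{soma}} -
F_{\mathrm{cer}}^{\mathrm{bg}}},$$

computed sample-wise by `compute_ratio()`. A non-positive donor denominator
is treated as an error (it indicates a mis-drawn background ROI), naming the
first offending sample. The ratio trace is low-pass filtered with a
zero-phase order-4 Butterworth filter at 0.6 Hz (`lowpass_filter()`). Two
numerical choices matter here:

* The filter order is not dictated by the measurement itself; order 4 is the
  conventional smoothing choice and is exposed as an argument.
* `signal::filtfilt()` leaves a large startup transient at this very low
  normalized cutoff (0.6 Hz against 7–10 Hz sampling). The trace is
  therefore extended by odd reflection over `12 * fs / cutoff` samples per
  side before filtering, which brings the DC response to machine precision
  and keeps the transient out of the recording.

Per-trace features (`trace_features()`):

* **basal ratio** — mean of the lowest 10% of sample values
  (`ceiling(0.1 N)` samples, selected by value).
* **maximum ratio** — maximum of the 1.5-s sliding boxcar average; only full
  windows are used, so a 2-min trace loses nothing to edge padding.
* **AUC/s** — trapezoidal integral of the trace minus a baseline, divided by
  the recording duration. The baseline defaults to the trace's own basal
  ratio (an event-area reading); zero is available for an absolute reading.
* **mid-reference crossings** — the signal's low and high state levels are
  estimated from a 100-bin histogram (modal bin of the lower and upper
  half); the crossing count is the number of sample pairs strictly
  straddling the midpoint of the two levels. Ties between equally tall bins
  take the *first* (lowest) bin of each half, the convention of the standard
  state-level estimator. We initially broke upper-half ties toward the top
  and found that with a sparse upper histogram (a cell with a handful of
  transients) this parks the high state at the trace maximum and collapses
  the count of a strongly fluctuating cell to ~2; the first-bin rule does
  not have this failure mode. Whether crossings are counted on the filtered
  or raw trace is configurable; filtered is the default.

## Fluctuation classification

Cells are classified as "with" or "without" spontaneous calcium
fluctuations by clustering the pooled crossing counts with univariate
Gaussian mixtures, selecting the number of components (1–5) by BIC
(`fit_crossing_gmm()`, built on mclust). Equal- and unequal-variance models
are searched jointly: on tight integer clusters the unequal-variance fit can
go singular, and without the equal-variance family those component numbers
would silently drop out of the BIC comparison.

Turning components into the binary label is where 1-D mixtures need care.
EM regularly describes a single low-activity cluster with two or more
nearby components; labeling only the minimum-mean component "without" then
calls half of the quiet cells fluctuating. Starting from the minimum-mean
component, we therefore merge successive components into the "without"
state while adjacent means differ by at most `merge_tol = 3` crossings —
about one fluctuation event's worth (each event contributes two crossings)
plus counting noise. Well-separated modes (tens of crossings apart) are
never merged, so a genuine three-mode population still labels the two upper
modes "with". If BIC selects a single component, the label falls back to a
threshold on the component mean (2 crossings by default). Counts are fitted
untransformed; a `log1p` option exists but performed worse on synthetic
cohorts (it compresses exactly the gap the classifier relies on).

Group comparisons (`compare_groups()`) follow the normality-gated route used
throughout the study: Shapiro–Wilk per group at 0.05; all normal leads to
Student's t-test or one-way ANOVA with Tukey contrasts, otherwise
Mann–Whitney or Kruskal–Wallis with Dunn's pairwise z tests
(Bonferroni-adjusted, with tie correction — implemented here because no
installed package provides Dunn's procedure).

## Odor responses

Odor trials express the ratio as $\Delta R/R$ relative to the mean over a
5-s pre-stimulus baseline. The trace is smoothed with a 0.3-s binomial
(Pascal-row) kernel; the raw-minus-smoothed residual over the baseline
window estimates the noise SD. Candidate transients are located by
normalized cross-correlation of the smoothed trace with a sharp-rise
difference-of-exponentials template (rise 0.2 s, decay 2 s, both
configurable) within the stimulus window plus a 2-s margin (the indicator
decays more slowly than the 4-s pulse). A candidate is accepted when

* its waveform actually matches the template (correlation at least
  `cc_min = 0.5`) — this gate is what makes the step template matching
  rather than peak picking; without it any smoothed-noise excursion above
  threshold inside the 6-s search window is called a response, a 15–20%
  per-trial false-positive rate on synthetic trials; and
* its amplitude is **strictly** greater than 3 times the baseline noise SD.
  An amplitude of exactly 3 SD is not a response.

A cell is responsive when at least half of its trials respond (so 1 of 2
qualifies); amplitude and AUC are medians over responding trials.

## Migration

Soma positions are tracked in 3-D (X, Y from the imaging plane, Z as depth
from the dura, no refractive-index correction). The step distance is the
Euclidean norm; speeds divide each step by its actual time interval and are
expressed per 15 min, so a missing stack simply lengthens one interval. A
cell is *moving* when any consecutive-timepoint translocation is strictly
greater than 4 µm — twice the 2-µm axial step of the stacks. The same 4-µm
gate, reused as the position-resolution tolerance, defines the longer-term
(session-to-session) migration flag; that threshold is not independently
measured for the multi-day case and is reported in the output metadata.

## Morphometry

Reconstructions are standard 7-column SWC. Total dendritic branch length
(TDBL) sums the Euclidean lengths of dendrite edges; branches are maximal
unbranched paths between the soma, branch points, and tips, and the primary
stem counts as a branch. Sholl profiles count crossings of the arbor with
concentric spheres at 10-µm increments centered on the soma centroid; each
segment is resampled at 0.1 µm so a chord dipping through a shell
contributes both crossings. Two degenerate-geometry rules keep the count
deterministic: a vertex lying exactly on a shell counts as a single
crossing, and radii within 1e-9 µm of a shell are snapped onto it so that
rigid rotations (which perturb coordinates at machine precision) cannot
create or destroy crossings. Shells are tested against an independent
analytic segment–sphere intersection oracle. The study's Poisson
mixed-model comparison of Sholl curves is out of scope; per-radius group
comparisons via `compare_groups()` are the documented simplification.

## Survival

Censuses from the 635 × 635 × 200 µm stacks are first trimmed by the 100-µm
XY safe margin (inclusive boundaries; Z unrestricted) so that cells leaving
the field are not scored as deaths. Survivors are then identified by a
one-to-one assignment between sessions that maximizes the number of matches
and, among those, minimizes total displacement (maximum-weight bipartite
matching with weight `BIG - distance`), gated at 4 µm **inclusive** — an
offset of exactly 4 µm survives. Optimal assignment rather than greedy
nearest-neighbor matching makes the result order-independent and resolves
near-neighbor ambiguities; newcomers beyond the gate cannot steal matches.
The gate uses 3-D distance by default (a 2-D option exists; the choice is
not determined by the measurement description and is flagged in output).

## Immunofluorescence, electrophysiology, transcript filtering

The relative pCREB level of each labeled adult-born cell is its
background-corrected pCREB fluorescence divided by the median
background-corrected pCREB fluorescence of the NeuN-positive mature neurons
in the same field of view; the Kv1.2 level is background-corrected soma
over surrounding neuropil. Negative background-corrected intensities are
clamped to zero with a warning (noise floor).

The AP threshold is the voltage at the first sustained crossing of dV/dt
(central differences) above 3 baseline SDs inside the stimulus window. The
sustain requirement (0.2 ms) is an addition: at 20 kHz the bare rule fires
on single noise samples. Cross-check modes implement the fixed
rate-of-rise criterion (default 50 V/s) and the third-derivative peak.
Input resistance is the through-origin least-squares slope of ΔV against
steady-state current; the resting potential is the zero-current intercept
of the least-squares I–V line through the −110/−90/−70 mV holding points.

Transcript filtering reproduces the printed rules on counts per million
(library size = raw column sum, no compositional normalization): the
default drops genes with CPM < 1 in ≥ 2 samples; the alternative reading
(keep genes with CPM ≥ 1 in ≥ 2 samples) is selectable, since the written
rule is ambiguous between the two. DEGs are genes whose pseudo-counted
(0.5) group-mean CPM changes strictly more than twofold between control and
either overexpression group (union by default, intersection available).
The negative-binomial GLM testing used upstream of that classification in
the original analysis is intentionally out of scope; outputs are labeled as
fold-change classifications.

## The synthetic cohorts

Every generator emits data plus a ground-truth sidecar, and downstream
tests consume only the data until scoring. Defaults are the control-group
study conditions: 60 cells over 8 mice recorded 2 min at 7–10 Hz (per-cell
frame rate drawn uniformly, so nothing may assume a fixed rate), 60% of
cells fluctuating at 0.12 events/s (10–20 transients per recording, the
range visible in control traces) with 0.5-ratio-unit double-exponential
events (rise 0.5 s, decay 2 s); 61.5% odor responders; 33% migratory cells
moving 10 µm per active interval with probability 0.4 under 0.5-µm
localization jitter; 66% survival with 2-µm re-identification drift; a
19.7-fold relative pCREB level; twofold planted expression changes at NB
dispersion 0.1.

Channel traces are derived from the generated ratio so that events appear
with opposite sign in donor and acceptor (`donor = bg + D_0 u^{-1/2}`,
`acceptor = bg + R\,D_0 u^{-1/2}`, `u = R/R_0`), which exercises the ratio
formula nontrivially while reproducing the generated ratio exactly.

One generator feature deserves emphasis: flat traces are **not** baseline
plus white noise. A stationary noisy signal crosses its own mid-reference
at the Rice rate — roughly 60–80 times per 2-min trace after 0.6-Hz
filtering, independent of the noise amplitude — which would make quiet
cells the high-crossing cluster. Real quiet traces are instead dominated by
slow baseline wander, so the generator adds a dominant slow sinusoid
(0.004–0.02 Hz) with two weaker harmonics and a per-cell log-normal
amplitude around 0.1 ratio units; the mid-reference then sits between the
wander extremes and is crossed only a few times. This is what gives the
crossing counts their bimodal structure. What passing tests show is
therefore that the pipeline recovers planted parameters under realistic
trace, track, tree, census, and count models; they do not exercise
pixel-level artifacts (motion, neuropil contamination, segmentation), which
are upstream of this package's inputs.

Known limits: on 60-cell cohorts roughly 1% of random cohorts still miss
the planted fluctuating fraction by slightly more than 10 percentage points
(worst observed −11.5 over a 110-cohort sweep) when the mixture boundary
absorbs a few low-count fluctuating cells; recovery tightens with cohort
size, as the consistency tests at n = 600 show.

## Problem sizes and determinism

All simulations in the test-suite and in `scripts/acceptance.R` are sized
to desk scale: cohorts of 60 cells (traces, odor trials), 100-cell
censuses, 100 random trees, 5000-gene count matrices with 5 samples per
group. Every stochastic step takes an explicit integer seed, and a fixed
seed reproduces outputs byte-for-byte; mixture fitting uses mclust's
deterministic hierarchical initialization, so no restart randomness enters
the classification.

```{r example}
g <- gen_traces(trace_sim_spec(n_cells = 60, seed = 1))
feats <- compute_trace_features(g$traces)
cl <- fit_crossing_gmm(feats, seed = 0)
fraction_with_fluctuations(cl)$per_group
```
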