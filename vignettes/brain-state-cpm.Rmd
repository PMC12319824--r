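---
title: "Identifying behaviorally relevant brain states with phase-synchrony dFC and CPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying behaviorally relevant brain states with phase-synchrony dFC and CPM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`statecpm` asks a temporal question about brain–behavior models: *when*
during a scan does functional connectivity predict a target, and does the
answer differ between stable subject traits and moment-to-moment behavior?
The machinery has four layers.

## Phase-coherence dynamic connectivity

Each region's cleaned time series is demeaned and its analytic signal is
formed by the FFT construction (negative-frequency half-spectrum zeroed,
positive half doubled); the argument of the analytic signal is the
instantaneous phase $\theta_i(t)$, wrapped to $(-\pi, \pi]$. Connectivity
between regions $i$ and $j$ at frame $t$ is
$A_{ij}(t) = \cos(\theta_i(t) - \theta_j(t))$: $+1$ for aligned phases, $0$
for quadrature, $-1$ for anti-alignment. One symmetric connectome per frame
is obtained; its upper triangle (row-major, diagonal excluded — the edge
convention every module and model file shares) gives $N(N-1)/2$ edge
features, 35,778 for a 268-node parcellation.

The key assumption is that the cleaned signal is narrowband enough for a
single instantaneous phase to be meaningful. This is why the preprocessing
low-pass (0.12 Hz default) matters, and why filtering must be zero-phase: a
causal filter's frequency-dependent delay would systematically bias phase
differences between regions with different spectra.

Windowed estimates are arithmetic means of the instantaneous edge values
over closed frame intervals $[c - (w-1)/2,\; c + (w-1)/2]$ around a 0-based
center $c$. Event-centered windows must be odd so equal numbers of frames
fall before and after the response. Convexity guarantees window means stay
in $[-1, 1]$, and a full-length window equals the temporal mean exactly.

## CPM with motion-partialed feature selection

Given per-subject windowed edge values, a target $y$ and the motion
covariate $z$ (scan-mean framewise displacement), the training procedure
is: partially correlate every edge with $y$ ($z$ regressed out of both
sides, Pearson correlation of the residuals, two-sided $t$ with
$df = n - 3$); keep edges with $r > 0$ and $p < 0.1$, uncorrected — the
generous, uncorrected threshold with subsequent summation is what defines
the CPM family; sum the kept edges per subject; fit one unregularized line.
Only the positive network is modeled; negative-network and combined
variants are deliberately out of scope.

Performance is the coefficient of determination on held-out predictions,
$R^2 = 1 - SS_{res}/SS_{tot}$, which can be negative and is never clipped.
The phrase "variance explained" is ambiguous between this and squared
Pearson correlation; the coefficient of determination is the stricter
reading (it punishes calibration error, not just ranking error) and is what
all outputs report. `r_squared_cor()` provides the squared-correlation
variant for sensitivity analyses.

## Split-half cross-validation and resample aggregation

Each of 50 iterations draws one random 50/50 partition; each half serves
once as training and once as test, so 50 iterations yield exactly 100
trained resamples. Per edge, the fraction of resamples in which it passed
selection forms a frequency vector; the aggregated "state model" keeps
edges at or above a 90% frequency threshold (inclusive, so exactly 90%
survives) and uses the unweighted mean of fold slopes and intercepts.
Weighting folds by performance, or weighting edge sums by frequency, are
deliberately not the defaults: the aggregated model should be a plain
consensus of its resamples, not a second-stage fit. (A frequency-weighted
scoring variant would be easy to add; the binary sum matches the
"features occurring in 90% or more of folds" construction.)

A frozen aggregated model is then evaluated two ways: on repeated random
subsamples of a held-out test set (the spread across draws quantifies
evaluation variance, reported as mean ± SD), and as a *temporal profile* —
the fixed model applied to the windowed connectivity of every timepoint of
unseen scans. A model that truly captures an event-locked state should peak
at its own training timepoint and fall off elsewhere; that is the
temporal-specificity signature `recovery_report()` scores.

## Null conditions

Two comparison conditions separate "connectivity predicts the target" from
"temporally specific connectivity predicts the target":

* **Within-scan shuffling** permutes frame order per subject (independent
  seeded permutation each, derived from one master seed by a counter-based
  substream scheme). Any order-invariant statistic — the static Fisher-z
  connectome in particular — is unchanged to machine precision, while phase
  dynamics and event alignment are destroyed.
* **Rest substitution** swaps in the subject's resting scan, truncated to
  the task scan's frame count, keeping nuisance structure but no task.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| low-pass cutoff | 0.12 | Hz | upper edge of the band where hemodynamic signal dominates; also enforces narrowband phases |
| filter | Butterworth order 5, forward–backward | — | maximally flat passband; zero phase so dFC is undistorted |
| selection threshold | p < 0.1, r > 0 | — | standard CPM; uncorrected by design |
| partial-correlation df | n − 3 | — | one covariate; degenerates to plain Pearson (df = n − 2) for a constant covariate |
| CV | 50 iterations × 2 folds | — | 100 resamples for frequency aggregation |
| frequency threshold | 0.90, inclusive | — | consensus edges only |
| behavior windows | odd, event-centered, e.g. 21–29 frames | frames | symmetric coverage around the response |
| trait windows | sweep, any length up to full scan | frames | traits have no event to center on |
| boundary policy | exclude partial windows | — | windows crossing the scan edge are dropped with a log entry, never padded |
| Fisher-z clipping | r to ±(1 − 1e−7) | — | collinear regions yield a large finite z instead of ±∞ |

Window lengths transfer across repetition times by scan-time coverage:
`equivalent_window_length(29, 0.72, 0.8, "odd")` returns 25, because the
default policy rounds the frame count *down* to the requested parity (a
"nearest" policy is available and would return 27). Rounding down is the
conservative choice — the matched window never covers more scan time than
the reference.

# The synthetic cohort generator

Real multi-subject fMRI with known behaviorally coupled states does not
exist, so the generator plants the effect directly in the measured
quantity. Regions are noisy oscillators: phase increments of
$2\pi f_i \cdot TR$ per frame ($f_i$ = 0.05 Hz base with 0.01 Hz per-region
jitter) plus Gaussian random-walk noise (SD 0.1 rad/frame). The observed
signal is the cosine of the phase plus white measurement noise (SD 0.1) and
a motion-locked global artifact scaled by the subject's framewise
displacement.

Two kinds of structure are planted:

* **A behavior state.** Two 4-region modules each lock to their own shared
  driver during one 21-frame window (default center: frame 200 of 405),
  giving exactly the 12 within-module pairs as planted edges (cross-module
  pairs follow different drivers and stay unlocked). Locking strength is
  $\kappa_s = \mathrm{clamp}(a + b z_s, 0, 1)$ with $a = 0.5$, $b = 1$, and
  $z_s \sim N(0,1)$ the subject's latent. Response time at the event trial
  is built from the *measured* mean planted-edge coherence, standardized
  across the cohort, plus Gaussian noise (SD 0.5 in standardized units,
  mapped to milliseconds as 800 ± 150 ms). The coupling sign defaults to
  "stronger locking → slower responses", which places the behaviorally
  relevant edges in the positive network that CPM models; the generic
  formula RT $= \mu - \gamma \cdot$ expression is kept, with
  $\gamma = -1$ by default.
* **A trait process.** Two other modules lock during eight 21-frame
  episodes whose onsets are drawn *per subject* — spontaneous, not
  task-locked. The trait score follows the subject's scan-wide mean
  coherence on those edges. Because episode timing is inconsistent across
  subjects, an ordered window at any fixed timepoint samples the trait
  state for some subjects and not others, whereas a temporally shuffled
  window samples the whole scan uniformly and recovers the scan-wide
  expression. This single asymmetry is what produces the framework's
  headline dissociation: shuffling helps (or at least does not hurt)
  trait prediction at mid-length windows, and clearly hurts event-locked
  behavior prediction.

All randomness flows from one master seed through named counter-based
substreams (signals, behavior, trait, motion, trials, per-subject shuffle
and rest streams), so identical seeds give byte-identical cohorts and any
single subject's draw is reproducible in isolation.

**What the generator does not emulate:** hemodynamic convolution,
autocorrelated scanner noise spectra, spatial smoothness between
neighboring parcels, image-space motion artifacts, or site/scanner
effects beyond TR. Passing tests therefore demonstrate that the pipeline
recovers phase-locked, behavior-coupled structure when it exists and stays
calibrated when it does not — not that such structure is recoverable at any
particular effect size in real data.

The reference cohort used by the test-suite is 200 subjects × 60 regions ×
405 frames at TR 0.72 s. Sixty regions (1,770 edges) keeps a full
simulate–CV–aggregate–profile cycle in the tens of seconds while leaving
the edge-selection problem genuinely high-dimensional relative to the
100-subject training halves; the region count is a config value, not a
constant, and nothing in the code depends on it.

# Numerical choices and degenerate inputs

* **Hilbert phase** is computed on the full demeaned series with no
  tapering; the frames nearest the scan boundaries are the least reliable,
  and filtered scans carry an `edge_frames` attribute marking
  $\lceil 1/(f_c \cdot TR) \rceil$ frames at each end. They are flagged,
  never dropped — full scans stay full.
* **Filtering** demeans before the forward–backward pass and restores the
  mean afterward, so a constant series passes through unchanged and the
  zero-padded filter sees no step at the boundaries.
* **Idempotence of preprocessing** is exact for the projection stages
  (confound regression and detrending commute once confounds carry no
  linear trend) but only approximate (sub-percent on interior frames) for
  the full pipeline: no finite-length zero-phase filter is exactly
  idempotent, and with broadband confounds the filtered residual regains
  small correlations with the confound columns because filtering and
  regression do not commute. The property tests assert exactly this.
* **Rank-deficient confound matrices** warn and fall back to the QR
  pseudoinverse fit; residuals remain orthogonal to the confound span.
* **Zero-variance regions** are an error in `analytic_phase()` (phase
  undefined) and `static_fc()` (correlation undefined), naming the region.
* **Empty selections** never break fold bookkeeping: a fold whose selection
  is empty contributes a flagged degenerate model that predicts the
  training mean, keeping resample counts fixed. An aggregated model whose
  active set is empty warns and predicts its intercept.
* **Partial correlation** clamps $1 - r^2$ away from zero before the $t$
  statistic, so $r = \pm 1$ yields $p = 0$ rather than NaN; edges with
  zero-variance residuals get NA and are never selected.
* **Split-half with odd n** puts the extra subject in the second half;
  both halves still serve once as training and once as test.
* **Model files** are versioned JSON at full precision (`digits = NA`);
  the reader rejects unknown versions and foreign edge conventions
  explicitly rather than guessing.

# Design decisions taken where the design was open

* **Event centers.** Models are indexed by scan timepoint; windows default
  to common (scan-level) centers from the event table rather than each
  subject's own response frame. Both are supported — pass per-subject
  centers to `window_mean()` — but common centers are what make per-model
  temporal profiles comparable across subjects.
* **Missing response times** (omitted trials) are preserved in event tables
  and excluded from modeling; imputing a behavioral value for a trial
  without a response would manufacture data.
* **Shuffling operates on parcellated frames**, not image volumes; the two
  are equivalent downstream because parcellation is frame-wise.
* **Selection p-values are two-sided** with the positivity filter applied
  to $r$; for a fixed threshold this selects the same edge set as a
  one-sided test at half the threshold, so the choice only relabels the
  threshold.
* **Sweep stride defaults to 1 frame** — profiles are computed at every
  timepoint; stride is configurable for coarser scans.

# Known limitations

* Phase coherence assumes one oscillatory component per region in the
  passband; multi-component or broadband signals fold into a single phase
  whose pairwise differences are harder to interpret.
* The instantaneous estimates are noisy by construction; everything
  stabilizing (windows, resample aggregation, frequency thresholds) trades
  temporal specificity for reliability, and the right trade-off depends on
  the behavior being modeled.
* The negative network is not modeled, cross-site harmonization is not
  implemented, and surrogate nulls that preserve autocorrelation
  (phase-randomized data) are intentionally absent — within-scan shuffling
  and rest substitution are the two supported comparisons.
* Group-level inference across models (comparing two profiles statistically)
  is out of scope; the package exports the profiles and leaves inference to
  the analyst.
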