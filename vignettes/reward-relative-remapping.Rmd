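---
title: "Reward-relative remapping analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reward-relative remapping analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewardremap)
```

## The scientific problem

Hippocampal place cells fire at restricted locations of an environment. When
a hidden reward zone is moved along a virtual-reality track, part of the
population keeps firing at its old track position (track-relative, TR),
while another part translates its field by the same distance the reward
moved, maintaining a fixed *circular* distance from the reward-zone start
(reward-relative, RR). This package implements a complete, testable
pipeline for distinguishing these populations in calcium-imaging data and
for asking *when*, at trial resolution, the population representation and
the animal's behavior switch from the old map to the new one.

The task geometry is fixed throughout: a 450-cm circular-trial track binned
into 45 bins of 10 cm, hidden 50-cm reward zones starting at 80, 200 or
320 cm, a zone switch after 30 trials, and reward omitted at random on
~15% of trials. Periodic coordinates map 0 cm to $-\pi$ and 450 cm to
$\pi$; a 50-cm span is therefore $2\pi \cdot 50/450 \approx 0.698$ rad, the
threshold used by every "within 50 cm" criterion.

## The synthetic-data generator

All tests run against simulated sessions with known ground truth
(`simulate_session()`). The generator emulates:

* **Behavior.** Per-frame position, speed and licking at 15.5 Hz (the
  imaging rate). Speed dips smoothly around the behaviorally-targeted zone;
  licking has a low baseline (0.2 Hz), an anticipatory ramp over the 50 cm
  before the zone (up to 8 Hz), consummatory licking after delivery, and
  search licking through the zone on omission trials. Trials end in a
  teleport period of 1–5 s (5–10 s after omissions) during which position is
  invalid; the distance run in the teleport is recorded for the
  trial-variability control. After the switch, anticipatory licking and
  slowing keep targeting the *old* zone for `lick_lag_trials` (default 2)
  trials — animals search the previous location before adapting — while
  reward delivery follows the new zone immediately. This adaptation lag is
  what the neural-versus-behavioral remap-timing analysis is designed to
  measure.
* **Neurons.** Ground-truth classes: TR (fixed track anchor), RR (fixed
  phase relative to the zone start, with half the anchors drawn from a
  wrapped-normal bump centered 0.35 rad ≈ 25 cm after the zone start to
  reproduce the over-representation of post-reward positions), appearing
  and disappearing cells (gain 0 in one trial set), randomly remapping
  cells (independent anchors per set), untuned cells, and optionally
  speed-coupled cells for the interneuron-exclusion filter. Events are
  Poisson draws from a circular-Gaussian rate (field s.d. 12 cm, peak
  ~3 events/s, baseline 0.05 events/s) with per-trial center jitter
  (s.d. 10 cm) and log-normal gain variability (s.d. 0.25). dF/F is the
  event train convolved with a single-exponential calcium kernel
  ($\tau = 0.7$ s) plus Gaussian noise (s.d. 0.05).

Defaults were chosen once as the study conditions: a default session has
400 neurons (110 TR, 110 RR, 30 appearing, 30 disappearing, 40 randomly
remapping, 80 untuned), 80 trials with the switch after trial 30. The
10-cm jitter deliberately places spatial-peak estimates in the noisy-but-
estimable regime so that shuffle tests are exercised near threshold. One
RNG stream drives behavior and each neuron draws from a sub-stream derived
by hashing (seed, neuron id), so adding neurons never perturbs behavior.

**What the simulator does not emulate** — and hence what green tests do
*not* show about real data: slow drift within a trial set, theta-timescale
structure, correlated noise across neurons, non-Poisson burstiness,
photobleaching, and behavioral idiosyncrasies (variable trial pacing,
licking lapses). Ground-truth recovery rates quantify the pipeline's
behavior under the stated noise model, not biological effect sizes.

## Place cells and spatial information

Activity is speed-filtered (≥ 2 cm/s), binned into 45 bins and
occupancy-normalized within trials (`bin_by_position()`). Spatial
information uses deconvolved events:
$\mathrm{SI} = \sum_i p_i (f_i/f)\log_2(f_i/f)$ with whole-session
occupancy $p_i$ (the same speed filter is applied to occupancy as to
activity). Significance comes from circularly shifting each cell's
activity relative to position independently within each trial, by a
uniform offset between ⌈frame rate⌉ samples (~1 s) and the trial length,
100 times; true SI must exceed the 95th percentile of the null values
*pooled across all cells* of the session (computed per trial set), which
is more stringent than a per-cell comparison. A place cell is significant
in either the pre- or the post-switch trial set.

## Remapping taxonomy and RR criteria

Spatial peaks are argmax bins of trial-averaged unsmoothed binned dF/F,
ties broken toward the lowest bin. The taxonomy (TR / appearing /
disappearing / remap near reward / remap far from reward) follows the
50-cm rules; RR cells require (1) reward-relative peaks within 0.698 rad
across the switch and (2) a circular cross-correlogram of the
reward-aligned trial-averaged dF/F whose peak beats the 97.5th percentile
of a per-trial circular-shift null (500 shuffles) at a lag within 5 bins.
Appearing/disappearing cells that satisfy both are reassigned RR
(precedence RR > remap near/far > appearing/disappearing). Note that the
RR criteria accept ~20% of randomly remapping cells by construction (the
candidate window is 100 cm of a 450-cm circle); the population-level
permutation test exists precisely to separate true RR structure from this
chance rate. Its above-chance fraction is defined as (observed count
within ±0.698 rad − mean shuffle count in that window) / number of place
cells, with significance when the observed count exceeds the 95th
percentile of shuffle window counts; the shuffle keeps each pre-switch
peak and circularly shifts the post-switch activity by 0–44 bins, which
shifts the post peak deterministically — the implementation exploits that
identity instead of re-running the argmax.

## Sequences, decoding, fields

Sequence preservation is quantified with the Jammalamadaka–SenGupta
circular–circular correlation between cross-validated peak positions
(sorted on odd pre-switch trials, evaluated on even pre-switch and on
post-switch trials), with a two-tailed cell-identity permutation P,
$P = (n_{|\rho_{shuf}|\ge|\rho_{obs}|}+1)/(N+1)$; 1000 permutations give a
floor of 1/1001. The estimator choice follows the phase-precession
lineage of the method; an exhaustive-enumeration mode (n ≤ 7) provides an
independent oracle in the tests.

The decoder maps deconvolved activity linearly onto $(\cos y, \sin y)$
with a small ridge ($\lambda = 10^{-3}$) and reads out
$\hat y = \mathrm{atan2}$; the per-sample score is $\cos(y - \hat y)$.
An iterated circular–linear regression would be an alternative
parameterization; the two-target least-squares form was chosen for
determinism and closed-form fitting. Occupancy is equalized across the 45
reward-relative phase bins by seeded downsampling without replacement to
the minimum bin count; chance is 100 refits on sessions in which each
neuron's time series is independently circularly shifted by ≥ 1 sample.

Field detection thresholds the 10-cm-smoothed trial-averaged tuning at
20% of maximum (regions ≥ 20 cm). A trial counts as significantly active
when its in-field activity exceeds the mean + 1 s.d. of the pooled
in-field samples across the 30-trial set; at least 8 active trials keep a
field. (Comparing each trial's in-field mean to the mean + 1 s.d. of those
per-trial means — a plausible alternative reading — would flag only ~16%
of trials for a perfectly reliable cell and reject every field, so the
pooled-sample reading is used.) Formation laps use the first five-trial
window with ≥ 3 active trials within the bounds ± 10 cm, post-switch
statistics only; field centers of mass use raw, un-binned activity for
maximum spatial resolution, and negative shifts are backward.

## Time warping and the reward-omission index

Trials are aligned on their speed profiles by monotone piecewise-linear
warps of the position axis, fit by alternating optimization (template =
mean of warped trials; per-trial coordinate descent over a 21-point grid
per parameter, 10 random restarts for the piecewise families). The five
model families — shift, linear, piecewise 1–3 knots — are fit as a
warm-started nested chain, each family starting from the previous one's
warps and accepting only improvements, so MSE is nonincreasing along the
chain by construction. No regularization beyond monotonicity is applied.
The fitted warps are then applied, behavior-blind, to the neural
activity, and the reward-versus-omission index
$\mathrm{RO} = \sum_j(\bar r_j - \bar o_j)/\sum_j(\bar r_j + \bar o_j)$
is computed over bins from the zone start to the track end for cells with
≥ 3 omission trials and a post-zone-start peak; the package reports RO on
both warped and raw activity, which are strongly correlated.

## The encoding model

The Poisson GLM's design matrix has 156 z-scored columns: 45 raised-cosine
bases per 10-cm track-position bin (half-width 1.5 bins, unit-sum
normalized), 45 for reward-relative phase, 45 rewarded-by-position
interaction columns (the rewarded indicator switches to 1 at delivery and
stays 1 to trial end; 0 throughout omissions), and 7 cubic B-spline bases
(5 uniform knots) for each of quantile-transformed speed, acceleration and
smoothed lick rate. Fitting is elastic-net Poisson regression (mixing 0.5,
10-value penalty path chosen by fivefold trial-grouped cross-validation
inside an 85/15 trial split stratified over rewarded-before /
rewarded-after / omission). Performance is the fraction deviance explained
on held-out trials, $\mathrm{FDE} = 1 - \mathrm{dev}_{model} /
\mathrm{dev}_{null}$ against a training-mean null; cells with FDE > 0.15
enter the ablation analysis, where zeroing one variable group's
coefficients yields the relative contribution
$(\mathrm{dev}_{abl} - \mathrm{dev}_{full}) / (\mathrm{dev}_{null} -
\mathrm{dev}_{full})$ on the training (cross-validation) data, overall and
per track bin. Z-scoring statistics are computed on the full design before
splitting; computing them per training fold would avoid a minor leakage at
the cost of fold-dependent column scales — the leakage affects only
column scaling, not the response.

## Trial-resolved remap timing

Per-neuron trial × bin event maps (10-cm smoothing) are min–max scaled to
[0, 1] per neuron over the session, stacked into a trials × bins × neurons
tensor and clustered with k-means (k = 2, 100 restarts) on the flattened
trial vectors — the factorized form $X_{ijn} = \sum_k U_i^{(k)}
V_{jn}^{(k)}$ with one-hot $U$. Cluster 1 is the cluster of the earliest
trial. The two-map structure is validated by a speckled 10% holdout
(50 repetitions): uncentered test $R^2$ of the reconstruction must beat
the same statistic on data randomized by a random orthogonal rotation
across trials (paired Wilcoxon signed-rank, P < 0.05). The data are
centered across trials first: the common mean map is captured by any
clustering while the rotation destroys it, so without centering even
one-map sessions would test significant. The distance score
is the signed normalized projection of each trial onto the inter-centroid
axis, fixed at −1 on the first centroid and +1 on the second. (The
published form of this expression multiplies by the centroid *sum* rather
than the centroid *difference*, which does not evaluate to −1/+1 at the
centroids; this implementation follows the stated −1/+1 contract.) The
remap trial is the inflection $t_0$ of a 4-parameter logistic
$P(t) = a + (b-a)/(1+e^{-s(t-t_0)})$ fit by Levenberg–Marquardt with
$t_0$ bounded to the trial range and $s > 0$, initialized at the trial of
maximum score change; a fit whose amplitude $|b-a|$ stays below 0.05 is
flagged non-converged. The same pipeline applied to maximum-normalized
lick and speed maps yields behavioral remap trials; sessions lacking
convergence in any domain are excluded from lag comparisons.

## Numerical choices and degenerate inputs

* Half-open 10-cm bins; the track end wraps to bin 1. All "≤ 50 cm"
  thresholds are evaluated in phase space as ≤ 0.698132 rad.
* Unoccupied bins are NaN, never 0; correlations are pairwise-complete.
* Maximin dF/F baselining truncates its 20-s windows at trial edges
  (edge behavior is not prescribed anywhere authoritative; truncation is
  the least-surprising choice), and zero baselines yield NA with a flag.
* Argmax ties break to the lowest bin; silent cells have SI 0; degenerate
  flat tuning fails the RR correlogram without erroring; zero-variance
  inputs give NA statistics rather than exceptions wherever the quantity
  is a ratio.
* Problem sizes in the tests (sessions of 40–80 trials, tens to hundreds
  of neurons, 20–500 shuffles) were chosen as the smallest sizes at which
  each statistical property is stable; the acceptance checks run the
  default 400-neuron condition across 5 seeds.

## Serialization and interfaces

Sessions round-trip through a plain-text TSV directory
(`write_session()` / `read_session()`). The exported functions are the
pipeline interface; `run_pipeline()` orchestrates the stages with
per-stage seeds derived from one root seed, so a manifest is reproducible
from (config, seed) alone and inserting a stage does not shift the
randomness of the others.

## Known limitations

Cross-day analyses (ROI matching, recruitment, drift) operate on
user-supplied masks and label tables; the simulator generates single
sessions, so multi-day fixtures are constructed in code. Mixed-effects
modeling across animals is out of scope — the pipeline exports the
per-session tables such models consume. The decoder and GLM are linear in
their bases by design; nonlinear decoders would need their own
calibration.
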