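---
title: "Whole-brain polarity dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain polarity dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainpolarity)
```

## The phenomenon and the model

In voxelwise-normalized BOLD fMRI, each gray-matter voxel's time series is
z-scored against its own history, so every voxel spends (by construction,
under empirical terciles; approximately, under Gaussian cuts) a third of the
scan in the top, middle and bottom third of its own *intrinsic activation
profile*. Nothing, however, constrains how many voxels sit in the same
tercile *simultaneously*. The analyses in this package quantify transient
whole-brain states in which an unusually large proportion of voxels is
simultaneously near its own ceiling or floor — "polarized" states — and
relate their occupancy to diagnosis, symptoms and network connectivity.

The processing chain is:

1. **Intrinsic activation levels (IALs).** Each voxel row of the masked
   $V \times T$ matrix is z-scored (`zscore_voxels()`, sample-SD
   convention) and discretized into $\{-1, 0, +1\}$ (`discretize_ial()`).
2. **Polarity proportions.** Per TR, $h(t), l(t), n(t)$ are the fractions
   of voxels at level $+1$, $-1$, $0$; $h + l + n = 1$ exactly
   (`polarity_proportions()`).
3. **Dynamic polarity regimes (dPRs).** The pooled $(h,l,n)$ 3-vectors from
   all subjects are k-means clustered with $k = 3$ (`fit_dpr()`), yielding
   a Polarized-High, a Polarized-Low and a Non-Polarized regime, plus
   per-subject occupancy rates.
4. **Polarity metric.** $\Pi(t) = -\,h_z(t)\,l_z(t)$ with $h_z, l_z$ the
   per-subject z-scored proportion series: large and positive when one of
   $h, l$ is far above $1/3$ while the other is far below, near zero when
   the brain is balanced, negative when both deviate together
   (`polarity_metric()`).
5. **Polarity participation maps (PPMs).** Per subject,
   $\mathrm{PPM}(v) = \frac{\#\{t: \text{High}, IAL_v(t)=+1\} +
   \#\{t: \text{Low}, IAL_v(t)=-1\}}{\#\{t: \text{polarized}\}} \in [0,1]$
   (`compute_ppm()`), clustered across subjects with $k = 2$ and projected
   onto z-scored, thresholded network maps (`network_participation()`).
6. **Co-polarization patterns (CoPPs).** The full polarity-coded volumes
   (one $V$-vector per subject-TR) are clustered (`fit_copps()`); each
   centroid's grand mean $\mu_i$ is tested against a conservative Gaussian
   null (below), and group-level transition matrices over pattern labels
   yield most-probable distinct-state itineraries
   (`most_probable_itinerary()`).
7. **Connectivity statistics.** Band-passed network timecourses, tapered
   22-TR sliding-window correlations, connectivity-state clustering, the
   polarized-occupancy-within-window t-tests, and nuisance-corrected
   regressions with BH-FDR control (`sliding_window_fnc()`,
   `dpr_within_dfnc_test()`, `nuisance_regression()`,
   `fnc_mediation_comparison()`).

## Discretization: two modes, on purpose

A fixed Gaussian cut at $\pm\Phi^{-1}(2/3) \approx \pm 0.431$ only yields
exact thirds when the z-scored series is exactly Gaussian; empirical
terciles guarantee thirds by construction but let the cut wander per voxel.
Both readings are defensible descriptions of "the top/middle/bottom third
of the voxel's profile", so both are implemented:

* `gaussian_threshold` (default): cuts at $\pm\Phi^{-1}(2/3)$, carried at
  full precision. Values exactly at a cut go to Neutral — a measure-zero
  event on real data, but a deterministic rule is required for integer
  synthetic inputs.
* `empirical_tercile`: rank-based thirds, group sizes equal within one
  sample (for $T = 160$: 53/54/53, the middle group taking the remainder);
  value ties are broken by time index so the result is deterministic.

The tercile level of analysis is what makes the downstream pipeline
insensitive to the float32 on-disk storage and to the sample-vs-population
SD convention in voxel z-scoring (sample SD, documented in
`zscore_voxels()`). One place the convention *does* matter: the polarity
metric z-scores $h$ and $l$ with the population SD so that
$\mathrm{mean}(\Pi) = -\mathrm{cor}(h, l)$ holds exactly, a useful
closed-form check; with sample-SD z-scores it holds only up to
$(T-1)/T$.

## The conservative strong-polarization null

CoPP centroid entries are means of $\{-1,0,+1\}$ values, so under an iid
uniform null each has mean 0 and variance $2/3$, and the grand mean
$\mu_i$ of a centroid computed from $c_i$ volumes of $V$ voxels would be
approximately $N(0, 1/(V c_i))$. At study scale $V c_i$ exceeds $10^7$,
making that null vacuous: any visible $\mu_i$ is "significant". Two
deliberate reductions produce a usable, conservative test:

* all TRs of a subject count as one dependent sample, so cluster $i$
  contributes $n_i = n_{\text{subjects}} \cdot r_i$ effective samples
  ($r_i$ = population occupancy rate);
* space is reduced to 47 independent units (the number of meaningful
  group-ICA networks in the motivating decomposition), configurable via
  `n_independent_units`.

The null becomes $N(0, 1/(47\, n_i))$ and a pattern is *strongly
polarized* when $|\mu_i|$ exceeds its upper-$\alpha$ quantile
($\alpha = 0.001$; "each" tail by default, a "total" two-sided option is
exposed). The threshold is strictly decreasing in $n_i$. Note the
consequence at desk scale: with 16 synthetic subjects, $n_i \approx 2$–3
puts the threshold near 0.3 while attainable $|\mu_i|$ is ~0.15, so
nothing is classified as strong — the test is honest about small cohorts,
and the analysis scripts fall back to the most-polarized centroids when
choosing itinerary sources. Fixture tests with pervasively polarized
planted templates (where $|\mu_i|$ approaches 1) verify the
classification logic itself.

## Itineraries

Group transition matrices pool one-step counts over a group's subjects
(scan boundaries contribute nothing); "group-averaged" could also mean
averaging per-subject row-normalized matrices, so both are exposed
(`method = "pooled"` is the default — it weights subjects by observed
transitions and is well-defined even when a subject never visits a state).
Itineraries follow the most probable *off-diagonal* transition repeatedly
until a state recurs, splitting the walk into a transient and a periodic
orbit; self-transition probabilities are reported separately. Argmax ties
are broken by the lowest state index, deterministically. By pigeonhole the
walk closes within $k$ distinct steps; an all-zero off-diagonal row ends
the walk with an empty orbit, flagged absorbing. The iterative extraction
is tested against a brute-force successor-map oracle over 100 random
5-state chains.

## Connectivity stage conventions

* **Band-pass**: 5th-order Butterworth, zero-phase via forward-backward
  filtering, default band [0.05, 0.15] Hz at TR = 2 s.
* **Taper**: a rectangle convolved with a Gaussian of sd 3 TRs (the common
  convention for "tapered rectangular" sliding windows), central 22
  weights kept; weighted Pearson correlations via `stats::cov.wt`.
* **Window-to-TR alignment**: a window starting at TR $s$ covers TRs
  $[s, s+21]$ (full span); polarized occupancy of a window is the fraction
  of its TRs in a polarized regime.
* **Static FNC** is the exact one-window untapered limit of the sliding
  estimator (tested).
* **Regressions**: correlations are Fisher-z transformed before modeling;
  gender enters as a binary factor; symptom categories are z-scored and
  the off-target categories included as covariates in symptom analyses.

## The synthetic cohort generator

No clinical data ship with the package; `generate_cohort()` produces
cohorts with the statistical structure the analysis assumes:

* voxel series $= g \cdot s_v \cdot g(t) + \text{network component} +
  \text{white noise}$, where $g(t) \in \{+1,-1,0\}$ follows a
  geometric-dwell 3-state chain (polarized dwell 5 TRs by default, Neutral
  1.5× longer and entered preferentially on exit, so the balanced regime
  is the most occupied);
* $s_v \in [0,1]$ is a smooth blob participation field with a
  ventricle-like central zone of zero participation;
* network components are band-limited [0.05, 0.15] Hz timecourses under
  approximately disjoint smooth spatial maps;
* group gains default to 1.4 (HC) versus 0.7 (SZ, with per-subject
  variation); patient positive-symptom scores are generated to correlate
  with each subject's realized gain suppression; meanFD is group-independent
  by default, with a `motion_confound` scenario (equal gains, motion both
  group-linked and gain-suppressing) for exercising nuisance correction.

Defaults were fixed once, by simulation, to place the cohort in a regime
where the three-regime structure is recoverable and the diagnosis effect
on polarized occupancy has a stable sign at desk-scale cohort sizes
(8–16 subjects): the default group difference (~0.2 occupancy units) is
deliberately larger than a realistic clinical effect, because a clinical
effect of a few percent of scan time is undetectable at $n = 16$ and the
generator's purpose is end-to-end testability, not effect-size realism.
The grid default (16×16×8, ellipsoidal mask of ~1100 voxels) keeps full
pipeline runs in seconds while leaving room for spatial structure.

What the generator does **not** emulate: hemodynamic convolution, spatial
autocorrelation of scanner noise, multi-site effects, non-stationary
motion artifacts, or any anatomically meaningful geometry. Passing tests
therefore show the *pipeline* is correct and the *statistics* behave as
designed (type-I control, sign recovery, parameter recovery) — not that
the clinical effects would reproduce on real scans.

## Numerical choices and degenerate inputs

* Constant voxel time series cannot be z-scored; they are excluded at load
  with a warning (and `zscore_voxels()` errors if one slips through).
* k-means runs are seeded best-of-`replicates` restarts (default 50 for
  regime fits; analysis scripts use 10–20); replicates that produce an
  empty cluster are re-seeded; all-identical inputs raise a degeneracy
  error. Regime clusters are relabeled canonically (argmax-$h$ → High,
  argmax-$l$ → Low, remainder Neutral; ties to the lowest index) so labels
  are stable across initializations.
* A subject with no polarized TRs has no defined PPM; the map is flagged
  invalid and excluded from clustering with a warning.
* A constant mediator in the FNC comparison cannot absorb anything; model
  B falls back to model A with a warning rather than erroring.
* Problem sizes in the test suite and analysis scripts (grids of 500–1100
  voxels, 60–160 TRs, 8–24 subjects, 5–20 k-means restarts) were chosen so
  a full run completes in minutes on a single core; all are parameters,
  not constants, and scale up unchanged.

## Known limitations

* The strong-CoPP criterion is intentionally conservative and effectively
  inert below a few dozen subjects (see above).
* The elbow criterion is reported as a curve (`elbow_curve()`); no
  automatic $k$ selection is performed — $k$ defaults follow the protocol
  (3 regimes, 2 PPM clusters, 13 CoPPs, 5 connectivity states) and are
  arguments everywhere.
* Convolutional dictionary learning is out of scope by design: the
  channel-encoding module produces the exact one-hot representation such
  solvers consume and scores externally supplied dictionaries and
  nonnegative activations (`element_contributions()`), but does not learn
  dictionaries.
* Spectral analysis of $\Pi(t)$ is not implemented; the metric itself and
  its separation across regime labels are.
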