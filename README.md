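# brainpolarity

Whole-brain **polarity regime dynamics** for resting-state fMRI: an R
implementation of a voxel-intrinsic analysis framework in which each
gray-matter voxel's BOLD time series is z-scored against its own history,
discretized into intrinsic activation levels (IALs) in {−1, 0, +1}, and the
resulting whole-brain polarity structure is summarized at several scales —
per-TR proportion vectors and their clustered *dynamic polarity regimes*
(dPRs), a scalar polarity metric Π(t), voxelwise *polarity participation
maps* (PPMs), brainwide *co-polarization patterns* (CoPPs) with a
conservative significance test for pervasive polarization, most-probable
state itineraries, and couplings with sliding-window functional network
connectivity. It is aimed at researchers studying supra-network whole-brain
BOLD dynamics and their disruption in clinical populations (the motivating
case is schizophrenia).

## The core quantities

For gray-matter voxels v ∈ V with z-scored series z_v(t):

* **IAL**: IAL_v(t) = +1 if z_v(t) > Φ⁻¹(2/3) ≈ 0.431, −1 if
  z_v(t) < −Φ⁻¹(2/3), else 0 (an empirical-tercile mode guarantees exact
  thirds per voxel instead).
* **Proportions**: h(t), l(t), n(t) = fraction of voxels at +1 / −1 / 0;
  h + l + n = 1. Pooled (h, l, n) 3-vectors across subjects are k-means
  clustered (k = 3) into Polarized-High, Polarized-Low and Non-Polarized
  regimes; per-subject occupancy rates are the main clinical endpoint.
* **Polarity metric**: Π(t) = −h_z(t)·l_z(t), rising with polarization,
  ≈0 when balanced, negative when h and l deviate together.
* **PPM**: per subject, PPM(v) = (#{t: High regime, IAL_v = +1} +
  #{t: Low regime, IAL_v = −1}) / #{t: polarized regime} ∈ [0, 1].
* **Strong CoPPs**: clustered polarity-coded volumes whose centroid grand
  mean |μ_i| exceeds the α = 0.001 quantile of the conservative null
  N(0, 1/(47·n_i)), with n_i = n_subjects · occupancy_i.
* **Statistics**: nuisance-corrected OLS (age, gender, meanFD; symptom
  models additionally correct for the other symptom categories),
  Benjamini–Hochberg FDR, two-sample t-tests of polarized-regime occupancy
  within connectivity-state windows, and a mediation-style comparison of
  static-FNC group effects with and without the polarized-occupancy
  covariate.

No clinical data are bundled: a first-class synthetic generator
(`generate_cohort()`) produces 4D cohorts with the structure the analysis
assumes (regime-driven voxel signals under a smooth participation field,
band-limited network components, diagnosis-linked polarization suppression,
symptom scores tracking the suppression), so the whole pipeline is testable
end to end.

## Worked example

The numbered scripts under `analysis/` run the study on a simulated
16-subject cohort (8 HC, 8 SZ; 1104 masked voxels × 160 TRs at TR = 2 s)
and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_polarity_regimes.R
Rscript analysis/03_participation.R
Rscript analysis/04_copp_itineraries.R
Rscript analysis/05_connectivity.R
```

Stage 2 prints the fitted regime centroids and the diagnosis effect:

```
dPR centroids (h, l, n):
                   h     l     n
Polarized-High 0.415 0.264 0.321
Polarized-Low  0.273 0.401 0.326
Non-Polarized  0.335 0.328 0.337

Mean polarized occupancy by group:
   HC    SZ
0.453 0.258

Diagnosis effect on polarized occupancy (nuisance-corrected):
             response predictor       beta         t            p
1 polarized_occupancy  SZ vs HC -0.2545557 -6.126339 7.453171e-05
```

Read: the clustering recovers one regime with far more than a third of
voxels high (h = 0.415), its mirror image, and a balanced regime near
(1/3, 1/3, 1/3); patients occupy the polarized regimes less than controls
(0.258 vs 0.453 of scan time), and the diagnosis coefficient from the
age/gender/motion-corrected regression is negative and significant — the
suppression the generator planted. Stage 3 shows controls concentrating in
the high-participation PPM cluster (6/8 HC vs 1/8 SZ), stage 4 reports
negative diagnosis effects on occupancy of the most polarized
co-polarization patterns and the group itineraries out of them, and stage
5 shows polarized-regime occupancy significantly elevated/depressed within
specific connectivity-state windows.

Equivalent programmatic entry point:

```r
library(brainpolarity)
res <- run_pipeline(pipeline_config(sim = sim_config(n_hc = 8, n_sz = 8,
                                                     seed = 1234)))
res$summary
```

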