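---
title: "Methods: multi-surface thrombus profiling with thrombotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-surface thrombus profiling with thrombotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thrombotype)
```

This vignette is the package's own account of its methods: the models and
procedures implemented, the assumptions they make, the tunable parameters and
their defaults, what the synthetic-data generators do and do not emulate, and
the numerical and design choices taken where more than one reasonable option
existed.

## 1. The measurement model

A microspot flow assay measures thrombus formation of whole blood perfused
over protein-coated spots. Each surface engages a defined subset of nine
platelet receptors (GPIb-V-IX, GPVI, CLEC-2, α2β1, α5β1, α6β1, αIIbβ3, αvβ3,
CD36 — the fixed, ordered `RECEPTOR_PANEL`), and microscopy yields up to
eight outcome parameters per surface (`THROMBUS_PARAMETERS`): morphological
score (0–5), integrated feature size, platelet deposition (% coverage),
stable adhesion (%), fibrinogen binding (%), P-selectin expression (%),
thrombus volume (µm³/µm², i.e. mean occupied height in µm) and procoagulant
activity (%). The pipeline is the composition

images → parameters → surfaces × parameters matrix → 0–10 normalization →
clustering into thrombus types I–III → receptor regression → patient
profiling.

## 2. Image quantification

**Segmentation** (`segment_coverage()`) uses a fixed operator order: linear
1st–99th percentile contrast stretch, separable horizontal and vertical
running-median filtering (length 3), thresholding, then binary closing
followed by opening with a 3×3 box. The original assay set thresholds
manually; for reproducibility the default threshold is Otsu's, with a
`method = "fixed"` override (in which case the stretch is skipped so the
threshold refers to raw intensities). Conventions for degenerate inputs are
explicit: a constant image under Otsu has no foreground (coverage 0), an
empty feature set has IFS 0 and morphological score 0.

**Integrated feature size** (`integrated_feature_size()`) is Σf²/Σf over the
connected-component areas of the segmented mask ("area above the cumulative
feature-size curve" in graphical terms; the formula reading is implemented).
Components are labelled at configurable 4- or 8-connectivity (default 8) by
a small compiled routine, because the established labeller in EBImage is
4-connective only; EBImage serves as the independent cross-check in the test
suite, together with a pure-R flood-fill oracle.

**Morphological score** is a visual rubric in the assay; the package
implements a declared deterministic proxy (`score_calibration()`): score 0
below 0.5% coverage; 1 vs 2 split at 10% coverage when all features are
below the 50-px single-platelet cut; 3/4/5 split on the largest feature at
500 and 2000 px. The cut-offs are calibrated for a ~0.2 µm/px field and are
fully configurable; the proxy is *not* claimed to reproduce a human scorer,
only to be monotone in the same visual features.

**Stable adhesion** thresholds the temporal mean frame (Otsu by default),
then counts pixels that are above background in at least a `persistence`
fraction of frames (default 1) and whose mean absolute frame-to-frame
differential stays below a quarter of the series' dynamic range.

**Thrombus volume** thresholds every optical section and counts occupied
voxels per unit field area. The automatic policy computes a single Otsu cut
on the *bottom* slice — where every thrombus is present, so the histogram is
reliably bimodal — and applies it to all slices. Per-slice Otsu would
threshold pure noise on nearly-empty top slices and report ~50% spurious
foreground there. Pixel columns are not filled in: occupancy is counted as
observed.

## 3. Matrix assembly, normalization, variability

Replicate runs are aggregated to per-cell means/s.d./counts
(`aggregate_replicates()`, fail-fast on duplicate keys and missing cells).
Normalization (`normalize_matrix()`) is column-wise min–max to 0–10.
Degenerate columns map to 0, not mid-scale: no dynamic range should not
suggest signal. The bounds computed on a reference (healthy-control) panel
are frozen and reused for patient data, which is what makes patient values
comparable to the reference heatmaps — patient values may then legitimately
leave [0, 10]. With intrinsic bounds the output is clamped to [0, 10] only
against floating-point overshoot at the column extremes (~1e-15).

Variability (`compute_cv()`): the intra-individual CV is the within-subject,
between-day CV, averaged over subjects; the inter-individual CV is the
between-subject s.d. of subject means over the grand mean. Both are pooled
over surfaces by unweighted mean (the source analysis reports "all surfaces
together" without a formula; the unweighted mean is the simplest choice that
is scale-invariant per surface). The cohort-level ratio reported by the
acceptance script is the mean of the per-parameter ratios. Note that with d
days the estimated between-subject variance contains an intra-component
σ²intra/d, so at the default design (inter/intra = 3, d = 4) the estimated
ratio concentrates slightly above 3 (~3.05–3.15).

## 4. Clustering and AU support

`hcluster()` performs agglomerative clustering under Euclidean distance and
complete linkage in compiled code, with fully deterministic tie-breaking
(among minimal-distance pairs, the pair whose members were created first —
leaves in input order, then internal nodes in merge order). It returns a
standard `hclust` object. The test suite proves merge-sequence equality with
an exhaustive from-scratch oracle on all small matrices and with
`stats::hclust` on tie-free data.

`multiscale_bootstrap()` resamples the matrix *columns* (parameters) with
replacement at ten scales r ∈ [0.5, 1.4] (n′ = round(r·p)), reclusters, and
records per-node recovery frequencies BP(r). Resampling columns when
assessing row (surface) clusters mirrors the reference implementation's
convention and is configurable by transposing. For panels of ≤64 surfaces a
compiled path represents clusters as 64-bit leaf masks; resample indices are
always drawn in R, so BP tables are exactly reproducible from the seed and
BP at r = 1 is bit-identical to an ordinary bootstrap with the same indices.
The default `n_boot = 1000` per scale across ten scales corresponds to the
full-fidelity 10,000-randomization assessment.

AU support (`au_from_bp()`) fits z(r) = v√r + c/√r to probit-transformed
BP values and reports AU = 1 − Φ(v − c) (per-cent in exports). Two numerical
choices matter:

* Profiles with BP exactly 0 or 1 at *every* scale have no information about
  (v, c) and are clamped to AU 0/1 with `flag = "clamped"`.
* A pure weighted-least-squares fit restricted to interior scales
  (0 < BP < 1) is unidentified precisely for strongly supported clusters,
  whose BP saturates at 1 at most scales: the few surviving scales span a
  flat sliver and the extrapolated v − c is noise (observed AU as low as
  0.42 for a cluster recovered in 99.6% of replicates). The estimator
  therefore refines a continuity-corrected WLS start by maximum likelihood
  on the binomial recovery counts, which is well defined at boundary counts.
  On noiseless probit-linear profiles the ML optimum coincides with WLS
  (the analytic fixed point BP ≡ 0.5 → AU = 0.5 holds exactly), and for
  saturated profiles it gives the intuitive AU ≈ 1.

`cut_types()` cuts at k = 3 and orders clusters by mean normalized value
(ascending → types I, II, III); ties break by cluster size descending, then
lowest surface index. A cut that falls among zero-height merges (identical
rows) is refused rather than returning an arbitrary partition.
`newick_export()` writes the dendrogram with AU percentages as node labels;
`loo_recluster()` is the generic leave-one-out sensitivity report (the
source analysis's manual robustness check, implemented without asserting its
specific conclusions).

## 5. Receptor models

`fit_pls()` is a NIPALS PLS1: predictors mean-centered (unit scaling
optional and off by default, since inputs are on a common 0–10 or 0/1
scale), sequential weight/score/loading extraction with deflation,
coefficients reported on the raw predictor scale. Variance explained is
cumulative predictor-space (X) variance per component. At full rank the
coefficients equal OLS to machine precision — the key correctness anchor,
also cross-checked against mixOmics in the tests.

Thrombus type is coded ordinal-as-numeric (1/2/3); predictions are rounded
half-up and clamped to [1, 3]. One-hot PLS-DA is out of scope. Cross
validation defaults to leave-one-out — deterministic and appropriate at
n ≈ 52. `receptor_beta()` gives the β-weight matrix (intercept + one weight
per receptor, never-engaged receptors dropped with a warning); negative
weights mark a relative inability to contribute to type III formation.
`refit_lowshear()` implements both published variants: a separate-scaled
refit on low-shear surfaces, and exclusion of a named receptor (GPIb at
venous shear). `subtraction_heatmap()` compares matched condition layouts
cell-wise with two-tailed Student's t-tests (pooled variance; Welch by
flag), uncorrected at α = 0.05 to match the per-cell presentation; a
Benjamini–Hochberg correction can be applied downstream by the user and is
deliberately not a default.

## 6. Patient profiling

`reference_ranges()` aggregates control data to subject level first, then
takes mean and s.d. *across subjects*: the reference band reflects
inter-individual variation, because a patient is compared with the healthy
population, not with replicate noise. `significance_map()` flags patient
cells outside mean ± 2 s.d. (multiplier configurable); cells whose s.d. is
unavailable are untestable and excluded from counts. `patient_subtraction()`
is the t-test route at run-level replicates (the replicate unit is
configurable by what the caller passes). `deviation_summary()` tallies
reduced/increased/tested cells.

Two statistical facts are worth stating plainly:

* The 2-s.d. flag rate under the null equals the normal-theory exceedance
  (≈4.55%) only when the reference mean and s.d. are effectively known. The
  calibration study therefore uses 200 control subjects; at n = 6 the
  exceedance is t-like and noticeably larger. This is a property of the
  map, not of the implementation.
* For a deficit of exactly −3 inter-individual s.d. at n = 6 controls, the
  map's sensitivity is structurally ≈93%, driven by s.d.-estimation noise
  (flagging requires the sample s.d. to satisfy 2ŝ < 3σ − noise;
  P(χ²₅ < 11.25) ≈ 0.953 before mean noise). The per-cell t-test reaches
  >95% sensitivity under the same conditions and is the route used for the
  sensitivity acceptance study. Consequently the demo patient's deviation
  count (12 planted deficits) typically reads 10–12, and the ±2 agreement
  check passes for ~97% of seeds.

## 7. The synthetic-data generators

The generators define the study conditions; all are pure functions of their
arguments plus a mandatory seed, and they record the exact truth they plant.

* `gen_scene()`: axis-aligned rectangular features (sides ≥ 3 px) placed by
  rejection sampling with a 3-px separation and a 2-px border margin, so the
  fixed segmentation pipeline is provably exact on noise-free scenes (a 3×3
  closing bridges 2-px gaps; curved shapes would be clipped by the opening —
  the reason rectangles were chosen over ellipses). Default 80/20
  foreground/background on the 8-bit scale with Gaussian noise s.d. 5.
  An `"aggregate"` mode allows overlaps and records merged components as
  truth. The generator emulates controllable feature-area distributions and
  coverage — not platelet morphology, texture, uneven illumination or
  optical blur; exact-recovery results on these scenes therefore validate
  the *operators*, not performance on real micrographs.
* `gen_series()`: a stable feature subset (greedy selection to the target
  stable fraction, exact up to one feature) plus transient features with
  random appear/disappear windows; frames reuse the scene's noise field so a
  fully stable series is bit-identical to the scene.
* `gen_stack()`: per-feature heights uniform over 1..n_slices (default 12 at
  0.5 µm), columns occupied contiguously from the base.
* `planted_matrix_truth()` / `gen_parameter_matrix()`: 52 surfaces × 8
  parameters, three types with constant type means 2/5/8 and replicate noise
  s.d. 0.75, i.e. adjacent-type separation of 4 noise s.d. — the
  "well-separated" regime of the clustering studies; duplicate runs.
* `planted_receptor_truth()` / `gen_receptor_design()`: random binary
  assignment (engagement probability 0.4, every surface ≥1 receptor);
  default planted weights follow the published high-shear receptor hierarchy
  (GPVI > CLEC-2 > GPIb > α6β1 > αIIbβ3 > α2β1 > 0 > α5β1 > αvβ3 > CD36),
  scaled by 0.5 with intercept 1.05 so that noise-free responses stay inside
  the type range [1, 3] and clamping is rare (~4% of rows). Responses are
  clamped to [1, 3]; the clamp is part of the model. For studies that
  require exact zero misassignment at zero noise, a *separable* design is
  used instead (weights {GPVI +0.9, α5β1 −0.9}, intercept 2): its noise-free
  responses are ≥0.4 from every rounding boundary and never clamp.
* `cohort_truth()` / `gen_cohort()`: two-level variance model (subject
  effects at `inter_sd`, day effects at `intra_sd`) over a 9 surfaces × 6
  parameters reference grid, 6 controls × 4 days, default CVs ~6%/18%
  (ratio 3), mirroring the reference-range study design. The patient's
  expected value is exactly `cell mean + shift × inter_sd` (so planted
  deviations are exact); `patient_subject_effect = TRUE` adds a drawn
  between-individual effect and is the correct null-patient model for
  calibration studies.

## 8. Problem sizes and runtime choices

The test suite runs the clustering oracle on all matrices up to 8 rows,
type-recovery on 100 planted 52×8 panels, AU support on 20 full-fidelity
runs (n_boot = 1000, ten scales), β recovery on 100 planted designs,
null-map calibration on 1000 simulated patients (3×2 grid, 200 controls),
t-test calibration on 1000 draws, CV recovery on 200 cohorts, and the
end-to-end demo twice (byte-identity). The acceptance script re-runs the
same studies at the sizes recorded in its JSON output. The bootstrap's
compiled path makes a full 10,000-randomization assessment of a 52×8 panel
take on the order of a second.

## 9. Known limitations

* The morphological score proxy is a calibrated rubric, not a learned
  classifier; agreement with human scoring is out of scope.
* Automatic (Otsu) thresholding on images that are entirely foreground or
  entirely noise is ill-posed; the conventions above apply, and a fixed
  threshold is available.
* The receptor model is linear in receptor engagement; receptor synergies
  enter only through the planted truth of the simulation, not the model.
* Normalization within versus across shear-rate datasets is a flag
  (`bounds`); the default normalizes within a condition.
* No multiple-testing correction is applied by default in the per-cell
  t-test maps, matching the per-cell α = 0.05 presentation convention.
* All validation is against synthetic scenes; none of the image-analysis
  results here certify accuracy on real phase-contrast or confocal data.
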