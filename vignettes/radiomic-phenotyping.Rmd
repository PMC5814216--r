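---
title: "Radiomic phenotyping of glioblastoma MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic phenotyping of glioblastoma MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Glioblastoma is molecularly heterogeneous: transcriptomic profiling divides
tumors into subtypes (classical, proneural/neural, mesenchymal) with
different prognoses, but profiling requires tissue. Physiologic MRI —
dynamic susceptibility contrast (DSC) perfusion and diffusion-weighted
imaging (DWI) — measures tumor vascularity and cellularity noninvasively.
`radiophen` implements a complete radiogenomic pipeline that asks whether
quantitative imaging phenotypes can stand in for transcriptomic class: it
computes physiologic maps, summarizes each tumor with 82 first-order and
volumetric features, discovers imaging subtypes by consensus clustering,
and tests their association with expression signatures, pathway scores,
somatic mutations, copy number, and survival.

Because no patient images ship with the package, a first-class synthetic
cohort generator (`simulate_cohort()`) produces a 65-patient cohort with
three planted subtypes expressed jointly in imaging, expression, genomics
and survival; every downstream stage is tested against this known ground
truth.

## Physiologic maps

**ADC.** From a two-b-value DWI pair, the apparent diffusion coefficient is
the voxelwise log-ratio `ADC = ln(S_b0 / S_b1000) / b` (mm²/s). Negative
estimates (noise) are clamped to zero and counted; clamped voxels are
marked invalid for the ADC-validity volume features.

**DSC perfusion.** The signal model is `S(t) = S0 * exp(-TE * dR2*(t))`;
`signal_to_relaxation()` inverts it against the mean pre-bolus baseline, so
the curve is invariant to any rescaling of the raw signal. The first pass
of the bolus is modelled by the gamma variate
`C(t) = K (t - t0)^alpha exp(-(t - t0)/beta)`. Fitting
(`fit_gamma_variate()`) uses only samples up to the first post-peak return
below 20% of the peak, which excises the recirculation bump; bolus arrival
is initialized at the last sample before the curve exceeds 10% of peak, and
the remaining parameters come from the log-linearized regression
`log C = log K + alpha log(t - t0) - (t - t0)/beta`, which is linear in
`(log K, alpha, 1/beta)`. Two refinement paths are provided:

* `method = "nls"` (default): bounded Levenberg-Marquardt on the original
  scale — the accurate path, used for single curves and round-trip checks;
* `method = "loglin"`: the iteratively reweighted log-linear solution
  (weights equal to the squared fitted concentration, which undoes the
  variance distortion of the log) — an order of magnitude faster, used for
  voxelwise maps.

A fit is reported `converged = FALSE` (never an error) for flat curves or
when the peak-to-residual ratio falls below 5; such voxels are excluded
from ROI histograms and their count is logged.

**Leakage.** Blood-brain-barrier breakdown adds a slow ramp to tumor
curves. `correct_leakage()` fits the two-parameter linear model
`curve ~ k1 * reference - k2 * cumint(reference)` against a non-leaky
whole-tissue reference curve and adds the `k2` term back, restoring the
tail to baseline. In `compute_perfusion_maps()` the same model is solved
for all voxels in one linear-algebra step because the design matrix depends
only on the shared reference curve.

**Indices.** The paper-style "relative" units never involve an arterial
input function, so the indices are defined directly on the fitted curve:
CBV is its area `K beta^(alpha+1) Gamma(alpha+1)`; MTT the first moment
about `t0` over the area, `beta (alpha + 1)`; TTP the peak location
`t0 + alpha beta`; and CBF = CBV / MTT by the central volume principle.
ADC, CBV and CBF maps are divided by the median of a user-supplied normal
tissue mask (median, not mean, for robustness), yielding rADC/rCBV/rCBF
with reference median exactly 1; MTT and TTP are already in seconds.

## The 82-feature profile

`feature_registry()` returns the fixed feature table: 12 volume/size
entries (voxel count, total in-plane area in cm², volume in mL, for the
contrast-enhancing and FLAIR ROIs and their ADC-valid counterparts) and 70
histogram entries — 7 statistics (mean, median, SD, 5th/95th percentile,
quartiles) x 5 maps (rCBF, rCBV, MTT, TTP, rADC) x 2 ROI bases. Registry
names are kept verbatim from the published parameter table, including its
`T2FALIR_VOL` spelling, so exported matrices match the published header.

Design choices a reader should know:

* "Number of pixels" is read as the voxel count of the mask, and "area" as
  count x pixel area summed over slices, which makes volume = area x slice
  thickness for uniform slices. Whether the published area was per-slice or
  total is not stated; this reading is the configurable default.
* The ADC-prefixed volume rows are implemented as counts/areas/volumes of
  ROI voxels where the ADC map is valid — the only reading under which they
  are not duplicates of the mask rows.
* Percentiles use linear interpolation between order statistics with
  inclusive endpoints; SD uses the n-1 denominator. Both are stated
  explicitly because the original analysis software is closed-source.
* Necrosis and vessel masks are subtracted from both ROIs before any
  feature is computed (`subtract_exclusions()`); voxels with failed
  perfusion fits are excluded listwise per feature family.

## Subtype discovery

Features are z-standardized per column (`standardize()`; constant columns
are dropped with a warning). Patient similarity is the Pearson correlation
of standardized feature profiles. `consensus_cluster()` draws 500 random
80% patient subsamples, clusters each by average-linkage agglomeration on
`1 - correlation`, and accumulates co-clustering frequencies into one
consensus matrix per candidate k (2-6 by default); final assignments come
from clustering the consensus matrix itself. The cluster number is chosen
by the proportion of ambiguous clustering (PAC): the fraction of
off-diagonal consensus entries strictly between 0.1 and 0.9, minimized
over k with ties to the smallest k. Linkage, resample count, subsample
fraction and PAC bounds are all arguments; the defaults are standard
consensus-clustering practice. A fixed-k mode is available by passing a
single value as `k_range`.

## Transcriptomic machinery

* **RPKM / log:** `rpkm()` applies `1e9 * count / (length x library size)`;
  `log_transform()` applies `log2(x + 1)` once (a tag prevents double
  transformation).
* **Balanced nearest centroids (ClaNC-style):** per gene and class,
  `d = (class mean - overall mean) / (m_c (pooled SD + s0))` with
  `m_c = sqrt(1/n_c - 1/n)` and shrinkage offset `s0` set to the median
  pooled SD. Genes are assigned greedily in decreasing `|d|` under an exact
  per-class quota with no gene reused; prediction minimizes the
  standardized squared distance to each class centroid over that class's
  own genes, ties to the first class. The quota is chosen by stratified
  cross-validation as the smallest size attaining minimal error
  (`clanc_cv()`). The signature size is deliberately a free parameter — the
  published account of the signature size is internally inconsistent, so no
  size is hard-coded.
* **ssGSEA:** per sample, genes are ranked by expression descending with
  ties broken by gene id; the enrichment score is the summed difference
  between the in-set ECDF weighted by `rank^alpha` (alpha = 0.25,
  normalized within the set) and the uniform out-of-set ECDF. Scores are
  rank-based, hence invariant to any monotone per-sample transformation.
  Cross-sample min-max normalization is available but off by default, as
  no normalization convention is stated in the source analysis.
* **Over-representation:** one-sided hypergeometric tail on the 2x2
  list-by-set table over the assayed universe, odds ratio with a 0.5
  continuity correction when a cell is zero, BH adjustment across the
  collection.

## Association testing and survival

Spearman screening uses midranks with the two-sided t-approximation,
keeping pairs with `|rho| > 0.6` and `p < 0.05` while reporting BH-adjusted
p-values computed over all tested pairs; constant vectors are skipped and
counted. The Mann-Whitney test is exact by enumeration for combined
samples of at most 12 without ties, otherwise the normal approximation
with tie and continuity corrections. Mutation and copy-number effects are
ordinary least squares of the phenotype on the variant indicator/dosage;
binary indicators with fewer than 3 carriers are flagged untestable rather
than tested, reflecting how unreliable per-gene statistics are at realistic
mutation frequencies. Multiple-testing adjustment is applied within each
analysis family, not globally. Survival is summarized per cluster by
Kaplan-Meier medians with Greenwood-based 95% CIs and compared by the
k-group log-rank test (via the survival package).

## What the synthetic cohort emulates

`cohort_config()` fixes the acquisition constants (TR/TE 1.72/0.035 s, 50
DSC volumes, b = 0/1000 s/mm², 5 mm slices) and a 32³ grid. Three default
profiles mimic the reported cluster phenotypes qualitatively:

| profile | planted rCBV | ADC (1e-3 mm²/s) | T1CE radius | median OS |
|---|---|---|---|---|
| mesenchymal-like | 3.0 | 0.70 | 6.5 mm | 9 mo |
| classical-like (intermediate) | ~2.1 | 0.95 | 10 mm | 14 mo |
| proneural/neural-like | 1.2 | 1.30 | 6.5 mm | 20 mo |

Tumor geometry is a contrast-enhancing sphere nested in a larger FLAIR
ellipsoid with an inner necrotic sphere and a small vessel, exercising the
mask algebra; a normal-tissue box provides the normalization reference.
Mixture medians of the three exponential survival distributions put the
cohort median OS near 13.2 months with ~29% censoring, matching the scale
of the study population the pipeline is designed for; the mesenchymal-like
profile is worst, as reported for the imaging cluster enriched for that
subtype.

Three design details matter for interpreting test results:

* **Severity latent.** Within each subtype one latent per-patient
  "aggressiveness" draws perfusion up and diffusivity/transit down
  together (`param_cv`), so within-subtype heterogeneity lies along the
  biological axis connecting the low- and high-perfusion subtypes. The
  intermediate profile is given the largest spread — intermediate tumors
  are the physiologically least stereotyped — which is what makes the
  two-cluster solution genuinely ambiguous under subsampling while three
  clusters remain stable. With homogeneous subtypes the two-cluster merge
  would be deterministic and any stability statistic would tie at k = 2.
* **Stratified draws.** Severities are stratified normal quantiles within
  each subtype (lightly truncated, randomly assigned), and subtype counts
  are largest-remainder allocations of the prevalences. Both are
  Monte-Carlo variance-reduction devices: every simulated cohort realizes
  the same within- and between-subtype structure, so structural claims
  (three clusters; recovery of the planted labels) hold across seeds
  rather than on lucky ones.
* **Calibrated symmetry.** The intermediate profile's perfusion/ADC/transit
  center was placed so its correlation distance to the two extreme
  profiles is balanced (K = 32.5, ADC 0.95e-3, beta 1.51 under the default
  mixture). This placement was calibrated once, at generator design time,
  by measuring between-cluster distances over seed sweeps.

The generator does **not** emulate real brain anatomy, bias fields, motion,
coil profiles, spatially correlated noise, arterial input variability, or
realistic transcriptome covariance (genes are independent given the
subtype). Passing tests therefore demonstrate that the pipeline's
algorithms are correct and that its statistics behave nominally under a
controlled generative model — not that the pipeline would reproduce any
particular clinical result on real data.

Noise scales (DWI sd 5 on S0 = 1000, DSC sd 1 on S0 = 100, expression sd 1
log2 units, CNV sd 0.3) are stated in `cohort_config()`; no magnitudes are
available from the source study, so these were chosen once as realistic
mid-range values and left fixed.

## Numerical choices and degenerate inputs

* Recirculation cutoff 20% of peak; arrival threshold 10% of peak;
  convergence SNR gate 5. All exposed as arguments.
* Magnitude MR signal is floored at a small positive value in the forward
  model (Rician bound), so the log conversion is always defined.
* Flat or all-zero curves fit to `converged = FALSE`; empty ROIs after
  exclusion subtraction, non-positive normalization medians, constant
  reference curves, overlapping marker blocks, and double log-transforms
  are errors naming the offending input.
* Ties: ssGSEA ranks break by gene id; nearest-centroid ties go to the
  first class in model order; PAC ties go to the smallest k. All are
  deterministic so identical seeds give bitwise-identical outputs.

## Problem sizes used by the test suite

The suite exercises the full default cohort (65 patients, 32³ voxel grids,
1000 genes) for the structural checks, 20 simulated cohorts for the
label-recovery summary, 100-replicate fit-accuracy and survival-power
simulations, and 5000-replicate null simulations for the type-I error of
the Mann-Whitney and slope tests. These sizes were chosen so the whole
suite runs in well under half an hour on a single core while keeping every
Monte-Carlo interval tight enough to be informative.

## Limitations

The pipeline is AIF-free by design: perfusion indices are relative, not
quantitative CBF/CBV in mL/100g units, and no deconvolution or
permeability modelling is attempted. DICOM handling, registration, motion
correction and manual segmentation are out of scope — inputs are
registered NIfTI volumes with masks. The radiomic profile is first-order
and volumetric only (no texture or wavelet features). Consensus clustering
inherits the known weaknesses of stability-based model selection; the PAC
statistic with its default bounds is one defensible choice among several,
which is why both the fixed-k mode and all thresholds are exposed.
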