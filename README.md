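# radiophen

Radiomic phenotyping and radiogenomic association for glioblastoma MRI.

`radiophen` is an R package for asking whether quantitative imaging
phenotypes of glioblastoma can stand in for its transcriptomic subtypes.
It implements the full analysis chain for a multi-modal MR cohort:

1. **Physiologic maps** — apparent diffusion coefficient from a
   two-b-value DWI pair, `ADC = ln(S_b0/S_b1000)/b`; and DSC-perfusion
   indices from gamma-variate first-pass fitting of the relaxation-rate
   curve `ΔR2*(t) = −ln(S(t)/S_base)/TE`, with recirculation windowing and
   Boxerman-style leakage correction. On the fitted curve
   `C(t) = K (t−t0)^α e^{−(t−t0)/β}` the indices are closed forms:
   CBV = K β^(α+1) Γ(α+1), MTT = β(α+1), TTP = t0 + αβ, CBF = CBV/MTT.
   ADC/CBV/CBF are normalized to a normal-tissue reference median
   (rADC/rCBV/rCBF).
2. **82-feature radiomic profile** — a fixed registry of volume/size
   features and first-order histogram statistics (mean, median, SD,
   5th/95th percentiles, quartiles) of the five maps on contrast-enhancing
   (T1CE) and FLAIR ROIs, after necrosis/vessel subtraction.
3. **Imaging subtypes** — consensus clustering of z-standardized feature
   profiles: 500 subsamples at 80%, average linkage on 1 − Pearson
   correlation, cluster number selected by the PAC statistic.
4. **Genomic association** — balanced nearest-centroid (ClaNC-style)
   signature genes with cross-validated size; ssGSEA per-sample pathway
   scores; Spearman screening (|rho| > 0.6, p < 0.05, BH adjustment);
   Fisher-exact over-representation; per-gene mutation/CNV regression;
   Kaplan–Meier/log-rank survival contrast between imaging clusters.

No patient data ship with the package. A first-class synthetic cohort
generator (`simulate_cohort()`) produces a 65-patient cohort with three
planted subtypes expressed jointly in imaging, expression, mutations/CNV
and survival, so the whole pipeline runs and is tested end to end against
known ground truth. See the vignette
(`vignettes/radiomic-phenotyping.Rmd`) for the models, parameter choices
and limitations.

## Worked example

```r
library(radiophen)

cfg <- cohort_config(seed = 7)                      # 65 synthetic patients
res <- run_pipeline(cfg, outdir = file.path(tempdir(), "gbm_run"))
cat(pipeline_report(res), sep = "\n")
```

```
Radiomic phenotyping pipeline report
seed: 7
selected cluster number k = 3 (PAC: k2=0.463, k3=0.039, k4=0.060, k5=0.082, k6=0.042)
cluster sizes: 1=24, 2=21, 3=20
3 significant pathway enrichment(s) at adjusted p <= 0.01:
  pathway_classical_markers (overlap 16/50, OR 9.46, adj p 1.38e-08)
  pathway_proneural_neural_markers (overlap 18/50, OR 11.86, adj p 1.79e-10)
  pathway_mesenchymal_markers (overlap 27/50, OR 31.63, adj p 9.55e-22)
118 radiomic-pathway association(s) passed the Spearman screen
survival by cluster (median months [95% CI]):
  cluster1: 9.0 [4.3, 13.8], 20/24 events
  cluster2: 13.0 [5.9, NA], 13/21 events
  cluster3: 10.7 [9.8, NA], 13/20 events
log-rank p = 0.175
```

Reading the output: the PAC (proportion of ambiguous clustering) curve is
minimized at k = 3 — splitting the cohort in two is unstable under
subsampling (PAC 0.46) while three clusters are nearly unambiguous (PAC
0.04) — and the three discovered imaging clusters recover the three
planted subtypes. Each cluster's over-expressed genes are enriched for
exactly one planted marker pathway (the Fisher-exact odds ratios and
BH-adjusted p-values shown), 118 (feature, pathway-score) pairs pass the
Spearman screen at |rho| > 0.6, and per-cluster Kaplan–Meier medians span
9–13 months. With only ~20 patients per cluster the three-group log-rank
test is under-powered at this effect size, and individual seeds (as here)
need not reach p < 0.05 — median estimates at this cohort size carry
multi-month confidence intervals.

All outputs (radiomic matrix, consensus matrix, cluster assignments,
ssGSEA scores, association tables, survival summary, manifest with md5
checksums) are written as TSV beside the run; `write_cohort()` exports the
synthetic volumes and masks as NIfTI.

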