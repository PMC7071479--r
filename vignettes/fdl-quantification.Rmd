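---
title: "Dual-channel immunofluorescence densitometry and chromogenic scoring with fdlquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-channel immunofluorescence densitometry and chromogenic scoring with fdlquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdlquant)
```

## The measurement problem

In Alzheimer-type neurodegeneration, the burden of hyperphosphorylated
tau (visualized with the AT8 antibody against phospho-Ser202/Thr205)
spreads across brain regions in a stereotyped sequence described by
Braak staging, while the serine/threonine kinase LMTK2 appears to be
depleted specifically where neurofibrillary tangles (NFTs) accumulate.
`fdlquant` implements the two quantification arms used to study this
relationship on postmortem tissue:

* **FDL-IHC** (fluorescent double-labelling): each slide carries two
  fluorophores imaged as a red channel (LMTK2) and a green channel
  (phospho-tau). The question is the *balance* between the two signals
  within each neuron, not their absolute brightness.
* **CHR-IHC** (chromogenic DAB staining): each neuron receives an
  ordinal intensity score 0, 1+, 2+ or 3+; scores are averaged per
  case and compared across groups.

The study design crosses two regions (middle frontal gyrus, MFG;
anterior hippocampus, aHPC) with two neuropathological stages (early =
Braak III or less; late = Braak VI), giving four groups. Early-stage
MFG is spared by NFTs and acts as the endogenous control.

## The fluorescence pipeline

For each image the pipeline performs:

1. **Merge** — the red and green rasters are averaged into one 8-bit
   gray image, `round((red + green)/2)` with half-up rounding
   (`merge_to_gray()`). A `mean3` variant reproduces an RGB-average
   with an all-zero blue channel; the default `mean2` keeps the merged
   scale comparable to a single channel.
2. **Threshold** — Otsu's method by default (`threshold_mask()`,
   exhaustive between-class-variance maximization over the 8-bit
   histogram), with a `fixed` override because thresholds on real
   slides are often adjusted manually. The chosen value is recorded in
   the run log.
3. **Object extraction** — connected components (8-connectivity by
   default, 4 available) with a *strict* pixel-area filter: only
   objects with more than 400 px survive (`extract_objects()`). A
   20 × 20 px square (exactly 400 px) is dropped; a 21 × 21 square is
   kept. The 400 px cut selects neuron-scale somata at the working
   magnification.
4. **Redirected densitometry** — intensities are summed *per original
   channel* over each object's pixel set (`measure_roi()`), giving the
   red and green raw integrated densities over the same area.
5. **Percentage of sum** — under the modelling assumption that the
   summed red + green signal per neuron is invariant, each ROI's
   signals are expressed as proportions of their sum:
   `R = rid_red / (rid_red + rid_green)`, `G = 1 − R`
   (`percent_of_sum()`). ROIs with zero summed density are flagged and
   counted, never silently dropped.
6. **The X index** — `X = (R − G)/(R + G)` maps the balance onto a
   unified scale: +1 is pure LMTK2 signal, −1 pure phospho-tau, and on
   normalized signals `X = 2R − 1` (`x_transform()`).

Case-level summaries are ROI means (`aggregate_case()`); group-level
summaries pool the per-ROI pairs (`aggregate_group()`).

### The forced anticorrelation, stated plainly

Because `G = 1 − R` for every measurable ROI, the Spearman rank
correlation between the R and G columns of any group with at least two
distinct R values is **−1 by construction**. The pipeline reproduces
this perfect negative correlation in all four groups on any seed — and
the package documentation treats it as what it is: an identity of the
percentage-of-sum transform, not an empirical discovery about the two
proteins. The scientifically informative quantities are the group
*means* of R (or X), which do vary freely.

## The synthetic virtual-slide generator

No imaging data accompany the original study, so the package ships a
generator (`fdl_sim_config()`, `generate_fdl_image()`,
`generate_fdl_group_set()`) that emulates what the analysis assumes:
bright, non-overlapping, roughly circular somata on a dark background.

* **Geometry.** Filled disks with radii drawn uniformly from 12–20 px
  (area ≈ 450–1300 px, safely above the 400 px filter) in a
  512 × 512 px field of 40 cells by default; placement is rejection
  sampling with a 1000-attempt cap per cell and a 3 px minimum rim
  gap, so neighbouring cells cannot fuse into one component. Disks are
  the simplest shape with an exact area oracle; real neurons are not
  disks, and no point-spread blur or neuropil texture is simulated.
* **Signal model.** Each cell draws a red fraction *f* from a
  normal truncated to [0, 1] and a total intensity *T* (uniform
  180–240 counts); in-disk pixels are `background + f·T` (red) and
  `background + (1 − f)·T` (green) plus Gaussian read noise (sd 2),
  rounded and clipped to 8 bits. Green is the complement of red by
  construction — the generator encodes the invariant-sum assumption
  the analysis itself makes.
* **Mean-calibrated truncation.** The truncated normal is
  parameterized so that its *truncated* mean equals
  `mean_red_fraction`: the location parameter is solved by `uniroot`
  on the monotone truncated-mean function. Naive truncation would
  bias the realized mean by up to ~0.03 at the wider group SDs,
  making the group parameter a misnomer; sampling uses the inverse
  CDF, so no rejection loop is involved.
* **Background.** The default background is 2 counts. This is a
  deliberate study condition: the densitometry stage performs no
  background subtraction (none is part of the analyzed workflow —
  autofluorescence was suppressed chemically on the real slides), so
  a bright pedestal would pull every measured fraction toward 0.5 by
  `(bg + fT)/(2bg + T)`. At 2 counts over totals near 200 the residual
  bias stays below 0.01.
* **Group conditions.** `fdl_group_configs()` fixes the four group
  means at 0.946 / 0.349 / 0.273 / 0.215 (early MFG, early aHPC, late
  MFG, late aHPC) with per-ROI SDs 0.087 / 0.233 / 0.237 / 0.159. The
  reported group dispersions are read here as the SD of the per-ROI
  red fraction; since it is ambiguous whether a single printed SD
  refers to R, G or X, group output reports all three.

The generator's ground-truth table (per-cell center, radius, true
fraction, true total) is the oracle for parameter-recovery tests: at
2000 ROIs per group the pipeline recovers the configured means within
±0.03 and preserves the group ordering. What passing these tests does
*not* show: robustness to overlapping or irregular cells, uneven
illumination, bleed-through, or out-of-focus fields — none of which
the generator emulates.

The chromogenic arm is simulated at the score level
(`chr_sim_config()`, `generate_chr_cohort()`): neurons draw i.i.d.
scores from a 4-point distribution. `generate_chr_group_cohort()`
additionally targets per-case mean scores spanning each group's
reported range (2.13–2.92, 1.07–1.70, 1.22–1.81, 1.00–1.55) by
stratified-uniform draws over the range, one per equal subinterval;
each case's neurons then come from the two-point distribution on the
adjacent integer scores whose expectation is the target. The default
sampling layout is 5 cases per group and 10 fields × 30 neurons = 300
neurons per case; the fields-per-case density is a free parameter, as
the per-field neuron count is not fixed by the design.

## The statistical plan

* **Normality gate** (`shapiro_gate()`): Shapiro–Wilk at α = 0.05.
  Case mean scores pass and proceed to t-tests; the bounded, skewed
  fluorescence proportions fail and are handled by rank-based
  correlation.
* **Six pairwise t-tests** (`pairwise_ttests()`): two-sample,
  two-sided, equal-variance comparisons of case mean scores for the
  control against each NFT-affected group and among the NFT-affected
  groups, in the design's reporting order. No multiplicity correction
  is applied by default, matching the original plan; Holm is available
  (`p_adjust = "holm"`).
* **ANCOVA** (`ancova_covariates()`): `lm(mean_score ~ stage + region
  + age + final_mmse + apoe_e4)` with Type II F-tests (`car::Anova`),
  which coincide with Type III for covariates outside interactions —
  the covariate test a SPSS-style full-factorial ANCOVA reports. APOE
  is coded as the ε4-allele count (0/1/2), the natural single-number
  risk coding; genotype strings parse via `apoe_e4_count()`. Cases
  with missing covariates are dropped listwise, with their ids in a
  message. Constant or aliased covariates are reported as
  inestimable, not silently dropped.
* **Spearman correlation** (`spearman_cor()`): rho is the Pearson
  correlation of midranks, so ties are handled exactly. The two-sided
  p-value is an exact full-permutation enumeration for n ≤ 9 and the
  t-approximation `t = rho·sqrt((n−2)/(1−rho²))` for larger n. No
  reporting floor is applied; at |rho| = 1 the asymptotic p underflows
  to 0 (software that floors p-values would print a constant small
  number instead — the package does not).

## Numerical and design choices

* Half-up rounding in the channel merge keeps results platform-stable
  at the .5 boundaries that `round()`'s banker's rounding would split.
* The area filter is a strict inequality (`> min_area_px`); lowering
  the cutoff can only add objects (monotonicity, under test).
* Otsu ties resolve to the lowest maximizing threshold; a constant
  image is an explicit degenerate-image error, as is a constant vector
  in the normality gate or correlation.
* 16-bit TIFF input is rescaled by integer division by 257
  (full-range linear), the common viewer behavior; camera settings of
  the original acquisition are fixed but unpublished, so no other
  transfer curve is defensible.
* Zero-sum ROIs are flagged and logged so `n_pairs` is auditable.
* One master seed fans out to fixed per-stage offsets
  (simulation, chromogenic arm), so a stage can be rerun in isolation
  and any run is reproducible from its `run.log`.

## A complete run

```{r, eval = FALSE}
cfg <- run_config(out_dir = "demo_run", seed = 5)
res <- run_all(cfg)

res$group_stats[, c("group", "spearman_rho", "mean_R", "mean_G", "n_pairs")]
res$chr_ttests[, c("group1", "group2", "t", "p_value")]
res$ancova$table
```

`run_all()` writes `signals.csv` (one row per ROI), `case_summaries.csv`,
`group_stats.csv`, `scores.csv`, `chr_cases.csv`, `stats.json` and a
`run.log` recording versions, seeds and the per-image thresholds. A
thin command-line wrapper over the same functions ships in
`inst/scripts/fdl-pipeline.R`.

## Problem sizes used by the test suite

The shipped tests exercise the pipeline at deliberately desk-scale
sizes chosen to keep the statistical checks well-powered: unit tests
use 64–256 px images with a handful of cells; the parameter-recovery
check uses 40 cells × 50 images per group (≈2000 ROIs each, the scale
at which the ±0.03 recovery band is ~5 sampling SEs wide); the t-test
separation property uses 200 simulated cohorts; the ANCOVA null
calibration uses 1000 replicates (3000 covariate tests, binomial SE
≈ 0.4%). The forced-correlation property is scale-free and is checked
on small cohorts across several seeds.

## Known limitations

* The chromogenic arm is simulated at the score level only; no DAB
  color-space or nucleus-level image simulation is attempted, so the
  auto-scoring path (`score_from_intensity()`) has configurable cut
  points rather than calibrated constants.
* No watershed splitting, hole filling or morphological cleanup:
  touching cells would merge into one ROI. The generator avoids
  overlap by construction; real tissue does not.
* No background subtraction or spectral unmixing; slides with
  substantial autofluorescence would bias fractions toward 0.5.
* Whole-slide pyramidal formats are out of scope; inputs are plain
  single- or two-sample TIFFs.
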