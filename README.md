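# fdlquant

Quantification of dual-channel immunofluorescence and semiquantitative
chromogenic immunohistochemistry, built for studying how LMTK2 (lemur
tyrosine kinase 2) immunolabelling relates to phospho-tau burden across
brain regions and neuropathological Braak tau stages of Alzheimer's
disease. The package is aimed at neuropathology image-analysis work:
it turns two-channel (red = LMTK2, green = phospho-tau AT8) microscopy
TIFFs into per-neuron signal balances and group statistics, scores
chromogenic DAB slides on the ordinal 0–3+ scale, and ships a
synthetic virtual-slide generator with ground truth so every stage is
testable without tissue.

## The method

For each segmented neuron-scale object (connected component of the
thresholded merged image with area strictly greater than 400 px), the
red and green **raw integrated densities** are measured over the same
pixel set by redirecting the measurement to the original channels:

    rid_c = Σ_{(i,j) ∈ ROI} c(i, j),   c ∈ {red, green}

Under the assumption that the summed red + green signal per neuron is
invariant, each ROI's signals are expressed as proportions of their
sum and mapped to a normalized difference index:

    R = rid_red / (rid_red + rid_green),   G = 1 − R
    X = (R − G) / (R + G)  ∈ [−1, +1]

`X = +1` means pure LMTK2 (red) signal, `X = −1` pure phospho-tau
(green). Because `G = 1 − R` by construction, the Spearman rank
correlation between a group's R and G columns equals −1 whenever two
distinct R values exist — a structural identity of the
percentage-of-sum transform that the pipeline reproduces exactly in
all four experimental groups (the informative quantities are the group
means of R and X, which vary freely).

The chromogenic arm averages per-neuron 0/1+/2+/3+ scores per case and
compares the four groups (region × stage) with the study's plan:
Shapiro–Wilk gate, six pairwise equal-variance t-tests, ANCOVA with
age, final MMSE and APOE ε4 count as covariates, and tie-aware
Spearman correlation with exact permutation p-values for n ≤ 9.

## Worked example

```r
library(fdlquant)

cfg <- run_config(out_dir = "demo_run", seed = 5)
res <- run_all(cfg)

res$group_stats[, c("group", "spearman_rho", "mean_R", "mean_G", "mean_X", "n_pairs")]
#>       group spearman_rho mean_R  mean_G  mean_X n_pairs
#>  early_aHPC           -1 0.3734 0.62658 -0.2532      48
#>   early_MFG           -1 0.9383 0.06168  0.8766      48
#>   late_aHPC           -1 0.2412 0.75877 -0.5175      48
#>    late_MFG           -1 0.3135 0.68646 -0.3729      48
```

Each simulated group was generated at its configured mean red fraction
(0.946 / 0.349 / 0.273 / 0.215): the NFT-spared control (early MFG) is
red-dominated (mean X ≈ +0.88) while the NFT-affected groups tilt
green, and every group shows the construction-forced ρ = −1 between
its R and G columns.

```r
res$chr_ttests[, c("group1", "group2", "t", "p_value")]
#>      group1     group2      t   p_value
#>   early_MFG early_aHPC 8.1903 3.686e-05
#>   early_MFG   late_MFG 7.4591 7.202e-05
#>   early_MFG  late_aHPC 8.8823 2.041e-05
#>    late_MFG early_aHPC 0.8865 4.012e-01
#>    late_MFG  late_aHPC 1.8050 1.087e-01
#>  early_aHPC  late_aHPC 0.9307 3.792e-01
```

The three control-vs-affected comparisons separate sharply; the three
comparisons among NFT-affected groups do not — the pattern the scoring
arm is designed to detect. `res$ancova$table` shows the covariate
F-tests (age, final MMSE, APOE ε4 count all non-significant under the
null simulation), and `x_transform(0.946, 0.054)` / `x_transform(0.215,
0.785)` give the worked index values `0.892` and `-0.570`.

`run_all()` writes `signals.csv`, `case_summaries.csv`,
`group_stats.csv`, `scores.csv`, `chr_cases.csv`, `stats.json` and a
`run.log` with seeds and per-image thresholds. A command-line wrapper
lives at `inst/scripts/fdl-pipeline.R`.

See `vignettes/fdl-quantification.Rmd` for the model, the generator's
assumptions, and every numerical choice.

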