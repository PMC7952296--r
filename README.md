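# pirchematch

Epitope-load scoring and survival comparison for HLA matching in kidney
transplantation.

## What this package is for

Deceased-donor kidney allocation matches donors and recipients on HLA-A, -B
and -DRB1 antigens, summarized as a 0–6 mismatch count. Epitope-based
matching refines this: the PIRCHE-II-style score counts donor HLA-derived
peptides that the recipient's immune system could recognize through the
indirect pathway — 15-mer peptides of the donor's HLA proteins (exon-2–5
region) that are absent from the recipient's self-HLA peptidome and are
predicted to be presented by the recipient's HLA-DRB1 molecules. Identical
9-mer binding cores are counted once per presenting DRB1 protein, so the raw
score is

```
score(D, R) = | { (core, presenter) : presenter ∈ DRB1(R),
                  core presented from a donor 15-mer ∉ self-peptidome(R) } |
```

Registry typings are split-level (serological), not two-field molecular, so
the score is imputed: every two-field genotype completion consistent with the
split typing is enumerated from an A~B~DRB1 haplotype frequency table,
weighted by Hardy–Weinberg pair probabilities renormalized over the
consistent set, and the frequency-weighted mean and SD of the score over the
product distribution of donor and recipient completions is reported.

Because raw scores (0 to a few hundred) and mismatch counts (0–6) live on
different scales, per-unit hazard ratios are not comparable. The package
adjusts scores onto the mismatch scale with the cohort-maximum log transform

```
adj_i = ln(raw_i + 1) * 6 / max_j ln(raw_j + 1)
```

so a raw score of 0 maps to 0 and the cohort maximum to 6, and then compares
both compatibility measures as predictors of 5-year death-censored graft
survival in multivariable Cox proportional-hazards models: each exposure
alone, both jointly, cross-categorized subgroup analyses (the per-unit effect
of one measure within categories of the other), AIC model ranking and
time-horizon ROC discrimination. Baseline hazards are stratified by country;
missing confounder values form explicit "unknown" categories; ties are
handled by Efron's method.

Registry data of this kind is not public, so the package ships a synthetic
cohort generator with full ground truth — toy allele sequences whose split
structure mirrors serology, haplotype pools, a pluggable position-weight-
matrix presentation predictor, and exponential proportional-hazards
graft-loss times with configurable true effects — making every stage of the
pipeline testable end to end.

## Worked example

```r
library(pirchematch)

cfg    <- generator_config(n_patients = 5000, seed = 1)
ref    <- synthesize_reference_data(cfg)
cohort <- simulate_cohort(cfg, ref)

spearman_correlation(cohort$pirche_adj, cohort$hla_mm)$rho
#> 0.54        # epitope load tracks the mismatch count, far from perfectly

fit_p <- fit_cox(cohort, "pirche")   # adjusted score only
fit_h <- fit_cox(cohort, "hla")      # mismatch count only
fit_b <- fit_cox(cohort, "both")     # both jointly
fit_b
#> <cox_fit> exposure = both, n = 5000, events = 454, AIC = 5877.2
#>   pirche_adj  HR 1.084 (95% CI 0.980-1.200), z = 1.6, p = 0.116
#>   hla_mm      HR 1.188 (95% CI 1.068-1.322), z = 3.2, p = 0.00156

compare_models(fit_p, fit_h, fit_b)
#>    model     aic delta_aic  best
#> 3   both 5877.25      0.00  TRUE
#> 2    hla 5877.76      0.51 FALSE
#> 1 pirche 5885.19      7.94 FALSE

discrimination_auc(fit_b)$auc
#> 0.65        # 5-year discrimination of the full model
```

The single-exposure hazard ratios (1.183 per adjusted-score unit, 1.247 per
mismatch in this cohort) shrink toward 1 when both measures enter one model —
they carry overlapping information about the same donor–recipient
incompatibility, which is exactly the collinearity the cross-categorized
subgroup analysis (`cross_subgroup_hrs()`) is designed to unpick:

```r
cross_subgroup_hrs(cohort, "hla_coarse")
#>   subgroup    n events       term    hr ci_lower ci_upper     p
#> 1      0-3 4739    418 pirche_adj 1.079    0.971    1.198 0.159
#> 2      4-6  261     36 pirche_adj 1.605    0.864    2.983 0.134
```

Split-typed cohorts without known genotypes are scored through the
imputation driver:

```r
scorer <- genotype_scorer(ref$library, ref$predictor)
scored <- score_cohort(typed_rows, ref$haplotypes, ref$library, scorer)
# appends pirche_mean, pirche_sd, n_completions, hla_mm, score_error
```

## Package layout

| File | Contents |
| --- | --- |
| `R/hla-core.R` | allele library, split typings, genotypes, mismatch counting |
| `R/epitope-engine.R` | 15-mer enumeration, self-peptidome, PWM predictor, score, naive oracle, cached scorer |
| `R/imputation.R` | haplotype tables, genotype completions, weighted score moments, cohort driver |
| `R/score-transform.R` | 0–6 log adjustment, category schemes, Spearman correlation |
| `R/survival-models.R` | Cox models, subgroup HRs, AIC comparison, ROC discrimination |
| `R/synthetic-cohort.R` | generator configuration, reference data synthesis, cohort simulation |

The methods vignette (`vignettes/epitope-matching.Rmd`) documents the model,
the generator's assumptions and every tunable default.
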