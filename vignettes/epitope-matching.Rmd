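---
title: "Epitope-load scoring versus HLA antigen matching: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope-load scoring versus HLA antigen matching: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirchematch)
```

## The scientific problem

Kidney allocation systems match donor and recipient on HLA-A, -B and -DRB1
at the antigen level, summarized as a mismatch count from 0 to 6. T-cell
allorecognition, however, operates on peptides, not whole antigens: in the
indirect pathway, recipient antigen-presenting cells process donor HLA
proteins and present the fragments on HLA class II to CD4+ helper T cells,
which in turn drive donor-specific antibody formation and graft injury. An
epitope-load score of the PIRCHE-II family quantifies this risk as the number
of donor-derived peptides that could feed that pathway.

This package implements the full analysis chain needed to ask whether such a
score adds predictive value over — or could replace — the antigen mismatch
count as a predictor of death-censored graft survival: scoring, imputation
from allocation-grade typing, scale adjustment, and the multivariable
survival comparison, together with a synthetic cohort generator that makes
the chain testable without registry data.

## The epitope-load score

For donor genotype $D$ and recipient genotype $R$ (two-field alleles at
HLA-A, -B, -DRB1), the raw score counts unique presentable foreign peptides:

1. enumerate all 15-mer sliding windows of every distinct donor allele
   protein (the exon-2–5 encoded region; the input FASTA is assumed to carry
   sequences already restricted to it);
2. remove every 15-mer that also occurs in the recipient's *self-peptidome*,
   the set of 15-mers of the recipient's own HLA proteins at the configured
   self loci (A, B, DRB1 here; C and DQB1 can be added when the library
   carries them);
3. submit each surviving 15-mer to a presentation predictor for each of the
   recipient's DRB1 alleles; a presented call names a 9-mer binding core
   within the 15-mer;
4. the raw score is the number of distinct (core, presenter) pairs.

Step 4 encodes two counting rules: identical cores arising from different
15-mers count once for a given presenting DRB1 protein, and the same core
presented by two distinct DRB1 alleles counts once per presenter. Counting
per presenter (rather than over a global core set) follows the natural
reading of "once per presented protein"; the deduplication key is isolated
in one place in the scoring code should the alternative global-core
convention ever be needed.

Self-peptidome subtraction operates on exact 15-mer identity, not core
identity: a donor 15-mer is foreign as soon as the window itself is absent
from the recipient's repertoire, even if a 9-mer core inside it also occurs
in some self protein.

The predictor is a contract, not a fixed engine: any deterministic
`(15-mer, DRB1 allele) → (presented?, core)` function can be plugged in.
The bundled `pwm_predictor()` scores each of the seven 9-mer windows of a
15-mer against a per-allele 9×20 position weight matrix, takes the maximal
window as the core (leftmost on ties, so results are reproducible), and calls
the peptide presented when that score reaches the allele's threshold. It is
a transparent, fast stand-in for trained MHC class II predictors, which are
deliberately out of scope; the contract allows swapping one in without
touching the scoring core.

`brute_force_score()` recomputes the same contract with naive nested loops
and no set machinery; the test suite holds the optimized path equal to it on
over a thousand randomized instances.

## Imputation from split-level typing

Allocation typings are split-antigen level, so the genotype is uncertain.
Given an A~B~DRB1 haplotype frequency table, `enumerate_completions()` finds
all unordered haplotype pairs $(h_1, h_2)$ whose per-locus split projection
equals the observed typing, weights each pair $f(h_1) f(h_2)$, doubled when
$h_1 \neq h_2$ (Hardy–Weinberg random pairing), renormalizes over the
consistent set — the conditional genotype distribution given the typing —
and merges pairs that collapse to the same two-field genotype.

`imputed_pair_score()` treats donor and recipient completions as independent
(no linkage exists between two unrelated individuals), forms the product
distribution, and returns the weighted mean and weighted population SD of
the score. The SD is the score's imputation uncertainty: zero exactly when
both typings resolve uniquely. The mean — not mode or median — is the
point estimate passed downstream, left unrounded.

Mismatch counting uses the donor-antigen-not-in-recipient convention at
split level: per locus, the number of *unique* donor split antigens absent
from the recipient's pair (a homozygous donor's mismatched antigen counts
once), summed over A, B, DRB1. This is the Eurotransplant-style convention
of the allocation systems this analysis speaks to.

## Adjustment onto the 0–6 scale

Hazard ratios per raw-score unit and per mismatch are incommensurable (the
scales differ by two orders of magnitude), and the epitope effect has a
diminishing-returns shape. Both are addressed by

$$\mathrm{adj}_i = \ln(\mathrm{raw}_i + 1) \cdot
  \frac{6}{\max_j \ln(\mathrm{raw}_j + 1)}$$

with the maximum taken over the analysis cohort: raw 0 maps to 0, the cohort
maximum to 6, and the transform is strictly monotone, hence rank-preserving.
The fitted `adjustment_context` is stored and reapplied to new data rather
than refit — required for any allocation-time use, where a single patient
must be placed on the cohort's scale. Applying a stored context to data
exceeding the original maximum yields values above 6 by design.

Raw-score categories (0–1, 2–12, 13–25, 26–43, 44–68, 69–102, >102, built to
mirror the seven mismatch groups) are fixed printed constants with inclusive
upper bounds — 12 falls in 2–12, 13 in 13–25 — applied identically to
integer raw scores and non-integer imputed means. Whether categorization is
done on the raw or the adjusted scale is immaterial as long as boundaries are
mapped through the same monotone transform; the package defaults to the raw
scale and the test suite verifies the equivalence. For synthetic cohorts
whose score range differs, `derive_category_scheme()` rebuilds similarly
sized groups from target proportions.

## The survival comparison

The endpoint is 5-year death-censored graft survival: time to graft loss in
months, death with a functioning graft treated as non-informative censoring,
follow-up administratively censored at 60 months (the horizon is a
parameter). Three Cox proportional-hazards models are fitted: mismatches
only, adjusted score only, and both jointly, each alongside the full
confounder set (recipient/donor age and sex, time on dialysis, underlying
disease, panel-reactive antibodies, marginal donor, induction therapy,
initial immunosuppression, transplant era, cold ischemia time). Categorical
confounders carry explicit `"unknown"` levels so records with missing values
are never dropped; continuous confounders enter linearly by default. The
baseline hazard is stratified by country — each country contributes its own
baseline, and only within-country contrasts inform the coefficients — and
tied event times use Efron's approximation (Breslow available as a switch).
Both exposures enter linearly, so each HR is per adjusted-score unit or per
mismatch. No multiple-testing correction is applied; p-values are nominal,
and stated as such.

Because both exposures measure the same donor–recipient incompatibility,
they are positively correlated and the joint model attenuates both HRs
toward 1 relative to the single-exposure fits. The cross-categorized
subgroup analysis (`cross_subgroup_hrs()`) therefore estimates the per-unit
effect of one measure *within* categories of the other: the score's HR in
each of the seven mismatch strata (where the mismatch count is constant it
drops out of the subgroup model automatically) and in the coarse 0–3 vs 4–6
grouping, and conversely the mismatch HR within score categories. Subgroups
below a configurable minimum of events are flagged rather than fitted, and
convergence warnings from sparse factor levels are collected onto the row.

Model comparison uses the partial-likelihood AIC; discrimination is the ROC
AUC of the fitted linear predictor against the binary outcome "graft lost by
the horizon", excluding subjects censored earlier without an event, computed
with pROC.

## The synthetic cohort generator

The generator emulates the statistical skeleton the analysis assumes — not
the demographic margins of any real registry. Its defaults are the study
conditions under which the package's claims are tested:

* **Reference data.** Per locus a random ancestral protein of 90 residues
  (a deliberately scaled-down exon-2–5 region); split-antigen ancestors
  diverge from it by point substitutions at rate 0.15 per position, alleles
  within a split at 0.03 — so alleles of one split are far more alike than
  alleles of different splits, mirroring serology. Four splits at A and B,
  three at DRB1, two alleles each; a pool of 20 A~B~DRB1 haplotypes with
  Dirichlet(1) frequencies. With these settings raw scores span roughly
  0–40 and correlate with the mismatch count at Spearman ρ ≈ 0.5, the
  qualitative regime of real cohorts (whose longer proteins and larger
  allele pools stretch the range further).
* **Presentation.** Each DRB1 allele receives an independent standard-normal
  9×20 PWM; its threshold is the 0.75 quantile of that matrix's window
  scores over the whole library peptidome, so roughly a quarter of windows
  present and different alleles present different peptide sets.
* **Outcomes.** True scores are computed from the true genotypes (no
  imputation noise) while split typings are also emitted, so imputation
  error can be studied against ground truth. Graft-loss times are
  exponential with hazard
  $\lambda_0 \exp(\beta_P \cdot \mathrm{adj} + \beta_H \cdot \mathrm{mm} +
  \text{confounder effects} + \text{country effect})$;
  $\beta_P = \ln 1.102$ and $\beta_H = \ln 1.095$ by default. An optional
  interaction mode restricts the epitope effect to pairs above a mismatch
  threshold (default 3). The exponential baseline is the simplest
  PH-consistent choice; $\lambda_0$ is calibrated by root-finding so the
  expected event fraction within the 120-month follow-up horizon hits the
  15% target under the closed-form exponential-censoring formula.
  Independent exponential censoring (rate 1/240 per month) stands in for
  death with function and loss to follow-up.
* **Confounders** are drawn independently of the exposures by default —
  so omitting one biases nothing, though the fits include them all (Cox
  effects are non-collapsible) — with 8% unknown rates where registries
  typically have gaps (PRA, dialysis, immunosuppression) and a 13%
  presensitized fraction. A `confound_donor_age` toggle couples donor age
  to the mismatch count for sensitivity analyses.

Everything is driven by one mandatory seed: reference data use `seed`,
the cohort draw `seed + 1` by default, and replicate cohorts over a fixed
reference are obtained by varying `cohort_seed`. Regeneration is
byte-identical.

### What passing tests do and do not show

The generator's alleles are random sequences, its predictor is a random PWM,
and its hazards are exponential. Tests built on it demonstrate that the
*pipeline* is correct — counting rules, weighting, adjustment algebra,
model specification, recovery of known effects at registry-like sample
sizes — not that any particular biological prediction is accurate. Real
IPD-IMGT/HLA sequences, NMDP-style frequency tables and a trained class II
predictor can be substituted file-for-file through the same interfaces, and
conclusions about real cohorts require them.

## Numerical and design choices

* Weighted SDs are population SDs computed from central moments (no
  $E[X^2]-E[X]^2$ cancellation); completion weights renormalize over the
  consistent set to $\sum w = 1$ within $10^{-9}$.
* Core selection ties break leftmost, deterministically, by contract.
* The all-zero-score cohort leaves the adjustment undefined
  (`fit_adjustment()` errors); the generator handles the degenerate
  zero-divergence case by pinning adjusted scores at 0.
* Scoring is memoised at two levels — an integer-coded peptide vocabulary
  with per-presenter core maps, and a per-genotype-pair score cache — safe
  because the predictor contract demands determinism. The naive oracle
  shares none of this machinery.
* Problem sizes in the test suite (twelve-allele toy libraries with 20–35
  residue proteins on a reduced 6-letter alphabet for oracle equivalence;
  50 replicate cohorts of 20,000 patients for parameter recovery) were
  chosen so exhaustive oracles stay exact and Monte-Carlo checks retain
  power while the suite remains quick to run.
* Parameter recovery is verified in two arms, each with the other exposure's
  true effect at zero, because a single-exposure fit on a cohort where both
  effects act on correlated exposures estimates a marginal (confounded)
  quantity, not the generating coefficient; the attenuation of the joint
  model is verified separately on the correlated default configuration.

## Known limitations

* Only DRB1 presents; DRB3/4/5, DQ and DP presentation are out of scope,
  as are PIRCHE-I (direct recognition), affinity regression and rank
  thresholds.
* Split labels are opaque strings: no broad/split hierarchy, no nomenclature
  translation beyond the user-supplied allele→split map, no G/P groups.
* One haplotype panel at a time; no admixture mixtures or EM frequency
  estimation. Imputation accuracy in populations poorly covered by the
  supplied panel will degrade silently — the SD column is the only warning.
* Competing risks are not modelled; death with function is censoring by
  definition of the endpoint.
* The exponential baseline and independent censoring of the generator are
  conveniences; a Weibull switch exists, but time-varying effects and
  informative censoring are not simulated.
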