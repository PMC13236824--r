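---
title: "Partitioned polygenic risk, the plasma metabolome, and incident type 2 diabetes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned polygenic risk, the plasma metabolome, and incident type 2 diabetes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`metaboprs` implements a three-stage analysis linking type 2 diabetes
polygenic risk to plasma metabolites and to incident disease:

1. **Scores and association scan.** An overall polygenic risk score (oPRS)
   and eight cluster-partitioned scores (pPRS) are built from a variant
   weight table, and every transformed metabolite is regressed on every
   standardized score, with Benjamini–Hochberg FDR control.
2. **Structure of the associations.** Cross-cluster heterogeneity of each
   multi-cluster metabolite's effects (Cochran's Q, I²), principal
   components and pairwise correlations of the cluster association
   profiles, and biochemical class / metabolic pathway enrichment.
3. **Mediation.** Quasi-Bayesian counterfactual mediation of each
   significant score–metabolite pair against incident disease, with
   proportion-mediated estimation, suppression exclusion, sensitivity
   adjustments, and an elastic-net joint metabolite score evaluated on a
   discovery/validation split.

Because the individual-level data such an analysis needs are controlled
access, the package ships a synthetic cohort generator with known ground
truth; every stage is exercised and tested against it.

## Score construction

For subject $k$, a score over variant set $M$ is
$\mathrm{PRS}_k = \sum_{j \in M} a_{kj} W_j$, where $a_{kj}$ is the
risk-allele imputation dosage and $W_j = \ln \mathrm{OR}_j$ the log odds
ratio from the source GWAS. The overall score uses all variants; each
partitioned score uses one of eight non-overlapping mechanistic clusters
(two beta-cell clusters distinguished by proinsulin, residual glycaemic,
body fat, metabolic syndrome, obesity, lipodystrophy, liver/lipid).
Alleles are aligned before scoring: dosages counting the other allele are
flipped ($2 - d$), variants matching neither allele are dropped and
reported. Strand-ambiguous (A/T, C/G) variants are aligned literally with
a warning — the variant list is assumed curated upstream, and no
frequency-based strand check is attempted.

Standardization is two-step: z-score the raw score, regress on an
intercept plus the first ten genetic principal components, z-score the
residuals. z-scores use the sample ($n-1$) SD; the intercept is included
(the text this follows does not say either way). The result has mean 0,
SD 1, and zero sample correlation with every PC.

Missing per-sample dosages (possible in user-supplied files) are
mean-imputed per variant by default, with a drop-samples option; an
exclusion list handles variants known to be imputed with low confidence.

## Metabolite transformation pipeline

The pipeline is `filter -> log -> impute -> residualize -> inverse-normal`,
enforced as forward-only stages on the `metabolite_matrix` container:

* **Filter.** Metabolites with missing fraction strictly greater than 50%
  are removed (a column at exactly 50% is retained), as are chemically
  unidentified metabolites.
* **Log.** Raw platform intensities are positively skewed; the natural log
  is taken before imputation by default (off-switch provided).
* **KNN imputation, k = 10.** The reference this scheme descends from
  leaves the metric unstated; we use Euclidean distance over z-scored,
  mutually observed metabolite columns (normalized by the number of shared
  columns), neighbours drawn from samples with the target metabolite
  observed, unweighted mean of the k nearest donors, deterministic
  index-based tie-breaks. Observed values are never altered.
* **Residualization.** OLS residuals on intercept + batch (categorical
  indicators), age, BMI, smoking, alcohol, lipid-lowering medication, ten
  genetic PCs, and baseline disease status. Samples with missing
  covariates must be excluded upstream; rank-deficient designs are
  rejected naming the collinear columns.
* **Inverse-normal.** $\Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$ with
  the Blom offset $c = 3/8$ (rankit $c = 1/2$ by flag); ties get average
  ranks so tied inputs map to identical outputs.

Sensitivity subsets (no baseline disease, normal glucose tolerance,
baseline disease) refit the whole transformation inside the subset rather
than inheriting full-cohort transforms; the source text does not resolve
this, and refitting is the self-consistent choice.

## Association scan and FDR

Each transformed metabolite is regressed on each standardized score by
simple OLS (both are already residualized; covariates are not re-entered),
or with the overall score as an extra covariate for the oPRS-adjusted
rescan of the partitioned scores. p-values use the t distribution at the
simple-regression residual df; with both variables pre-residualized this
slightly overstates df, a negligible bias at cohort sizes in the
thousands. FDR families are per score (one score × all metabolites), with
a pooled mode by flag; per-score families match how per-cluster
significant counts are reported.

Disease associations use logistic regression (prevalent) and Cox
proportional hazards with Breslow ties (incident, baseline cases
excluded), adjusted for age, BMI and batch. Lipid chain-feature analysis
computes Spearman correlations between association betas and total
acyl-chain carbons / double bonds within pathways holding at least five
annotated lipids.

## Heterogeneity and enrichment

For metabolites significant in two or more clusters, Cochran's Q uses
inverse-variance weights; $I^2 = \max(0, (Q - df)/Q)$; a metabolite is
flagged heterogeneous when $p_Q < 0.05$ and $I^2 > 0.75$, both strict.
Only the significant clusters' estimates enter by default (the candidate
set is defined by significance); an all-eight mode is a flag. Association
profile PCA runs on the clusters × metabolites beta matrix with centered
columns and no scaling (betas share SD/SD units).

Enrichment fold is the ratio of a group's share among significant
metabolites to its share of the tested universe (all tested metabolites,
at both the class and pathway level). Significance uses a one-df Pearson
goodness-of-fit test per group, switching to the exact binomial when an
expected count falls below 5 — the uncorrected chi-square is unreliable
there, and the two branches necessarily differ away from the expectation
point. FDR is applied within each (score, level) family.

## Quasi-Bayesian mediation

For a significant (score, metabolite) pair among subjects free of
baseline disease, two models are fitted: a linear mediator model
(metabolite on score + covariates, the association covariate set minus
baseline status) and a logistic outcome model (incident indicator on
score + metabolite + covariates; follow-up time does not enter). The
algorithm draws `n_sims` coefficient vectors from each fit's asymptotic
normal; for each draw it simulates counterfactual mediator values under
the control and treated exposure levels (shared residual draws — common
random numbers reduce Monte-Carlo noise without changing the estimand),
pushes them through the outcome model, and averages the predicted
outcome-probability differences over the observed covariate distribution.
ACME and ADE are each the average of their two treatment-arm versions;
the total effect is their sum on the risk-difference scale. The treatment
contrast is mean vs mean + 1 SD of the (standardized) exposure. p-values
are twice the smaller tail fraction of draws crossing zero, floored at
`1/n_sims` (documented so FDR behaves with finite simulation); `n_sims`
defaults to 1000 and a seed is mandatory.

Proportion mediated is the point-estimate ratio
$(\mathrm{ACME}/\mathrm{total}) \times 100\%$ — not the draw-wise averaged
ratio, which differs. Triplets where ACME and ADE have opposite signs are
flagged as suppression and excluded from proportion summaries (the ratio
is uninterpretable there). Sensitivity re-runs append the overall score,
baseline HbA1c, or fasting glucose to both component models.

Joint mediation splits the baseline-free subjects 70/30 (unstratified by
default; stratified by incident status by flag), selects metabolites by
elastic net (mixing parameter 0.5 — unstated in the source, the
symmetric default; penalty by 10-fold cross-validation at `lambda.min`)
of the score on that score's significant metabolites in discovery, forms
the weighted metabolite score in validation, and runs single-mediator
mediation there.

On an identity-link outcome the whole machinery collapses to the
product-of-coefficients form ($\mathrm{ACME} = ab$,
$\mathrm{total} = ab + c'$), which the tests use as a closed-form oracle
(a = 0.5, b = 0.3, c' = 0.2 gives 0.15, 0.35, and 42.86% mediated).

## The synthetic cohort and its ground truth

The generator emulates a middle-aged male cohort: ~5000 subjects by
default (desk scale), 160 variants in 8 clusters with risk-allele
frequencies uniform on (0.05, 0.5) and GWAS-scale odds ratios
$\exp(N(0, 0.08))$; 200 metabolites of which 3 per cluster are genetic;
age uniform 45–74, log-normal BMI, binary smoking/alcohol/medication,
categorical batch, 10 standard-normal PCs; covariates independent of
genotype unless the confounding knob is set. Baseline disease depends on
age and BMI; its prevalence, and the 14% incident rate anchoring the
liability intercept, mirror a cohort of this design followed for about
15 years. Missingness is completely at random (the mechanism is not
characterized in the source; a configurable high-missingness block
exercises the >50% filter).

A genetic metabolite's per-variant effects are
$\beta_{mj} = \gamma_m W_j / \mathrm{sd}(\mathrm{PRS}_c) + N(0, \sigma_e)$:
an aligned component proportional to the risk weights plus idiosyncratic
deviations. The alignment is deliberate — a purely random effect vector is
nearly orthogonal to the weight vector, so the metabolite would barely
correlate with the weighted score and the generator would produce no
associations of the kind the analysis studies. $|\gamma_m|$ is log-normal
around 0.28 (median SD of log abundance per SD of cluster score) with
random sign. Optional "shared" metabolites draw aligned effects from two
clusters with independent magnitudes, producing genuine multi-cluster
associations and cross-cluster heterogeneity; without them every
metabolite is single-cluster by construction and the heterogeneity stage
has an empty candidate set.

Disease liability is
$\mathrm{logit}(p_0) + \text{covariates} + \theta(1-f)\,z(\mathrm{oPRS})
 + \sum_m b_m (\text{metabolite}_m - \bar\cdot)$,
with $\theta$ the total genetic effect per SD of the overall score and
$f$ the mediated fraction. The $b_m$ are calibrated per cluster,
$b_m \propto \theta_c f a_{cm} / \sum a^2$ with $a_{cm}$ the realized
slope of the complete (pre-missingness) metabolite on the standardized
cluster score, so the product-method proportion mediated on the liability
scale equals $f$ for every cluster jointly; ground truth records the
realized $a \cdot b$ products, which also covers the shared-metabolite
case exactly. The incident indicator is Bernoulli on the liability scale;
the estimand recovered downstream is on the risk-difference scale, and
the two stay close in this moderate-incidence regime — recovery tests
therefore use tolerance bands, not equalities. Follow-up time is
exponential within a 15-year horizon with independent uniform censoring
applied to a configurable fraction.

Every operation derives its own RNG stream from the master seed by fixed
offsets, so modules can be regenerated independently and all outputs are
bit-identical under a fixed seed.

**What passing tests do and do not show.** The generator has no linkage
disequilibrium, no metabolite correlation beyond shared genetic and
covariate components, no population stratification, and missingness is
MCAR. Passing recovery and calibration tests therefore demonstrates that
the estimators are correctly implemented and well calibrated under the
model's assumptions — not that those assumptions hold in real cohort
data, where unmeasured confounding of the metabolite–disease relation in
particular cannot be ruled out.

## Numerical choices and problem sizes

* OLS throughout via QR decomposition; logistic fits run to a gradient
  tolerance of 1e-10; singular designs are errors, not silent drops.
* BH q-values via the standard step-up procedure; p-values from the scan
  are floored at the smallest positive double so q-values stay in (0,1].
* KNN imputation computes pairwise distances in blocked matrix
  cross-products, making cohort-scale imputation a few seconds.
* Test problem sizes were chosen as the package's own desk-scale
  defaults: cohort recovery runs use n = 8000 with 24 metabolites over
  20 seeds; null calibration uses n = 5000 with 500 null metabolites over
  20 seeds and 500 null mediation triplets at n = 2000 with 200 draws;
  the full suite runs in a few minutes on one CPU.

## Known limitations

* Survival-scale mediation is out of scope: the outcome model is the
  incident indicator, not the Cox model used for the incident
  association scan.
* Proportion mediated is a ratio of noisy estimates; near-zero total
  effects make it unstable, which is why suppression triplets are
  excluded and joint estimates are summarized by medians across seeds.
* The per-score FDR family choice and the subset-refit choice are
  documented assumptions; both have flags to run the alternative.
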