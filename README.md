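# metaboprs

Partitioned polygenic risk scores, metabolome-wide association, and
causal mediation for incident type 2 diabetes.

## What this package is for

Type 2 diabetes genetic risk is heterogeneous: genome-wide significant
variants group into mechanistic clusters (beta-cell function with and
without disproportionate proinsulin, residual glycaemic, body fat,
metabolic syndrome, obesity, lipodystrophy, liver/lipid). `metaboprs` is
for statistical geneticists and metabolomics analysts who want to ask,
in a cohort with genotypes, untargeted plasma metabolomics and incident
disease follow-up:

1. Which metabolites track overall and cluster-partitioned polygenic
   risk?
2. Do those associations differ across clusters (heterogeneity), and do
   they concentrate in particular biochemical classes or metabolic
   pathways (enrichment)?
3. Are the associated metabolites statistically consistent with
   *mediating* part of the genetic effect on incident disease, and how
   much of that effect do they account for?

The score for subject *k* over variant set *M* is

```
PRS_k = Σ_{j∈M} a_kj · W_j,   W_j = ln(OR_j)
```

with `a_kj` the risk-allele dosage. Heterogeneity across the eight
cluster-specific effect estimates uses Cochran's Q with inverse-variance
weights and `I² = max(0, (Q − df)/Q)`; enrichment uses the fold
`(share of a group among significant metabolites) / (its share of the
universe)` with a χ²/exact-binomial goodness-of-fit test; mediation uses
the quasi-Bayesian counterfactual algorithm (simulated coefficient
draws, counterfactual mediator values, outcome-probability differences
averaged over the covariate distribution), reporting the average causal
mediation effect (ACME), average direct effect (ADE), total effect, and
the proportion mediated `(ACME/total)×100%` with suppression triplets
excluded.

Because cohort data of this kind are controlled access, the package
includes a first-class synthetic cohort generator with known ground
truth — including a tunable fraction of the genetic effect on disease
liability routed through metabolites — so the whole pipeline is testable
end to end.

## Worked example

```r
library(metaboprs)

cfg <- sim_config(n_subjects = 2000, n_metabolites = 60,
                  n_genetic_metabolites_per_cluster = 2,
                  n_shared_metabolites = 4, mediated_fraction = 0.3,
                  seed = 7)
cohort <- simulate_cohort(cfg)
cohort
#> <synthetic_cohort> 2000 subjects, 160 variants, 60 metabolites; incident cases: 239

rc <- run_config(out_dir = file.path(tempdir(), "demo"), n_sims = 300,
                 seed = 7, do_subsets = FALSE, do_disease = FALSE)
res <- run_pipeline(rc, cohort = cohort)
res
#> <run_summary>
#>   58 metabolites tested; significant: oPRS 14, any pPRS 20 (both 14)
#>   heterogeneous: 3 of 5 multi-cluster metabolites; enriched groups: 7
#>   mediation: 39 triplets, 9 significant ACME, median mediated 7.71%

head(res$assoc[order(res$assoc$q),
               c("score_id", "metabolite_id", "beta", "se", "p", "q")], 3)
#>              score_id metabolite_id      beta         se            p            q
#> 251          body_fat       met_019 0.3856544 0.02061970 4.638924e-72 2.690576e-70
#> 59  beta_cell_plus_PI       met_001 0.3498986 0.02093646 8.648152e-59 5.015928e-57
#> 239          body_fat       met_007 0.3280264 0.02111295 1.773118e-51 5.142043e-50
```

Reading the output: of 60 simulated metabolites (2 genetic per cluster,
4 shared between cluster pairs, the rest null; 2 dropped as unnamed), 20
are significantly associated with at least one partitioned score at
FDR < 5%, and the top hits are exactly the planted genetic metabolites
of their clusters, with betas in SD of metabolite per SD of score. Three
of the five metabolites significant in two or more clusters show
heterogeneous effects (Q test p < 0.05 and I² > 75%) — these are the
"shared" metabolites whose two cluster effects were drawn with different
magnitudes. The mediation screen runs one quasi-Bayesian triplet per
significant pair among subjects free of baseline disease; the median
proportion mediated across non-suppressed triplets (7.7%) sits near the
per-metabolite ground truth implied by the generating mediated fraction
of 0.3 split across each cluster's mediators.

Everything is also runnable from files (`weights.tsv`, dosage TSV or
DS-field VCF, metabolite/annotation/covariate/phenotype TSVs — see
`write_cohort_dir()` for the dialects) and from the CLI:

```sh
Rscript inst/cli/metaboprs.R simulate --out cohort_dir --seed 7
Rscript inst/cli/metaboprs.R run-all --cohort-dir cohort_dir --out results --seed 7
```

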