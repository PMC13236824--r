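test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(allele_freq_range = c(0.1, 1)), "allele_freq_range")
  expect_error(sim_config(allele_freq_range = c(0, 0.5)), "allele_freq_range")
  expect_error(sim_config(mediated_fraction = 1.2), "mediated_fraction")
  expect_error(sim_config(missing_rate = 0.9), "missing_rate")
  expect_error(sim_config(baseline_incidence = 0), "baseline_incidence")
  expect_error(sim_config(n_metabolites = 10,
                          n_genetic_metabolites_per_cluster = 2),
               "n_genetic_metabolites_per_cluster")
})

test_that("dosage means match binomial expectation within 3 SEs for every variant", {
  cfg <- sim_config(n_subjects = 5000, n_variants_per_cluster = rep(20L, 8),
                    seed = 101)
  g <- simulate_genotypes(cfg)
  f <- g$weights$freq
  n <- cfg$n_subjects
  se <- sqrt(2 * f * (1 - f) / n)
  dev <- abs(colMeans(g$dosages$dosage) - 2 * f) / se
  # ~0.3% of 160 variants may exceed 3 SEs by chance; none should be far out
  expect_lte(sum(dev > 3), 2)
  expect_lt(max(dev), 4)
  expect_true(all(g$dosages$dosage >= 0 & g$dosages$dosage <= 2))
  # clusters partition the variants exhaustively
  expect_equal(sort(unique(g$weights$cluster)), sort(cluster_labels()))
  expect_equal(as.vector(table(g$weights$cluster)[cluster_labels()]),
               rep(20L, 8))
})

test_that("noise-free metabolome equals the dosage-weighted genetic component", {
  cfg <- sim_config(n_subjects = 120, n_variants_per_cluster = rep(3L, 8),
                    n_metabolites = 20, n_genetic_metabolites_per_cluster = 1,
                    noise_sd = 0, covariate_effect_sd = 0, missing_rate = 0,
                    seed = 5)
  g <- simulate_genotypes(cfg)
  covars <- simulate_covariates(cfg)
  met <- simulate_metabolome(g$dosages, g$weights, covars, cfg)
  for (cl in cluster_labels()) {
    ids <- met$truth$truly_genetic_metabolites[[cl]]
    beta <- met$truth$genetic_effects[[cl]]
    expected <- g$dosages$dosage[, rownames(beta), drop = FALSE] %*% beta
    expect_equal(unname(met$truth$latent[, ids, drop = FALSE]),
                 unname(expected), tolerance = 1e-12)
  }
  # null metabolites carry no genetic component at all here
  nulls <- met$truth$true_null_metabolites
  expect_true(all(met$truth$latent[, nulls] == 0))
})

test_that("missingness is injected at the configured MCAR rate", {
  cfg0 <- sim_config(n_subjects = 300, n_variants_per_cluster = rep(3L, 8),
                     n_metabolites = 30, missing_rate = 0, seed = 9)
  coh0 <- simulate_cohort(cfg0)
  expect_false(anyNA(coh0$metabolites$abundance))

  cfg <- sim_config(n_subjects = 400, n_variants_per_cluster = rep(3L, 8),
                    n_metabolites = 200, n_genetic_metabolites_per_cluster = 1,
                    missing_rate = 0.1, seed = 9)
  coh <- simulate_cohort(cfg)
  frac <- mean(is.na(coh$metabolites$abundance))
  n_cells <- length(coh$metabolites$abundance)
  se <- sqrt(0.1 * 0.9 / n_cells)
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("genetic and null metabolite sets are disjoint and truth is coherent", {
  coh <- shared_cohort()
  tg <- unlist(coh$truth$truly_genetic_metabolites)
  expect_length(intersect(tg, coh$truth$true_null_metabolites), 0)
  expect_setequal(c(tg, coh$truth$true_null_metabolites),
                  colnames(coh$metabolites$abundance))
  # every metabolite has an annotation row
  expect_setequal(coh$annotation$metabolite_id,
                  colnames(coh$metabolites$abundance))
  ps <- coh$truth$true_mediated_proportion_single
  # per-cluster single proportions sum to the cluster's joint proportion
  for (cl in cluster_labels()) {
    expect_equal(sum(ps$true_prop_mediated[ps$cluster == cl]),
                 unname(coh$truth$true_mediated_proportion_cluster[[cl]]),
                 tolerance = 1e-8)
  }
})

test_that("mediated_fraction = 0 yields zero true mediated proportion everywhere", {
  cfg <- sim_config(n_subjects = 200, n_variants_per_cluster = rep(3L, 8),
                    n_metabolites = 20, n_genetic_metabolites_per_cluster = 1,
                    mediated_fraction = 0, missing_rate = 0, seed = 2)
  coh <- simulate_cohort(cfg)
  expect_true(all(coh$truth$true_mediated_proportion_single$true_prop_mediated == 0))
  expect_equal(coh$truth$true_mediated_proportion_overall, 0)
  expect_true(all(coh$truth$b_paths == 0))
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_subjects = 150, n_variants_per_cluster = rep(3L, 8),
                    n_metabolites = 15, n_genetic_metabolites_per_cluster = 1,
                    seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$dosages$dosage, b$dosages$dosage)
  expect_identical(a$metabolites$abundance, b$metabolites$abundance)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$truth$b_paths, b$truth$b_paths)
})

test_that("shared metabolites create genuine multi-cluster associations", {
  cfg <- sim_config(n_subjects = 2500, n_variants_per_cluster = rep(12L, 8),
                    n_metabolites = 40, n_genetic_metabolites_per_cluster = 2,
                    n_shared_metabolites = 6, missing_rate = 0, seed = 55)
  coh <- simulate_cohort(cfg)
  sets <- coh$truth$truly_genetic_metabolites
  shared <- names(which(table(unlist(sets)) == 2))
  expect_length(shared, 6)
  norm <- prep_metabolites(coh$metabolites, coh$covariates, coh$annotation)
  assoc <- scan_associations(coh$scores, norm)
  cand <- select_heterogeneity_candidates(assoc)
  # shared metabolites dominate the multi-cluster candidate set
  expect_gt(length(intersect(cand$multi_cluster, shared)), 0)
  het <- heterogeneity_scan(assoc)
  expect_gt(nrow(het), 0)
  expect_true(all(het$I2 >= 0 & het$I2 < 1))
  # ground truth stays coherent: per-cluster singles sum to the joint value
  ps <- coh$truth$true_mediated_proportion_single
  for (cl in cluster_labels()) {
    expect_equal(sum(ps$true_prop_mediated[ps$cluster == cl]),
                 unname(coh$truth$true_mediated_proportion_cluster[[cl]]),
                 tolerance = 1e-8)
  }
})

test_that("misaligned sample IDs are rejected", {
  cfg <- sim_config(n_subjects = 50, n_variants_per_cluster = rep(3L, 8),
                    n_metabolites = 10, n_genetic_metabolites_per_cluster = 1,
                    seed = 3)
  g <- simulate_genotypes(cfg)
  covars <- simulate_covariates(cfg)
  covars$sample_id <- rev(covars$sample_id)
  expect_error(simulate_metabolome(g$dosages, g$weights, covars, cfg),
               "not aligned")
})

test_that("lipid annotations carry chain features and pathways partition the universe", {
  coh <- shared_cohort()
  ann <- coh$annotation
  lip <- ann[ann$super_class == "Lipid", ]
  expect_true(all(!is.na(lip$n_carbons) & !is.na(lip$n_double_bonds)))
  expect_true(all(is.na(ann$n_carbons[ann$super_class != "Lipid"])))
  expect_false(any(is.na(ann$super_class)))
  expect_false(any(is.na(ann$sub_pathway)))
})
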