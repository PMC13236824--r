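#' Simulate the plasma metabolome with cluster-structured genetic effects
#'
#' Each cluster contributes genetic effects to its own
#' `n_genetic_metabolites_per_cluster` metabolites: on the latent (log
#' abundance) scale a genetic metabolite is the sum over that cluster's
#' variants of a per-variant effect times the risk-allele dosage, plus
#' random covariate terms and Gaussian noise. The remaining metabolites are
#' null (covariates + noise only). Reported abundances are exp(latent),
#' matching the positive raw scale of an untargeted platform, with
#' completely-at-random missingness injected at `config$missing_rate`.
#'
#' The annotation assigns each metabolite one of eight biochemical classes
#' and a metabolic sub-pathway; the genetic metabolites of one cluster
#' share a dedicated pathway, which gives enrichment tests a planted
#' signal. Lipid-class metabolites carry total acyl-chain carbon and
#' double-bond counts.
#'
#' @param dosages A `dosage_matrix` (risk-allele oriented).
#' @param weights A `variant_weights` table with a `cluster` column.
#' @param covariates Covariate table from [simulate_covariates()].
#' @param config A [sim_config()].
#' @return List with `metabolites` (a raw-stage `metabolite_matrix`),
#'   `annotation` (data frame), and `truth` (latent complete matrix,
#'   per-cluster genetic effect matrices, genetic/null metabolite sets).
#' @export
simulate_metabolome <- function(dosages, weights, covariates, config) {
  validate_sim_config(config)
  check_aligned_samples(sample_ids(dosages), covariates$sample_id,
                        "dosages", "covariates")
  n <- nrow(dosages$dosage)
  p <- config$n_metabolites
  g_per <- config$n_genetic_metabolites_per_cluster
  labels <- cluster_labels()
  met_ids <- sprintf("met_%03d", seq_len(p))
  genetic_sets <- list()
  with_stream(config$seed, "metabolome", {
    # covariate design shared by every metabolite
    z_age <- zscore(covariates$age, "age")
    z_bmi <- zscore(log(covariates$bmi), "log BMI")
    batch_mm <- model.matrix(~ batch - 1, data = covariates)
    covar_design <- cbind(z_age, z_bmi,
                          smoking = covariates$smoking,
                          alcohol = covariates$alcohol,
                          lipid_med = covariates$lipid_med,
                          batch_mm[, -1, drop = FALSE])
    latent <- matrix(0, n, p, dimnames = list(rownames(dosages$dosage), met_ids))
    effects <- list()
    idx <- 1L
    for (c_i in seq_along(labels)) {
      if (g_per == 0) { genetic_sets[[labels[c_i]]] <- character(0); next }
      ids <- met_ids[idx:(idx + g_per - 1L)]
      genetic_sets[[labels[c_i]]] <- ids
      vsel <- weights$variant_id[weights$cluster == labels[c_i]]
      w_c <- weights$weight[match(vsel, weights$variant_id)]
      sd_c <- sd(as.vector(dosages$dosage[, vsel, drop = FALSE] %*% w_c))
      # per-variant effect = aligned component (proportional to the risk
      # weight, giving the metabolite a real score association) plus an
      # idiosyncratic deviation
      gamma <- sample(c(-1, 1), g_per, replace = TRUE) *
        rlnorm(g_per, log(config$metabolite_prs_effect), 0.4)
      if (config$metabolite_prs_effect == 0) gamma <- rep(0, g_per)
      beta <- outer(w_c / sd_c, gamma) +
        matrix(rnorm(length(vsel) * g_per, 0, config$effect_size_sd),
               nrow = length(vsel), ncol = g_per)
      dimnames(beta) <- list(vsel, ids)
      latent[, ids] <- dosages$dosage[, vsel, drop = FALSE] %*% beta
      effects[[labels[c_i]]] <- beta
      idx <- idx + g_per
    }
    # shared metabolites: aligned effects from two clusters, with
    # independent magnitudes, so their cluster-specific association
    # coefficients genuinely differ (cross-cluster heterogeneity)
    shared_ids <- character(0)
    if (config$n_shared_metabolites > 0) {
      pairs <- cbind(1L + (seq_len(config$n_shared_metabolites) - 1L) %% 8,
                     1L + seq_len(config$n_shared_metabolites) %% 8)
      shared_ids <- met_ids[idx:(idx + config$n_shared_metabolites - 1L)]
      for (k in seq_along(shared_ids)) {
        id <- shared_ids[k]
        for (c_i in pairs[k, ]) {
          cl <- labels[c_i]
          vsel <- weights$variant_id[weights$cluster == cl]
          w_c <- weights$weight[match(vsel, weights$variant_id)]
          sd_c <- sd(as.vector(dosages$dosage[, vsel, drop = FALSE] %*% w_c))
          gamma <- sample(c(-1, 1), 1) *
            rlnorm(1, log(max(config$metabolite_prs_effect, 1e-8)), 0.4)
          if (config$metabolite_prs_effect == 0) gamma <- 0
          beta <- matrix(w_c / sd_c * gamma +
                           rnorm(length(vsel), 0, config$effect_size_sd),
                         ncol = 1, dimnames = list(vsel, id))
          latent[, id] <- latent[, id] +
            dosages$dosage[, vsel, drop = FALSE] %*% beta
          genetic_sets[[cl]] <- c(genetic_sets[[cl]], id)
          effects[[cl]] <- cbind(effects[[cl]], beta)
        }
      }
      idx <- idx + config$n_shared_metabolites
    }
    genetic_ids <- unique(unlist(genetic_sets, use.names = FALSE))
    null_ids <- setdiff(met_ids, genetic_ids)
    covar_coefs <- matrix(rnorm(ncol(covar_design) * p, 0, config$covariate_effect_sd),
                          nrow = ncol(covar_design), ncol = p)
    latent <- latent + covar_design %*% covar_coefs
    if (config$noise_sd > 0) {
      latent <- latent + matrix(rnorm(n * p, 0, config$noise_sd), n, p)
    }
    base_level <- rnorm(p, 2, 0.5)
    abundance <- exp(sweep(latent, 2, base_level, "+"))

    # missingness: MCAR everywhere, plus a block of high-missingness columns
    # among the null metabolites to exercise the >50% filter
    observed <- abundance
    with_stream(config$seed, "missing", {
      if (config$missing_rate > 0) {
        drop <- matrix(runif(n * p) < config$missing_rate, n, p)
        observed[drop] <- NA
      }
      if (config$n_high_missing > 0) {
        hi <- utils::head(null_ids, config$n_high_missing)
        for (id in hi) {
          extra <- runif(n) < config$high_missing_rate
          observed[extra, id] <- NA
        }
      }
    })

    annotation <- build_annotation(met_ids, genetic_sets, null_ids, config)
    list(
      metabolites = metabolite_matrix(observed, "raw"),
      annotation = annotation,
      truth = list(
        latent = latent,
        genetic_effects = effects,
        truly_genetic_metabolites = genetic_sets,
        true_null_metabolites = null_ids
      )
    )
  })
}

# classes follow the broad composition of an untargeted plasma platform
cluster_class_map <- function() {
  c(beta_cell_plus_PI = "Carbohydrate", beta_cell_minus_PI = "Amino Acid",
    residual_glycaemic = "Energy", body_fat = "Lipid",
    metabolic_syndrome = "Lipid", obesity = "Amino Acid",
    lipodystrophy = "Lipid", liver_lipid = "Lipid")
}

build_annotation <- function(met_ids, genetic_sets, null_ids, config) {
  classes <- c("Lipid", "Amino Acid", "Carbohydrate", "Nucleotide",
               "Peptide", "Cofactors and Vitamins", "Energy", "Xenobiotics")
  class_probs <- c(0.40, 0.20, 0.08, 0.07, 0.07, 0.08, 0.03, 0.07)
  cmap <- cluster_class_map()
  ann <- data.frame(metabolite_id = met_ids,
                    super_class = NA_character_,
                    sub_pathway = NA_character_,
                    n_carbons = NA_integer_,
                    n_double_bonds = NA_integer_,
                    named = TRUE,
                    stringsAsFactors = FALSE)
  rownames(ann) <- met_ids
  for (cl in names(genetic_sets)) {
    ids <- genetic_sets[[cl]]
    if (!length(ids)) next
    ann[ids, "super_class"] <- cmap[[cl]]
    ann[ids, "sub_pathway"] <- paste0("pw_", cl)
  }
  if (length(null_ids)) {
    cls <- sample(classes, length(null_ids), replace = TRUE, prob = class_probs)
    ann[null_ids, "super_class"] <- cls
    # a handful of generic pathways per class, partitioning the universe
    for (cc in unique(cls)) {
      ids <- null_ids[cls == cc]
      npw <- max(1L, ceiling(length(ids) / 8))
      ann[ids, "sub_pathway"] <- paste0(gsub(" ", "_", cc), "_pw",
                                        1L + (seq_along(ids) - 1L) %% npw)
    }
    n_unnamed <- round(config$frac_unnamed * length(null_ids))
    if (n_unnamed > 0) {
      ann[utils::tail(null_ids, n_unnamed), "named"] <- FALSE
    }
  }
  lip <- ann$super_class == "Lipid"
  ann$n_carbons[lip] <- sample(seq(14L, 44L, 2L), sum(lip), replace = TRUE)
  ann$n_double_bonds[lip] <- sample(0:6, sum(lip), replace = TRUE)
  rownames(ann) <- NULL
  ann
}
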