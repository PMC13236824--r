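#' Simulate incident disease with a tunable metabolite-mediated fraction
#'
#' Disease liability (log-odds scale) is
#' `logit(baseline_incidence) + covariate terms +
#'  theta * (1 - f) * z(oPRS) + sum_m b_m * (latent_m - mean)`,
#' where `theta = direct_logOR_per_sd_prs`, `f = mediated_fraction`, and the
#' mediator coefficients `b_m` are calibrated per cluster so that the
#' mediated path carries exactly a fraction `f` of each cluster's total
#' effect: writing `a_cm` for the realized slope of latent metabolite `m` on
#' the standardized cluster score, `b_m = theta_c * f * a_cm / sum(a_cm^2)`
#' with `theta_c = theta * sd(PRS_c) / sd(oPRS)`, so that
#' `sum_m a_cm * b_m = theta_c * f`. The product-method proportion mediated
#' on the liability scale is therefore `f` for every cluster jointly (and
#' for the overall score), and `f * a_cm^2 / sum(a^2)` for each single
#' metabolite; these are recorded as ground truth.
#'
#' The incident indicator is Bernoulli(expit(liability)) among subjects free
#' of baseline disease. Follow-up time is exponential within an
#' administrative horizon; an independent uniform censoring time is applied
#' to a `censoring_rate` fraction of subjects.
#'
#' @param scores A `score_set` from [compute_score_set()] (raw columns used).
#' @param metabolites_latent Complete latent metabolite matrix (the
#'   ground-truth copy produced by [simulate_metabolome()]).
#' @param covariates Covariate table.
#' @param config A [sim_config()].
#' @param truth Truth list from [simulate_metabolome()].
#' @return List with `phenotype` (data frame: sample_id, baseline_t2d,
#'   incident_t2d, followup_years) and the updated `truth` carrying b-paths,
#'   a-paths and true mediated proportions.
#' @export
simulate_outcomes <- function(scores, metabolites_latent, covariates, config,
                              truth) {
  validate_sim_config(config)
  check_aligned_samples(scores$sample_id, covariates$sample_id,
                        "scores", "covariates")
  check_aligned_samples(rownames(metabolites_latent), covariates$sample_id,
                        "metabolites", "covariates")
  n <- nrow(covariates)
  theta <- config$direct_logOR_per_sd_prs
  f <- config$mediated_fraction
  labels <- cluster_labels()

  raw_o <- scores$raw_oPRS
  sd_o <- sd(raw_o)
  z_o <- zscore(raw_o, "raw oPRS")

  # pass 1: realized a-paths per (cluster, metabolite) and the per-cluster
  # b-path allocations; a metabolite shared by two clusters accumulates both
  a_paths <- list()
  theta_cluster <- setNames(numeric(length(labels)), labels)
  alloc <- list()
  for (cl in labels) {
    ids <- truth$truly_genetic_metabolites[[cl]]
    raw_c <- scores[[paste0("raw_", cl)]]
    theta_cluster[[cl]] <- theta * sd(raw_c) / sd_o
    if (!length(ids)) next
    z_c <- zscore(raw_c, cl)
    a <- as.vector(stats::cov(metabolites_latent[, ids, drop = FALSE], z_c))
    a_paths[[cl]] <- setNames(a, ids)
    ssq <- sum(a^2)
    alloc[[cl]] <- if (ssq < 1e-12 || f == 0) setNames(rep(0, length(a)), ids)
      else setNames(theta_cluster[[cl]] * f * a / ssq, ids)
  }
  all_gen <- unique(unlist(lapply(alloc, names), use.names = FALSE))
  b_paths <- setNames(rep(0, length(all_gen)), all_gen)
  for (cl in names(alloc)) {
    b_paths[names(alloc[[cl]])] <- b_paths[names(alloc[[cl]])] + alloc[[cl]]
  }

  mediated_term <- numeric(n)
  if (length(b_paths) && any(b_paths != 0)) {
    gm <- metabolites_latent[, names(b_paths), drop = FALSE]
    centered <- sweep(gm, 2, colMeans(gm))
    mediated_term <- as.vector(centered %*% b_paths)
  }

  # pass 2: ground-truth proportions from the realized products a * b on
  # the liability scale (exactly mediated_fraction when no metabolite is
  # shared between clusters)
  prop_single <- data.frame(cluster = character(0), metabolite_id = character(0),
                            a_path = numeric(0), b_path = numeric(0),
                            true_prop_mediated = numeric(0),
                            stringsAsFactors = FALSE)
  cluster_joint <- setNames(rep(0, length(labels)), labels)
  for (cl in names(a_paths)) {
    a <- a_paths[[cl]]
    b <- b_paths[names(a)]
    th <- theta_cluster[[cl]]
    prop_single <- rbind(prop_single, data.frame(
      cluster = cl, metabolite_id = names(a), a_path = unname(a),
      b_path = unname(b), true_prop_mediated = unname(100 * a * b / th),
      stringsAsFactors = FALSE))
    cluster_joint[[cl]] <- 100 * sum(a * b) / th
  }
  overall_joint <- 0
  if (length(b_paths) && any(b_paths != 0)) {
    a_o <- as.vector(stats::cov(metabolites_latent[, names(b_paths),
                                                   drop = FALSE], z_o))
    indirect_o <- sum(a_o * b_paths)
    overall_joint <- 100 * indirect_o / (theta * (1 - f) + indirect_o)
  }

  z_age <- zscore(covariates$age, "age")
  z_bmi <- zscore(log(covariates$bmi), "log BMI")
  liability <- qlogis(config$baseline_incidence) +
    0.35 * z_age + 0.45 * z_bmi +
    theta * (1 - f) * z_o + mediated_term

  with_stream(config$seed, "outcomes", {
    at_risk <- covariates$baseline_t2d == 0
    incident <- integer(n)
    incident[at_risk] <- rbinom(sum(at_risk), 1, expit(liability[at_risk]))
    horizon <- config$followup_horizon_years
    t_event <- rexp(n, rate = 1 / (horizon / 2))
    followup <- ifelse(incident == 1, pmin(t_event, horizon * 0.99), horizon)
    censored <- runif(n) < config$censoring_rate
    c_time <- runif(n, 0.1, horizon)
    flip <- censored & c_time < followup
    incident[flip] <- 0L
    followup[flip] <- c_time[flip]
    phenotype <- data.frame(
      sample_id = covariates$sample_id,
      baseline_t2d = covariates$baseline_t2d,
      incident_t2d = incident,
      followup_years = followup,
      stringsAsFactors = FALSE
    )
    truth$a_paths <- a_paths
    truth$b_paths <- b_paths
    truth$liability <- liability
    truth$theta_total <- theta
    truth$direct_logOR <- theta * (1 - f)
    truth$mediated_fraction <- f
    truth$true_mediated_proportion_single <- prop_single
    truth$true_mediated_proportion_cluster <- cluster_joint
    truth$true_mediated_proportion_overall <- overall_joint
    list(phenotype = phenotype, truth = truth)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_covariates()], [simulate_metabolome()], raw score computation
#' and [simulate_outcomes()] in order, all driven by the master seed in the
#' config (each operation uses its own derived RNG stream).
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_cohort` with elements `config`,
#'   `weights`, `dosages`, `covariates`, `metabolites`, `annotation`,
#'   `scores` (raw + standardized), `phenotype` and `truth`.
#' @export
#' @examples
#' coh <- simulate_cohort(sim_config(n_subjects = 300, n_metabolites = 30,
#'                                   n_variants_per_cluster = rep(5L, 8),
#'                                   seed = 7))
#' names(coh)
simulate_cohort <- function(config) {
  geno <- simulate_genotypes(config)
  covars <- simulate_covariates(config, geno$dosages, geno$weights)
  met <- simulate_metabolome(geno$dosages, geno$weights, covars, config)
  pcs <- as.matrix(covars[, paste0("PC", 1:10)])
  scores <- compute_score_set(geno$dosages, geno$weights, pcs = pcs)
  out <- simulate_outcomes(scores, met$truth$latent, covars, config, met$truth)
  structure(list(
    config = config,
    weights = geno$weights,
    dosages = geno$dosages,
    covariates = covars,
    metabolites = met$metabolites,
    annotation = met$annotation,
    scores = scores,
    phenotype = out$phenotype,
    truth = out$truth
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d variants, %d metabolites; incident cases: %d\n",
              nrow(x$covariates), ncol(x$dosages$dosage),
              ncol(x$metabolites$abundance), sum(x$phenotype$incident_t2d)))
  invisible(x)
}
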