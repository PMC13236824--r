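#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a middle-aged male
#' cohort genotyped at cluster-assigned diabetes risk variants, profiled on
#' an untargeted metabolomics platform with missing values, and followed for
#' incident type 2 diabetes. Defaults are chosen once to resemble a
#' desk-scale version of such a cohort; see the methods vignette.
#'
#' @param n_subjects Number of subjects.
#' @param n_variants_per_cluster Integer vector of length 8: variants in each
#'   mechanistic cluster (see [cluster_labels()]).
#' @param allele_freq_range Interval strictly inside (0,1) from which risk
#'   allele frequencies are drawn uniformly.
#' @param n_metabolites Total number of metabolites (genetic + null).
#' @param n_genetic_metabolites_per_cluster Number of metabolites per cluster
#'   receiving genetic effects from that cluster's variants.
#' @param n_shared_metabolites Number of additional metabolites receiving
#'   genetic effects from two clusters (cycling over cluster pairs), with
#'   independent aligned magnitudes per cluster. These create genuine
#'   multi-cluster associations and cross-cluster heterogeneity; default 0.
#' @param effect_size_sd SD of the per-variant idiosyncratic effect on a
#'   genetic metabolite's latent (log) abundance (the component not
#'   aligned with the disease weights).
#' @param metabolite_prs_effect Median magnitude of a genetic metabolite's
#'   aligned effect: the expected latent change (in SD of log abundance)
#'   per SD of its cluster's score. Magnitudes are log-normal around this
#'   median (sdlog 0.4) with random sign, so every genetic metabolite has
#'   a non-degenerate score association.
#' @param or_log_sd SD of per-variant log odds ratios in the weight table.
#' @param covariate_effect_sd SD of random covariate coefficients on latent
#'   metabolite abundance and on disease liability.
#' @param noise_sd Residual SD of latent (log) metabolite abundance.
#' @param mediated_fraction Share of each cluster's effect on disease
#'   liability routed through that cluster's genetic metabolites, in [0,1].
#' @param direct_logOR_per_sd_prs Total genetic effect on liability per SD of
#'   the overall PRS (log-odds scale); the direct part is
#'   `(1 - mediated_fraction)` of it.
#' @param baseline_incidence Marginal incidence anchor in (0,1) for the
#'   liability intercept.
#' @param censoring_rate Probability a subject receives an independent early
#'   censoring time, in [0, 1].
#' @param missing_rate Completely-at-random missingness rate for metabolite
#'   cells, in [0, 0.7].
#' @param n_high_missing Number of metabolites additionally given
#'   `high_missing_rate` missingness (to exercise the >50% filter).
#' @param high_missing_rate Missingness rate for those metabolites.
#' @param frac_unnamed Fraction of metabolites flagged as unnamed
#'   (chemically unidentified).
#' @param confounding Strength of optional genotype-covariate confounding
#'   (0 = none, the default): the standardized overall genetic burden is
#'   added to z-scored log-BMI with this coefficient.
#' @param n_batches Number of metabolomics experiment batches.
#' @param followup_horizon_years Administrative follow-up horizon in years.
#' @param seed Master seed; every operation derives its own stream from it.
#'
#' @return An object of class `sim_config` (validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_subjects = 500, n_metabolites = 40, seed = 1)
sim_config <- function(n_subjects = 5000,
                       n_variants_per_cluster = rep(20L, 8),
                       allele_freq_range = c(0.05, 0.5),
                       n_metabolites = 200,
                       n_genetic_metabolites_per_cluster = 3,
                       n_shared_metabolites = 0,
                       effect_size_sd = 0.05,
                       metabolite_prs_effect = 0.28,
                       or_log_sd = 0.08,
                       covariate_effect_sd = 0.10,
                       noise_sd = 1,
                       mediated_fraction = 0.3,
                       direct_logOR_per_sd_prs = 0.45,
                       baseline_incidence = 0.14,
                       censoring_rate = 0.2,
                       missing_rate = 0.10,
                       n_high_missing = 0,
                       high_missing_rate = 0.6,
                       frac_unnamed = 0.05,
                       confounding = 0,
                       n_batches = 4,
                       followup_horizon_years = 15,
                       seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects,
    n_variants_per_cluster = as.integer(n_variants_per_cluster),
    allele_freq_range = allele_freq_range,
    n_metabolites = n_metabolites,
    n_genetic_metabolites_per_cluster = n_genetic_metabolites_per_cluster,
    n_shared_metabolites = n_shared_metabolites,
    effect_size_sd = effect_size_sd,
    metabolite_prs_effect = metabolite_prs_effect,
    or_log_sd = or_log_sd,
    covariate_effect_sd = covariate_effect_sd,
    noise_sd = noise_sd,
    mediated_fraction = mediated_fraction,
    direct_logOR_per_sd_prs = direct_logOR_per_sd_prs,
    baseline_incidence = baseline_incidence,
    censoring_rate = censoring_rate,
    missing_rate = missing_rate,
    n_high_missing = n_high_missing,
    high_missing_rate = high_missing_rate,
    frac_unnamed = frac_unnamed,
    confounding = confounding,
    n_batches = n_batches,
    followup_horizon_years = followup_horizon_years,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 1) {
    fail("n_subjects", "must be a positive count")
  }
  if (length(cfg$n_variants_per_cluster) != 8 ||
      any(cfg$n_variants_per_cluster < 1)) {
    fail("n_variants_per_cluster", "must be 8 positive counts")
  }
  r <- cfg$allele_freq_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] > r[2]) {
    fail("allele_freq_range",
         "must be an interval strictly inside (0,1); monomorphic variants (f = 0 or 1) are excluded")
  }
  if (cfg$n_metabolites < 1) fail("n_metabolites", "must be positive")
  if (cfg$n_genetic_metabolites_per_cluster < 0) {
    fail("n_genetic_metabolites_per_cluster", "must be nonnegative")
  }
  if (cfg$n_shared_metabolites < 0) {
    fail("n_shared_metabolites", "must be nonnegative")
  }
  if (8 * cfg$n_genetic_metabolites_per_cluster + cfg$n_shared_metabolites >
        cfg$n_metabolites) {
    fail("n_genetic_metabolites_per_cluster",
         "8 x n_genetic_metabolites_per_cluster + n_shared_metabolites exceeds n_metabolites")
  }
  if (cfg$mediated_fraction < 0 || cfg$mediated_fraction > 1) {
    fail("mediated_fraction", "must lie in [0,1]")
  }
  if (cfg$baseline_incidence <= 0 || cfg$baseline_incidence >= 1) {
    fail("baseline_incidence", "must lie in (0,1)")
  }
  if (cfg$censoring_rate < 0 || cfg$censoring_rate > 1) {
    fail("censoring_rate", "must lie in [0,1]")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate > 0.7) {
    fail("missing_rate", "must lie in [0,0.7]")
  }
  if (cfg$noise_sd < 0) fail("noise_sd", "must be nonnegative")
  if (cfg$metabolite_prs_effect < 0) {
    fail("metabolite_prs_effect", "must be nonnegative")
  }
  if (cfg$or_log_sd <= 0) fail("or_log_sd", "must be positive")
  if (cfg$n_batches < 1) fail("n_batches", "must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d subjects, %d variants in 8 clusters, %d metabolites (%d genetic)\n",
              x$n_subjects, sum(x$n_variants_per_cluster), x$n_metabolites,
              8 * x$n_genetic_metabolites_per_cluster))
  cat(sprintf("  mediated fraction %.2f, total logOR/SD oPRS %.2f, seed %d\n",
              x$mediated_fraction, x$direct_logOR_per_sd_prs, x$seed))
  invisible(x)
}
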