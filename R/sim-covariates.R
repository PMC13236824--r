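#' Simulate the covariate table
#'
#' Covariates mimic a middle-aged male cohort: age uniform on 45-74 years,
#' BMI log-normal, binary smoking / alcohol / lipid-lowering medication,
#' a categorical metabolomics batch, ten genetic principal components,
#' baseline type 2 diabetes status with its HbA1c and fasting glucose
#' correlates, and a normal-glucose-tolerance (NGT) flag. By default
#' covariates are independent of genotype; `config$confounding` adds the
#' standardized overall genetic burden into log-BMI.
#'
#' @param config A [sim_config()].
#' @param dosages Optional `dosage_matrix`; required when
#'   `config$confounding != 0`.
#' @param weights Optional `variant_weights`; required with `dosages`.
#' @return Data frame keyed by `sample_id`.
#' @export
simulate_covariates <- function(config, dosages = NULL, weights = NULL) {
  validate_sim_config(config)
  n <- config$n_subjects
  with_stream(config$seed, "covariates", {
    age <- runif(n, 45, 74)
    log_bmi <- log(27) + rnorm(n, 0, 0.15)
    if (config$confounding != 0) {
      if (is.null(dosages) || is.null(weights)) {
        stop("confounding != 0 requires dosages and weights", call. = FALSE)
      }
      burden <- as.vector(dosages$dosage %*% weights$weight)
      log_bmi <- log_bmi + config$confounding * zscore(burden, "genetic burden")
    }
    bmi <- exp(log_bmi)
    smoking <- rbinom(n, 1, 0.22)
    alcohol <- rbinom(n, 1, 0.55)
    lipid_med <- rbinom(n, 1, 0.25)
    batch <- sample(paste0("B", seq_len(config$n_batches)), n, replace = TRUE)
    pcs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    z_age <- zscore(age, "age")
    z_bmi <- zscore(log_bmi, "log BMI")
    lp_base <- qlogis(0.13) + 0.35 * z_age + 0.45 * z_bmi
    baseline_t2d <- rbinom(n, 1, expit(lp_base))
    hba1c <- 39 + 9 * baseline_t2d + 1.5 * z_age + 1.2 * z_bmi + rnorm(n, 0, 3)
    fasting_glucose <- 5.6 + 1.8 * baseline_t2d + 0.15 * z_age +
      0.2 * z_bmi + rnorm(n, 0, 0.5)
    ngt <- as.integer(baseline_t2d == 0 & fasting_glucose < 6.1)
    out <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      age = age, bmi = bmi, smoking = smoking, alcohol = alcohol,
      lipid_med = lipid_med, batch = batch,
      baseline_t2d = baseline_t2d, hba1c = hba1c,
      fasting_glucose = fasting_glucose, ngt = ngt,
      stringsAsFactors = FALSE
    )
    cbind(out, as.data.frame(pcs))
  })
}

# Default covariate sets used across the analysis stages.
metabolite_covariate_set <- function() {
  c("batch", "age", "bmi", "smoking", "alcohol", "lipid_med",
    paste0("PC", 1:10), "baseline_t2d")
}

mediation_covariate_set <- function() {
  setdiff(metabolite_covariate_set(), "baseline_t2d")
}
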