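#' Fit the mediator model (metabolite on score plus covariates)
#'
#' Ordinary least squares of the transformed metabolite on the
#' standardized score and the mediation covariate set. Returns the pieces
#' the quasi-Bayesian algorithm needs: coefficients, their covariance, the
#' residual SD, and the observed design.
#'
#' @param metabolite Numeric mediator vector.
#' @param score Numeric exposure vector (standardized score).
#' @param covariates Optional numeric matrix of covariates (no intercept).
#' @return List of class `mediator_fit`.
#' @export
fit_mediator_model <- function(metabolite, score, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, treat = score)
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0) {
    X <- cbind(X, as.matrix(covariates))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop("rank-deficient mediator design", call. = FALSE)
  }
  cf <- qr.coef(qx, metabolite)
  res <- qr.resid(qx, metabolite)
  df <- length(metabolite) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  vc <- sigma2 * XtXinv
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coef = cf, vcov = vc, sigma = sqrt(sigma2),
                 df_resid = df, X = X), class = "mediator_fit")
}

#' Fit the outcome model (incident disease on score, mediator, covariates)
#'
#' Maximum-likelihood logistic regression by default; `family =
#' gaussian()` gives the identity-link linear surrogate used by the
#' closed-form checks. Separation (non-convergence or runaway slope) is
#' flagged as failure.
#'
#' @param outcome Numeric outcome vector (0/1 for the binomial family).
#' @param score Exposure vector.
#' @param metabolite Mediator vector.
#' @param covariates Optional numeric covariate matrix.
#' @param family A [stats::family] object, `binomial()` or `gaussian()`.
#' @return List of class `outcome_fit` (with `converged`/`separation`).
#' @export
fit_outcome_model <- function(outcome, score, metabolite, covariates = NULL,
                              family = binomial()) {
  X <- cbind(`(Intercept)` = 1, treat = score, mediator = metabolite)
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0) {
    X <- cbind(X, as.matrix(covariates))
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, outcome, family = family,
                   control = list(epsilon = 1e-10, maxit = 100)))
  cf <- fit$coefficients
  separation <- identical(family$family, "binomial") &&
    (!fit$converged || any(abs(cf[c("treat", "mediator")]) > 15))
  # dispersion: 1 for binomial; residual MSE for gaussian
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  if (is.null(vc)) {
    stop("singular information matrix in outcome model", call. = FALSE)
  }
  if (identical(family$family, "gaussian")) {
    disp <- sum(fit$residuals^2 * w) / fit$df.residual
    vc <- vc * disp
  }
  dimnames(vc) <- list(colnames(X), colnames(X))
  structure(list(coef = cf, vcov = vc, family = family, X = X,
                 converged = fit$converged, separation = separation),
            class = "outcome_fit")
}

#' Quasi-Bayesian counterfactual mediation
#'
#' Implements the parametric quasi-Bayesian (King-Tomz-Wittenberg style)
#' algorithm for a continuous exposure, a linear mediator model and a
#' logistic (or linear) outcome model. `n_sims` parameter vectors are drawn
#' from each fit's asymptotic normal; for each draw, counterfactual
#' mediator values under the control and treated exposure levels are
#' simulated (shared residual draws), pushed through the outcome model,
#' and averaged over the observed covariate distribution. The average
#' causal mediation effect (ACME) and average direct effect (ADE) are the
#' averages of the two treatment-arm versions; the total effect is their
#' sum on the outcome (risk-difference) scale.
#'
#' The treatment contrast is control = sample mean of the exposure and
#' treated = mean + 1 SD, matching a standardized score.
#'
#' @param mediator_fit A `mediator_fit`.
#' @param outcome_fit An `outcome_fit` (must not be flagged for
#'   separation).
#' @param n_sims Number of quasi-Bayesian draws (>= 100).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param conf_level Percentile interval level.
#' @return One-row data frame of class `mediation_result`: `acme`, `ade`,
#'   `total`, percentile CIs, `p_acme`, `p_ade`, `p_total` (draw-crossing
#'   p-values, floored at `1/n_sims`), `prop_mediated_pct` (point-estimate
#'   ratio, absent under suppression), `suppression_flag`, `n_sims`,
#'   `seed`.
#' @export
quasi_bayesian_mediate <- function(mediator_fit, outcome_fit, n_sims = 1000,
                                   seed, conf_level = 0.95) {
  if (n_sims < 100) stop("n_sims must be at least 100", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (isTRUE(outcome_fit$separation)) {
    stop("outcome model flagged for separation; mediation not run",
         call. = FALSE)
  }
  set.seed(as.integer(seed) %% 2147483647)
  Xm <- mediator_fit$X
  Xo <- outcome_fit$X
  n <- nrow(Xm)
  stopifnot(nrow(Xo) == n)
  treat <- Xm[, "treat"]
  t0 <- mean(treat)
  t1 <- t0 + sd(treat)
  linkinv <- if (identical(outcome_fit$family$family, "binomial"))
    plogis else identity

  A <- MASS::mvrnorm(n_sims, mediator_fit$coef, mediator_fit$vcov)
  B <- MASS::mvrnorm(n_sims, outcome_fit$coef, outcome_fit$vcov)
  if (n_sims == 1) { A <- matrix(A, 1); B <- matrix(B, 1) }

  # mediator means under each exposure level: n x n_sims
  m_cols <- setdiff(colnames(Xm), "treat")
  Mbase <- Xm[, m_cols, drop = FALSE] %*% t(A[, m_cols, drop = FALSE])
  aT <- A[, "treat"]
  E <- matrix(rnorm(n * n_sims), n, n_sims) * rep(mediator_fit$sigma, each = n)
  M0 <- Mbase + rep(aT * t0, each = n) + E
  M1 <- Mbase + rep(aT * t1, each = n) + E

  o_cols <- setdiff(colnames(Xo), c("treat", "mediator"))
  Obase <- Xo[, o_cols, drop = FALSE] %*% t(B[, o_cols, drop = FALSE])
  bT <- B[, "treat"]
  bM <- B[, "mediator"]
  pr <- function(t, M) {
    colMeans(linkinv(Obase + rep(bT * t, each = n) +
                       M * rep(bM, each = n)))
  }
  y_t0_m0 <- pr(t0, M0); y_t0_m1 <- pr(t0, M1)
  y_t1_m0 <- pr(t1, M0); y_t1_m1 <- pr(t1, M1)
  acme_d <- ((y_t0_m1 - y_t0_m0) + (y_t1_m1 - y_t1_m0)) / 2
  ade_d <- ((y_t1_m0 - y_t0_m0) + (y_t1_m1 - y_t0_m1)) / 2
  tot_d <- acme_d + ade_d

  summ <- function(d) {
    alpha <- (1 - conf_level) / 2
    pv <- 2 * min(mean(d <= 0), mean(d >= 0))
    c(est = mean(d), lo = unname(quantile(d, alpha)),
      hi = unname(quantile(d, 1 - alpha)),
      p = min(1, max(pv, 1 / n_sims)))
  }
  sa <- summ(acme_d); sd_ <- summ(ade_d); st <- summ(tot_d)
  acme <- sa[["est"]]; ade <- sd_[["est"]]; total <- st[["est"]]
  suppression <- (acme != 0 && ade != 0 && sign(acme) != sign(ade))
  prop <- if (suppression || total == 0) NA_real_ else 100 * acme / total
  out <- data.frame(
    acme = acme, acme_lo = sa[["lo"]], acme_hi = sa[["hi"]], p_acme = sa[["p"]],
    ade = ade, ade_lo = sd_[["lo"]], ade_hi = sd_[["hi"]], p_ade = sd_[["p"]],
    total = total, total_lo = st[["lo"]], total_hi = st[["hi"]],
    p_total = st[["p"]],
    prop_mediated_pct = prop, suppression_flag = suppression,
    n_sims = as.integer(n_sims), seed = as.integer(seed),
    stringsAsFactors = FALSE)
  class(out) <- c("mediation_result", "data.frame")
  out
}

# Build the per-subject pieces mediation needs from a prepared bundle:
# subjects free of baseline disease, scores standardized and metabolites
# re-transformed within that subset, covariates as a numeric design.
mediation_bundle <- function(cohort, covariate_set = mediation_covariate_set(),
                             log_transform = TRUE) {
  keep <- cohort$phenotype$baseline_t2d == 0
  covars <- cohort$covariates[keep, , drop = FALSE]
  pheno <- cohort$phenotype[keep, , drop = FALSE]
  met_raw <- cohort$metabolites
  met_raw$abundance <- met_raw$abundance[keep, , drop = FALSE]
  prepped <- prep_metabolites(met_raw, covars, cohort$annotation,
                              covariate_set = covariate_set,
                              log_transform = log_transform)
  pcs <- as.matrix(covars[, paste0("PC", 1:10)])
  scores <- cohort$scores[keep, , drop = FALSE]
  std <- data.frame(sample_id = scores$sample_id, stringsAsFactors = FALSE)
  for (nm in c("oPRS", cluster_labels())) {
    raw_col <- paste0("raw_", nm)
    if (raw_col %in% names(scores)) {
      std[[paste0("std_", nm)]] <- residual_standardize(scores[[raw_col]], pcs)
    }
  }
  cov_design <- covariate_design(covars, covariate_set)
  list(scores = std, metabolites = prepped, covariates = covars,
       cov_design = cov_design, phenotype = pheno)
}

covariate_design <- function(covariates, covariate_set) {
  if (!length(covariate_set)) return(NULL)
  form <- stats::as.formula(paste("~", paste(covariate_set, collapse = " + ")))
  X <- model.matrix(form, data = covariates)
  X[, -1, drop = FALSE]  # intercept supplied by the fitters
}

#' Mediation screen over significant score-metabolite pairs
#'
#' For every FDR-significant (score, metabolite) association, fits the
#' mediator and outcome models among subjects free of baseline disease and
#' runs [quasi_bayesian_mediate()]. q-values over `p_acme` are computed per
#' score family. Suppression-flagged triplets stay in the output but are
#' excluded from proportion-mediated summaries.
#'
#' @param assoc Association records (used only to pick significant pairs).
#' @param cohort A `synthetic_cohort`-shaped bundle (or output of
#'   [read_cohort_dir()]): weights/scores/metabolites/covariates/phenotype.
#' @param n_sims Draws per triplet.
#' @param seed Master seed; each triplet derives its own stream.
#' @param q_threshold Association significance threshold.
#' @param adjustment One of `"base"`, `"oPRS"`, `"hba1c"`, `"glucose"`:
#'   extra covariate appended to both component models.
#' @param pairs Optional data frame (`score_id`, `metabolite_id`)
#'   overriding the significance-based pair selection.
#' @return Data frame of `MediationResult` rows.
#' @export
mediation_screen <- function(assoc, cohort, n_sims = 1000, seed,
                             q_threshold = 0.05,
                             adjustment = c("base", "oPRS", "hba1c", "glucose"),
                             pairs = NULL) {
  adjustment <- match.arg(adjustment)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  if (is.null(pairs)) {
    sig <- assoc[!assoc$error & !is.na(assoc$q) & assoc$q < q_threshold,
                 c("score_id", "metabolite_id")]
    pairs <- unique(sig)
  }
  empty <- data.frame(score_id = character(0), metabolite_id = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(cbind(empty))
  bundle <- mediation_bundle(cohort)
  run_mediation_pairs(pairs, bundle, n_sims = n_sims, seed = seed,
                      adjustment = adjustment)
}

run_mediation_pairs <- function(pairs, bundle, n_sims, seed, adjustment) {
  M <- bundle$metabolites$abundance
  y <- bundle$phenotype$incident_t2d
  Xc_base <- bundle$cov_design
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    sid <- pairs$score_id[i]; mid <- pairs$metabolite_id[i]
    s <- bundle$scores[[paste0("std_", sid)]]
    if (is.null(s)) stop("unknown score: ", sid, call. = FALSE)
    if (!mid %in% colnames(M)) next
    Xc <- Xc_base
    adj_tag <- "base"
    if (adjustment == "oPRS") {
      if (identical(sid, "oPRS")) {
        stop("cannot adjust the overall score for itself", call. = FALSE)
      }
      Xc <- cbind(Xc, adj_oPRS = bundle$scores$std_oPRS)
      adj_tag <- "oPRS_adjusted"
    } else if (adjustment == "hba1c") {
      Xc <- cbind(Xc, adj_hba1c = bundle$covariates$hba1c)
      adj_tag <- "hba1c_adjusted"
    } else if (adjustment == "glucose") {
      Xc <- cbind(Xc, adj_glucose = bundle$covariates$fasting_glucose)
      adj_tag <- "glucose_adjusted"
    }
    m <- M[, mid]
    mfit <- fit_mediator_model(m, s, Xc)
    ofit <- fit_outcome_model(y, s, m, Xc)
    if (ofit$separation) {
      rows[[i]] <- data.frame(score_id = sid, metabolite_id = mid,
                              acme = NA_real_, acme_lo = NA_real_,
                              acme_hi = NA_real_, p_acme = NA_real_,
                              ade = NA_real_, ade_lo = NA_real_,
                              ade_hi = NA_real_, p_ade = NA_real_,
                              total = NA_real_, total_lo = NA_real_,
                              total_hi = NA_real_, p_total = NA_real_,
                              prop_mediated_pct = NA_real_,
                              suppression_flag = NA,
                              n_sims = as.integer(n_sims),
                              seed = NA_integer_, q_acme = NA_real_,
                              adjustment_tag = adj_tag,
                              stringsAsFactors = FALSE)
      next
    }
    triplet_seed <- (as.numeric(seed) + seed_offsets[["mediate"]] +
                       7919 * i) %% 2147483647
    res <- quasi_bayesian_mediate(mfit, ofit, n_sims = n_sims,
                                  seed = triplet_seed)
    res$q_acme <- NA_real_
    res$adjustment_tag <- adj_tag
    rows[[i]] <- cbind(data.frame(score_id = sid, metabolite_id = mid,
                                  stringsAsFactors = FALSE),
                       as.data.frame(res))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out) || !nrow(out)) return(out)
  for (sid in unique(out$score_id)) {
    sel <- out$score_id == sid & !is.na(out$p_acme)
    if (any(sel)) out$q_acme[sel] <- bh_fdr(out$p_acme[sel])
  }
  rownames(out) <- NULL
  out
}

#' Sensitivity re-run of mediation triplets under extra adjustment
#'
#' Re-runs both component models with the overall score, baseline HbA1c or
#' fasting glucose appended to the covariates.
#'
#' @param triplets Data frame with `score_id`, `metabolite_id`.
#' @param cohort Cohort bundle as in [mediation_screen()].
#' @param adjustment `"oPRS"`, `"hba1c"` or `"glucose"`.
#' @param n_sims,seed As in [mediation_screen()].
#' @return Data frame of `MediationResult` rows with `adjustment_tag` set.
#' @export
mediation_sensitivity <- function(triplets, cohort,
                                  adjustment = c("oPRS", "hba1c", "glucose"),
                                  n_sims = 1000, seed) {
  adjustment <- match.arg(adjustment)
  mediation_screen(assoc = NULL, cohort = cohort, n_sims = n_sims,
                   seed = seed, adjustment = adjustment,
                   pairs = triplets[, c("score_id", "metabolite_id")])
}

#' Elastic-net joint mediation with a discovery/validation split
#'
#' Splits subjects free of baseline disease into discovery (70%) and
#' validation (30%) sets; fits an elastic net of the standardized score on
#' the score's significant metabolites in discovery (penalty chosen by
#' cross-validation); forms a metabolite score in validation from the
#' nonzero weights; and runs a single-mediator quasi-Bayesian mediation of
#' the exposure through that metabolite score.
#'
#' @param score_id Score to analyse.
#' @param assoc Association records giving the significant metabolites.
#' @param cohort Cohort bundle.
#' @param split Discovery fraction (default 0.7).
#' @param en_alpha Elastic-net mixing parameter (default 0.5).
#' @param split_seed Seed controlling the partition, the cross-validation
#'   folds and the mediation draws.
#' @param n_sims Mediation draws.
#' @param q_threshold Association significance threshold.
#' @param stratify Stratify the split by incident status.
#' @return List of class `joint_mediation_result`.
#' @export
joint_mediation <- function(score_id, assoc, cohort, split = 0.7,
                            en_alpha = 0.5, split_seed, n_sims = 1000,
                            q_threshold = 0.05, stratify = FALSE) {
  if (missing(split_seed)) stop("split_seed is required", call. = FALSE)
  sig <- assoc$metabolite_id[assoc$score_id == score_id & !assoc$error &
                               !is.na(assoc$q) & assoc$q < q_threshold]
  sig <- unique(sig)
  if (length(sig) < 2) {
    stop("joint mediation needs at least 2 significant metabolites for ",
         score_id, call. = FALSE)
  }
  bundle <- mediation_bundle(cohort)
  M <- bundle$metabolites$abundance
  sig <- intersect(sig, colnames(M))
  s <- bundle$scores[[paste0("std_", score_id)]]
  y <- bundle$phenotype$incident_t2d
  n <- length(s)
  set.seed((as.numeric(split_seed) + seed_offsets[["split"]]) %% 2147483647)
  if (stratify) {
    idx1 <- which(y == 1); idx0 <- which(y == 0)
    disc <- c(sample(idx1, round(split * length(idx1))),
              sample(idx0, round(split * length(idx0))))
  } else {
    disc <- sample(n, round(split * n))
  }
  disc <- sort(disc)
  valid <- setdiff(seq_len(n), disc)
  cvfit <- glmnet::cv.glmnet(M[disc, sig, drop = FALSE], s[disc],
                             alpha = en_alpha, nfolds = 10)
  w <- as.vector(coef(cvfit, s = "lambda.min"))[-1]
  names(w) <- sig
  selected <- sig[w != 0]
  result <- list(score_id = score_id, selected_metabolites = selected,
                 elastic_net_weights = w[w != 0], split_seed = split_seed,
                 n_discovery = length(disc), n_validation = length(valid),
                 validation = NULL)
  if (!length(selected)) {
    class(result) <- "joint_mediation_result"
    return(result)
  }
  met_score <- as.vector(M[valid, selected, drop = FALSE] %*% w[selected])
  Xc <- bundle$cov_design[valid, , drop = FALSE]
  mfit <- fit_mediator_model(met_score, s[valid], Xc)
  ofit <- fit_outcome_model(y[valid], s[valid], met_score, Xc)
  med <- quasi_bayesian_mediate(mfit, ofit, n_sims = n_sims,
                                seed = split_seed)
  result$validation <- med
  result$validation_acme <- med$acme
  result$validation_total <- med$total
  result$validation_prop_pct <- med$prop_mediated_pct
  class(result) <- "joint_mediation_result"
  result
}

#' @export
print.joint_mediation_result <- function(x, ...) {
  cat(sprintf("<joint_mediation> %s: %d metabolites selected", x$score_id,
              length(x$selected_metabolites)))
  if (!is.null(x$validation)) {
    cat(sprintf("; validation ACME %.4f, total %.4f, mediated %.1f%%",
                x$validation_acme, x$validation_total,
                x$validation_prop_pct))
  }
  cat("\n")
  invisible(x)
}
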