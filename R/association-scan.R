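#' Benjamini-Hochberg q-values
#'
#' Step-up FDR q-values for one testing family (monotone, bounded by 1).
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return q-values in the same order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) stop("empty FDR family", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Metabolome-wide association scan
#'
#' Regresses every transformed metabolite on every standardized score by
#' ordinary least squares (`metabolite ~ score`, both already residualized
#' by their upstream pipelines), optionally with extra covariates in the
#' model — used for the overall-score-adjusted rescan of the partitioned
#' scores. q-values are computed by Benjamini-Hochberg, by default within
#' one family per score.
#'
#' @param scores A `score_set` with `std_` columns (or any data frame with
#'   `sample_id` plus numeric score columns).
#' @param metabolites A normalized-stage `metabolite_matrix`.
#' @param score_ids Score columns to scan (default: all `std_` columns,
#'   reported without the prefix).
#' @param subset_tag Label recorded on every record (for example `"all"`,
#'   `"no_baseline_t2d"`, `"NGT"`, `"baseline_t2d"`, `"oPRS_adjusted"`).
#' @param extra_covariates Optional numeric matrix/data frame (aligned to
#'   samples) entered alongside the score.
#' @param fdr_family `"per_score"` (default) or `"pooled"`.
#' @return Data frame of association records: `score_id`, `metabolite_id`,
#'   `subset_tag`, `beta`, `se`, `p`, `q`, `n`, `error`.
#' @export
scan_associations <- function(scores, metabolites,
                              score_ids = NULL,
                              subset_tag = "all",
                              extra_covariates = NULL,
                              fdr_family = c("per_score", "pooled")) {
  fdr_family <- match.arg(fdr_family)
  stopifnot(inherits(metabolites, "metabolite_matrix"))
  if (metabolites$stage != "normalized") {
    stop("association scan expects metabolites at stage 'normalized'",
         call. = FALSE)
  }
  M <- metabolites$abundance
  common <- intersect(scores$sample_id, rownames(M))
  if (length(common) < 30) {
    stop("fewer than 30 overlapping samples between scores and metabolites",
         call. = FALSE)
  }
  M <- M[common, , drop = FALSE]
  scores <- scores[match(common, scores$sample_id), , drop = FALSE]
  if (is.null(score_ids)) {
    score_ids <- sub("^std_", "", grep("^std_", names(scores), value = TRUE))
  }
  n <- length(common)
  res_list <- vector("list", length(score_ids))
  for (si in seq_along(score_ids)) {
    sid <- score_ids[si]
    col <- if (paste0("std_", sid) %in% names(scores)) paste0("std_", sid) else sid
    s <- scores[[col]]
    if (is.null(s)) stop("score column not found: ", sid, call. = FALSE)
    if (sd(s) == 0) {
      res_list[[si]] <- data.frame(
        score_id = sid, metabolite_id = colnames(M), subset_tag = subset_tag,
        beta = NA_real_, se = NA_real_, p = NA_real_, q = NA_real_,
        n = n, error = TRUE, stringsAsFactors = FALSE)
      next
    }
    X <- cbind(intercept = 1, score = s)
    if (!is.null(extra_covariates)) {
      ec <- as.matrix(extra_covariates)
      if (is.null(rownames(ec))) {
        stop("extra_covariates must carry sample IDs as rownames", call. = FALSE)
      }
      X <- cbind(X, ec[common, , drop = FALSE])
    }
    qx <- qr(X)
    coefs <- qr.coef(qx, M)
    resid <- qr.resid(qx, M)
    df <- n - ncol(X)
    sigma2 <- colSums(resid^2) / df
    xtx_inv_22 <- chol2inv(qr.R(qx))[2, 2]
    beta <- coefs["score", ]
    se <- sqrt(sigma2 * xtx_inv_22)
    tval <- beta / se
    p <- 2 * pt(-abs(tval), df)
    p <- pmax(p, .Machine$double.xmin)  # keep p in (0,1] for FDR
    res_list[[si]] <- data.frame(
      score_id = sid, metabolite_id = colnames(M), subset_tag = subset_tag,
      beta = unname(beta), se = unname(se), p = unname(p), q = NA_real_,
      n = n, error = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res_list)
  ok <- !out$error
  if (any(ok)) {
    if (fdr_family == "per_score") {
      for (sid in unique(out$score_id)) {
        sel <- ok & out$score_id == sid
        if (any(sel)) out$q[sel] <- bh_fdr(out$p[sel])
      }
    } else {
      out$q[ok] <- bh_fdr(out$p[ok])
    }
  }
  rownames(out) <- NULL
  out
}

#' Prevalent and incident disease associations per metabolite
#'
#' Prevalent: logistic regression of baseline disease on the metabolite
#' adjusted for age, BMI and batch. Incident: Cox proportional hazards
#' (Breslow ties) on follow-up time among subjects free of baseline
#' disease, same adjustment.
#'
#' @param metabolites A `metabolite_matrix` at stage `normalized` (or any
#'   later-stage numeric matrix container).
#' @param phenotype Data frame with `sample_id`, `baseline_t2d`,
#'   `incident_t2d`, `followup_years`.
#' @param covariates Covariate table with `age`, `bmi`, `batch`.
#' @return Data frame per metabolite: prevalent log-OR/CI/p, incident
#'   log-HR/CI/p, and a `flagged` column for separation or fit failure.
#' @export
disease_association <- function(metabolites, phenotype, covariates) {
  M <- metabolites$abundance
  check_aligned_samples(rownames(M), phenotype$sample_id,
                        "metabolites", "phenotype")
  check_aligned_samples(rownames(M), covariates$sample_id,
                        "metabolites", "covariates")
  if (all(phenotype$followup_years <= 0)) {
    stop("all follow-up times are zero; no person-time to analyse",
         call. = FALSE)
  }
  base <- data.frame(age = covariates$age, bmi = covariates$bmi,
                     batch = factor(covariates$batch))
  at_risk <- phenotype$baseline_t2d == 0
  out <- vector("list", ncol(M))
  for (j in seq_len(ncol(M))) {
    d <- cbind(met = M[, j], base,
               y = phenotype$baseline_t2d,
               time = phenotype$followup_years,
               ev = phenotype$incident_t2d)
    fit_l <- suppressWarnings(glm(y ~ met + age + bmi + batch,
                                  data = d, family = binomial()))
    sep <- !fit_l$converged || abs(coef(fit_l)["met"]) > 15
    lor <- if (sep) NA_real_ else unname(coef(fit_l)["met"])
    lse <- if (sep) NA_real_ else sqrt(vcov(fit_l)["met", "met"])
    fit_c <- tryCatch(
      coxph(Surv(time, ev) ~ met + age + bmi + batch,
            data = d[at_risk, , drop = FALSE], ties = "breslow"),
      error = function(e) NULL)
    lhr <- if (is.null(fit_c)) NA_real_ else unname(coef(fit_c)["met"])
    hse <- if (is.null(fit_c)) NA_real_ else sqrt(vcov(fit_c)["met", "met"])
    out[[j]] <- data.frame(
      metabolite_id = colnames(M)[j],
      prevalent_logOR = lor, prevalent_se = lse,
      prevalent_lo = lor - 1.96 * lse, prevalent_hi = lor + 1.96 * lse,
      prevalent_p = if (sep) NA_real_ else 2 * pnorm(-abs(lor / lse)),
      incident_logHR = lhr, incident_se = hse,
      incident_lo = lhr - 1.96 * hse, incident_hi = lhr + 1.96 * hse,
      incident_p = if (is.null(fit_c)) NA_real_ else 2 * pnorm(-abs(lhr / hse)),
      flagged = sep || is.null(fit_c),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Spearman correlation of lipid chain features with association betas
#'
#' Within each metabolic pathway containing at least `min_lipids` lipids
#' with annotated acyl-chain features, correlates total carbon count and
#' total double-bond count with the per-lipid association coefficients for
#' each score. Pathways below the size threshold are skipped.
#'
#' @param assoc Association records from [scan_associations()].
#' @param annotation Annotation with `super_class`, `sub_pathway`,
#'   `n_carbons`, `n_double_bonds`.
#' @param min_lipids Minimum annotated lipids per pathway (default 5).
#' @return Data frame: `score_id`, `sub_pathway`, `feature`, `rho`, `p`,
#'   `n_lipids`.
#' @export
lipid_feature_correlation <- function(assoc, annotation, min_lipids = 5) {
  lip <- annotation[annotation$super_class == "Lipid" &
                      !is.na(annotation$n_carbons), , drop = FALSE]
  rows <- list()
  for (sid in unique(assoc$score_id)) {
    a <- assoc[assoc$score_id == sid & !assoc$error, , drop = FALSE]
    for (pw in unique(lip$sub_pathway)) {
      ids <- lip$metabolite_id[lip$sub_pathway == pw]
      sel <- a[a$metabolite_id %in% ids, , drop = FALSE]
      if (nrow(sel) < min_lipids) next
      ann <- lip[match(sel$metabolite_id, lip$metabolite_id), ]
      for (feat in c("n_carbons", "n_double_bonds")) {
        ct <- suppressWarnings(
          cor.test(ann[[feat]], sel$beta, method = "spearman", exact = FALSE))
        rows[[length(rows) + 1L]] <- data.frame(
          score_id = sid, sub_pathway = pw, feature = feat,
          rho = unname(ct$estimate), p = ct$p.value, n_lipids = nrow(sel),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(score_id = character(0), sub_pathway = character(0),
                      feature = character(0), rho = numeric(0), p = numeric(0),
                      n_lipids = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
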