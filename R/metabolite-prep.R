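#' Filter metabolites on missingness and chemical identification
#'
#' Removes metabolites whose missing fraction is strictly greater than
#' `max_missing` (a column at exactly the threshold is retained), and
#' optionally removes unnamed (chemically unidentified) metabolites.
#'
#' @param x A raw-stage `metabolite_matrix`.
#' @param max_missing Maximum tolerated missing fraction (default 0.5).
#' @param drop_unnamed Drop metabolites flagged unnamed in `annotation`.
#' @param annotation Annotation data frame with `metabolite_id` and `named`;
#'   required when `drop_unnamed = TRUE`.
#' @return A filtered-stage `metabolite_matrix` with attribute `removal_log`
#'   (data frame: metabolite_id, reason).
#' @export
filter_missingness <- function(x, max_missing = 0.5, drop_unnamed = TRUE,
                               annotation = NULL) {
  stopifnot(inherits(x, "metabolite_matrix"))
  ab <- x$abundance
  frac <- colMeans(is.na(ab))
  reason <- setNames(rep(NA_character_, ncol(ab)), colnames(ab))
  reason[frac > max_missing] <- "missingness"
  if (drop_unnamed) {
    if (is.null(annotation)) {
      stop("drop_unnamed = TRUE requires an annotation table", call. = FALSE)
    }
    unnamed <- annotation$metabolite_id[!annotation$named]
    reason[colnames(ab) %in% unnamed & is.na(reason)] <- "unnamed"
  }
  keep <- names(reason)[is.na(reason)]
  if (!length(keep)) {
    stop("no metabolites survive the missingness/identification filter",
         call. = FALSE)
  }
  out <- advance_stage(x, "raw", "filtered")
  out$abundance <- ab[, keep, drop = FALSE]
  removed <- reason[!is.na(reason)]
  attr(out, "removal_log") <- data.frame(metabolite_id = names(removed),
                                         reason = unname(removed),
                                         stringsAsFactors = FALSE)
  out
}

#' Impute missing metabolite values by k nearest neighbours
#'
#' For each missing cell, the k nearest samples (Euclidean distance over
#' z-scored metabolite columns observed in both samples, normalized by the
#' number of shared columns) among those with the target metabolite
#' observed donate their values; the imputed value is their unweighted
#' mean. Observed values are never altered; the result is deterministic.
#'
#' @param x A filtered-stage `metabolite_matrix`.
#' @param k Number of neighbours (default 10); capped at the number of
#'   eligible donors.
#' @return An imputed-stage `metabolite_matrix` with no missing cells.
#' @export
knn_impute <- function(x, k = 10) {
  stopifnot(inherits(x, "metabolite_matrix"), k >= 1)
  ab <- x$abundance
  out <- advance_stage(x, "filtered", "imputed")
  if (!anyNA(ab)) {
    return(out)
  }
  all_missing <- rowSums(!is.na(ab)) == 0
  if (any(all_missing)) {
    stop("samples with all metabolites missing: ",
         paste(rownames(ab)[all_missing], collapse = ", "), call. = FALSE)
  }
  mu <- colMeans(ab, na.rm = TRUE)
  sdv <- apply(ab, 2, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(ab, 2, mu), 2, sdv, "/")
  obs <- !is.na(z)
  obsd <- matrix(as.double(obs), nrow(obs), ncol(obs))
  z0 <- z; z0[!obs] <- 0
  n <- nrow(ab)
  need <- which(rowSums(!obs) > 0)
  filled <- ab
  sq_obs <- z0^2                       # zero where missing already
  row_idx <- seq_len(n)
  # mean squared difference over mutually observed columns, computed in
  # blocks via cross-products on the zero-filled z matrix:
  # sum_shared (zi - zj)^2 = sum_shared zi^2 + sum_shared zj^2 - 2 zi.zj
  block <- 256L
  for (b0 in seq(1L, length(need), by = block)) {
    rows <- need[b0:min(b0 + block - 1L, length(need))]
    Zb <- z0[rows, , drop = FALSE]
    Ob <- obsd[rows, , drop = FALSE]
    cross <- Zb %*% t(z0)
    self_b <- (Zb^2) %*% t(obsd)
    other <- Ob %*% t(sq_obs)
    shared <- Ob %*% t(obsd)
    d2 <- (self_b + other - 2 * cross) / pmax(shared, 1)
    d2[shared == 0] <- Inf
    for (bi in seq_along(rows)) {
      i <- rows[bi]
      di <- d2[bi, ]
      di[i] <- Inf
      ord <- row_idx[order(di, row_idx)]   # deterministic tie-break by index
      ord <- ord[is.finite(di[ord])]
      for (j in which(!obs[i, ])) {
        donors <- ord[obs[ord, j]]
        if (!length(donors)) {             # no informative neighbour: column mean
          filled[i, j] <- mean(ab[, j], na.rm = TRUE)
          next
        }
        filled[i, j] <- mean(ab[donors[seq_len(min(k, length(donors)))], j])
      }
    }
  }
  out$abundance <- filled
  out
}

#' Regress covariates out of every metabolite
#'
#' Replaces each metabolite column by its ordinary-least-squares residuals
#' on an intercept plus the requested covariates; categorical covariates
#' (for example the metabolomics batch) enter as indicator columns.
#' Samples with incomplete covariates must be excluded upstream.
#'
#' @param x An imputed-stage `metabolite_matrix`.
#' @param covariates Covariate data frame aligned to the matrix samples.
#' @param covariate_set Character vector of covariate column names; empty
#'   set means centering only.
#' @return A residualized-stage `metabolite_matrix`.
#' @export
residualize_covariates <- function(x, covariates,
                                   covariate_set = metabolite_covariate_set()) {
  stopifnot(inherits(x, "metabolite_matrix"))
  out <- advance_stage(x, "imputed", "residualized")
  ab <- x$abundance
  check_aligned_samples(rownames(ab), covariates$sample_id,
                        "metabolites", "covariates")
  if (!length(covariate_set)) {
    out$abundance <- sweep(ab, 2, colMeans(ab))
    return(out)
  }
  miss <- setdiff(covariate_set, names(covariates))
  if (length(miss)) {
    stop("covariates absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(covariates[, covariate_set])) {
    stop("covariates contain missing values; exclude those samples upstream",
         call. = FALSE)
  }
  form <- stats::as.formula(paste("~", paste(covariate_set, collapse = " + ")))
  X <- model.matrix(form, data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_cols <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear columns: ",
         paste(drop_cols, collapse = ", "), call. = FALSE)
  }
  out$abundance <- qr.resid(qx, ab)
  out
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles via
#' `qnorm((rank - c) / (n - 2c + 1))` with the Blom offset `c = 3/8` by
#' default (`c = 1/2` gives the rankit variant). Ties receive average
#' ranks, so tied inputs map to identical outputs.
#'
#' @param v Numeric vector with finite values.
#' @param offset Rank offset constant (3/8 Blom, 1/2 rankit).
#' @return Transformed numeric vector.
#' @export
inverse_normal <- function(v, offset = 3 / 8) {
  if (anyNA(v) || any(!is.finite(v))) {
    stop("inverse_normal requires finite, complete input", call. = FALSE)
  }
  if (length(unique(v)) < 2) {
    stop("cannot inverse-normal transform a constant vector", call. = FALSE)
  }
  r <- rank(v, ties.method = "average")
  qnorm((r - offset) / (length(v) - 2 * offset + 1))
}

#' Run the full metabolite transformation pipeline
#'
#' filter (missingness > 50% and unnamed) -> natural-log -> KNN imputation
#' (k = 10) -> covariate residualization -> inverse-normal transform, the
#' order the downstream association scan expects.
#'
#' @param x A raw-stage `metabolite_matrix` (positive raw abundances when
#'   `log_transform = TRUE`).
#' @param covariates Covariate data frame.
#' @param annotation Annotation data frame (for the unnamed filter).
#' @param covariate_set Covariates to residualize out.
#' @param max_missing Missingness threshold (strict `>` exclusion).
#' @param k Neighbours for imputation.
#' @param log_transform Natural-log the abundances before imputation
#'   (platform convention for positively skewed raw intensities).
#' @param offset Inverse-normal rank offset.
#' @return A normalized-stage `metabolite_matrix`.
#' @export
prep_metabolites <- function(x, covariates, annotation,
                             covariate_set = metabolite_covariate_set(),
                             max_missing = 0.5, k = 10,
                             log_transform = TRUE, offset = 3 / 8) {
  filt <- filter_missingness(x, max_missing = max_missing,
                             drop_unnamed = TRUE, annotation = annotation)
  if (log_transform) {
    if (any(filt$abundance <= 0, na.rm = TRUE)) {
      stop("log transform requires strictly positive abundances", call. = FALSE)
    }
    filt$abundance <- log(filt$abundance)
  }
  imp <- knn_impute(filt, k = k)
  res <- residualize_covariates(imp, covariates, covariate_set)
  out <- advance_stage(res, "residualized", "normalized")
  out$abundance <- apply(res$abundance, 2, inverse_normal, offset = offset)
  rownames(out$abundance) <- rownames(res$abundance)
  out
}
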