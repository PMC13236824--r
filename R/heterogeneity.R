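#' Cochran's Q and I-squared across cluster-specific effect estimates
#'
#' Inverse-variance weights `w = 1/se^2`, fixed-effect pooled mean
#' `mu = sum(w b) / sum(w)`, `Q = sum(w (b - mu)^2)` referred to a
#' chi-square with `k - 1` degrees of freedom, and
#' `I2 = max(0, (Q - df) / Q)` (0 when Q is 0).
#'
#' @param betas Numeric vector of effect estimates (length >= 2).
#' @param ses Positive standard errors, same length.
#' @param p_threshold,i2_threshold Flag thresholds: heterogeneous when
#'   `p_Q < p_threshold` and `I2 > i2_threshold` (both strict).
#' @return One-row data frame: `Q`, `df`, `p_Q`, `I2`,
#'   `n_clusters_included`, `heterogeneous_flag`.
#' @export
#' @examples
#' cochran_q(c(0.2, -0.2), c(0.05, 0.05))  # Q = 32, I2 = 31/32
cochran_q <- function(betas, ses, p_threshold = 0.05, i2_threshold = 0.75) {
  if (length(betas) < 2) {
    stop("Cochran's Q needs at least 2 estimates", call. = FALSE)
  }
  stopifnot(length(betas) == length(ses))
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / ses^2
  mu <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - mu)^2)
  df <- length(betas) - 1L
  p <- pchisq(Q, df, lower.tail = FALSE)
  I2 <- if (Q > 0) max(0, (Q - df) / Q) else 0
  data.frame(Q = Q, df = df, p_Q = p, I2 = I2,
             n_clusters_included = length(betas),
             heterogeneous_flag = (p < p_threshold && I2 > i2_threshold))
}

#' Partition score-significant metabolites by cluster multiplicity
#'
#' Among metabolites significant (q below threshold) for at least one
#' partitioned score, splits those significant for exactly one cluster
#' from those significant for two or more; the heterogeneity test is run
#' only on the multi-cluster set.
#'
#' @param assoc Association records covering the partitioned scores.
#' @param q_threshold FDR threshold (default 0.05).
#' @return List with character vectors `single_cluster` and
#'   `multi_cluster`.
#' @export
select_heterogeneity_candidates <- function(assoc, q_threshold = 0.05) {
  pp <- assoc[assoc$score_id %in% cluster_labels() & !assoc$error &
                !is.na(assoc$q) & assoc$q < q_threshold, , drop = FALSE]
  if (!nrow(pp)) {
    return(list(single_cluster = character(0), multi_cluster = character(0)))
  }
  counts <- table(pp$metabolite_id)
  list(single_cluster = names(counts)[counts == 1],
       multi_cluster = names(counts)[counts >= 2])
}

#' Heterogeneity scan over multi-cluster metabolites
#'
#' Runs [cochran_q()] for every metabolite significant in two or more
#' clusters. By default only the significant clusters' estimates enter the
#' test (the candidate definition is framed by significance); set
#' `clusters_used = "all"` to use all eight estimates.
#'
#' @param assoc Association records for the partitioned scores.
#' @param q_threshold FDR threshold defining significance.
#' @param clusters_used `"significant"` (default) or `"all"`.
#' @param p_threshold,i2_threshold Passed to [cochran_q()].
#' @return Data frame of heterogeneity records keyed by `metabolite_id`.
#' @export
heterogeneity_scan <- function(assoc, q_threshold = 0.05,
                               clusters_used = c("significant", "all"),
                               p_threshold = 0.05, i2_threshold = 0.75) {
  clusters_used <- match.arg(clusters_used)
  cand <- select_heterogeneity_candidates(assoc, q_threshold)
  pp <- assoc[assoc$score_id %in% cluster_labels() & !assoc$error, , drop = FALSE]
  rows <- lapply(cand$multi_cluster, function(m) {
    a <- pp[pp$metabolite_id == m, , drop = FALSE]
    if (clusters_used == "significant") {
      a <- a[!is.na(a$q) & a$q < q_threshold, , drop = FALSE]
    }
    cbind(metabolite_id = m,
          cochran_q(a$beta, a$se, p_threshold, i2_threshold))
  })
  if (!length(rows)) {
    return(data.frame(metabolite_id = character(0), Q = numeric(0),
                      df = integer(0), p_Q = numeric(0), I2 = numeric(0),
                      n_clusters_included = integer(0),
                      heterogeneous_flag = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Principal components of the cluster-by-metabolite association profile
#'
#' Rows are clusters, columns metabolites; columns are centered and the
#' singular value decomposition gives cluster coordinates and variance
#' fractions. Betas share units (SD metabolite per SD score) so no column
#' scaling is applied by default.
#'
#' @param beta_matrix Complete numeric matrix, clusters in rows.
#' @param scale. Scale columns to unit variance before the SVD.
#' @return List with `coordinates` (clusters by PCs), `variance_fraction`,
#'   and the `prcomp` object.
#' @export
association_pca <- function(beta_matrix, scale. = FALSE) {
  if (nrow(beta_matrix) < 2) {
    stop("association PCA needs at least 2 cluster profiles", call. = FALSE)
  }
  if (anyNA(beta_matrix)) stop("beta matrix must be complete", call. = FALSE)
  pc <- prcomp(beta_matrix, center = TRUE, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x, variance_fraction = vf, fit = pc)
}

#' Pairwise Pearson correlation of cluster association profiles
#'
#' @param beta_matrix Clusters-by-metabolites matrix (>= 3 metabolites).
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   profiles give NA entries with a warning.
#' @export
pairwise_profile_correlation <- function(beta_matrix) {
  if (ncol(beta_matrix) < 3) {
    stop("need at least 3 metabolites to correlate profiles", call. = FALSE)
  }
  zero_var <- apply(beta_matrix, 1, sd) == 0
  if (any(zero_var)) {
    warning("zero-variance cluster profiles: ",
            paste(rownames(beta_matrix)[zero_var], collapse = ", "),
            call. = FALSE)
  }
  suppressWarnings(cm <- cor(t(beta_matrix)))
  diag(cm) <- ifelse(zero_var, NA_real_, 1)
  cm
}
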