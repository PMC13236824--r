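#' Load a variant weight table
#'
#' Reads a TSV with columns `variant_id`, `chrom`, `pos`, `risk_allele`,
#' `other_allele`, `OR` (or `odds_ratio`) and `cluster`, and computes the
#' score weight as the natural logarithm of the association odds ratio.
#'
#' @param path Path to the tab-separated weight file.
#' @param on_bad_cluster How to handle rows with a missing/empty cluster
#'   label: `"unassigned"` keeps them with cluster `"unassigned"` (they
#'   enter the overall score only), `"reject"` errors.
#' @param exclude Optional character vector of variant IDs to drop (for
#'   example variants imputed with low confidence upstream).
#' @return A `variant_weights` data frame.
#' @export
load_weights <- function(path, on_bad_cluster = c("unassigned", "reject"),
                         exclude = NULL) {
  on_bad_cluster <- match.arg(on_bad_cluster)
  if (!file.exists(path)) stop("weight file not found: ", path, call. = FALSE)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
  names(tab)[names(tab) == "OR"] <- "odds_ratio"
  needed <- c("variant_id", "chrom", "pos", "risk_allele", "other_allele",
              "odds_ratio")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    stop("weight file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(tab$odds_ratio) | tab$odds_ratio <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive or missing OR at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  }
  same <- which(tab$risk_allele == tab$other_allele)
  if (length(same)) {
    stop(sprintf("risk and other allele identical at line %d", same[1] + 1L),
         call. = FALSE)
  }
  dup <- tab$variant_id[duplicated(tab$variant_id)]
  if (length(dup)) {
    stop("duplicated variant_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(exclude)) tab <- tab[!tab$variant_id %in% exclude, , drop = FALSE]
  if (is.null(tab$cluster)) tab$cluster <- NA_character_
  no_cl <- is.na(tab$cluster) | tab$cluster == ""
  if (any(no_cl)) {
    if (on_bad_cluster == "reject") {
      stop(sprintf("%d variants lack a cluster label", sum(no_cl)),
           call. = FALSE)
    }
    tab$cluster[no_cl] <- "unassigned"
  }
  known <- c(cluster_labels(), "unassigned")
  unknown <- setdiff(unique(tab$cluster), known)
  if (length(unknown)) {
    stop("unknown cluster labels: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tab$weight <- log(tab$odds_ratio)
  # strand-ambiguous variants are aligned literally; flag them for the user
  amb <- (tab$risk_allele == "A" & tab$other_allele == "T") |
    (tab$risk_allele == "T" & tab$other_allele == "A") |
    (tab$risk_allele == "C" & tab$other_allele == "G") |
    (tab$risk_allele == "G" & tab$other_allele == "C")
  if (any(amb)) {
    warning(sprintf("%d strand-ambiguous (A/T or C/G) variants; aligned literally",
                    sum(amb)), call. = FALSE)
  }
  class(tab) <- c("variant_weights", "data.frame")
  tab
}

#' Orient dosages to count the risk allele
#'
#' Matches dosage columns to the weight table (by variant ID, falling back
#' to `chrom:pos` with allele check), flips dosages (`2 - d`) where the
#' file's counted allele is the other allele, drops variants whose alleles
#' match neither, and reports the accounting.
#'
#' @param dosages A `dosage_matrix`.
#' @param weights A `variant_weights` table.
#' @return List with `dosages` (risk-allele oriented, restricted to usable
#'   variants) and `report` (data frame: variant_id, status in
#'   used/flipped/dropped/missing).
#' @export
align_alleles <- function(dosages, weights) {
  have <- colnames(dosages$dosage)
  status <- setNames(rep("missing", nrow(weights)), weights$variant_id)
  new_dos <- dosages$dosage
  keep <- character(0)
  for (i in seq_len(nrow(weights))) {
    vid <- weights$variant_id[i]
    if (!vid %in% have) next
    counted <- dosages$counted_allele[[vid]]
    if (identical(counted, weights$risk_allele[i])) {
      status[vid] <- "used"
      keep <- c(keep, vid)
    } else if (identical(counted, weights$other_allele[i])) {
      new_dos[, vid] <- 2 - new_dos[, vid]
      status[vid] <- "flipped"
      keep <- c(keep, vid)
    } else {
      status[vid] <- "dropped"
    }
  }
  if (!length(keep)) {
    stop("no variants overlap between dosage data and weight table after allele matching",
         call. = FALSE)
  }
  counted <- dosages$counted_allele
  counted[keep] <- weights$risk_allele[match(keep, weights$variant_id)]
  report <- data.frame(variant_id = names(status), status = unname(status),
                       stringsAsFactors = FALSE)
  list(
    dosages = dosage_matrix(new_dos[, keep, drop = FALSE], counted),
    report = report
  )
}

#' Compute a raw polygenic score
#'
#' The score for subject k is the weighted sum over variants j of the
#' risk-allele dosage times the log odds ratio: `PRS_k = sum_j a_kj W_j`.
#' Weight-table variants absent from the dosage data contribute nothing and
#' are reported in `n_variants_used`.
#'
#' @param dosages Risk-allele-oriented `dosage_matrix`.
#' @param weights A `variant_weights` table.
#' @param subset `"all"` for the overall score, or one cluster label.
#' @param missing_dosage `"mean"` imputes missing per-sample dosages with
#'   the variant's mean dosage; `"drop"` drops affected samples (their
#'   score is NA).
#' @return Numeric vector named by sample ID, with attribute
#'   `n_variants_used`.
#' @export
compute_prs <- function(dosages, weights, subset = "all",
                        missing_dosage = c("mean", "drop")) {
  missing_dosage <- match.arg(missing_dosage)
  if (subset != "all") {
    if (!subset %in% weights$cluster) {
      stop("no variants in cluster '", subset, "'", call. = FALSE)
    }
    weights <- weights[weights$cluster == subset, , drop = FALSE]
  }
  use <- intersect(weights$variant_id, colnames(dosages$dosage))
  if (!length(use)) {
    stop("no usable variants after alignment for subset '", subset, "'",
         call. = FALSE)
  }
  d <- dosages$dosage[, use, drop = FALSE]
  if (anyNA(d)) {
    if (missing_dosage == "mean") {
      for (j in seq_len(ncol(d))) {
        nas <- is.na(d[, j])
        if (any(nas)) d[nas, j] <- mean(d[, j], na.rm = TRUE)
      }
    }
  }
  w <- weights$weight[match(use, weights$variant_id)]
  score <- as.vector(d %*% w)
  names(score) <- rownames(d)
  attr(score, "n_variants_used") <- length(use)
  score
}

#' Two-step standardization of a raw score against genetic PCs
#'
#' z-scores the raw score, regresses it on an intercept plus the ten
#' genetic principal components by ordinary least squares, and z-scores the
#' residuals. z-scores use the sample (n-1) standard deviation. The result
#' has mean 0, SD 1 and zero sample correlation with every PC.
#'
#' @param raw Numeric raw score vector.
#' @param pcs Numeric matrix of principal components (columns).
#' @return Standardized numeric vector.
#' @export
residual_standardize <- function(raw, pcs) {
  pcs <- as.matrix(pcs)
  if (length(raw) <= ncol(pcs) + 2) {
    stop("too few samples to residualize against ", ncol(pcs), " PCs",
         call. = FALSE)
  }
  z <- zscore(raw, "raw score")
  X <- cbind(1, pcs)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    kap <- kappa(X, exact = TRUE)
    stop(sprintf("collinear PC design (rank %d < %d, condition number %.3g)",
                 qx$rank, ncol(X), kap), call. = FALSE)
  }
  res <- qr.resid(qx, z)
  zscore(res, "PC-residualized score")
}

#' Compute the full score set: overall and eight partitioned scores
#'
#' Computes the raw overall PRS and the eight cluster-partitioned PRSs,
#' then (when `pcs` is supplied) applies [residual_standardize()] to each.
#'
#' @param dosages Risk-allele-oriented `dosage_matrix`.
#' @param weights A `variant_weights` table.
#' @param pcs Optional matrix of genetic PCs for standardization.
#' @param clusters Cluster labels to score (default all eight present).
#' @return A `score_set` data frame: `sample_id`, `raw_oPRS`,
#'   `raw_<cluster>` for each cluster, and `std_` counterparts when `pcs`
#'   is given; attribute `n_variants_used` is a named count vector.
#' @export
compute_score_set <- function(dosages, weights, pcs = NULL,
                              clusters = NULL) {
  clusters <- clusters %||% intersect(cluster_labels(), unique(weights$cluster))
  o <- compute_prs(dosages, weights, "all")
  out <- data.frame(sample_id = names(o), raw_oPRS = as.vector(o),
                    stringsAsFactors = FALSE)
  nused <- c(oPRS = attr(o, "n_variants_used"))
  for (cl in clusters) {
    s <- compute_prs(dosages, weights, cl)
    out[[paste0("raw_", cl)]] <- as.vector(s)
    nused[[cl]] <- attr(s, "n_variants_used")
  }
  if (!is.null(pcs)) {
    for (nm in c("oPRS", clusters)) {
      raw_col <- if (nm == "oPRS") "raw_oPRS" else paste0("raw_", nm)
      out[[paste0("std_", nm)]] <- residual_standardize(out[[raw_col]], pcs)
    }
  }
  attr(out, "n_variants_used") <- nused
  class(out) <- c("score_set", "data.frame")
  out
}
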