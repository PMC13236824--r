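#' Simulate genotype dosages and a cluster-assigned variant weight table
#'
#' Draws, for each variant, a risk-allele frequency uniformly from
#' `config$allele_freq_range` and per-subject allele counts from
#' Binomial(2, f), stored as real dosages in \[0,2\] (as imputed dosages
#' would be). Variants are partitioned exhaustively into the eight
#' mechanistic clusters; each variant receives an association odds ratio
#' `exp(N(0, effect_size_sd))` whose natural log is its score weight.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dosages` (a `dosage_matrix`) and
#'   `weights` (a `variant_weights` data frame).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  labels <- cluster_labels()
  m <- sum(config$n_variants_per_cluster)
  with_stream(config$seed, "genotypes", {
    f <- runif(m, config$allele_freq_range[1], config$allele_freq_range[2])
    alleles <- c("A", "C", "G", "T")
    complement <- c(A = "T", C = "G", G = "C", T = "A")
    risk <- sample(alleles, m, replace = TRUE)
    # avoid strand-ambiguous (complementary) pairs so alignment is clean
    other <- vapply(risk, function(a)
      sample(setdiff(alleles, c(a, complement[[a]])), 1), "")
    or <- exp(rnorm(m, 0, config$or_log_sd))  # GWAS-scale per-variant ORs
    cluster <- rep(labels, times = config$n_variants_per_cluster)
    variant_id <- sprintf("var_%03d", seq_len(m))
    weights <- data.frame(
      variant_id = variant_id,
      chrom = as.character(1 + (seq_len(m) - 1) %% 22),
      pos = 10000L + 100L * seq_len(m),
      risk_allele = unname(risk),
      other_allele = unname(other),
      odds_ratio = or,
      weight = log(or),
      cluster = cluster,
      freq = f,
      stringsAsFactors = FALSE
    )
    class(weights) <- c("variant_weights", "data.frame")
    dos <- matrix(rbinom(config$n_subjects * m, 2L, rep(f, each = config$n_subjects)),
                  nrow = config$n_subjects, ncol = m)
    storage.mode(dos) <- "double"
    rownames(dos) <- sprintf("S%05d", seq_len(config$n_subjects))
    colnames(dos) <- variant_id
    dosages <- dosage_matrix(dos, counted_allele = setNames(weights$risk_allele,
                                                            variant_id))
    list(dosages = dosages, weights = weights)
  })
}

#' Construct a dosage matrix container
#'
#' @param dosage Numeric samples-by-variants matrix with entries in \[0,2\];
#'   dimnames give sample and variant IDs.
#' @param counted_allele Named character vector: the allele whose expected
#'   count each column stores.
#' @return An object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(dosage, counted_allele) {
  stopifnot(is.matrix(dosage), !is.null(rownames(dosage)),
            !is.null(colnames(dosage)))
  if (anyDuplicated(rownames(dosage))) stop("duplicated sample IDs", call. = FALSE)
  if (anyDuplicated(colnames(dosage))) stop("duplicated variant IDs", call. = FALSE)
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  counted_allele <- counted_allele[colnames(dosage)]
  structure(list(dosage = dosage, counted_allele = counted_allele),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.dosage_matrix <- function(x) rownames(x$dosage)
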