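# Internal helpers shared across modules.

#' The eight mechanistic variant clusters
#'
#' Cluster labels used throughout: two beta-cell clusters (with and without
#' disproportionately elevated proinsulin), residual glycaemic, body fat,
#' metabolic syndrome, obesity, lipodystrophy and liver/lipid.
#'
#' @return Character vector of the eight cluster labels, in canonical order.
#' @export
cluster_labels <- function() {
  c("beta_cell_plus_PI", "beta_cell_minus_PI", "residual_glycaemic",
    "body_fat", "metabolic_syndrome", "obesity", "lipodystrophy",
    "liver_lipid")
}

expit <- function(x) plogis(x)

# Per-operation RNG streams: each operation seeds from the master seed plus a
# fixed offset so modules can be regenerated independently and reproducibly.
seed_offsets <- c(
  genotypes = 101L, covariates = 211L, metabolome = 307L,
  outcomes = 401L, missing = 503L, mediate = 601L, split = 701L,
  scan_null = 811L
)

with_stream <- function(master_seed, stream, expr) {
  stopifnot(stream %in% names(seed_offsets))
  # keep derived seeds inside 32-bit integer range
  derived <- (as.numeric(master_seed) + seed_offsets[[stream]]) %% 2147483647
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(derived))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# z-score with sample (n-1) SD; errors on zero variance
zscore <- function(x, what = "vector") {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("cannot z-score %s: zero or non-finite variance", what),
         call. = FALSE)
  }
  (x - mean(x)) / s
}

# order-invariant content hash used for provenance headers (FNV-1a over the
# serialized object, hex-encoded); avoids a dependency on digest
content_hash <- function(x) {
  bytes <- serialize(x, connection = NULL, version = 2)
  # drop serialization header (R version stamp) so the hash tracks content
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

check_aligned_samples <- function(ids_a, ids_b, what_a, what_b) {
  if (length(ids_a) != length(ids_b) || !all(ids_a == ids_b)) {
    stop(sprintf("sample IDs of %s and %s are not aligned", what_a, what_b),
         call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
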