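# Shared fixtures, built in code. The medium cohort is memoized so several
# test files can reuse it without re-simulating.

.fixture_env <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    cfg <- sim_config(n_subjects = 1500,
                      n_variants_per_cluster = rep(12L, 8),
                      n_metabolites = 60,
                      n_genetic_metabolites_per_cluster = 2,
                      mediated_fraction = 0.3,
                      missing_rate = 0.05,
                      seed = 42)
    .fixture_env$cohort <- simulate_cohort(cfg)
  }
  .fixture_env$cohort
}

shared_normalized <- function() {
  if (is.null(.fixture_env$norm)) {
    coh <- shared_cohort()
    .fixture_env$norm <- prep_metabolites(coh$metabolites, coh$covariates,
                                          coh$annotation)
  }
  .fixture_env$norm
}

shared_assoc <- function() {
  if (is.null(.fixture_env$assoc)) {
    .fixture_env$assoc <- scan_associations(shared_cohort()$scores,
                                            shared_normalized())
  }
  .fixture_env$assoc
}

# tiny deterministic dosage fixture for PRS unit tests
toy_dosages <- function() {
  m <- matrix(c(0, 1, 2,
                2, 0, 1,
                1, 1, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("v1", "v2", "v3")))
  storage.mode(m) <- "double"
  dosage_matrix(m, c(v1 = "A", v2 = "C", v3 = "G"))
}

toy_weights <- function(or = c(1.1, 1.0, 0.9),
                        cluster = c("body_fat", "body_fat", "liver_lipid")) {
  w <- data.frame(
    variant_id = c("v1", "v2", "v3"),
    chrom = c("1", "2", "3"),
    pos = c(100L, 200L, 300L),
    risk_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    odds_ratio = or,
    weight = suppressWarnings(log(or)),
    cluster = cluster,
    stringsAsFactors = FALSE
  )
  class(w) <- c("variant_weights", "data.frame")
  w
}

write_weights_tsv <- function(w, path = tempfile(fileext = ".tsv")) {
  w$OR <- w$odds_ratio
  write.table(w[, c("variant_id", "chrom", "pos", "risk_allele",
                    "other_allele", "OR", "cluster")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
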