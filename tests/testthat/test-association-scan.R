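fake_scores <- function(s, id = "oPRS") {
  df <- data.frame(sample_id = names(s), stringsAsFactors = FALSE)
  df[[paste0("std_", id)]] <- unname(s)
  df
}

norm_matrix <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("m", seq_len(ncol(m)))
  metabolite_matrix(m, "normalized")
}

test_that("scan beta equals the closed-form simple-regression slope", {
  set.seed(4)
  n <- 40
  s <- rnorm(n); names(s) <- paste0("s", 1:n)
  m <- matrix(0.4 * s + rnorm(n, 0, 0.5), n, 1,
              dimnames = list(names(s), "m1"))
  out <- scan_associations(fake_scores(s), norm_matrix(m))
  xc <- s - mean(s); yc <- m[, 1] - mean(m[, 1])
  beta_hat <- sum(xc * yc) / sum(xc^2)
  expect_equal(out$beta, beta_hat, tolerance = 1e-10)
  # reported p is consistent with the t distribution at n - 2 df
  expect_equal(out$p, 2 * pt(-abs(out$beta / out$se), n - 2),
               tolerance = 1e-6)
  # metabolite identical to the score
  m2 <- matrix(s, n, 1, dimnames = list(names(s), "m1"))
  out2 <- scan_associations(fake_scores(s), norm_matrix(m2))
  expect_equal(out2$beta, 1, tolerance = 1e-10)
  expect_lt(out2$p, 1e-30)
})

test_that("null metabolites reject at the nominal 5% rate", {
  set.seed(21)
  n <- 1000; p <- 500
  s <- rnorm(n); names(s) <- paste0("s", 1:n)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(names(s), paste0("m", 1:p)))
  out <- scan_associations(fake_scores(s), norm_matrix(m))
  frac <- mean(out$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / p))
})

test_that("Benjamini-Hochberg q-values match the step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  # manual step-up oracle on a random vector
  set.seed(2)
  p <- runif(20)
  q <- bh_fdr(p)
  o <- order(p)
  oracle <- rev(cummin(rev(p[o] * 20 / seq_len(20))))
  expect_equal(q[o], pmin(oracle, 1))
  # q nondecreasing in p within a family
  expect_true(all(diff(q[o]) >= 0))
  expect_true(all(q >= p))
})

test_that("scan betas are invariant to affine rescaling of the raw score", {
  coh <- shared_cohort()
  norm <- shared_normalized()
  pcs <- as.matrix(coh$covariates[, paste0("PC", 1:10)])
  raw <- coh$scores$raw_oPRS
  s1 <- residual_standardize(raw, pcs)
  s2 <- residual_standardize(7 * raw - 3, pcs)
  df <- data.frame(sample_id = coh$scores$sample_id, std_a = s1, std_b = s2)
  out <- scan_associations(df, norm, score_ids = c("a", "b"),
                           fdr_family = "pooled")
  expect_equal(out$beta[out$score_id == "a"], out$beta[out$score_id == "b"],
               tolerance = 1e-10)
})

test_that("oPRS-adjusted partitioned betas track unadjusted betas", {
  coh <- shared_cohort()
  norm <- shared_normalized()
  base <- shared_assoc()
  adj <- scan_associations(
    coh$scores, norm, score_ids = cluster_labels(),
    subset_tag = "oPRS_adjusted",
    extra_covariates = matrix(coh$scores$std_oPRS, ncol = 1,
                              dimnames = list(coh$scores$sample_id, "oPRS")))
  b0 <- base$beta[base$score_id != "oPRS"]
  key <- paste(base$score_id, base$metabolite_id)[base$score_id != "oPRS"]
  b1 <- adj$beta[match(key, paste(adj$score_id, adj$metabolite_id))]
  expect_gt(cor(b0, b1), 0.9)
})

test_that("zero-variance scores are flagged and small overlap rejected", {
  set.seed(5)
  n <- 40
  s <- rnorm(n); names(s) <- paste0("s", 1:n)
  df <- fake_scores(s)
  df$std_flat <- 0
  m <- norm_matrix(matrix(rnorm(n * 3), n, 3,
                          dimnames = list(names(s), paste0("m", 1:3))))
  out <- scan_associations(df, m, score_ids = c("oPRS", "flat"))
  expect_true(all(out$error[out$score_id == "flat"]))
  expect_true(all(is.na(out$q[out$score_id == "flat"])))
  expect_false(any(out$error[out$score_id == "oPRS"]))
  tiny <- norm_matrix(matrix(rnorm(10 * 2), 10, 2,
                             dimnames = list(names(s)[1:10], c("a", "b"))))
  expect_error(scan_associations(df, tiny), "30")
})

test_that("disease associations have nominal null coverage and the right sign", {
  set.seed(31)
  cover <- 0L
  for (r in 1:100) {
    n <- 250
    pheno <- data.frame(sample_id = paste0("s", 1:n),
                        baseline_t2d = rbinom(n, 1, 0.15),
                        incident_t2d = rbinom(n, 1, 0.12),
                        followup_years = runif(n, 5, 15))
    covars <- data.frame(sample_id = pheno$sample_id,
                         age = runif(n, 45, 74), bmi = rnorm(n, 27, 3),
                         batch = sample(c("B1", "B2"), n, TRUE))
    m <- norm_matrix(matrix(rnorm(n), n, 1,
                            dimnames = list(pheno$sample_id, "m1")))
    da <- disease_association(m, pheno, covars)
    if (!da$flagged && da$prevalent_lo < 0 && da$prevalent_hi > 0) {
      cover <- cover + 1L
    }
  }
  expect_gte(cover, 93)
})

test_that("a metabolite tracking the generating liability associates positively", {
  coh <- shared_cohort()
  lia <- coh$truth$liability
  m <- norm_matrix(matrix(scale(lia), length(lia), 1,
                          dimnames = list(coh$covariates$sample_id, "m1")))
  da <- disease_association(m, coh$phenotype, coh$covariates)
  expect_gt(da$incident_logHR, 0)
  expect_lt(da$incident_p, 0.01)
  # degenerate follow-up is rejected
  pheno0 <- coh$phenotype
  pheno0$followup_years <- 0
  expect_error(disease_association(m, pheno0, coh$covariates), "person-time")
})

test_that("lipid chain-feature correlations follow the five-lipid rule and rank oracle", {
  ann <- data.frame(
    metabolite_id = paste0("m", 1:10),
    super_class = c(rep("Lipid", 10)),
    sub_pathway = c(rep("pwA", 6), rep("pwB", 4)),
    n_carbons = c(14, 16, 18, 20, 22, 24, 30, 32, 34, 36),
    n_double_bonds = c(0, 1, 2, 3, 4, 5, 0, 1, 2, 3))
  assoc <- data.frame(score_id = "oPRS", metabolite_id = paste0("m", 1:10),
                      beta = c(0.1, 0.15, 0.2, 0.35, 0.4, 0.45,
                               0.1, 0.3, 0.2, 0.25),
                      error = FALSE)
  out <- lipid_feature_correlation(assoc, ann)
  # pwB has only 4 lipids -> skipped entirely
  expect_false("pwB" %in% out$sub_pathway)
  rowA <- out[out$sub_pathway == "pwA" & out$feature == "n_carbons", ]
  expect_equal(rowA$rho, 1)           # betas strictly increasing in carbons
  expect_equal(rowA$n_lipids, 6)
  # rank-correlation oracle: Pearson on ranks
  rowD <- out[out$sub_pathway == "pwA" & out$feature == "n_double_bonds", ]
  oracle <- cor(rank(ann$n_double_bonds[1:6]), rank(assoc$beta[1:6]))
  expect_equal(rowD$rho, oracle, tolerance = 1e-10)
})
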