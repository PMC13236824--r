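make_matrix <- function(m, stage = "raw") {
  if (is.null(rownames(m))) rownames(m) <- paste0("s", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("m", seq_len(ncol(m)))
  metabolite_matrix(m, stage)
}

test_that("missingness filter applies a strict greater-than rule", {
  set.seed(1)
  n <- 20
  m <- matrix(rlnorm(n * 3), n, 3,
              dimnames = list(paste0("s", 1:n), c("m45", "m50", "m55")))
  m[1:9, 1] <- NA    # 45%
  m[1:10, 2] <- NA   # 50% exactly -> retained
  m[1:11, 3] <- NA   # 55% -> removed
  out <- filter_missingness(make_matrix(m), drop_unnamed = FALSE)
  expect_setequal(colnames(out$abundance), c("m45", "m50"))
  expect_equal(attr(out, "removal_log")$metabolite_id, "m55")
  expect_equal(out$stage, "filtered")
})

test_that("unnamed metabolites are removed when requested and empty results error", {
  m <- matrix(rlnorm(40), 10, 4)
  ann <- data.frame(metabolite_id = paste0("m", 1:4),
                    named = c(TRUE, FALSE, TRUE, FALSE))
  out <- filter_missingness(make_matrix(m), annotation = ann)
  expect_setequal(colnames(out$abundance), c("m1", "m3"))
  m2 <- matrix(NA_real_, 10, 2)
  m2[1, ] <- 1  # 90% missing everywhere
  expect_error(filter_missingness(make_matrix(m2), drop_unnamed = FALSE),
               "no metabolites survive")
  # complete matrix passes through identically
  m3 <- make_matrix(matrix(rlnorm(30), 10, 3))
  expect_equal(filter_missingness(m3, drop_unnamed = FALSE)$abundance,
               m3$abundance)
})

test_that("KNN imputation matches the exhaustive-distance oracle on a 5x3 toy", {
  m <- matrix(c(1.0, 2.0, 3.0,
                1.1, 2.1, 3.2,
                5.0, 6.0, 7.0,
                1.2, 1.9, NA,
                5.1, 6.2, 7.1), nrow = 5, byrow = TRUE,
              dimnames = list(paste0("s", 1:5), paste0("m", 1:3)))
  out <- knn_impute(make_matrix(m, "filtered"), k = 2)
  # oracle: z-score columns on observed values, mean squared distance over
  # columns observed in both samples, take the 2 nearest donors with m3
  mu <- colMeans(m, na.rm = TRUE); sdv <- apply(m, 2, sd, na.rm = TRUE)
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  d <- sapply(c(1, 2, 3, 5), function(j) {
    sh <- which(!is.na(z[4, ]) & !is.na(z[j, ]))
    mean((z[4, sh] - z[j, sh])^2)
  })
  donors <- c(1, 2, 3, 5)[order(d)][1:2]
  expect_equal(out$abundance[4, 3], mean(m[donors, 3]))
  # observed cells never change
  obs <- !is.na(m)
  expect_equal(out$abundance[obs], m[obs])
  expect_false(anyNA(out$abundance))
})

test_that("a single missing cell with k >= n-1 gets the column mean of the others", {
  set.seed(3)
  m <- matrix(rnorm(24), 8, 3)
  m[5, 2] <- NA
  out <- knn_impute(make_matrix(m, "filtered"), k = 10)
  expect_equal(out$abundance[5, 2], mean(m[-5, 2], na.rm = TRUE))
})

test_that("KNN with no missing cells is the identity and all-missing samples error", {
  m <- make_matrix(matrix(rnorm(30), 10, 3), "filtered")
  expect_identical(knn_impute(m)$abundance, m$abundance)
  m2 <- matrix(rnorm(30), 10, 3)
  m2[4, ] <- NA
  expect_error(knn_impute(make_matrix(m2, "filtered")), "s4")
})

test_that("covariate residualization matches the closed-form OLS oracle", {
  set.seed(8)
  n <- 6
  covars <- data.frame(sample_id = paste0("s", 1:n),
                       age = c(50, 55, 60, 47, 71, 66),
                       bmi = c(24, 31, 27, 29, 25, 33))
  m <- matrix(rnorm(n * 2), n, 2,
              dimnames = list(covars$sample_id, c("a", "b")))
  out <- residualize_covariates(make_matrix(m, "imputed"), covars,
                                c("age", "bmi"))
  X <- cbind(1, covars$age, covars$bmi)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  expect_equal(unname(out$abundance), unname((diag(n) - H) %*% m),
               tolerance = 1e-10)
})

test_that("residualization handles exact linear dependence and empty sets", {
  covars <- data.frame(sample_id = paste0("s", 1:10),
                       bmi = rnorm(10, 27, 3), dup = NA_real_)
  covars$dup <- covars$bmi * 2
  m <- matrix(3 * covars$bmi, 10, 1,
              dimnames = list(covars$sample_id, "m1"))
  out <- residualize_covariates(make_matrix(m, "imputed"), covars, "bmi")
  expect_lt(max(abs(out$abundance)), 1e-8)
  expect_error(residualize_covariates(make_matrix(m, "imputed"), covars,
                                      c("bmi", "dup")), "collinear")
  cen <- residualize_covariates(make_matrix(m, "imputed"), covars,
                                character(0))
  expect_equal(unname(cen$abundance[, 1]), unname(m[, 1] - mean(m[, 1])))
})

test_that("inverse-normal transform matches direct quantile evaluation", {
  v <- c(3.2, -1, 7, 0.5, 2)
  out <- inverse_normal(v)
  oracle <- qnorm((rank(v) - 0.375) / (5 - 0.75 + 1))
  expect_equal(out, oracle, tolerance = 1e-12)
  expect_equal(sort(oracle), qnorm(c(0.625, 1.625, 2.625, 3.625, 4.625) / 5.25))
  # the median of an odd-length distinct vector maps to exactly zero
  expect_equal(out[which(rank(v) == 3)], 0)
  # rank invariance: shuffling permutes but preserves the value multiset
  expect_equal(sort(inverse_normal(sample(v))), sort(out))
  # ties map to identical outputs
  tied <- inverse_normal(c(1, 2, 2, 3))
  expect_equal(tied[2], tied[3])
  expect_error(inverse_normal(rep(1, 5)), "constant")
  expect_error(inverse_normal(c(1, NA, 2)), "finite")
})

test_that("inverse-normal output of skewed input passes Shapiro-Wilk", {
  set.seed(11)
  x <- rexp(1000)^2
  expect_gt(shapiro.test(inverse_normal(x))$p.value, 0.01)
})

test_that("stage transitions are enforced in order", {
  m <- make_matrix(matrix(rlnorm(30), 10, 3))
  expect_error(knn_impute(m), "stage 'filtered'")
  f <- filter_missingness(m, drop_unnamed = FALSE)
  expect_error(filter_missingness(f, drop_unnamed = FALSE), "stage 'raw'")
})

test_that("the full preparation pipeline is sample-permutation equivariant", {
  coh <- shared_cohort()
  norm <- shared_normalized()
  perm <- sample(nrow(coh$metabolites$abundance))
  met_p <- coh$metabolites
  met_p$abundance <- met_p$abundance[perm, , drop = FALSE]
  cov_p <- coh$covariates[perm, , drop = FALSE]
  norm_p <- prep_metabolites(met_p, cov_p, coh$annotation)
  expect_equal(norm_p$abundance, norm$abundance[perm, , drop = FALSE],
               tolerance = 1e-10)
  # normalized columns are centered
  expect_lt(max(abs(colMeans(norm$abundance))), 1e-8)
})
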