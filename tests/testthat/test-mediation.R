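# tight-noise linear toy with known paths a, b, c'
linear_toy <- function(n = 2000, a = 0.5, b = 0.3, cp = 0.2, noise = 0.01,
                       seed = 1) {
  set.seed(seed)
  t <- rnorm(n)
  t <- (t - mean(t)) / sd(t)
  m <- a * t + rnorm(n, 0, noise)
  y <- b * m + cp * t + rnorm(n, 0, noise)
  list(t = t, m = m, y = y)
}

test_that("mediator model recovers exact and hand-solved coefficients", {
  d <- linear_toy(n = 500, noise = 0)
  f <- fit_mediator_model(d$m, d$t)
  expect_equal(unname(f$coef["treat"]), 0.5, tolerance = 1e-10)
  # toy 8-row dataset against the normal-equations oracle
  set.seed(2)
  t8 <- rnorm(8); c8 <- rnorm(8); m8 <- rnorm(8)
  f8 <- fit_mediator_model(m8, t8, matrix(c8, ncol = 1,
                                          dimnames = list(NULL, "c1")))
  X <- cbind(1, t8, c8)
  oracle <- solve(t(X) %*% X, t(X) %*% m8)
  expect_equal(unname(f8$coef), as.vector(oracle), tolerance = 1e-10)
  expect_error(fit_mediator_model(m8, t8, matrix(t8, ncol = 1)),
               "rank-deficient")
})

test_that("logistic outcome model matches the contingency-table log-odds", {
  # binary exposure/mediator groups with closed-form cell log-odds
  grid <- expand.grid(t = c(0, 1), m = c(0, 1))
  counts <- c(100, 100, 100, 100)
  p_cell <- plogis(-1 + 0.8 * grid$t + 0.5 * grid$m)
  y <- unlist(mapply(function(n1, p) rep(c(1, 0), c(round(n1 * p),
                                                    n1 - round(n1 * p))),
                     counts, p_cell, SIMPLIFY = FALSE))
  t_v <- rep(grid$t, counts)
  m_v <- rep(grid$m, counts)
  f <- fit_outcome_model(y, t_v, m_v)
  oracle <- glm(y ~ t_v + m_v, family = binomial())
  expect_equal(unname(f$coef), unname(coef(oracle)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(f$vcov))),
               unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-6)
  # duplicating the data keeps estimates, halves the variance
  f2 <- fit_outcome_model(c(y, y), c(t_v, t_v), c(m_v, m_v))
  expect_equal(f2$coef, f$coef, tolerance = 1e-6)
  expect_equal(diag(f2$vcov), diag(f$vcov) / 2, tolerance = 1e-4)
})

test_that("identity-link mediation recovers the product-of-coefficients form", {
  d <- linear_toy(n = 3000, a = 0.5, b = 0.3, cp = 0.2, noise = 0.02)
  mf <- fit_mediator_model(d$m, d$t)
  of <- fit_outcome_model(d$y, d$t, d$m, family = gaussian())
  res <- quasi_bayesian_mediate(mf, of, n_sims = 1000, seed = 10)
  # the draw spread estimates the sampling SE of each effect
  se_acme <- (res$acme_hi - res$acme_lo) / 3.92
  se_tot <- (res$total_hi - res$total_lo) / 3.92
  expect_lt(abs(res$acme - 0.15), 3 * se_acme)
  expect_lt(abs(res$total - 0.35), 3 * se_tot)
  expect_lt(abs(res$acme - 0.15), 0.02)
  expect_lt(abs(res$prop_mediated_pct - 42.86), 3)
  expect_false(res$suppression_flag)
  # acme + ade = total identically
  expect_equal(res$acme + res$ade, res$total, tolerance = 1e-12)
})

test_that("mediation is bit-identical under a fixed seed and needs enough draws", {
  d <- linear_toy(n = 400, noise = 0.1, seed = 3)
  mf <- fit_mediator_model(d$m, d$t)
  of <- fit_outcome_model(d$y, d$t, d$m, family = gaussian())
  r1 <- quasi_bayesian_mediate(mf, of, n_sims = 200, seed = 99)
  r2 <- quasi_bayesian_mediate(mf, of, n_sims = 200, seed = 99)
  expect_identical(r1, r2)
  expect_error(quasi_bayesian_mediate(mf, of, n_sims = 50, seed = 1), "100")
  expect_error(quasi_bayesian_mediate(mf, of, n_sims = 200), "seed")
})

test_that("a null b-path yields a null ACME at the nominal rate", {
  set.seed(14)
  hits <- 0L
  for (r in 1:10) {
    n <- 600
    t <- rnorm(n); m <- 0.4 * t + rnorm(n)
    y <- rbinom(n, 1, plogis(-2 + 0.3 * t))  # outcome ignores the mediator
    mf <- fit_mediator_model(m, t)
    of <- fit_outcome_model(y, t, m)
    res <- quasi_bayesian_mediate(mf, of, n_sims = 200, seed = r)
    if (res$p_acme > 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})

test_that("ACME is stable under an orthogonal extra covariate", {
  d <- linear_toy(n = 2000, noise = 0.3, seed = 5)
  set.seed(55)
  z <- rnorm(2000)
  mf0 <- fit_mediator_model(d$m, d$t)
  of0 <- fit_outcome_model(d$y, d$t, d$m, family = gaussian())
  r0 <- quasi_bayesian_mediate(mf0, of0, n_sims = 1000, seed = 8)
  zc <- matrix(z, ncol = 1, dimnames = list(NULL, "z"))
  mf1 <- fit_mediator_model(d$m, d$t, zc)
  of1 <- fit_outcome_model(d$y, d$t, d$m, zc, family = gaussian())
  r1 <- quasi_bayesian_mediate(mf1, of1, n_sims = 1000, seed = 8)
  # Monte-Carlo SE of the ACME mean, from the percentile-interval width
  mc_se <- (r0$acme_hi - r0$acme_lo) / (2 * 1.96) / sqrt(1000)
  expect_lt(abs(r1$acme - r0$acme), 3 * max(mc_se, 0.002))
})

test_that("suppression (opposite-sign indirect and direct effects) is flagged", {
  d <- linear_toy(n = 3000, a = 0.5, b = 0.4, cp = -0.5, noise = 0.05,
                  seed = 7)
  mf <- fit_mediator_model(d$m, d$t)
  of <- fit_outcome_model(d$y, d$t, d$m, family = gaussian())
  res <- quasi_bayesian_mediate(mf, of, n_sims = 500, seed = 2)
  expect_true(res$suppression_flag)
  expect_true(is.na(res$prop_mediated_pct))
})

test_that("the mediation screen runs only significant pairs and computes q-values", {
  coh <- shared_cohort()
  assoc <- shared_assoc()
  med <- mediation_screen(assoc, coh, n_sims = 150, seed = 4)
  sig_pairs <- unique(assoc[!is.na(assoc$q) & assoc$q < 0.05,
                            c("score_id", "metabolite_id")])
  expect_equal(nrow(med), nrow(sig_pairs))
  expect_true(all(med$adjustment_tag == "base"))
  for (sid in unique(med$score_id)) {
    sel <- med$score_id == sid & !is.na(med$p_acme)
    if (sum(sel) > 1) {
      o <- order(med$p_acme[sel])
      expect_true(all(diff(med$q_acme[sel][o]) >= -1e-12))
    }
  }
  # no significant associations -> empty screen
  none <- assoc; none$q <- 0.9
  expect_equal(nrow(mediation_screen(none, coh, n_sims = 150, seed = 4)), 0)
})

test_that("sensitivity adjustments tag output and block the mediator path", {
  coh <- shared_cohort()
  assoc <- shared_assoc()
  sig <- unique(assoc[!is.na(assoc$q) & assoc$q < 0.05 &
                        assoc$score_id != "oPRS",
                      c("score_id", "metabolite_id")])
  trip <- utils::head(sig, 2)
  out <- mediation_sensitivity(trip, coh, adjustment = "hba1c",
                               n_sims = 150, seed = 9)
  expect_true(all(out$adjustment_tag == "hba1c_adjusted"))
  # adjusting for a near-copy of the mediator collapses the ACME toward 0
  d <- linear_toy(n = 1500, a = 0.5, b = 0.4, cp = 0.2, noise = 0.2, seed = 8)
  set.seed(88)
  copy <- matrix(d$m + rnorm(1500, 0, 0.02), ncol = 1,
                 dimnames = list(NULL, "copy"))
  mf <- fit_mediator_model(d$m, d$t, copy)
  of <- fit_outcome_model(d$y, d$t, d$m, copy, family = gaussian())
  r_adj <- quasi_bayesian_mediate(mf, of, n_sims = 300, seed = 6)
  mf0 <- fit_mediator_model(d$m, d$t)
  of0 <- fit_outcome_model(d$y, d$t, d$m, family = gaussian())
  r0 <- quasi_bayesian_mediate(mf0, of0, n_sims = 300, seed = 6)
  expect_lt(abs(r_adj$acme), abs(r0$acme) / 5)
})

test_that("elastic-net joint mediation selects the dominant mediator", {
  sel_hits <- 0L
  for (r in 1:10) {
    set.seed(100 + r)
    n <- 600
    t <- rnorm(n)
    M <- cbind(strong = 0.6 * t + rnorm(n, 0, 0.5),
               matrix(rnorm(n * 5), n, 5))
    colnames(M) <- c("strong", paste0("noise", 1:5))
    cv <- glmnet::cv.glmnet(M, t, alpha = 0.5, nfolds = 5)
    w <- as.vector(coef(cv, s = "lambda.min"))[-1]
    if (w[1] != 0) sel_hits <- sel_hits + 1L
  }
  expect_gte(sel_hits, 9)

  coh <- shared_cohort()
  assoc <- shared_assoc()
  jm1 <- joint_mediation("oPRS", assoc, coh, split_seed = 21, n_sims = 150)
  jm2 <- joint_mediation("oPRS", assoc, coh, split_seed = 21, n_sims = 150)
  expect_identical(jm1$selected_metabolites, jm2$selected_metabolites)
  expect_identical(jm1$validation_acme, jm2$validation_acme)
  expect_true(all(jm1$selected_metabolites %in%
                    assoc$metabolite_id[assoc$q < 0.05 &
                                          assoc$score_id == "oPRS"]))
  expect_error(joint_mediation("obesity",
                               within(assoc, q <- 0.9), coh, split_seed = 1),
               "at least 2")
})
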