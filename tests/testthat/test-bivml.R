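test_that("household covariance operator matches its dense construction", {
  sh <- cov_from_corr(4, 9, 0.5)
  se <- cov_from_corr(16, 25, -0.3)

  op1 <- household_marginal_covariance(sh, se, 1)
  expect_equal(op1$dense(), unname(sh + se))
  expect_equal(op1$logdet, as.numeric(determinant(sh + se)$modulus))

  op0 <- household_marginal_covariance(matrix(0, 2, 2), diag(2), 3)
  expect_equal(op0$logdet, 0)
  x <- rnorm(6)
  expect_equal(op0$solve(x), x)

  set.seed(99)
  for (n in c(2, 3, 5)) {
    A <- rand_pd(2); B <- rand_pd(2)
    op <- household_marginal_covariance(A, B, n)
    V <- op$dense()
    expect_equal(op$logdet, as.numeric(determinant(V)$modulus),
                 tolerance = 1e-8)
    for (r in 1:3) {
      x <- rnorm(2 * n)
      expect_equal(sum(x * op$solve(x)), sum(x * solve(V, x)),
                   tolerance = 1e-8)
    }
  }
  expect_error(household_marginal_covariance(diag(2), matrix(0, 2, 2), 2),
               "positive")
})

test_that("structured log-likelihood agrees with independence and duplication limits", {
  set.seed(12)
  N <- 40
  X <- cbind(1, rnorm(N))
  Y <- cbind(sbp = rnorm(N, 120, 12), dbp = rnorm(N, 75, 9))
  hh <- rep(1:20, each = 2)
  beta <- matrix(c(118, 1, 74, -0.5), 2, 2)
  se <- cov_from_corr(100, 60, 0.6)
  zero <- matrix(0, 2, 2)

  # sigma_h = 0: independent bivariate normals woman by woman
  ll <- joint_loglik(beta, zero, se, Y, X, hh)
  R <- Y - X %*% beta
  Ci <- solve(se)
  ll_ind <- sum(vapply(seq_len(N), function(i) {
    -0.5 * (2 * log(2 * pi) + as.numeric(determinant(se)$modulus) +
              as.numeric(R[i, ] %*% Ci %*% R[i, ]))
  }, numeric(1)))
  expect_equal(ll, ll_ind, tolerance = 1e-10)

  # duplicating every household doubles the log-likelihood exactly
  ll2 <- joint_loglik(beta, zero, se, rbind(Y, Y), rbind(X, X),
                      c(hh, hh + 100))
  expect_equal(ll2, 2 * ll, tolerance = 1e-10)

  expect_error(joint_loglik(beta[1, , drop = FALSE], zero, se, Y, X, hh),
               "conformable")
})

test_that("structured likelihood equals the dense oracle on random instances", {
  set.seed(2024)
  for (r in 1:20) {
    n_hh <- sample(3:12, 1)
    sizes <- sample(1:5, n_hh, replace = TRUE)
    hh <- rep(seq_len(n_hh), sizes)
    N <- length(hh)
    X <- cbind(1, matrix(rnorm(N * 2), N, 2))
    beta <- matrix(rnorm(6, sd = 2), 3, 2)
    sh <- rand_pd(2, scale = runif(1, 0.1, 5))
    se <- rand_pd(2, scale = runif(1, 0.5, 5))
    Y <- X %*% beta + rmvn_oracle(hh, sh, se)
    expect_equal(joint_loglik(beta, sh, se, Y, X, hh),
                 dense_loglik(beta, sh, se, Y, X, hh),
                 tolerance = 1e-8)
  }
})

test_that("single-level multivariate fit equals per-outcome least squares", {
  dat <- small_dataset(seed = 44, n_households = 200)
  X <- mini_design(dat)
  fit <- fit_single_level_multivariate(dat, mini_scheme())
  ols <- stats::lm.fit(X, cbind(dat$sbp, dat$dbp))
  expect_equal(unname(coef(fit)), unname(ols$coefficients), tolerance = 1e-10)
  expect_equal(fit$n_params, 2 * ncol(X) + 3)
  expect_identical(fit$model_tag, "single_level_multivariate")
  # and its loglik never exceeds the full model's on the same data
  full <- fit_bivariate_multilevel(dat, mini_scheme())
  expect_gte(full$loglik + 1e-6, fit$loglik)
  expect_equal(full$n_params, 2 * ncol(X) + 6)
})

test_that("null household variance is recovered at the boundary", {
  cfg <- mini_config(n_households = 800, sigma_h = matrix(0, 2, 2))
  dat <- simulate_population(cfg, seed = 77)
  fit <- fit_bivariate_multilevel(dat, mini_scheme())
  # generating sigma_h = 0: estimates should be tiny relative to sigma_e
  expect_lt(max(abs(fit$sigma_h)), 0.05 * max(diag(fit$sigma_e)))
  # and the LRT against the single-level model should be unremarkable
  lt <- lr_test(fit, fit_single_level_multivariate(dat, mini_scheme()))
  expect_lt(lt$chi2, stats::qchisq(0.999, df = 3))
})

test_that("estimates are invariant to row permutation and equivariant to outcome swap", {
  dat <- small_dataset(seed = 52, n_households = 250)
  fit <- fit_bivariate_multilevel(dat, mini_scheme())

  perm <- sample(nrow(dat))
  fitp <- fit_bivariate_multilevel(dat[perm, ], mini_scheme())
  expect_equal(fitp$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(coef(fitp), coef(fit), tolerance = 1e-6)

  swapped <- dat
  swapped$sbp <- dat$dbp
  swapped$dbp <- dat$sbp
  fits <- fit_bivariate_multilevel(swapped, mini_scheme())
  expect_equal(unname(coef(fits)[, 1]), unname(coef(fit)[, 2]),
               tolerance = 1e-4)
  expect_equal(unname(coef(fits)[, 2]), unname(coef(fit)[, 1]),
               tolerance = 1e-4)
  expect_equal(fits$sigma_h[1, 1], fit$sigma_h[2, 2], tolerance = 1e-2)
  expect_equal(fits$sigma_e[1, 1], fit$sigma_e[2, 2], tolerance = 1e-2)
  expect_equal(fits$loglik, fit$loglik, tolerance = 1e-5)
})

test_that("univariate multilevel fit matches an independent mixed-model implementation", {
  suppressMessages(require(lme4, quietly = TRUE))
  dat <- small_dataset(seed = 5, n_households = 600)
  fit <- fit_univariate_multilevel(dat, "sbp", mini_scheme())
  expect_identical(fit$model_tag, "univariate_multilevel")
  expect_equal(fit$n_params, 2L + 2L)  # p + 2 with the mini design

  df <- data.frame(y = dat$sbp,
                   obese = as.numeric(dat$obesity == "Obese"),
                   hh = dat$household_id)
  fm <- lme4::lmer(y ~ obese + (1 | hh), data = df, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(stats::logLik(fm)), tolerance = 1e-5)
  expect_equal(unname(coef(fit)[, 1]), unname(lme4::fixef(fm)),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(fm))
  expect_equal(fit$sigma_h[1, 1], vc$vcov[1], tolerance = 1e-2)
  expect_equal(fit$sigma_e[1, 1], vc$vcov[2], tolerance = 1e-2)
})

test_that("univariate margins track the bivariate fit on shared data", {
  dat <- small_dataset(seed = 66, n_households = 500)
  biv <- fit_bivariate_multilevel(dat, mini_scheme())
  uni <- fit_univariate_multilevel(dat, "sbp", mini_scheme())
  sb <- summary(biv)$coefficients$sbp
  su <- summary(uni)$coefficients$sbp
  # near-identical point estimates; CIs overlap for every coefficient
  expect_equal(sb$estimate, su$estimate, tolerance = 0.15)
  expect_true(all(sb$lower <= su$upper & su$lower <= sb$upper))
})

test_that("degenerate designs are rejected with the offending column named", {
  dat <- small_dataset(seed = 9, n_households = 60)
  X <- mini_design(dat)
  X <- cbind(X, dup = X[, 2])
  expect_error(bpml_fit(cbind(dat$sbp, dat$dbp), X, dat$household_id),
               "rank deficient.*dup|dup.*rank deficient")
})

test_that("the formula interface reproduces the scheme-based fit", {
  dat <- small_dataset(seed = 13, n_households = 200)
  f1 <- fit_bivariate_multilevel(dat, mini_scheme())
  f2 <- bpml(cbind(sbp, dbp) ~ obesity, dat, household = ~household_id)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(unname(coef(f2)), unname(coef(f1)), tolerance = 1e-5)
  # incomplete rows are dropped with a message
  dat$sbp[3] <- NA
  expect_message(bpml(cbind(sbp, dbp) ~ obesity, dat, ~household_id),
                 "incomplete")
})
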