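# minimal hand-built fit objects for pure-arithmetic checks
fake_fit <- function(coefficients, vcov, loglik = -100, n_params = 5,
                     n_women = 10, model_tag = "bivariate_multilevel") {
  structure(list(coefficients = coefficients, vcov = vcov,
                 sigma_h = cov_from_corr(1, 1, 0),
                 sigma_e = cov_from_corr(1, 1, 0),
                 loglik = loglik, n_params = n_params, n_women = n_women,
                 n_households = n_women, n_multiwoman = 0L,
                 converged = TRUE, boundary = FALSE,
                 model_tag = model_tag,
                 outcome_names = c("sbp", "dbp")),
            class = "bpml")
}

test_that("variance partition coefficients match the closed form", {
  v <- vpc(c(sbp = 38.91, dbp = 16.37), c(sbp = 224.49, dbp = 101.75))
  expect_equal(v$vpc, c(38.91 / (38.91 + 224.49), 16.37 / (16.37 + 101.75)),
               tolerance = 1e-12)
  expect_equal(v$percent, c(15L, 14L))

  expect_equal(vpc(0, 10)$vpc, 0)
  expect_equal(vpc(7, 7)$percent, 50L)
  expect_error(vpc(0, 0), "positive")
  expect_error(vpc(-1, 2), "non-negative")

  # scale equivariance: multiplying both outcomes by c scales variances by c^2
  expect_equal(vpc(38.91 * 4, 224.49 * 4)$vpc, vpc(38.91, 224.49)$vpc)
})

test_that("residual correlations are the normalized covariances per level", {
  rc <- residual_correlations(list(sigma_h = diag(c(2, 3)),
                                   sigma_e = diag(c(1, 5))))
  expect_equal(rc$household_r, 0)
  expect_equal(rc$woman_r, 0)

  rc1 <- residual_correlations(list(sigma_h = cov_from_corr(4, 9, 1),
                                    sigma_e = cov_from_corr(2, 2, 0.73)))
  expect_equal(rc1$household_r, 1)
  expect_equal(rc1$woman_r, 0.73)

  # scale equivariance
  s <- list(sigma_h = cov_from_corr(38.91, 16.37, 0.81),
            sigma_e = cov_from_corr(224.49, 101.75, 0.73))
  s2 <- lapply(s, function(m) 2.5^2 * m)
  expect_equal(residual_correlations(s2), residual_correlations(s))

  expect_error(residual_correlations(list(sigma_h = matrix(0, 2, 2),
                                          sigma_e = diag(2))),
               "zero variance")
})

test_that("the equality Wald statistic follows its quadratic form", {
  b <- matrix(c(0, 2, 0, 0), 2, 2,
              dimnames = list(c("(Intercept)", "x"), c("sbp", "dbp")))
  ft <- fake_fit(b, diag(4))
  w <- wald_equality(ft, "x")
  expect_equal(w$chi2, 2.0)
  expect_equal(w$df, 1L)
  expect_equal(w$p_value, stats::pchisq(2, 1, lower.tail = FALSE))

  # correlated estimates shrink the denominator
  V <- diag(4); V[2, 4] <- V[4, 2] <- 0.5
  w2 <- wald_equality(fake_fit(b, V), "x")
  expect_equal(w2$chi2, 4 / (1 + 1 - 2 * 0.5))

  expect_error(wald_equality(ft, "nope"), "not in the fit")
  uni <- fake_fit(b, diag(4))
  uni$coefficients <- b[, 1, drop = FALSE]
  expect_error(wald_equality(uni), "univariate")
})

test_that("equality test is symmetric in outcome labels and shift invariant", {
  dat <- small_dataset(seed = 7, n_households = 400)
  fit <- fit_bivariate_multilevel(dat, mini_scheme())
  w <- wald_equality(fit, "obesity=Obese")

  swapped <- dat
  swapped$sbp <- dat$dbp; swapped$dbp <- dat$sbp
  ws <- wald_equality(fit_bivariate_multilevel(swapped, mini_scheme()),
                      "obesity=Obese")
  expect_equal(ws$chi2, w$chi2, tolerance = 1e-3)

  shifted <- dat
  shifted$sbp <- dat$sbp + 7; shifted$dbp <- dat$dbp + 7
  wt <- wald_equality(fit_bivariate_multilevel(shifted, mini_scheme()),
                      "obesity=Obese")
  expect_equal(wt$chi2, w$chi2, tolerance = 1e-4)
})

test_that("likelihood-ratio test arithmetic, clipping and nesting rules", {
  full <- fake_fit(matrix(0, 2, 2), diag(4), loglik = -100, n_params = 8)
  nested <- fake_fit(matrix(0, 2, 2), diag(4), loglik = -110, n_params = 5,
                     model_tag = "single_level_multivariate")
  lt <- lr_test(full, nested)
  expect_equal(lt$chi2, 20)
  expect_equal(lt$df, 3L)
  expect_equal(lt$p_value, stats::pchisq(20, 3, lower.tail = FALSE))

  same <- lr_test(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  expect_error(lr_test(nested, full), "not nested")
})

test_that("information criteria use the women count and favour real structure", {
  ft <- fake_fit(matrix(0, 2, 2), diag(4), loglik = -100, n_params = 5,
                 n_women = 10)
  ic <- information_criteria(ft)
  expect_equal(unname(ic["AIC"]), 210)
  expect_equal(unname(ic["BIC"]), 200 + 5 * log(10))

  # chi2 > 2 * delta_k implies the full model has the lower AIC
  dat <- small_dataset(seed = 19, n_households = 700)
  full <- fit_bivariate_multilevel(dat, mini_scheme())
  nested <- fit_single_level_multivariate(dat, mini_scheme())
  lt <- lr_test(full, nested)
  dk <- full$n_params - nested$n_params
  if (lt$chi2 > 2 * dk) {
    expect_lt(information_criteria(full)[["AIC"]],
              information_criteria(nested)[["AIC"]])
  }
  # logLik method exposes df and nobs so stats::AIC/BIC agree
  expect_equal(stats::AIC(full), information_criteria(full)[["AIC"]])
  expect_equal(stats::BIC(full), information_criteria(full)[["BIC"]])
})

test_that("empirical outcome correlation matches cor.test behaviour", {
  d <- data.frame(sbp = c(1, 2, 3, 4), dbp = c(2, 4, 6, 8))
  expect_equal(empirical_outcome_correlation(d)$r, 1)

  set.seed(61)
  d2 <- data.frame(sbp = rnorm(500), dbp = rnorm(500))
  ec <- empirical_outcome_correlation(d2)
  expect_lt(abs(ec$r), 0.15)

  dat <- simulate_population(default_sim_config(), seed = 33)
  r <- empirical_outcome_correlation(dat)$r
  # implied marginal correlation from the generating components is ~0.74
  expect_lt(abs(r - 0.74), 0.03)
  expect_error(empirical_outcome_correlation(d2[1:2, ]), "at least 3")
})

test_that("QQ data are standardized, ordered and normal for Gaussian data", {
  dat <- small_dataset(seed = 23, n_households = 900)
  fit <- fit_bivariate_multilevel(dat, mini_scheme())
  qq <- residual_qq_data(fit)
  expect_setequal(unique(qq$outcome), c("sbp", "dbp"))
  sub <- qq[qq$outcome == "sbp", ]
  n <- nrow(sub)
  expect_equal(sub$theoretical, stats::qnorm((seq_len(n) - 0.5) / n))
  expect_false(is.unsorted(sub$observed))
  # Kolmogorov distance below the 1% critical value for Gaussian residuals
  ks <- max(abs(stats::pnorm(sub$observed) - (seq_len(n) - 0.5) / n))
  expect_lt(ks, 1.63 / sqrt(n))

  # heavy-tailed contamination is visible
  contaminated <- dat
  set.seed(5)
  idx <- sample(nrow(dat), 60)
  contaminated$sbp[idx] <- contaminated$sbp[idx] + rnorm(60, 0, 80)
  qc <- residual_qq_data(fit_bivariate_multilevel(contaminated, mini_scheme()))
  subc <- qc[qc$outcome == "sbp", ]
  ksc <- max(abs(stats::pnorm(subc$observed) -
                   (seq_len(nrow(subc)) - 0.5) / nrow(subc)))
  expect_gt(ksc, 1.63 / sqrt(nrow(subc)))

  # single observation sits at the median quantile
  one <- fake_fit(matrix(c(1, 1), 1, 2,
                         dimnames = list("(Intercept)", c("sbp", "dbp"))),
                  diag(2))
  one$X <- matrix(1, 1, 1)
  one$Y <- matrix(c(1.5, 0.5), 1, 2)
  q1 <- residual_qq_data(one)
  expect_equal(q1$theoretical, c(0, 0))
})
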