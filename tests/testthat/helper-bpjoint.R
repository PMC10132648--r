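# shared fixtures: reduced generator configurations and a dense-likelihood
# oracle, all built in code

mini_scheme <- function() {
  structure(list(
    factors = list(obesity = c("Not obese", "Obese")),
    reference = c(obesity = "Not obese"),
    woman_level = "obesity",
    household_level = character(0)
  ), class = "covariate_scheme")
}

# one binary covariate; covariance truth as in the full default config unless
# overridden
mini_config <- function(n_households = 500,
                        beta_sbp = 5, beta_dbp = 5,
                        sigma_h = cov_from_corr(38.91, 16.37, 0.81),
                        sigma_e = cov_from_corr(224.49, 101.75, 0.73),
                        size_probs = c(`1` = 0.76, `2` = 0.21, `3` = 0.03),
                        obese_prob = 0.128) {
  cfg <- default_sim_config(n_households = n_households)
  cfg$scheme <- mini_scheme()
  cfg$covariate_marginals <- list(
    obesity = c("Not obese" = 1 - obese_prob, "Obese" = obese_prob))
  cfg$beta <- matrix(c(beta_sbp, beta_dbp), 1, 2,
                     dimnames = list("obesity=Obese", c("sbp", "dbp")))
  cfg$sigma_h <- sigma_h
  cfg$sigma_e <- sigma_e
  cfg$household_size_probs <- size_probs
  validate_sim_config(cfg)
  cfg
}

mini_design <- function(dat) {
  build_design(dat, mini_scheme())
}

# independent oracle: per-household dense multivariate-normal evaluation with
# the covariance assembled by explicit Kronecker products
dense_loglik <- function(beta, sigma_h, sigma_e, Y, X, household) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  beta <- matrix(beta, ncol = ncol(Y))
  ll <- 0
  for (j in unique(household)) {
    ix <- which(household == j)
    n <- length(ix)
    V <- kronecker(diag(n), sigma_e) + kronecker(matrix(1, n, n), sigma_h)
    r <- as.vector(t(Y[ix, , drop = FALSE] - X[ix, , drop = FALSE] %*% beta))
    ll <- ll - 0.5 * (length(r) * log(2 * pi) +
                        as.numeric(determinant(V)$modulus) +
                        sum(r * solve(V, r)))
  }
  ll
}

# clustered bivariate noise with household effect sh and residual se
rmvn_oracle <- function(household, sigma_h, sigma_e) {
  ids <- match(household, unique(household))
  H <- max(ids)
  chol_draw <- function(n, S) {
    ev <- eigen(S, symmetric = TRUE)
    rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    matrix(rnorm(n * nrow(S)), n, nrow(S)) %*% rt
  }
  chol_draw(H, sigma_h)[ids, , drop = FALSE] +
    chol_draw(length(ids), sigma_e)
}

rand_pd <- function(d = 2, scale = 1) {
  crossprod(matrix(rnorm(d * d), d)) * scale + diag(d) * 0.5 * scale
}

# small clustered dataset for fit-level tests
small_dataset <- function(seed, n_households = 300) {
  simulate_population(mini_config(n_households = n_households), seed = seed)
}
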