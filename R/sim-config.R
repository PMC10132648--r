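#' Default generator configuration
#'
#' Parameters of the household-clustered bivariate blood-pressure generator.
#' Defaults emulate the study population the model targets: 3727 households
#' (mostly 1–2 eligible women each, about 4744 women in expectation), covariate
#' category probabilities equal to the published cohort frequencies, fixed
#' effects equal to the published joint-model point estimates, a household
#' random-effect covariance with variances 38.91 / 16.37 mmHg² and correlation
#' 0.81, and a woman-level residual covariance with variances 224.49 / 101.75
#' mmHg² and correlation 0.73. Reference-group intercepts (112 / 72 mmHg) are
#' clinically plausible defaults, as intercepts are not published.
#'
#' @param n_households Number of households to simulate.
#' @param intercepts Named numeric, mean SBP and DBP (mmHg) for a woman at all
#'   reference categories.
#' @param ever_told_prob Probability a woman reports having ever been told she
#'   has hypertension (drawn independently of the outcomes; used only in
#'   descriptives and maps).
#' @param household_size_probs Named numeric probability table over women per
#'   household (names are the sizes).
#' @param seed Optional default seed stored in the config (the `seed` argument
#'   of [simulate_population()] takes precedence).
#' @return An object of class `"sim_config"`; see Details for fields.
#' @details Fields: `n_households`, `household_size_probs`, `scheme`
#'   (a [covariate_scheme()]), `covariate_marginals` (per factor, named
#'   probabilities over its levels), `intercepts`, `beta` (matrix, one row per
#'   non-reference indicator named `"factor=level"`, columns `sbp`, `dbp`),
#'   `sigma_h` and `sigma_e` (2x2 covariance matrices of the household effects
#'   and woman residuals), `region_names`, `region_probs`, `ever_told_prob`,
#'   `seed`.
#' @examples
#' cfg <- default_sim_config()
#' diag(cfg$sigma_h)            # household-level variances
#' cfg$beta["age_group=45–49", ]
#' @export
default_sim_config <- function(n_households = 3727,
                               intercepts = c(sbp = 112, dbp = 72),
                               ever_told_prob = 0.069,
                               household_size_probs = c(`1` = 0.76, `2` = 0.21,
                                                        `3` = 0.03),
                               seed = NULL) {
  scheme <- covariate_scheme()
  counts <- list(
    age_group             = c(1688, 1452, 1179, 425),
    obesity               = c(4138, 606),
    cooking_fuel          = c(890, 1439, 2415),
    education             = c(2688, 1160, 896),
    wealth                = c(1689, 2071, 984),
    water_source          = c(668, 4076),
    toilet_type           = c(1707, 3037),
    household_size        = c(3362, 1382),
    wall_type             = c(1431, 3313),
    vegetable_consumption = c(4094, 650)
  )
  marginals <- lapply(names(counts), function(f) {
    p <- counts[[f]] / sum(counts[[f]])
    names(p) <- scheme$factors[[f]]
    p
  })
  names(marginals) <- names(counts)

  beta <- rbind(
    "age_group=25–34"                          = c( 2.45,   3.29),
    "age_group=35–44"                          = c( 8.72,   6.78),
    "age_group=45–49"                          = c(15.85,  10.05),
    "obesity=Obese"                            = c( 5.10,   4.20),
    "cooking_fuel=Transition"                  = c(-0.02,  -0.46),
    "cooking_fuel=Primitive"                   = c(-0.75,  -2.06),
    "education=No education"                   = c(-2.05,  -1.23),
    "education=Primary"                        = c( 0.61,   0.43),
    "wealth=Poorer/poorest"                    = c(-0.73,  -0.14),
    "wealth=Middle"                            = c(-0.11,  -0.14),
    "water_source=Unimproved"                  = c(-0.68,  -0.39),
    "toilet_type=Unimproved"                   = c( 1.75,   0.61),
    "household_size=1–3 members"               = c( 0.78,   0.65),
    "wall_type=Non-durable materials"          = c(-0.003,  0.47),
    "vegetable_consumption=Didn’t eat vegetable" = c(0.31,  0.34)
  )
  colnames(beta) <- c("sbp", "dbp")

  sigma_h <- cov_from_corr(var1 = 38.91, var2 = 16.37, corr = 0.81)
  sigma_e <- cov_from_corr(var1 = 224.49, var2 = 101.75, corr = 0.73)

  regions <- c("Western", "Central", "Greater Accra", "Volta", "Eastern",
               "Ashanti", "Brong Ahafo", "Northern", "Upper East",
               "Upper West")

  cfg <- structure(list(
    n_households = as.integer(n_households),
    household_size_probs = household_size_probs,
    scheme = scheme,
    covariate_marginals = marginals,
    intercepts = intercepts,
    beta = beta,
    sigma_h = sigma_h,
    sigma_e = sigma_e,
    region_names = regions,
    region_probs = stats::setNames(rep(1 / length(regions), length(regions)),
                                   regions),
    ever_told_prob = ever_told_prob,
    seed = seed
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Assemble a 2x2 covariance matrix from variances and a correlation
#'
#' @param var1,var2 Variances (mmHg²) of the SBP and DBP components.
#' @param corr Correlation between the components.
#' @return A 2x2 covariance matrix with dimnames `c("sbp", "dbp")`.
#' @export
cov_from_corr <- function(var1, var2, corr) {
  stopifnot(var1 >= 0, var2 >= 0, abs(corr) <= 1)
  m <- matrix(c(var1, corr * sqrt(var1 * var2),
                corr * sqrt(var1 * var2), var2), 2, 2,
              dimnames = list(c("sbp", "dbp"), c("sbp", "dbp")))
  m
}

#' Validate a generator configuration
#'
#' Checks every probability table sums to one (within 1e-12), the covariance
#' components are symmetric and (semi-)definite, and the fixed-effect rows are
#' indexed identically for both outcomes.
#'
#' @param config A `"sim_config"` object.
#' @return The config, invisibly; stops on violation.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_households <= 0) stop("n_households must be positive")
  check_ptab <- function(p, name) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      stop(sprintf("probability table '%s' must be non-negative and sum to 1",
                   name))
    }
  }
  check_ptab(config$household_size_probs, "household_size_probs")
  check_ptab(config$region_probs, "region_probs")
  for (f in names(config$covariate_marginals)) {
    check_ptab(config$covariate_marginals[[f]], f)
    if (!identical(names(config$covariate_marginals[[f]]),
                   config$scheme$factors[[f]])) {
      stop(sprintf("marginals for '%s' do not match the scheme's levels", f))
    }
  }
  .check_cov(config$sigma_h, "sigma_h", positive_definite = FALSE)
  .check_cov(config$sigma_e, "sigma_e", positive_definite = TRUE)
  if (is.null(rownames(config$beta)) || ncol(config$beta) != 2) {
    stop("beta must be a named matrix with columns for SBP and DBP")
  }
  if (config$ever_told_prob < 0 || config$ever_told_prob > 1) {
    stop("ever_told_prob must be in [0, 1]")
  }
  if (anyDuplicated(config$region_names)) stop("region names must be unique")
  invisible(config)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Generator configuration\n")
  cat("  households:", x$n_households,
      sprintf("(expected women: %.0f)\n",
              x$n_households * sum(as.numeric(names(x$household_size_probs)) *
                                   x$household_size_probs)))
  cat("  intercepts (mmHg):", paste(x$intercepts, collapse = " / "), "\n")
  cat(sprintf("  sigma_h: var %.2f / %.2f, corr %.2f\n",
              x$sigma_h[1, 1], x$sigma_h[2, 2],
              stats::cov2cor(x$sigma_h)[1, 2]))
  cat(sprintf("  sigma_e: var %.2f / %.2f, corr %.2f\n",
              x$sigma_e[1, 1], x$sigma_e[2, 2],
              stats::cov2cor(x$sigma_e)[1, 2]))
  cat("  regions:", length(x$region_names), "\n")
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' Round-trippable plain-text serialization of a `"sim_config"`.
#'
#' @param config A `"sim_config"`.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly; `read_sim_config()`
#'   returns the reconstructed `"sim_config"`.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  ser <- list(
    n_households = config$n_households,
    household_size_probs = as.list(config$household_size_probs),
    covariate_marginals = lapply(config$covariate_marginals, as.list),
    intercepts = as.list(config$intercepts),
    beta = list(labels = rownames(config$beta),
                sbp = unname(config$beta[, "sbp"]),
                dbp = unname(config$beta[, "dbp"])),
    sigma_h = list(var_sbp = config$sigma_h[1, 1],
                   var_dbp = config$sigma_h[2, 2],
                   cov = config$sigma_h[1, 2]),
    sigma_e = list(var_sbp = config$sigma_e[1, 1],
                   var_dbp = config$sigma_e[2, 2],
                   cov = config$sigma_e[1, 2]),
    region_names = config$region_names,
    region_probs = as.list(config$region_probs),
    ever_told_prob = config$ever_told_prob,
    seed = config$seed
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_sim_config()
  cfg$n_households <- as.integer(y$n_households)
  cfg$household_size_probs <- unlist(y$household_size_probs)
  cfg$covariate_marginals <- lapply(y$covariate_marginals, unlist)
  cfg$intercepts <- unlist(y$intercepts)
  beta <- cbind(sbp = unlist(y$beta$sbp), dbp = unlist(y$beta$dbp))
  rownames(beta) <- unlist(y$beta$labels)
  cfg$beta <- beta
  m <- function(b) matrix(c(b$var_sbp, b$cov, b$cov, b$var_dbp), 2, 2,
                          dimnames = list(c("sbp", "dbp"), c("sbp", "dbp")))
  cfg$sigma_h <- m(y$sigma_h)
  cfg$sigma_e <- m(y$sigma_e)
  cfg$region_names <- unlist(y$region_names)
  cfg$region_probs <- unlist(y$region_probs)
  cfg$ever_told_prob <- y$ever_told_prob
  cfg$seed <- y$seed
  validate_sim_config(cfg)
  cfg
}
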