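#' Variance partition coefficient (household-level ICC)
#'
#' Share of total outcome variance attributable to the household level:
#' `rho_k = var_h_k / (var_h_k + var_e_k)` per outcome. Under the
#' random-intercept model this coincides with the intraclass correlation.
#' The percent form is rounded to the nearest integer (half away from zero)
#' for report parity.
#'
#' @param object Either a `"bpml"` fit, or a numeric vector of household-level
#'   variances (mmHg²).
#' @param var_woman For the numeric form, the woman-level residual variances.
#' @param ... Unused.
#' @return A data frame with columns `outcome`, `vpc` (proportion in `[0,1]`)
#'   and `percent` (integer).
#' @examples
#' vpc(c(sbp = 38.91, dbp = 16.37), c(sbp = 224.49, dbp = 101.75))
#' @export
vpc <- function(object, ...) UseMethod("vpc")

#' @rdname vpc
#' @export
vpc.default <- function(object, var_woman, ...) {
  var_household <- object
  if (length(var_household) != length(var_woman)) {
    stop("variance vectors must have equal length")
  }
  if (any(var_household < 0) || any(var_woman < 0)) {
    stop("variances must be non-negative")
  }
  tot <- var_household + var_woman
  if (any(tot <= 0)) stop("total variance must be positive")
  rho <- var_household / tot
  nm <- names(var_household)
  if (is.null(nm)) nm <- paste0("outcome", seq_along(rho))
  data.frame(outcome = nm, vpc = unname(rho),
             percent = as.integer(round_half_away(100 * unname(rho))))
}

#' @rdname vpc
#' @export
vpc.bpml <- function(object, ...) {
  vpc.default(stats::setNames(diag(object$sigma_h), object$outcome_names),
              diag(object$sigma_e))
}

#' Cross-outcome residual correlations by level
#'
#' Correlation between the SBP and DBP unexplained components at the household
#' level (`cov_h / sqrt(var_h1 var_h2)`) and at the woman level
#' (`cov_e / sqrt(var_e1 var_e2)`).
#'
#' @param object A `"bpml"` bivariate fit, or a list with 2x2 matrices
#'   `sigma_h` and `sigma_e`.
#' @param ... Unused.
#' @return A list with elements `household_r` and `woman_r`.
#' @examples
#' residual_correlations(list(sigma_h = cov_from_corr(38.91, 16.37, 0.81),
#'                            sigma_e = cov_from_corr(224.49, 101.75, 0.73)))
#' @export
residual_correlations <- function(object, ...) {
  UseMethod("residual_correlations")
}

#' @rdname residual_correlations
#' @export
residual_correlations.default <- function(object, ...) {
  r_of <- function(S) {
    v <- diag(S)
    if (any(v <= 0)) stop("zero variance: correlation undefined")
    S[1, 2] / sqrt(v[1] * v[2])
  }
  list(household_r = unname(r_of(object$sigma_h)),
       woman_r = unname(r_of(object$sigma_e)))
}

#' @rdname residual_correlations
#' @export
residual_correlations.bpml <- function(object, ...) {
  if (ncol(object$coefficients) != 2L) {
    stop("residual correlations need a bivariate fit")
  }
  residual_correlations.default(object)
}

#' Wald test of equal risk-factor effect across the two outcomes
#'
#' For a coefficient present in both outcome equations, tests
#' `H0: beta_sbp = beta_dbp` with `chi2 = (b1 - b2)^2 / (V11 + V22 - 2 V12)`
#' on 1 df, using the joint fixed-effect covariance — the comparison the joint
#' model enables and separate univariate fits cannot provide.
#'
#' @param fit A bivariate `"bpml"` fit (two outcome columns).
#' @param levels Coefficient names to test; defaults to every non-intercept
#'   design column.
#' @return A data frame with columns `level`, `estimate_sbp`, `estimate_dbp`,
#'   `diff`, `chi2`, `df`, `p_value`. No multiplicity adjustment is applied
#'   across rows.
#' @export
wald_equality <- function(fit, levels = NULL) {
  stopifnot(inherits(fit, "bpml"))
  if (ncol(fit$coefficients) != 2L) {
    stop("equality testing needs the joint (bivariate) fit: ",
         "univariate fits carry no cross-outcome covariance")
  }
  cn <- rownames(fit$coefficients)
  if (is.null(levels)) levels <- setdiff(cn, "(Intercept)")
  missing_lv <- setdiff(levels, cn)
  if (length(missing_lv)) {
    stop("coefficient(s) not in the fit: ", paste(missing_lv, collapse = ", "))
  }
  p <- nrow(fit$coefficients)
  out <- lapply(levels, function(lv) {
    k <- match(lv, cn)
    b1 <- fit$coefficients[k, 1]; b2 <- fit$coefficients[k, 2]
    v <- fit$vcov[k, k] + fit$vcov[p + k, p + k] - 2 * fit$vcov[k, p + k]
    chi2 <- (b1 - b2)^2 / v
    data.frame(level = lv, estimate_sbp = b1, estimate_dbp = b2,
               diff = b1 - b2, chi2 = chi2, df = 1L,
               p_value = stats::pchisq(chi2, 1L, lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Likelihood-ratio test of nested fits
#'
#' `chi2 = 2 (loglik_full - loglik_nested)` clipped at zero, with the naive
#' chi-square reference on `df = ` difference in parameter count. For the
#' household-variance comparison (3 df) the true null lies on the boundary of
#' the parameter space, so the naive p-value is conservative; the result
#' carries a `note` saying so.
#'
#' @param fit_full,fit_nested `"bpml"` fits of the same data, the second
#'   nested in the first.
#' @return A list of class `"bp_lrt"`: `chi2`, `df`, `p_value`, `note`.
#' @export
lr_test <- function(fit_full, fit_nested) {
  stopifnot(inherits(fit_full, "bpml"), inherits(fit_nested, "bpml"))
  nested_pairs <- list(
    c("bivariate_multilevel", "single_level_multivariate"),
    c("univariate_multilevel", "single_level_univariate")
  )
  ok <- any(vapply(nested_pairs, function(pr) {
    fit_full$model_tag == pr[1] && fit_nested$model_tag == pr[2]
  }, logical(1))) || identical(fit_full$model_tag, fit_nested$model_tag)
  if (!ok) {
    stop(sprintf("'%s' is not nested in '%s'", fit_nested$model_tag,
                 fit_full$model_tag))
  }
  if (fit_full$n_women != fit_nested$n_women ||
      !identical(dim(fit_full$coefficients), dim(fit_nested$coefficients))) {
    stop("fits must share the same data and design")
  }
  df <- fit_full$n_params - fit_nested$n_params
  chi2 <- max(0, 2 * (fit_full$loglik - fit_nested$loglik))
  p <- if (df > 0L) stats::pchisq(chi2, df, lower.tail = FALSE) else
    as.numeric(chi2 == 0)
  structure(list(chi2 = chi2, df = df, p_value = p,
                 note = paste("variance components lie on the boundary under",
                              "H0; the naive chi-square p-value is",
                              "conservative")),
            class = "bp_lrt")
}

#' @export
print.bp_lrt <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: chi2 = %.2f on %d df, p %s\n",
              x$chi2, x$df,
              if (x$p_value < 1e-4) "< 0.0001" else
                sprintf("= %.4f", x$p_value)))
  cat("  note:", x$note, "\n")
  invisible(x)
}

#' Information criteria of a fit
#'
#' `AIC = -2 loglik + 2 k`; `BIC = -2 loglik + k log(N)` with `N` the number
#' of women (level-1 units).
#'
#' @param fit A `"bpml"` fit.
#' @return Named numeric vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(fit) {
  stopifnot(inherits(fit, "bpml"))
  k <- fit$n_params
  c(AIC = -2 * fit$loglik + 2 * k,
    BIC = -2 * fit$loglik + k * log(fit$n_women))
}

#' Empirical (unadjusted) correlation of the two outcomes
#'
#' Pearson correlation of observed SBP and DBP with its two-sided t-test;
#' the covariate-unadjusted counterpart of the model's residual correlations.
#'
#' @param data Data frame with `sbp` and `dbp` columns (>= 3 complete rows).
#' @return A list: `r`, `p_value`, `n`, `conf_int`.
#' @export
empirical_outcome_correlation <- function(data) {
  ok <- stats::complete.cases(data$sbp, data$dbp)
  if (sum(ok) < 3L) stop("need at least 3 complete records")
  ct <- stats::cor.test(data$sbp[ok], data$dbp[ok])
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       conf_int = as.numeric(ct$conf.int))
}

#' Data for normal quantile-quantile residual diagnostics
#'
#' Marginal residuals `y - x' beta_hat` standardized by the model's total
#' standard deviation `sqrt(var_h + var_e)` per outcome, ordered and paired
#' with theoretical normal quantiles at `(i - 0.5) / N`.
#'
#' @param fit A `"bpml"` fit.
#' @return A data frame with columns `outcome`, `theoretical`, `observed`.
#' @export
residual_qq_data <- function(fit) {
  stopifnot(inherits(fit, "bpml"))
  R <- residuals(fit)
  tot_sd <- sqrt(diag(fit$sigma_h) + diag(fit$sigma_e))
  out <- lapply(seq_len(ncol(R)), function(k) {
    z <- sort(R[, k] / tot_sd[k])
    n <- length(z)
    data.frame(outcome = fit$outcome_names[k],
               theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
               observed = z)
  })
  do.call(rbind, out)
}
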