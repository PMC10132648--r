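#' @export
print.bpml <- function(x, ...) {
  cat("Joint multilevel blood-pressure model (", x$model_tag, ")\n", sep = "")
  cat(sprintf("  %d women in %d households (%d with >1 woman)\n",
              x$n_women, x$n_households, x$n_multiwoman))
  cat(sprintf("  log-likelihood %.2f on %d parameters%s\n", x$loglik,
              x$n_params,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  if (x$boundary) cat("  note: household variance at its lower boundary\n")
  cat("Fixed effects:\n")
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Summarize a joint multilevel fit
#'
#' Per-outcome coefficient tables with standard errors, Wald z statistics and
#' symmetric 95% confidence intervals, plus the variance components, the
#' level-specific residual correlations, the variance partition coefficients
#' and the information criteria.
#'
#' @param object A `"bpml"` fit.
#' @param level Confidence level for the intervals.
#' @param ... Unused.
#' @return An object of class `"summary.bpml"`.
#' @export
summary.bpml <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  p <- nrow(object$coefficients)
  d <- ncol(object$coefficients)
  z <- stats::qnorm(1 - (1 - level) / 2)
  tables <- lapply(seq_len(d), function(k) {
    est <- object$coefficients[, k]
    s <- se[(k - 1L) * p + seq_len(p)]
    data.frame(estimate = est, se = s,
               z = est / s,
               lower = est - z * s, upper = est + z * s,
               p_value = 2 * stats::pnorm(-abs(est / s)),
               row.names = rownames(object$coefficients))
  })
  names(tables) <- object$outcome_names
  out <- list(coefficients = tables,
              sigma_h = object$sigma_h, sigma_e = object$sigma_e,
              vpc = vpc(object),
              residual_correlations =
                if (d == 2L && all(diag(object$sigma_h) > 0) &&
                    all(diag(object$sigma_e) > 0))
                  residual_correlations(object) else NULL,
              loglik = object$loglik,
              information_criteria = information_criteria(object),
              n_women = object$n_women, n_households = object$n_households,
              n_multiwoman = object$n_multiwoman,
              model_tag = object$model_tag, converged = object$converged,
              boundary = object$boundary, level = level)
  class(out) <- "summary.bpml"
  out
}

#' @export
print.summary.bpml <- function(x, digits = 3, ...) {
  cat("Joint multilevel blood-pressure model (", x$model_tag, ")\n", sep = "")
  cat(sprintf("  %d women in %d households (%d with >1 woman)\n",
              x$n_women, x$n_households, x$n_multiwoman))
  for (nm in names(x$coefficients)) {
    cat("\n", toupper(nm), " fixed effects (", 100 * x$level, "% CI):\n",
        sep = "")
    print(round(x$coefficients[[nm]], digits))
  }
  cat("\nVariance components (mmHg^2):\n")
  cat("  household:\n"); print(round(x$sigma_h, digits))
  cat("  woman:\n"); print(round(x$sigma_e, digits))
  if (!is.null(x$residual_correlations)) {
    rc <- x$residual_correlations
    cat(sprintf("\nResidual correlation: woman %.2f, household %.2f\n",
                rc$woman_r, rc$household_r))
  }
  if (!is.null(x$vpc)) {
    cat("VPC (household share of total variance): ",
        paste(sprintf("%s %d%%", x$vpc$outcome, x$vpc$percent),
              collapse = ", "), "\n", sep = "")
  }
  ic <- x$information_criteria
  cat(sprintf("\nlogLik %.2f, AIC %.1f, BIC %.1f%s\n", x$loglik,
              ic[["AIC"]], ic[["BIC"]],
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
coef.bpml <- function(object, ...) object$coefficients

#' @export
vcov.bpml <- function(object, ...) object$vcov

#' @export
logLik.bpml <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_women,
            class = "logLik")
}

#' @export
nobs.bpml <- function(object, ...) object$n_women

#' @export
confint.bpml <- function(object, parm, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  est <- as.vector(object$coefficients)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(est - z * se, est + z * se)
  dimnames(out) <- list(rownames(object$vcov),
                        paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               " %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
fitted.bpml <- function(object, ...) {
  f <- object$X %*% object$coefficients
  colnames(f) <- object$outcome_names
  f
}

#' Marginal residuals of a joint multilevel fit
#'
#' Raw residuals `y - X beta_hat` per outcome (random effects not subtracted).
#'
#' @param object A `"bpml"` fit.
#' @param ... Unused.
#' @return An `N x d` matrix.
#' @export
residuals.bpml <- function(object, ...) {
  r <- object$Y - fitted(object)
  colnames(r) <- object$outcome_names
  r
}

#' Predict fixed-effect means
#'
#' Population-average predictions `x' beta_hat` per outcome; for `newdata`,
#' the design is rebuilt with the fit's covariate scheme (scheme-based fits)
#' or its model terms (formula fits).
#'
#' @param object A `"bpml"` fit.
#' @param newdata Optional data frame.
#' @param ... Unused.
#' @return An `n x d` matrix of predicted means (mmHg).
#' @export
predict.bpml <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  X <- if (!is.null(object$scheme)) {
    build_design(newdata, object$scheme)
  } else if (!is.null(object$terms)) {
    stats::model.matrix(stats::delete.response(object$terms), newdata)
  } else {
    stop("fit carries neither a covariate scheme nor model terms")
  }
  out <- X %*% object$coefficients
  colnames(out) <- object$outcome_names
  out
}

#' Simulate outcomes from a fitted model
#'
#' Redraws household effects and woman residuals at the fitted parameters over
#' the fit's own design and household structure (a parametric-bootstrap draw).
#'
#' @param object A `"bpml"` fit.
#' @param nsim Number of replicate outcome sets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` outcome matrices (`N x d`).
#' @export
simulate.bpml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  d <- ncol(mu)
  hh <- if (is.null(object$household)) seq_len(object$n_women) else
    match(object$household, unique(object$household))
  H <- max(hh)
  lapply(seq_len(nsim), function(s) {
    h <- rmvn(H, object$sigma_h)
    e <- rmvn(object$n_women, object$sigma_e)
    out <- mu + h[hh, , drop = FALSE] + e
    colnames(out) <- object$outcome_names
    out
  })
}

#' QQ diagnostic plot of standardized marginal residuals
#'
#' One normal quantile-quantile panel per outcome, from [residual_qq_data()].
#'
#' @param x A `"bpml"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bpml <- function(x, ...) {
  qq <- residual_qq_data(x)
  d <- length(unique(qq$outcome))
  op <- graphics::par(mfrow = c(1, d))
  on.exit(graphics::par(op))
  for (nm in unique(qq$outcome)) {
    sub <- qq[qq$outcome == nm, ]
    graphics::plot(sub$theoretical, sub$observed,
                   xlab = "theoretical N(0,1) quantile",
                   ylab = "standardized residual",
                   main = toupper(nm), ...)
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' @param object The full-model `"bpml"` fit.
#' @param ... The nested fit (exactly one).
#' @return The [lr_test()] result.
#' @export
anova.bpml <- function(object, ...) {
  others <- list(...)
  others <- others[vapply(others, inherits, logical(1), "bpml")]
  if (length(others) != 1L) {
    stop("supply exactly two fits: anova(full, nested)")
  }
  lr_test(object, others[[1L]])
}
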