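#' Marginal covariance operator for one household
#'
#' For a household with `n_women` women and stacked outcomes ordered
#' outcome-major within woman, the marginal covariance of the `d*n` outcome
#' vector is `V = I_n (x) sigma_e + J_n (x) sigma_h` (exchangeable across
#' women). The operator exposes the log-determinant and a solve using the
#' mean/deviation decomposition
#' `V^{-1} = I (x) A^{-1} + (1/n) J (x) (B^{-1} - A^{-1})` with `A = sigma_e`
#' and `B = sigma_e + n sigma_h`, so the dense `dn x dn` matrix is never formed
#' on the fast path; `log det V = (n-1) log det A + log det B`.
#'
#' @param sigma_h Household-level covariance (PSD, `d x d`).
#' @param sigma_e Woman-level residual covariance (PD, `d x d`).
#' @param n_women Number of women in the household (>= 1).
#' @return An object of class `"household_covariance"`: a list with `logdet`,
#'   `solve(x)` (x a length-`d*n` vector or a matrix with `d*n` rows), and
#'   `dense()` (explicit matrix, for checking).
#' @examples
#' op <- household_marginal_covariance(diag(2), diag(2), 3)
#' op$logdet
#' @export
household_marginal_covariance <- function(sigma_h, sigma_e, n_women) {
  stopifnot(n_women >= 1)
  sigma_h <- as.matrix(sigma_h); sigma_e <- as.matrix(sigma_e)
  .check_cov(sigma_h, "sigma_h", positive_definite = FALSE)
  .check_cov(sigma_e, "sigma_e", positive_definite = TRUE)
  d <- nrow(sigma_e)
  n <- as.integer(n_women)
  A <- sigma_e
  B <- sigma_e + n * sigma_h
  Ai <- solve(A)
  Bi <- solve(B)
  Dn <- (Bi - Ai) / n
  structure(list(
    n_women = n, d = d, sigma_h = sigma_h, sigma_e = sigma_e,
    logdet = (n - 1) * log_det(A) + log_det(B),
    solve = function(x) {
      xm <- matrix(x, nrow = d * n)
      out <- apply(xm, 2, function(col) {
        W <- matrix(col, nrow = d)                 # d x n, one column per woman
        as.vector(Ai %*% W + as.vector(Dn %*% rowSums(W)))  # recycles by woman
      })
      if (is.null(dim(x))) as.vector(out) else matrix(out, nrow = d * n)
    },
    dense = function() {
      kronecker(diag(n), A) + kronecker(matrix(1, n, n), sigma_h)
    }
  ), class = "household_covariance")
}

# ---- sufficient statistics ---------------------------------------------------
# Everything the profiled likelihood needs, collapsed once per dataset:
# X'X, X'Y, Y'Y plus, for each distinct household size n, the cross-products of
# the per-household column sums of X and Y. All variance-component iterations
# then cost O(p^2 * #sizes), independent of N.
.suffstats <- function(X, Y, household) {
  N <- nrow(X)
  if (is.null(household)) household <- seq_len(N)
  hh <- match(household, unique(household))
  nj <- tabulate(hh)
  s <- rowsum(X, hh)
  tt <- rowsum(Y, hh)
  sizes <- sort(unique(nj))
  bysize <- lapply(sizes, function(n) which(nj == n))
  list(N = N, p = ncol(X), d = ncol(Y), H = length(nj),
       sizes = sizes, counts = vapply(bysize, length, integer(1)),
       Sxx = crossprod(X), Sxy = crossprod(X, Y), Syy = crossprod(Y),
       Sss = lapply(bysize, function(ix) crossprod(s[ix, , drop = FALSE])),
       Sst = lapply(bysize, function(ix) crossprod(s[ix, , drop = FALSE],
                                                   tt[ix, , drop = FALSE])),
       Stt = lapply(bysize, function(ix) crossprod(tt[ix, , drop = FALSE])),
       hh = hh, nj = nj)
}

# Exact marginal log-likelihood (and, when beta is NULL, the profiled GLS
# solution) from sufficient statistics. Blocks are stacked per outcome:
# vec(beta) = (beta_1; beta_2).
.vc_eval <- function(sigma_h, sigma_e, ss, beta = NULL) {
  d <- ss$d
  Ce <- solve(sigma_e)
  ld_e <- log_det(sigma_e)
  XtVX <- kronecker(Ce, ss$Sxx)
  M1 <- ss$Sxy %*% Ce
  yVy <- sum(Ce * ss$Syy)
  logdet <- 0
  for (k in seq_along(ss$sizes)) {
    n <- ss$sizes[k]
    Bn <- sigma_e + n * sigma_h
    Bi <- solve(Bn)
    Dn <- (Bi - Ce) / n
    XtVX <- XtVX + kronecker(Dn, ss$Sss[[k]])
    M1 <- M1 + ss$Sst[[k]] %*% Dn
    yVy <- yVy + sum(Dn * ss$Stt[[k]])
    logdet <- logdet + ss$counts[k] * ((n - 1) * ld_e + log_det(Bn))
  }
  XtVy <- as.vector(M1)
  if (is.null(beta)) {
    b <- solve(XtVX, XtVy)
    quad <- yVy - sum(b * XtVy)
  } else {
    b <- as.vector(beta)
    quad <- yVy - 2 * sum(b * XtVy) + sum(b * (XtVX %*% b))
  }
  ll <- -0.5 * (d * ss$N * log(2 * pi) + logdet + quad)
  list(ll = ll, beta = matrix(b, ss$p, d), XtVX = XtVX, XtVy = XtVy)
}

# ---- log-Cholesky parameterization ------------------------------------------
.theta_to_cov <- function(th) {
  if (length(th) == 1L) return(matrix(exp(2 * th), 1, 1))
  L <- matrix(0, 2, 2)
  L[1, 1] <- exp(th[1]); L[2, 1] <- th[2]; L[2, 2] <- exp(th[3])
  tcrossprod(L)
}

.cov_to_theta <- function(S, floor = 1e-6) {
  if (nrow(S) == 1L) return(log(sqrt(max(S[1, 1], floor))))
  S <- psd_clip(S, floor)
  L <- t(chol(S))
  c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
}

#' Joint marginal log-likelihood of the two-level model
#'
#' Exact Gaussian log-likelihood of the stacked outcomes under the
#' household-exchangeable covariance `V_j = I (x) sigma_e + J (x) sigma_h`,
#' at given fixed effects — no approximation.
#'
#' @param beta Fixed-effect matrix (`p x d`, one column per outcome) or the
#'   stacked vector `(beta_1; beta_2)`.
#' @param sigma_h,sigma_e Covariance components (`d x d`).
#' @param Y Outcome matrix (`N x d`).
#' @param X Design matrix (`N x p`).
#' @param household Household identifier vector of length `N`, or `NULL` for a
#'   single-level model (all households of size one).
#' @return The log-likelihood (numeric scalar).
#' @export
joint_loglik <- function(beta, sigma_h, sigma_e, Y, X, household = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  sigma_h <- as.matrix(sigma_h); sigma_e <- as.matrix(sigma_e)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same number of rows")
  d <- ncol(Y)
  if (!all(dim(sigma_e) == d) || !all(dim(sigma_h) == d)) {
    stop("covariance components must be d x d for d outcomes")
  }
  beta <- matrix(beta, ncol = d)
  if (nrow(beta) != ncol(X)) stop("beta not conformable with the design")
  ss <- .suffstats(X, Y, household)
  .vc_eval(sigma_h, sigma_e, ss, beta = beta)$ll
}

# starting values: per-outcome OLS residuals; sigma_e from the pooled
# within-household covariance, sigma_h from the household-mean ANOVA estimator,
# clipped to PSD.
.start_values <- function(X, Y, ss) {
  b0 <- solve(crossprod(X), crossprod(X, Y))
  E <- Y - X %*% b0
  d <- ncol(Y)
  tot <- crossprod(E) / nrow(E)
  multi <- which(ss$nj >= 2L)
  if (length(multi) >= 2L) {
    means <- rowsum(E, ss$hh) / ss$nj
    Ec <- E - means[ss$hh, , drop = FALSE]
    keep <- ss$hh %in% multi
    W <- crossprod(Ec[keep, , drop = FALSE]) / sum(ss$nj[multi] - 1L)
    nbar <- mean(ss$nj[multi])
    Bm <- crossprod(means[multi, , drop = FALSE]) / length(multi)
    sh0 <- psd_clip(Bm - W / nbar, 1e-3)
    se0 <- psd_clip(W, 1e-3)
  } else {
    sh0 <- 0.1 * tot
    se0 <- 0.9 * tot
  }
  list(sigma_h = sh0, sigma_e = se0)
}

#' Low-level fitter for the joint multilevel model
#'
#' Maximizes the exact marginal likelihood over `(beta, sigma_h, sigma_e)`.
#' Fixed effects are profiled out by generalized least squares at each
#' variance-component iterate; the covariance components are optimized in a
#' log-Cholesky parameterization with L-BFGS-B, the household-level Cholesky
#' diagonal floored at 1e-4 (variance floor 1e-8) so a zero household variance
#' is reachable as a boundary. The fixed-effect covariance is the inverse GLS
#' information at the optimum.
#'
#' Three model variants arise from the inputs: two outcome columns with a
#' household id give the bivariate multilevel model; one outcome column the
#' univariate multilevel model; `household = NULL` with two outcomes the
#' single-level multivariate model (`sigma_h` identically zero, fitted in
#' closed form).
#'
#' @param Y Outcome matrix (`N x d`, `d` in 1:2), columns named.
#' @param X Design matrix (`N x p`) with an intercept column; must be full
#'   column rank.
#' @param household Household id vector of length `N`, or `NULL`.
#' @param control Optional list: `maxit` (default 500), `factr` (default 1e3,
#'   the L-BFGS-B relative-reduction tolerance in units of machine epsilon),
#'   `start` (list with `sigma_h`, `sigma_e`).
#' @return An object of class `"bpml"`; see [summary.bpml()].
#' @seealso [bpml()] for the formula interface, [fit_bivariate_multilevel()]
#'   and friends for the scheme-based wrappers.
#' @export
bpml_fit <- function(Y, X, household = NULL, control = list()) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X)) stop("Y and X must have the same number of rows")
  if (!all(is.finite(Y)) || !all(is.finite(X))) stop("non-finite values in Y or X")
  d <- ncol(Y); p <- ncol(X); N <- nrow(Y)
  if (!d %in% 1:2) stop("Y must have one or two outcome columns")
  if (is.null(colnames(Y))) colnames(Y) <- c("sbp", "dbp")[seq_len(d)]
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  if (!is.null(household) && length(household) != N) {
    stop("household id length must match the number of rows")
  }

  model_tag <- if (is.null(household)) {
    if (d == 2L) "single_level_multivariate" else "single_level_univariate"
  } else if (d == 2L) "bivariate_multilevel" else "univariate_multilevel"

  ss <- .suffstats(X, Y, household)
  n_multi <- sum(ss$nj >= 2L)
  if (!is.null(household) && ss$H < 2L) stop("need at least 2 households")

  ctrl <- list(maxit = 500L, factr = 1e3)
  ctrl[names(control)] <- control
  diag_floor <- log(1e-4)

  if (is.null(household)) {
    # sigma_h == 0: GLS reduces to per-outcome OLS and sigma_e has the
    # closed-form ML solution E'E / N.
    b <- solve(crossprod(X), crossprod(X, Y))
    E <- Y - X %*% b
    se <- crossprod(E) / N
    sh <- matrix(0, d, d)
    ev <- .vc_eval(sh, se, ss)
    n_params <- d * p + d * (d + 1L) / 2L
    converged <- TRUE; boundary <- FALSE; counts <- c(0L, 0L)
  } else {
    st <- if (!is.null(ctrl$start)) ctrl$start else .start_values(X, Y, ss)
    nth <- if (d == 2L) 3L else 1L
    th0 <- c(.cov_to_theta(st$sigma_h), .cov_to_theta(st$sigma_e))
    lower <- rep(-Inf, 2L * nth)
    # floor only the household-level log-Cholesky diagonal
    lower[if (d == 2L) c(1L, 3L) else 1L] <- diag_floor
    th0 <- pmax(th0, lower)
    split_th <- function(th) list(sh = .theta_to_cov(th[seq_len(nth)]),
                                  se = .theta_to_cov(th[nth + seq_len(nth)]))
    negll <- function(th) {
      pa <- split_th(th)
      out <- tryCatch(.vc_eval(pa$sh, pa$se, ss)$ll,
                      error = function(e) -Inf)
      if (!is.finite(out)) return(1e10)
      -out
    }
    opt <- stats::optim(th0, negll, method = "L-BFGS-B", lower = lower,
                        control = list(maxit = ctrl$maxit, factr = ctrl$factr,
                                       ndeps = rep(1e-5, length(th0))))
    pa <- split_th(opt$par)
    sh <- pa$sh; se <- pa$se
    ev <- .vc_eval(sh, se, ss)
    b <- ev$beta
    n_params <- d * p + d * (d + 1L)  # two covariance blocks
    converged <- opt$convergence == 0L
    hdiag <- opt$par[if (d == 2L) c(1L, 3L) else 1L]
    boundary <- any(hdiag <= diag_floor + 1e-6)
    counts <- opt$counts
  }

  dimnames(sh) <- dimnames(se) <- list(colnames(Y), colnames(Y))
  b <- matrix(b, p, d, dimnames = list(colnames(X), colnames(Y)))
  vc <- solve(ev$XtVX)
  vc_names <- as.vector(outer(colnames(X), colnames(Y),
                              function(cf, oc) paste(oc, cf, sep = ":")))
  dimnames(vc) <- list(vc_names, vc_names)

  structure(list(
    coefficients = b,
    sigma_h = sh, sigma_e = se,
    vcov = vc,
    loglik = ev$ll,
    n_params = n_params,
    n_women = N, n_households = ss$H, n_multiwoman = n_multi,
    converged = converged, boundary = boundary,
    optim_counts = counts,
    model_tag = model_tag,
    outcome_names = colnames(Y),
    X = X, Y = Y, household = household,
    call = match.call()
  ), class = "bpml")
}

#' Joint multilevel model for blood pressure outcomes (formula interface)
#'
#' Fits, by exact maximum likelihood, a linear mixed model with a random
#' household intercept per outcome: for woman `i` in household `j`,
#' `y_kij = x_ij' beta_k + h_kj + e_kij`, with `(h_1j, h_2j) ~ N(0, sigma_h)`
#' and `(e_1ij, e_2ij) ~ N(0, sigma_e)`. A two-column response (via `cbind`)
#' gives the bivariate model; a single response the univariate one;
#' `household = NULL` the single-level model with `sigma_h = 0`.
#'
#' @param formula Model formula, e.g. `cbind(sbp, dbp) ~ age_group + obesity`.
#' @param data Data frame containing the variables.
#' @param household Household identifier: a one-sided formula (`~household_id`),
#'   a column name, a vector of ids, or `NULL` for a single-level fit.
#' @param ... Passed to [bpml_fit()] (e.g. `control`).
#' @return An object of class `"bpml"`.
#' @examples
#' dat <- simulate_population(default_sim_config(n_households = 300), seed = 7)
#' fit <- bpml(cbind(sbp, dbp) ~ age_group + obesity, dat, ~household_id)
#' coef(fit)
#' @export
bpml <- function(formula, data, household = NULL, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  hh <- .resolve_household(household, data, nrow(data))
  keep <- stats::complete.cases(mf)
  if (!is.null(hh)) keep <- keep & !is.na(hh)
  if (!all(keep)) {
    message(sum(!keep), " incomplete record(s) excluded (complete-case analysis)")
    mf <- mf[keep, , drop = FALSE]
    hh <- hh[keep]
  }
  Y <- stats::model.response(mf)
  if (is.null(dim(Y))) {
    Y <- matrix(Y, ncol = 1,
                dimnames = list(NULL, deparse(formula[[2]])))
  }
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- bpml_fit(Y, X, hh, ...)
  fit$call <- match.call()
  fit$terms <- attr(mf, "terms")
  fit
}

.resolve_household <- function(household, data, n) {
  if (is.null(household)) return(NULL)
  if (inherits(household, "formula")) {
    v <- all.vars(household)
    if (length(v) != 1L || !v %in% names(data)) {
      stop("household formula must name one column of 'data'")
    }
    household <- data[[v]]
  } else if (is.character(household) && length(household) == 1L &&
             household %in% names(data)) {
    household <- data[[household]]
  }
  if (length(household) != n) {
    stop("household ids must match the rows of 'data'")
  }
  household
}

#' Scheme-based fits of the study's model variants
#'
#' Convenience wrappers around [bpml_fit()] using the full design of
#' [build_design()] (intercept + 15 indicators with the default scheme) on a
#' woman-level table as produced by [simulate_population()]. Incomplete
#' records are excluded with a message.
#'
#' @param data Woman-level data frame with `sbp`, `dbp`, `household_id` and
#'   the scheme's covariate columns.
#' @param scheme A [covariate_scheme()].
#' @param outcome For the univariate fit, which outcome to model.
#' @param ... Passed to [bpml_fit()].
#' @return A `"bpml"` fit.
#' @export
fit_bivariate_multilevel <- function(data, scheme = covariate_scheme(), ...) {
  data <- drop_incomplete(data, scheme)
  X <- build_design(data, scheme)
  fit <- bpml_fit(cbind(sbp = data$sbp, dbp = data$dbp), X,
                  data$household_id, ...)
  fit$scheme <- scheme
  fit$call <- match.call()
  fit
}

#' @rdname fit_bivariate_multilevel
#' @export
fit_univariate_multilevel <- function(data, outcome = c("sbp", "dbp"),
                                      scheme = covariate_scheme(), ...) {
  outcome <- match.arg(outcome)
  data <- drop_incomplete(data, scheme)
  X <- build_design(data, scheme)
  Y <- matrix(data[[outcome]], ncol = 1, dimnames = list(NULL, outcome))
  fit <- bpml_fit(Y, X, data$household_id, ...)
  fit$scheme <- scheme
  fit$call <- match.call()
  fit
}

#' @rdname fit_bivariate_multilevel
#' @export
fit_single_level_multivariate <- function(data, scheme = covariate_scheme(),
                                          ...) {
  data <- drop_incomplete(data, scheme)
  X <- build_design(data, scheme)
  fit <- bpml_fit(cbind(sbp = data$sbp, dbp = data$dbp), X,
                  household = NULL, ...)
  fit$scheme <- scheme
  fit$call <- match.call()
  fit
}
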