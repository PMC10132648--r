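# shared internal helpers

# round half away from zero (Table-style reporting; base round() is banker's)
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  # tiny eps guards against values like 71.4999999 from decimal representation
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# draw n rows from N(0, sigma); eigen square root so PSD (incl. singular) is fine
rmvn <- function(n, sigma) {
  d <- nrow(sigma)
  ev <- eigen(sigma, symmetric = TRUE)
  rt <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
  matrix(stats::rnorm(n * d), n, d) %*% rt
}

.check_cov <- function(m, name, positive_definite = FALSE, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  }
  if (max(abs(m - t(m))) > tol * (1 + max(abs(m)))) {
    stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  lim <- if (positive_definite) tol * max(abs(ev), 1) else -tol * max(abs(ev), 1)
  if (min(ev) < lim || (positive_definite && min(ev) <= 0)) {
    stop(sprintf("'%s' must be positive %sdefinite", name,
                 if (positive_definite) "" else "semi-"), call. = FALSE)
  }
  invisible(m)
}

# clip a symmetric matrix to PSD (used for starting values only)
psd_clip <- function(m, floor = 0) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ev$vectors %*% (pmax(ev$values, floor) * t(ev$vectors))
}

log_det <- function(m) as.numeric(determinant(m, logarithm = TRUE)$modulus)
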