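#' Gaussian component density with additive error covariance
#'
#' Density of the d-variate normal `N(mu, sigma + lam)` at `y`: the marginal
#' law of an observation from a component with mean `mu` and covariance
#' `sigma` measured with independent Gaussian error of covariance `lam`.
#' Covariances add, so this equals the error-free density evaluated with
#' covariance `sigma + lam`.
#'
#' All densities are computed in log space through a Cholesky factorization of
#' `sigma + lam`; the linear-scale value is just `exp()` of that. A Cholesky
#' failure or a reciprocal condition number below 1e-12 raises an error rather
#' than silently regularizing.
#'
#' @param y Numeric d-vector (or `n x d` matrix of rows to evaluate at once).
#' @param mu Component mean (d-vector).
#' @param sigma Component covariance (`d x d` PSD).
#' @param lam Error covariance (`d x d` PSD); `sigma + lam` must be positive
#'   definite.
#' @param log Return the log density?
#' @return Numeric scalar (or vector, one per row of `y`).
#' @export
component_density <- function(y, mu, sigma, lam, log = FALSE) {
  mu <- as.numeric(mu)
  d <- length(mu)
  y <- if (d == 1L && !is.matrix(y)) matrix(as.numeric(y), ncol = 1) else rbind(y)
  if (ncol(y) != d) stop("`y` and `mu` dimension mismatch")
  A <- .check_psd(as.matrix(sigma) + as.matrix(lam), what = "total covariance")
  ld <- .logdens_rows(y, mu, A)
  if (log) drop(ld) else drop(exp(ld))
}

#' Mixture density with a shared error covariance
#'
#' Evaluates `sum_k tau_k * N(y; mu_k, Sigma_k + lam)`, the marginal mixture
#' density of an observation whose error covariance is `lam`. With a single
#' component this reduces to [component_density()].
#'
#' @inheritParams component_density
#' @param params A [mixture_params()] object.
#' @return Numeric scalar (or vector for a matrix `y`).
#' @export
mixture_density <- function(y, lam, params, log = FALSE) {
  stopifnot(inherits(params, "mixture_params"))
  y <- if (params$d == 1L && !is.matrix(y)) matrix(as.numeric(y), ncol = 1) else rbind(y)
  if (ncol(y) != params$d) stop("`y` dimension does not match `params`")
  L <- matrix(-Inf, nrow(y), params$G)
  for (k in seq_len(params$G)) {
    if (params$weights[k] == 0) next
    A <- .check_psd(params$covs[, , k] + as.matrix(lam), what = "total covariance")
    L[, k] <- log(params$weights[k]) + .logdens_rows(y, params$means[k, ], A)
  }
  out <- .row_logsumexp(L)
  if (log) drop(out) else drop(exp(out))
}

#' Observed-data log-likelihood
#'
#' The log-likelihood of a fitted or candidate mixture over a dataset with
#' per-observation error covariances:
#' `sum_i log sum_k tau_k N(y_i; mu_k, Sigma_k + Lambda_i)`, computed with
#' log-sum-exp stabilization.
#'
#' @param data A wide data frame or an [error_dataset()].
#' @param params A [mixture_params()] object.
#' @return A single numeric value.
#' @export
observed_loglik <- function(data, params) {
  data <- as_error_dataset(data)
  L <- .loglik_matrix(data, params)
  ll <- .row_logsumexp(L)
  if (any(!is.finite(ll))) {
    stop("non-finite log-likelihood contribution at observation(s): ",
         paste(utils::head(which(!is.finite(ll)), 5), collapse = ", "))
  }
  sum(ll)
}

#' Complete-data log-likelihood
#'
#' `sum_i sum_k z_ik * log(tau_k * N(y_i; mu_k, Sigma_k + Lambda_i))` for a
#' soft or one-hot membership matrix `z`. Terms with `z_ik = 0` contribute
#' zero; a positive `z_ik` paired with `tau_k = 0` is an error (the complete
#' likelihood would be -Inf).
#'
#' @inheritParams observed_loglik
#' @param z `n x G` membership matrix with rows summing to 1.
#' @return A single numeric value.
#' @export
complete_loglik <- function(data, params, z) {
  data <- as_error_dataset(data)
  z <- .check_membership(z, n = nrow(data$points), G = params$G)
  if (any(z[, params$weights == 0, drop = FALSE] > 0)) {
    stop("membership mass assigned to a component with zero weight")
  }
  L <- .loglik_matrix(data, params)
  terms <- z * L
  terms[z == 0] <- 0
  if (any(!is.finite(terms))) stop("non-finite complete-data log-likelihood term")
  sum(terms)
}

# ---- internal density machinery ----------------------------------------

# log N(y; mu, A) for all rows of Y, via one Cholesky of A
.logdens_rows <- function(Y, mu, A) {
  d <- length(mu)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R) || .rcond_from_chol(R) < 1e-12) {
    stop("singular total covariance (condition number beyond 1e12); ",
         "check the error covariances of the offending observations")
  }
  # quadratic form via triangular solve: z = R^-T (y - mu)
  ctr <- t(Y) - mu
  zq <- backsolve(R, ctr, transpose = TRUE)
  quad <- colSums(zq^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) + quad)
}

# cheap reciprocal condition estimate from a Cholesky factor
.rcond_from_chol <- function(R) {
  dg <- diag(R)^2
  min(dg) / max(dg)
}

.row_logsumexp <- function(L) {
  m <- apply(L, 1L, max)
  finite <- is.finite(m)
  out <- m
  out[finite] <- m[finite] + log(rowSums(exp(L[finite, , drop = FALSE] - m[finite])))
  out
}

# n x G matrix of log(tau_k) + log g_k(y_i); vectorized over groups of
# observations sharing an error covariance, with a fully vectorized
# closed-form path for bivariate data (the dominant use case)
.loglik_matrix <- function(data, params) {
  n <- nrow(data$points)
  G <- params$G
  if (ncol(data$points) == 2L) return(.loglik_matrix2(data, params))
  L <- matrix(-Inf, n, G)
  ngrp <- dim(data$group_covs)[3]
  for (g in seq_len(ngrp)) {
    idx <- which(data$group == g)
    lam <- data$group_covs[, , g]
    Y <- data$points[idx, , drop = FALSE]
    for (k in seq_len(G)) {
      if (params$weights[k] == 0) next
      A <- params$covs[, , k] + lam
      ld <- tryCatch(.logdens_rows(Y, params$means[k, ], A),
                     error = function(e) {
                       stop("component ", k, ", observation(s) ",
                            paste(utils::head(idx, 3), collapse = ","), ": ",
                            conditionMessage(e))
                     })
      L[idx, k] <- log(params$weights[k]) + ld
    }
  }
  L
}

# explicit 2x2 algebra, vectorized over observations
.loglik_matrix2 <- function(data, params) {
  n <- nrow(data$points)
  G <- params$G
  L <- matrix(-Inf, n, G)
  l11 <- data$covs[1, 1, ]
  l12 <- data$covs[1, 2, ]
  l22 <- data$covs[2, 2, ]
  y1 <- data$points[, 1]
  y2 <- data$points[, 2]
  for (k in seq_len(G)) {
    if (params$weights[k] == 0) next
    s <- params$covs[, , k]
    a11 <- s[1, 1] + l11
    a12 <- s[1, 2] + l12
    a22 <- s[2, 2] + l22
    det <- a11 * a22 - a12^2
    tr <- a11 + a22
    disc <- sqrt(pmax((a11 - a22)^2 + 4 * a12^2, 0))
    lmin <- (tr - disc) / 2
    lmax <- (tr + disc) / 2
    bad <- det <= 0 | lmin / lmax < 1e-12
    if (any(bad)) {
      stop("singular total covariance (condition number beyond 1e12) for component ",
           k, " at observation(s): ",
           paste(utils::head(which(bad), 5), collapse = ", "))
    }
    r1 <- y1 - params$means[k, 1]
    r2 <- y2 - params$means[k, 2]
    quad <- (a22 * r1^2 - 2 * a12 * r1 * r2 + a11 * r2^2) / det
    L[, k] <- log(params$weights[k]) -
      (log(2 * pi) + 0.5 * log(det) + 0.5 * quad)
  }
  L
}
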