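#' E step: posterior membership probabilities
#'
#' Computes `z_ik = tau_k g_k(y_i) / sum_j tau_j g_j(y_i)` where `g_k` is the
#' Gaussian component density evaluated with that observation's error
#' covariance added, using log-densities and log-sum-exp so near-underflow
#' observations stay well defined.
#'
#' @param data A wide data frame or [error_dataset()].
#' @param params A [mixture_params()] object.
#' @return `n x G` matrix of membership probabilities; rows sum to 1.
#' @export
e_step <- function(data, params) {
  data <- as_error_dataset(data)
  L <- .loglik_matrix(data, params)
  lse <- .row_logsumexp(L)
  if (any(!is.finite(lse))) {
    stop("zero mixture density at observation(s): ",
         paste(utils::head(which(!is.finite(lse)), 5), collapse = ", "))
  }
  exp(L - lse)
}

#' M step for the mixing proportions
#'
#' Closed form: `tau_k = mean(z[, k])`.
#'
#' @param z `n x G` membership matrix.
#' @return Length-G simplex vector.
#' @export
m_step_tau <- function(z) {
  z <- .check_membership(z)
  colMeans(z)
}

#' M step for a component mean at fixed component covariance
#'
#' Solves the mean estimating equation
#' `sum_i z_ik (Sigma + Lambda_i)^-1 (y_i - mu) = 0`, i.e. the
#' precision-weighted mean
#' `mu = [sum_i z_ik P_i]^-1 sum_i z_ik P_i y_i` with `P_i = (Sigma+Lambda_i)^-1`,
#' computed as a d-dimensional linear solve.
#'
#' @param data A wide data frame or [error_dataset()].
#' @param z_col Length-n vector of membership weights for this component.
#' @param sigma Component covariance (`d x d`, with `sigma + Lambda_i`
#'   positive definite for every observation).
#' @return The component mean (d-vector).
#' @export
m_step_mu <- function(data, z_col, sigma) {
  data <- as_error_dataset(data)
  ss <- .group_suffstats(data, z_col)
  .mu_hat(as.matrix(sigma), ss, data$group_covs)
}

#' M step for a component covariance (profiled objective)
#'
#' Maximizes the cluster's contribution to the complete-data log-likelihood
#' profiled over the mean: `Q(Sigma) = sum_i z_ik log N(y_i; mu(Sigma),
#' Sigma + Lambda_i)` where `mu(Sigma)` is the precision-weighted mean of
#' [m_step_mu()]. `Sigma` is parameterized through a Cholesky factor with
#' log-transformed diagonal so every optimizer iterate is positive definite;
#' L-BFGS-B does the maximization with the analytic profile gradient (the
#' covariance estimating-equation residual mapped through the
#' parameterization).
#'
#' @inheritParams m_step_mu
#' @param sigma_init Positive definite starting value.
#' @param gtol Gradient tolerance passed to the optimizer (`pgtol`).
#' @param maxit Iteration cap for the optimizer.
#' @return The optimized covariance, with attributes `converged` (logical) and
#'   `grad_norm` (Frobenius norm of the estimating-equation residual at the
#'   optimum). Warns when the optimizer stops before meeting `gtol`.
#' @export
m_step_sigma <- function(data, z_col, sigma_init, gtol = 1e-6, maxit = 200) {
  data <- as_error_dataset(data)
  ss <- .group_suffstats(data, z_col)
  .opt_sigma(as.matrix(sigma_init), ss, data$group_covs, gtol = gtol, maxit = maxit)
}

#' Fit the error-aware Gaussian mixture by EM
#'
#' Alternates M and E steps starting from a one-hot initialization (the first
#' move is an M step). The M step has a closed form for the weights, while
#' each component covariance is optimized numerically with the mean profiled
#' out; iteration stops when the observed-data log-likelihood increment falls
#' below `tol` or after `max_iter` EM cycles. A decrease of the observed
#' log-likelihood beyond numerical noise (1e-6) is treated as an internal
#' error, because EM ascent is guaranteed when each M step succeeds.
#'
#' @param data A wide data frame (see [as_error_dataset()] for the layout) or
#'   an [error_dataset()].
#' @param G Number of mixture components.
#' @param init Initialization strategy: `"hierarchical"` (model-based greedy
#'   agglomeration, the default), `"kmeans"`, `"labels"` (supply `labels`), or
#'   `"params"` (supply `params`; one E step then hardened). See [em_init()].
#' @param labels Optional hard initial labels (used when `init = "labels"`).
#' @param params Optional [mixture_params()] starting values (when
#'   `init = "params"`).
#' @param tol Convergence threshold on the absolute log-likelihood increment.
#' @param max_iter Maximum number of EM cycles.
#' @param opt_gtol,opt_maxit Inner optimizer controls for [m_step_sigma()].
#' @param seed Optional RNG seed (only the `"kmeans"` strategy draws random
#'   numbers).
#' @return An object of class `errmix_fit` with elements `params`
#'   ([mixture_params()]), `z` (membership matrix), `hard_labels` (argmax of
#'   `z`, ties toward the lowest index), `uncertainty` (`1 - max_k z_ik`),
#'   `loglik`, `loglik_trace`, `converged`, `n_iter`, and the ingested
#'   `data`. Supports [tidy()], [glance()], [augment()] and
#'   [ggplot2::autoplot()].
#' @examples
#' sim <- sim_bernoulli_errors(n = 120, eta = 0.5, seed = 1)
#' fit <- errmix_fit(sim$data, G = 2, init = "labels", labels = sim$truth$label)
#' glance(fit)
#' @export
errmix_fit <- function(data, G = 2, init = c("hierarchical", "kmeans", "labels", "params"),
                       labels = NULL, params = NULL, tol = 1e-6, max_iter = 500,
                       opt_gtol = 1e-6, opt_maxit = 200, seed = NULL) {
  data <- as_error_dataset(data)
  init <- match.arg(init)
  z0 <- em_init(data, G, method = init, labels = labels, params = params, seed = seed)
  fit <- .em_run(data, G, z0, tol = tol, max_iter = max_iter,
                 opt_gtol = opt_gtol, opt_maxit = opt_maxit, closed_form = FALSE)
  fit$method <- "errmix"
  fit$init <- init
  fit
}

#' @export
print.errmix_fit <- function(x, ...) {
  cat(sprintf("<%s fit: G = %d, n = %d, d = %d>\n",
              if (identical(x$method, "gmm")) "error-free GMM" else "error-aware mixture",
              x$params$G, nrow(x$z), x$params$d))
  cat(sprintf("log-likelihood %.6f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter, if (x$converged) "converged" else "not converged"))
  cat("cluster sizes:", paste(tabulate(x$hard_labels, x$params$G), collapse = ", "), "\n")
  invisible(x)
}

#' Estimating-equation residuals of a fit
#'
#' At a stationary point the mean equation
#' `sum_i z_ik (Sigma_k+Lambda_i)^-1 (y_i - mu_k) = 0` and the covariance
#' equation
#' `(1/2) sum_i z_ik [(Sigma_k+Lambda_i)^-1 S_ik (Sigma_k+Lambda_i)^-1 -
#' (Sigma_k+Lambda_i)^-1] = 0` (with `S_ik` the outer product of the residual)
#' hold. This returns their norms per component — a direct check on M-step
#' optimality at the converged parameters.
#'
#' @param fit An `errmix_fit`.
#' @return A tibble with columns `component`, `mu_residual` (Euclidean norm)
#'   and `sigma_residual` (Frobenius norm).
#' @export
estimating_residuals <- function(fit) {
  stopifnot(inherits(fit, "errmix_fit"))
  data <- fit$data
  params <- fit$params
  out <- vector("list", params$G)
  for (k in seq_len(params$G)) {
    ss <- .group_suffstats(data, fit$z[, k])
    sig <- params$covs[, , k]
    mu <- params$means[k, ]
    r_mu <- numeric(params$d)
    r_sig <- matrix(0, params$d, params$d)
    for (g in seq_len(dim(data$group_covs)[3])) {
      P <- chol2inv(chol(sig + data$group_covs[, , g]))
      bg <- ss$B[g, ]
      Mg <- ss$C[, , g] - tcrossprod(bg, mu) - tcrossprod(mu, bg) +
        ss$W[g] * tcrossprod(mu)
      r_mu <- r_mu + P %*% (bg - ss$W[g] * mu)
      r_sig <- r_sig + 0.5 * (P %*% Mg %*% P - ss$W[g] * P)
    }
    out[[k]] <- tibble::tibble(component = k,
                               mu_residual = sqrt(sum(r_mu^2)),
                               sigma_residual = sqrt(sum(r_sig^2)))
  }
  dplyr::bind_rows(out)
}

# ---- internal EM machinery ---------------------------------------------

# per-error-covariance-group sufficient statistics for one component's weights:
# W_g = sum z_i, B_g = sum z_i y_i, C_g = sum z_i y_i y_i^T
.group_suffstats <- function(data, z_col) {
  z_col <- as.numeric(z_col)
  n <- nrow(data$points)
  if (length(z_col) != n) stop("`z_col` must have one weight per observation")
  d <- ncol(data$points)
  ngrp <- dim(data$group_covs)[3]
  grp <- factor(data$group, levels = seq_len(ngrp))
  W <- as.numeric(rowsum(z_col, grp))
  B <- rowsum(z_col * data$points, grp)
  C <- array(0, dim = c(d, d, ngrp))
  for (j in seq_len(d)) for (k in j:d) {
    v <- as.numeric(rowsum(z_col * data$points[, j] * data$points[, k], grp))
    C[j, k, ] <- v
    C[k, j, ] <- v
  }
  list(W = W, B = as.matrix(B), C = C)
}

# precision-weighted mean for a component at covariance sigma
.mu_hat <- function(sigma, ss, group_covs) {
  d <- nrow(sigma)
  if (sum(ss$W) < 1e-8) stop("empty cluster: total membership weight is ~0")
  if (d == 2L) return(.profile_Q2(sigma, ss, group_covs, mu_only = TRUE))
  lhs <- matrix(0, d, d)
  rhs <- numeric(d)
  for (g in seq_along(ss$W)) {
    if (ss$W[g] == 0) next
    P <- chol2inv(chol(sigma + group_covs[, , g]))
    lhs <- lhs + ss$W[g] * P
    rhs <- rhs + P %*% ss$B[g, ]
  }
  drop(solve(lhs, rhs))
}

# profiled objective Q(Sigma) and its analytic gradient in Sigma space.
# By the envelope theorem the gradient at the profiled mean equals the
# covariance estimating-equation residual evaluated at mu_hat(Sigma).
.profile_Q <- function(sigma, ss, group_covs) {
  d <- nrow(sigma)
  if (d == 2L) return(.profile_Q2(sigma, ss, group_covs))
  mu <- .mu_hat(sigma, ss, group_covs)
  Q <- 0
  Gm <- matrix(0, d, d)
  for (g in seq_along(ss$W)) {
    if (ss$W[g] == 0) next
    A <- sigma + group_covs[, , g]
    R <- chol(A)
    P <- chol2inv(R)
    bg <- ss$B[g, ]
    Mg <- ss$C[, , g] - tcrossprod(bg, mu) - tcrossprod(mu, bg) + ss$W[g] * tcrossprod(mu)
    Q <- Q - 0.5 * ss$W[g] * (d * log(2 * pi) + 2 * sum(log(diag(R)))) -
      0.5 * sum(P * Mg)
    Gm <- Gm + 0.5 * (P %*% Mg %*% P - ss$W[g] * P)
  }
  list(Q = Q, grad = Gm, mu = mu)
}

# explicit 2x2 algebra vectorized over error-covariance groups
.profile_Q2 <- function(sigma, ss, group_covs, mu_only = FALSE) {
  s11 <- sigma[1, 1]; s12 <- sigma[1, 2]; s22 <- sigma[2, 2]
  a11 <- s11 + group_covs[1, 1, ]
  a12 <- s12 + group_covs[1, 2, ]
  a22 <- s22 + group_covs[2, 2, ]
  det <- a11 * a22 - a12^2
  if (any(det <= 0)) stop("total covariance not positive definite")
  p11 <- a22 / det; p12 <- -a12 / det; p22 <- a11 / det
  W <- ss$W
  b1 <- ss$B[, 1]; b2 <- ss$B[, 2]
  lhs11 <- sum(W * p11); lhs12 <- sum(W * p12); lhs22 <- sum(W * p22)
  rhs1 <- sum(p11 * b1 + p12 * b2)
  rhs2 <- sum(p12 * b1 + p22 * b2)
  dl <- lhs11 * lhs22 - lhs12^2
  if (abs(dl) < 1e-300) stop("empty cluster: total membership weight is ~0")
  mu1 <- (lhs22 * rhs1 - lhs12 * rhs2) / dl
  mu2 <- (lhs11 * rhs2 - lhs12 * rhs1) / dl
  if (mu_only) return(c(mu1, mu2))
  c11 <- ss$C[1, 1, ]; c12 <- ss$C[1, 2, ]; c22 <- ss$C[2, 2, ]
  m11 <- c11 - 2 * b1 * mu1 + W * mu1^2
  m12 <- c12 - b1 * mu2 - b2 * mu1 + W * mu1 * mu2
  m22 <- c22 - 2 * b2 * mu2 + W * mu2^2
  Q <- sum(-0.5 * W * (2 * log(2 * pi) + log(det)) -
             0.5 * (p11 * m11 + 2 * p12 * m12 + p22 * m22))
  # P M P, exploiting symmetry
  t11 <- p11 * m11 + p12 * m12
  t12 <- p11 * m12 + p12 * m22
  t21 <- p12 * m11 + p22 * m12
  t22 <- p12 * m12 + p22 * m22
  u11 <- t11 * p11 + t12 * p12
  u12 <- t11 * p12 + t12 * p22
  u21 <- t21 * p11 + t22 * p12
  u22 <- t21 * p12 + t22 * p22
  g11 <- 0.5 * sum(u11 - W * p11)
  g12 <- 0.5 * sum((u12 + u21) / 2 - W * p12)
  g22 <- 0.5 * sum(u22 - W * p22)
  list(Q = Q, grad = matrix(c(g11, g12, g12, g22), 2, 2), mu = c(mu1, mu2))
}

.theta_to_L <- function(theta, d) {
  L <- matrix(0, d, d)
  diag(L) <- exp(theta[seq_len(d)])
  if (d > 1) L[lower.tri(L)] <- theta[-seq_len(d)]
  L
}

.sigma_to_theta <- function(sigma) {
  L <- t(chol(sigma))
  c(log(diag(L)), L[lower.tri(L)])
}

# L-BFGS-B on the Cholesky parameterization (log diagonal) of Sigma
.opt_sigma <- function(sigma_init, ss, group_covs, gtol = 1e-6, maxit = 200) {
  d <- nrow(sigma_init)
  theta0 <- tryCatch(.sigma_to_theta(sigma_init),
                     error = function(e) stop("`sigma_init` must be positive definite"))
  f0 <- tryCatch(.profile_Q(tcrossprod(.theta_to_L(theta0, d)), ss, group_covs)$Q,
                 error = function(e) NaN)
  if (!is.finite(f0)) stop("profiled objective is non-finite at `sigma_init`")
  negQ <- function(theta) {
    L <- .theta_to_L(theta, d)
    q <- tryCatch(.profile_Q(tcrossprod(L), ss, group_covs)$Q,
                  error = function(e) -Inf)
    if (!is.finite(q)) return(1e10)
    -q
  }
  negG <- function(theta) {
    L <- .theta_to_L(theta, d)
    pr <- tryCatch(.profile_Q(tcrossprod(L), ss, group_covs),
                   error = function(e) NULL)
    if (is.null(pr)) return(rep(0, length(theta)))
    GL <- pr$grad %*% L
    g <- numeric(length(theta))
    g[seq_len(d)] <- 2 * diag(GL) * diag(L)
    if (d > 1) g[-seq_len(d)] <- 2 * GL[lower.tri(GL)]
    -g
  }
  opt <- stats::optim(theta0, fn = negQ, gr = negG, method = "L-BFGS-B",
                      lower = c(rep(-30, d), rep(-1e6, length(theta0) - d)),
                      upper = c(rep(30, d), rep(1e6, length(theta0) - d)),
                      control = list(maxit = maxit, pgtol = gtol, factr = 1e4))
  L <- .theta_to_L(opt$par, d)
  sigma <- tcrossprod(L)
  sigma <- (sigma + t(sigma)) / 2
  pr <- .profile_Q(sigma, ss, group_covs)
  gnorm <- sqrt(sum(pr$grad^2))
  converged <- opt$convergence == 0
  if (!converged) {
    warning("covariance optimizer stopped early (code ", opt$convergence,
            "); returning best iterate (residual norm ", format(gnorm), ")")
  }
  attr(sigma, "converged") <- converged
  attr(sigma, "grad_norm") <- gnorm
  attr(sigma, "mu") <- pr$mu
  sigma
}

# moment starting value: weighted sample covariance minus average error
# covariance, eigenvalue-floored to positive definiteness
.sigma_moment_init <- function(ss, group_covs) {
  d <- dim(group_covs)[1]
  W <- sum(ss$W)
  btot <- colSums(ss$B)
  mu <- btot / W
  Ctot <- apply(ss$C, c(1, 2), sum)
  Semp <- Ctot / W - tcrossprod(mu)
  lbar <- matrix(0, d, d)
  for (g in seq_along(ss$W)) lbar <- lbar + ss$W[g] * group_covs[, , g]
  S0 <- Semp - lbar / W
  S0 <- (S0 + t(S0)) / 2
  ev <- eigen(S0, symmetric = TRUE)
  floorv <- max(1e-6 * max(diag(Semp)), 1e-8)
  ev$values <- pmax(ev$values, floorv)
  ev$vectors %*% (ev$values * t(ev$vectors))
}

.em_run <- function(data, G, z0, tol = 1e-6, max_iter = 500,
                    opt_gtol = 1e-6, opt_maxit = 200, closed_form = FALSE) {
  n <- nrow(data$points)
  d <- ncol(data$points)
  if (n <= G) stop("need more observations than components")
  z <- .check_membership(z0, n = n, G = G)
  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  sigma_warm <- vector("list", G)
  opt_ok <- TRUE
  iter <- 0
  params <- NULL
  repeat {
    iter <- iter + 1
    Wk <- colSums(z)
    if (any(Wk < 1e-8)) {
      stop("cluster ", which(Wk < 1e-8)[1],
           " became empty during EM; try a different initialization")
    }
    tau <- Wk / n
    means <- matrix(0, G, d)
    covs <- array(0, dim = c(d, d, G))
    for (k in seq_len(G)) {
      ss <- .group_suffstats(data, z[, k])
      if (closed_form) {
        mu <- colSums(ss$B) / Wk[k]
        Semp <- apply(ss$C, c(1, 2), sum) / Wk[k] - tcrossprod(mu)
        covs[, , k] <- (Semp + t(Semp)) / 2
        means[k, ] <- mu
      } else {
        s0 <- if (is.null(sigma_warm[[k]])) .sigma_moment_init(ss, data$group_covs)
              else sigma_warm[[k]]
        sig <- withCallingHandlers(
          .opt_sigma(s0, ss, data$group_covs, gtol = opt_gtol, maxit = opt_maxit),
          warning = function(w) {
            opt_ok <<- FALSE
            invokeRestart("muffleWarning")
          })
        covs[, , k] <- sig
        means[k, ] <- attr(sig, "mu")
        sigma_warm[[k]] <- matrix(as.numeric(sig), d, d)
      }
    }
    params <- mixture_params(tau, means, covs)
    L <- .loglik_matrix(data, params)
    lse <- .row_logsumexp(L)
    if (any(!is.finite(lse))) {
      stop("zero mixture density at observation(s): ",
           paste(utils::head(which(!is.finite(lse)), 5), collapse = ", "))
    }
    ll <- sum(lse)
    if (ll < prev_ll - 1e-6) {
      stop(sprintf("observed log-likelihood decreased (%.8g -> %.8g); this indicates an M-step failure",
                   prev_ll, ll))
    }
    trace <- c(trace, ll)
    z <- exp(L - lse)
    if (is.finite(prev_ll) && ll - prev_ll < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- ll
    if (iter >= max_iter) break
  }
  hard <- .hard_labels(z)
  structure(
    list(params = params, z = z, hard_labels = hard,
         uncertainty = 1 - apply(z, 1L, max),
         loglik = trace[length(trace)], loglik_trace = trace,
         converged = converged, n_iter = iter,
         optimizer_clean = opt_ok, data = data),
    class = "errmix_fit")
}
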