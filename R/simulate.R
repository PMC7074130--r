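#' Simulate a two-component mixture with Bernoulli error indicators
#'
#' Generates bivariate data from a two-component Gaussian mixture in which a
#' random subset of points carries a fixed, known error covariance: an error
#' indicator `h_i ~ Bernoulli(eta)` decides whether observation i is
#' measured with error covariance `lam` (or exactly error-free), a component
#' indicator `z_i ~ Bernoulli(tau)` picks the component (`z_i = 1` means
#' component 1), and the observation is the latent component draw plus an
#' independent error draw:
#' `y_i = w_i + e_i`, `w_i ~ N(mu_z, Sigma_z)`, `e_i ~ N(0, h_i * lam)`.
#' The defaults reproduce the study design this generator emulates:
#' well-overlapping clusters 8 units apart with unequal spreads and a
#' substantial error covariance.
#'
#' Draw order is fixed (all `h`, then all `z`, then one block of latent
#' standard normals, then one block of error standard normals) so a given
#' seed always yields the same sample.
#'
#' @param n Sample size.
#' @param eta Probability that an observation carries the error covariance.
#' @param tau Mixing proportion of component 1.
#' @param mu1,mu2 Component means (length-2).
#' @param sigma1,sigma2 Component covariances (2x2).
#' @param lam Error covariance (2x2) attached to points with `h_i = 1`.
#' @param seed Optional RNG seed.
#' @return List of class `errmix_sim`: `data` (wide tibble with `id`,
#'   `y_1`, `y_2`, `cov_*` columns) and `truth` (tibble with `id`, `label`
#'   in 1/2, `error_flag`, latent `w_1`, `w_2` and errors `eps_1`, `eps_2`),
#'   plus a `config` element echoing the generator settings.
#' @export
sim_bernoulli_errors <- function(n = 300, eta = 0.5, tau = 0.5,
                                 mu1 = c(0, 0), mu2 = c(8, 0),
                                 sigma1 = diag(64, 2), sigma2 = diag(16, 2),
                                 lam = diag(36, 2), seed = NULL) {
  if (eta < 0 || eta > 1) stop("`eta` must lie in [0, 1]")
  if (tau < 0 || tau > 1) stop("`tau` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  d <- 2L
  h <- stats::rbinom(n, 1, eta)
  z <- stats::rbinom(n, 1, tau)
  label <- ifelse(z == 1, 1L, 2L)
  W <- matrix(stats::rnorm(n * d), n, d)
  E <- matrix(stats::rnorm(n * d), n, d)
  R1 <- chol(.check_psd(sigma1, "sigma1"))
  R2 <- chol(.check_psd(sigma2, "sigma2"))
  RL <- chol(.check_psd(lam, "lam"))
  w <- matrix(0, n, d)
  w[label == 1, ] <- sweep(W[label == 1, , drop = FALSE] %*% R1, 2, mu1, `+`)
  w[label == 2, ] <- sweep(W[label == 2, , drop = FALSE] %*% R2, 2, mu2, `+`)
  eps <- matrix(0, n, d)
  eps[h == 1, ] <- E[h == 1, , drop = FALSE] %*% RL
  y <- w + eps
  covs <- array(0, dim = c(d, d, n))
  for (i in which(h == 1)) covs[, , i] <- lam
  ds <- error_dataset(y, covs)
  truth <- tibble::tibble(id = ds$ids, label = label, error_flag = h,
                          w_1 = w[, 1], w_2 = w[, 2],
                          eps_1 = eps[, 1], eps_2 = eps[, 2])
  structure(list(data = tibble::as_tibble(ds), truth = truth,
                 config = list(design = "bernoulli", n = n, eta = eta, tau = tau,
                               mu1 = mu1, mu2 = mu2, sigma1 = sigma1,
                               sigma2 = sigma2, lam = lam, seed = seed)),
            class = "errmix_sim")
}

#' Simulate a two-component mixture with uniformly distributed error magnitudes
#'
#' Like [sim_bernoulli_errors()] but every observation carries an isotropic
#' error covariance `S_i * I_2` whose magnitude is drawn
#' `S_i ~ Uniform(0, s_max)`. The defaults place two equal, widely spread
#' clusters 20 units apart so that many points sit near the decision boundary
#' — the regime where error-aware and error-blind uncertainties differ most.
#'
#' @param n Sample size.
#' @param tau Mixing proportion of component 1.
#' @param mu1,mu2 Component means (length-2).
#' @param sigma Common component covariance (2x2).
#' @param s_max Upper bound of the uniform error-magnitude distribution.
#' @param seed Optional RNG seed.
#' @return List of class `errmix_sim` as in [sim_bernoulli_errors()]; the
#'   `truth` tibble carries `error_magnitude` (`S_i`) instead of
#'   `error_flag`.
#' @export
sim_uniform_errors <- function(n = 200, tau = 0.5,
                               mu1 = c(-10, 0), mu2 = c(10, 0),
                               sigma = diag(100, 2), s_max = 100, seed = NULL) {
  if (s_max < 0) stop("`s_max` must be nonnegative")
  if (tau < 0 || tau > 1) stop("`tau` must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  d <- 2L
  S <- stats::runif(n, 0, s_max)
  z <- stats::rbinom(n, 1, tau)
  label <- ifelse(z == 1, 1L, 2L)
  W <- matrix(stats::rnorm(n * d), n, d)
  E <- matrix(stats::rnorm(n * d), n, d)
  Rs <- chol(.check_psd(sigma, "sigma"))
  w <- matrix(0, n, d)
  w[label == 1, ] <- sweep(W[label == 1, , drop = FALSE] %*% Rs, 2, mu1, `+`)
  w[label == 2, ] <- sweep(W[label == 2, , drop = FALSE] %*% Rs, 2, mu2, `+`)
  eps <- E * sqrt(S)
  y <- w + eps
  covs <- array(0, dim = c(d, d, n))
  for (i in seq_len(n)) covs[, , i] <- diag(S[i], d)
  ds <- error_dataset(y, covs)
  truth <- tibble::tibble(id = ds$ids, label = label, error_magnitude = S,
                          w_1 = w[, 1], w_2 = w[, 2],
                          eps_1 = eps[, 1], eps_2 = eps[, 2])
  structure(list(data = tibble::as_tibble(ds), truth = truth,
                 config = list(design = "uniform", n = n, tau = tau, mu1 = mu1,
                               mu2 = mu2, sigma = sigma, s_max = s_max,
                               seed = seed)),
            class = "errmix_sim")
}

#' @export
print.errmix_sim <- function(x, ...) {
  cat(sprintf("<errmix_sim (%s design): %d observations>\n",
              x$config$design, nrow(x$data)))
  invisible(x)
}

#' Replicated comparison of error-aware and error-free clustering
#'
#' For each error proportion in `etas` and each of `n_seeds` replicates,
#' simulates a dataset with [sim_bernoulli_errors()], fits both the
#' error-aware mixture and the error-free baseline with `G = 2` starting
#' from the true memberships, and records each method's adjusted Rand index
#' against the ground truth. Fit failures are recorded as `NA` rows rather
#' than aborting the sweep.
#'
#' @param etas Error proportions to sweep.
#' @param n_seeds Number of replicate seeds per `eta`.
#' @param n Sample size per replicate.
#' @param seed Base seed; replicate r of eta index e uses
#'   `seed + 1000 * e + r`.
#' @param ... Further arguments passed to [sim_bernoulli_errors()].
#' @return A tibble with columns `eta`, `replicate`, `seed`, `ari_errmix`,
#'   `ari_gmm`, `ari_diff`.
#' @export
sim_error_sweep <- function(etas = c(0.1, 0.3, 0.5, 0.7, 0.9), n_seeds = 100,
                            n = 300, seed = 1, ...) {
  rows <- list()
  for (e in seq_along(etas)) {
    for (r in seq_len(n_seeds)) {
      s <- seed + 1000L * e + r
      sim <- sim_bernoulli_errors(n = n, eta = etas[e], seed = s, ...)
      a_me <- tryCatch({
        fit <- errmix_fit(sim$data, G = 2, init = "labels", labels = sim$truth$label)
        adjusted_rand_index(sim$truth$label, fit$hard_labels)
      }, error = function(err) NA_real_)
      a_gm <- tryCatch({
        fit <- gmm_fit(sim$data, G = 2, init = "labels", labels = sim$truth$label)
        adjusted_rand_index(sim$truth$label, fit$hard_labels)
      }, error = function(err) NA_real_)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        eta = etas[e], replicate = r, seed = s,
        ari_errmix = a_me, ari_gmm = a_gm, ari_diff = a_me - a_gm)
    }
  }
  dplyr::bind_rows(rows)
}

#' Perturb error covariances by unit-mean multiplicative noise
#'
#' Robustness utility: rescales each observation's error covariance by an
#' independent positive factor with mean 1 (log-normal with log-scale
#' standard deviation `sdlog`), emulating re-estimated error covariances.
#' Refitting on the perturbed covariances should move far fewer memberships
#' than discarding the covariances altogether.
#'
#' @param data A wide data frame or [error_dataset()].
#' @param sdlog Log-scale standard deviation of the multiplicative noise.
#' @param seed Optional RNG seed.
#' @return A wide tibble with the perturbed covariances.
#' @export
perturb_error_covs <- function(data, sdlog = 0.2, seed = NULL) {
  data <- as_error_dataset(data)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data$points)
  fac <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  covs <- data$covs
  for (i in seq_len(n)) covs[, , i] <- covs[, , i] * fac[i]
  tibble::as_tibble(error_dataset(data$points, covs, data$ids))
}
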