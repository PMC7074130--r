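#' Number of free parameters of the unconstrained mixture
#'
#' For a G-component mixture of d-variate Gaussians with unconstrained means
#' and covariances: `G - 1` mixing proportions, `G * d` mean coordinates, and
#' one symmetric covariance per component. The `"standard"` mode counts
#' `d(d+1)/2` free entries per covariance; `"as_printed"` retains an
#' alternative convention with `d(d-1)/2` per covariance (which undercounts
#' the diagonal) so that published BIC values computed under it remain
#' auditable.
#'
#' @param G Number of components.
#' @param d Data dimension.
#' @param mode `"standard"` (default) or `"as_printed"`.
#' @return Integer parameter count.
#' @export
free_param_count <- function(G, d, mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(G >= 1, d >= 1)
  percov <- if (mode == "standard") d * (d + 1) / 2 else d * (d - 1) / 2
  as.integer((G - 1) + G * d + G * percov)
}

#' Bayesian information criterion of a fit
#'
#' `BIC = 2 * logLik - nu_G * log(n)`; larger is better under this sign
#' convention.
#'
#' @param fit An `errmix_fit`.
#' @param mode Parameter-counting mode, see [free_param_count()].
#' @return Numeric BIC value.
#' @export
bic <- function(fit, mode = c("standard", "as_printed")) {
  stopifnot(inherits(fit, "errmix_fit"))
  mode <- match.arg(mode)
  n <- nrow(fit$z)
  nu <- free_param_count(fit$params$G, fit$params$d, mode)
  2 * fit$loglik - nu * log(n)
}

#' Scan BIC over a range of component counts
#'
#' Fits the mixture for each `G` in `g_min:g_max` and tabulates
#' log-likelihood, free-parameter count and BIC. Fit failures for a
#' particular `G` (e.g., an emptied cluster) are recorded as `NA` rows rather
#' than aborting the scan.
#'
#' @param data A wide data frame or [error_dataset()].
#' @param g_min,g_max Range of component counts to scan.
#' @param method `"errmix"` (error-aware, default) or `"gmm"` (error-free
#'   baseline).
#' @param mode Parameter-counting mode, see [free_param_count()].
#' @param ... Passed on to [errmix_fit()] / [gmm_fit()] (initialization,
#'   tolerances, seed).
#' @return A tibble of class `errmix_bic` with columns `G`, `loglik`, `df`,
#'   `bic`, `converged`, plus attributes `counting_mode` and `best_g`.
#' @export
bic_scan <- function(data, g_min = 1, g_max = 4, method = c("errmix", "gmm"),
                     mode = c("standard", "as_printed"), ...) {
  data <- as_error_dataset(data)
  method <- match.arg(method)
  mode <- match.arg(mode)
  fitter <- if (method == "errmix") errmix_fit else gmm_fit
  rows <- purrr::map(g_min:g_max, function(g) {
    fit <- tryCatch(fitter(data, G = g, ...), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(G = g, loglik = NA_real_,
                            df = free_param_count(g, ncol(data$points), mode),
                            bic = NA_real_, converged = NA))
    }
    tibble::tibble(G = g, loglik = fit$loglik,
                   df = free_param_count(g, ncol(data$points), mode),
                   bic = bic(fit, mode), converged = fit$converged)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "counting_mode") <- mode
  attr(out, "best_g") <- if (all(is.na(out$bic))) NA_integer_ else out$G[which.max(out$bic)]
  class(out) <- c("errmix_bic", class(out))
  out
}
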