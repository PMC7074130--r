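#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the component parameters of a fit
#'
#' One row per mixture component: weight, mean coordinates (`mu_1 ... mu_d`)
#' and upper-triangle covariance entries (`sigma_j_k`).
#'
#' @param x An `errmix_fit`.
#' @param ... Unused.
#' @return A tibble with `G` rows.
#' @export
tidy.errmix_fit <- function(x, ...) {
  d <- x$params$d
  out <- tibble::tibble(component = seq_len(x$params$G),
                        weight = x$params$weights)
  for (j in seq_len(d)) out[[paste0("mu_", j)]] <- x$params$means[, j]
  for (j in seq_len(d)) for (k in j:d) {
    out[[paste0("sigma_", j, "_", k)]] <- x$params$covs[j, k, ]
  }
  out
}

#' One-row model summary of a fit
#'
#' @param x An `errmix_fit`.
#' @param ... Unused.
#' @return A tibble with columns `method`, `G`, `n`, `d`, `logLik`, `df`,
#'   `BIC`, `n_iter`, `converged`.
#' @export
glance.errmix_fit <- function(x, ...) {
  tibble::tibble(method = x$method, G = x$params$G, n = nrow(x$z),
                 d = x$params$d, logLik = x$loglik,
                 df = free_param_count(x$params$G, x$params$d),
                 BIC = bic(x), n_iter = x$n_iter, converged = x$converged)
}

#' Attach per-observation results to the data
#'
#' Returns the wide data tibble augmented with `.cluster` (hard label),
#' `.z_k` membership probabilities, and `.uncertainty`.
#'
#' @param x An `errmix_fit`.
#' @param ... Unused.
#' @return A tibble with one row per observation.
#' @export
augment.errmix_fit <- function(x, ...) {
  out <- tibble::as_tibble(x$data)
  out$.cluster <- factor(x$hard_labels)
  for (k in seq_len(x$params$G)) out[[paste0(".z_", k)]] <- x$z[, k]
  out$.uncertainty <- x$uncertainty
  out
}

#' @export
tidy.kerror_fit <- function(x, ...) {
  d <- ncol(x$centers)
  out <- tibble::tibble(component = seq_len(nrow(x$centers)),
                        size = tabulate(x$labels, nrow(x$centers)))
  for (j in seq_len(d)) out[[paste0("mu_", j)]] <- x$centers[, j]
  for (j in seq_len(d)) for (k in j:d) {
    out[[paste0("psi_", j, "_", k)]] <- x$center_covs[j, k, ]
  }
  out
}

#' @export
glance.kerror_fit <- function(x, ...) {
  tibble::tibble(method = "kerror", G = nrow(x$centers), n = length(x$labels),
                 objective = x$objective, n_iter = x$n_iter,
                 converged = x$converged)
}

#' Plot a fitted clustering
#'
#' Scatter plot of 2-D data colored by hard cluster label, with point size
#' mapped to classification uncertainty. With `boundaries = TRUE` (G = 2
#' only) the per-error-covariance decision boundaries are overlaid, one
#' linetype per distinct error covariance.
#'
#' @param object An `errmix_fit` on 2-D data.
#' @param boundaries Overlay decision boundaries?
#' @param resolution Grid resolution for boundary tracing.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.errmix_fit <- function(object, boundaries = FALSE, resolution = 151, ...) {
  if (object$params$d != 2) stop("autoplot supports 2-D fits only")
  df <- augment.errmix_fit(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$y_1, y = .data$y_2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$.cluster,
                                     size = .data$.uncertainty),
                        alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(0.8, 3.5)) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  colour = "cluster", size = "uncertainty") +
    ggplot2::theme_minimal()
  if (boundaries && object$params$G == 2) {
    bd <- decision_boundary(object, resolution = resolution)
    if (nrow(bd)) {
      p <- p + ggplot2::geom_path(
        data = bd,
        ggplot2::aes(x = .data$y_1, y = .data$y_2,
                     group = interaction(.data$lam_id, .data$piece),
                     linetype = factor(.data$lam_id)),
        colour = "grey25", inherit.aes = FALSE) +
        ggplot2::labs(linetype = "error covariance")
    }
  }
  p
}

#' Plot a BIC scan
#'
#' BIC (larger is better) against the number of components.
#'
#' @param object An `errmix_bic` tibble from [bic_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.errmix_bic <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$G, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of components", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Plot a replicated accuracy sweep
#'
#' Boxplots of per-replicate adjusted Rand indices for the error-aware and
#' error-free fits across error proportions, from [sim_error_sweep()].
#'
#' @param data A tibble from [sim_error_sweep()].
#' @return A ggplot object.
#' @export
plot_ari_sweep <- function(data) {
  long <- tidyr::pivot_longer(data, c("ari_errmix", "ari_gmm"),
                              names_to = "method", values_to = "ari",
                              names_prefix = "ari_")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$eta), y = .data$ari,
                                     fill = .data$method)) +
    ggplot2::geom_boxplot(alpha = 0.8, outlier.size = 0.7) +
    ggplot2::labs(x = "error proportion", y = "adjusted Rand index",
                  fill = "method") +
    ggplot2::theme_minimal()
}
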