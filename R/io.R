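#' Read a dataset of points with error covariances from CSV
#'
#' Expects the wide layout documented in [as_error_dataset()]: an `id`
#' column, point columns `y_1 ... y_d`, and either upper-triangle covariance
#' columns `cov_j_k` or standard-error columns `se_1 ... se_d` (optionally
#' with `corr_j_k`). The parsed matrices are symmetrized and validated;
#' schema problems and non-PSD rows raise errors naming the offending
#' columns or rows.
#'
#' @param path Path to a CSV file.
#' @return A validated wide tibble in canonical `cov_j_k` form (ready for
#'   [errmix_fit()] and friends).
#' @export
read_error_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  tibble::as_tibble(as_error_dataset(df))
}

#' Write a dataset of points with error covariances to CSV
#'
#' Inverse of [read_error_dataset()]; the write/read round trip preserves
#' values to full double precision.
#'
#' @param data A wide data frame or [error_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_error_dataset <- function(data, path) {
  df <- tibble::as_tibble(as_error_dataset(data))
  readr::write_csv(df, path)
  invisible(path)
}

#' Read log-fold-change estimates with standard errors
#'
#' Convenience reader for the motivating use case: per-gene log fold change
#' estimates at `d` conditions/time points with their standard errors, as
#' produced by gene-wise regression. The expected columns are `id`,
#' `lfc_1 ... lfc_d` and `se_1 ... se_d` (plus optional `corr_j_k`); the
#' covariance of each gene's estimates is assembled as
#' `diag(se) %*% corr %*% diag(se)` (diagonal when no correlations are
#' given). Note this assumes the deposited file stores estimates and
#' standard errors per gene; files storing full covariances should be
#' reshaped to the `cov_j_k` layout of [read_error_dataset()] instead.
#'
#' @param path Path to a CSV file.
#' @return A wide tibble in canonical form (columns `id`, `y_*`, `cov_*`).
#' @export
read_lfc_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- readr::read_csv(path, show_col_types = FALSE)
  lfc <- grep("^lfc_[0-9]+$", names(df), value = TRUE)
  if (length(lfc) == 0L) stop("no `lfc_1 ... lfc_d` columns found")
  for (j in seq_along(lfc)) names(df)[names(df) == paste0("lfc_", j)] <- paste0("y_", j)
  tibble::as_tibble(as_error_dataset(df))
}

#' Write fit results to CSV and JSON
#'
#' Writes a per-observation CSV (`id`, `cluster`, `z_1 ... z_G`,
#' `uncertainty`) and a parameters JSON (weights, means, covariances,
#' log-likelihood, BIC, convergence info, and an echo of the configuration).
#'
#' @param fit An `errmix_fit`.
#' @param csv_path Path of the per-observation CSV (or `NULL` to skip).
#' @param json_path Path of the parameters JSON (or `NULL` to skip).
#' @param seed Seed to echo into the JSON (for provenance of CLI runs).
#' @return Invisibly, a list with the written paths.
#' @export
write_fit_results <- function(fit, csv_path = NULL, json_path = NULL, seed = NULL) {
  stopifnot(inherits(fit, "errmix_fit"))
  if (!is.null(csv_path)) {
    tab <- tibble::tibble(id = fit$data$ids, cluster = fit$hard_labels)
    for (k in seq_len(fit$params$G)) tab[[paste0("z_", k)]] <- fit$z[, k]
    tab$uncertainty <- fit$uncertainty
    readr::write_csv(tab, csv_path)
  }
  if (!is.null(json_path)) {
    G <- fit$params$G
    pj <- list(
      method = fit$method,
      G = G,
      weights = fit$params$weights,
      means = lapply(seq_len(G), function(k) fit$params$means[k, ]),
      covariances = lapply(seq_len(G), function(k) fit$params$covs[, , k]),
      loglik = fit$loglik,
      bic = bic(fit),
      converged = fit$converged,
      n_iter = fit$n_iter,
      init = fit$init,
      seed = seed,
      version = as.character(utils::packageVersion("errmix")))
    jsonlite::write_json(pj, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(csv = csv_path, json = json_path))
}
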