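#' Construct a dataset of points with per-observation error covariances
#'
#' Bundles an `n x d` matrix of observed points with one `d x d` symmetric
#' positive semidefinite error covariance matrix per observation. This is the
#' internal container every fitting function works on; most users will instead
#' pass a wide data frame (see [as_error_dataset()]) straight to [errmix_fit()].
#'
#' Covariance matrices are symmetrized as `(A + t(A))/2` on ingest, because
#' covariances obtained by inverting an observed information matrix are only
#' numerically symmetric. A matrix is rejected when its smallest eigenvalue
#' falls below `-1e-10` times its largest eigenvalue.
#'
#' @param points Numeric matrix (`n x d`), one observation per row.
#' @param error_covs Either a `d x d x n` array, a list of `n` matrices, or a
#'   single `d x d` matrix recycled for every observation.
#' @param ids Optional character vector of observation labels; defaults to
#'   row numbers.
#' @return An object of class `error_dataset`: a list with elements `points`,
#'   `covs` (a `d x d x n` array), `ids`, and a precomputed grouping of
#'   observations that share an identical error covariance (used to vectorize
#'   likelihood evaluations).
#' @seealso [as_error_dataset()], [read_error_dataset()]
#' @export
error_dataset <- function(points, error_covs, ids = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  n <- nrow(points)
  d <- ncol(points)
  if (n < 1L || d < 1L) stop("need at least one observation and one dimension")
  if (!all(is.finite(points))) {
    bad <- which(!stats::complete.cases(points) | rowSums(!is.finite(points)) > 0)
    stop("non-finite point values at rows: ", paste(utils::head(bad, 5), collapse = ", "))
  }
  covs <- .as_cov_array(error_covs, n = n, d = d)
  for (i in seq_len(n)) {
    covs[, , i] <- .check_psd(covs[, , i, drop = FALSE][, , 1],
                              what = paste0("error covariance of observation ", i))
  }
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("`ids` must have one entry per observation")
  grp <- .cov_groups(covs)
  structure(
    list(points = points, covs = covs, ids = ids,
         group = grp$index, group_covs = grp$covs),
    class = "error_dataset"
  )
}

#' @export
print.error_dataset <- function(x, ...) {
  cat(sprintf("<error_dataset: %d observations, %d dimensions, %d distinct error covariances>\n",
              nrow(x$points), ncol(x$points), dim(x$group_covs)[3]))
  invisible(x)
}

#' @export
dim.error_dataset <- function(x) dim(x$points)

# coerce list / single matrix / array to d x d x n array
.as_cov_array <- function(error_covs, n, d) {
  if (is.list(error_covs)) {
    if (length(error_covs) != n) stop("need one error covariance per observation")
    covs <- array(0, dim = c(d, d, n))
    for (i in seq_len(n)) covs[, , i] <- as.matrix(error_covs[[i]])
    return(covs)
  }
  if (is.array(error_covs) && length(dim(error_covs)) == 3L) {
    if (!all(dim(error_covs) == c(d, d, n))) stop("error covariance array must be d x d x n")
    return(error_covs)
  }
  m <- as.matrix(error_covs)
  if (!all(dim(m) == c(d, d))) stop("single error covariance must be d x d")
  array(rep(m, n), dim = c(d, d, n))
}

# symmetrize and validate PSD within relative tolerance; returns repaired matrix
.check_psd <- function(a, what = "covariance", tol = 1e-10) {
  if (!all(is.finite(a))) stop(what, " has non-finite entries")
  a <- (a + t(a)) / 2
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1e-300)
  if (min(ev) < -tol * scale) {
    stop(what, " is not positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  }
  a
}

# group observations sharing a bit-identical covariance; most simulated designs
# have very few distinct matrices, which lets the E/M steps vectorize per group
.cov_groups <- function(covs) {
  n <- dim(covs)[3]
  keys <- vapply(seq_len(n), function(i) paste(covs[, , i], collapse = "\r"), "")
  uk <- unique(keys)
  index <- match(keys, uk)
  d <- dim(covs)[1]
  gc <- array(0, dim = c(d, d, length(uk)))
  for (g in seq_along(uk)) gc[, , g] <- covs[, , which(index == g)[1]]
  list(index = index, covs = gc)
}

#' Convert a wide data frame to an `error_dataset`
#'
#' Accepts the package's canonical wide layout: an optional `id` column,
#' point columns `y_1 ... y_d`, and then either
#' * explicit covariance columns `cov_j_k` for `1 <= j <= k <= d`
#'   (upper triangle), or
#' * standard-error columns `se_1 ... se_d`, optionally with correlation
#'   columns `corr_j_k` (`j < k`); the covariance is assembled as
#'   `diag(se) %*% corr %*% diag(se)` (identity correlation when absent).
#'
#' @param df A data frame in the wide layout above, or an `error_dataset`
#'   (returned unchanged).
#' @return An [error_dataset()].
#' @export
as_error_dataset <- function(df) {
  if (inherits(df, "error_dataset")) return(df)
  df <- as.data.frame(df)
  ycols <- grep("^y_[0-9]+$", names(df), value = TRUE)
  if (length(ycols) == 0L) stop("no point columns `y_1 ... y_d` found")
  d <- length(ycols)
  ycols <- paste0("y_", seq_len(d))
  if (!all(ycols %in% names(df))) stop("point columns must be y_1 ... y_d without gaps")
  pts <- as.matrix(df[ycols])
  n <- nrow(pts)
  ids <- if ("id" %in% names(df)) as.character(df$id) else as.character(seq_len(n))

  covcols <- outer(seq_len(d), seq_len(d), function(j, k) paste0("cov_", j, "_", k))
  upper <- covcols[upper.tri(covcols, diag = TRUE)]
  if (all(upper %in% names(df))) {
    covs <- array(0, dim = c(d, d, n))
    for (j in seq_len(d)) for (k in j:d) {
      v <- df[[paste0("cov_", j, "_", k)]]
      covs[j, k, ] <- v
      covs[k, j, ] <- v
    }
    return(error_dataset(pts, covs, ids))
  }
  secols <- paste0("se_", seq_len(d))
  if (all(secols %in% names(df))) {
    covs <- array(0, dim = c(d, d, n))
    se <- as.matrix(df[secols])
    for (j in seq_len(d)) covs[j, j, ] <- se[, j]^2
    for (j in seq_len(max(d - 1, 1))) for (k in seq_len(d)[-seq_len(j)]) {
      cc <- paste0("corr_", j, "_", k)
      if (cc %in% names(df)) {
        covs[j, k, ] <- df[[cc]] * se[, j] * se[, k]
        covs[k, j, ] <- covs[j, k, ]
      }
    }
    return(error_dataset(pts, covs, ids))
  }
  stop("missing covariance columns: expected either cov_j_k (upper triangle) ",
       "or se_1..se_", d, " [+ optional corr_j_k]")
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.error_dataset <- function(x, ...) {
  d <- ncol(x$points)
  out <- tibble::tibble(id = x$ids)
  for (j in seq_len(d)) out[[paste0("y_", j)]] <- x$points[, j]
  for (j in seq_len(d)) for (k in j:d) {
    out[[paste0("cov_", j, "_", k)]] <- x$covs[j, k, ]
  }
  out
}
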