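#' Construct mixture parameters
#'
#' Holds the parameters of a G-component Gaussian mixture: mixing proportions
#' `weights` (tau_k), component means `means` (mu_k, one row per component) and
#' component covariances `covs` (Sigma_k). These are the *cluster* covariances;
#' each observation's error covariance is added on top when densities are
#' evaluated.
#'
#' @param weights Length-G nonnegative vector summing to 1 (within 1e-12).
#' @param means `G x d` matrix of component means (a vector is taken as one
#'   row per component for d = 1).
#' @param covs `d x d x G` array, list of G matrices, or a single matrix for
#'   G = 1.
#' @return An object of class `mixture_params`.
#' @export
mixture_params <- function(weights, means, covs) {
  weights <- as.numeric(weights)
  G <- length(weights)
  if (G < 1L) stop("need at least one component")
  if (any(weights < -1e-12)) stop("weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1 (within 1e-12)")
  means <- as.matrix(means)
  if (nrow(means) != G && ncol(means) == G) means <- t(means)
  if (nrow(means) != G) stop("`means` must have one row per component")
  d <- ncol(means)
  covs <- .as_cov_array(covs, n = G, d = d)
  for (k in seq_len(G)) {
    covs[, , k] <- .check_psd(covs[, , k, drop = FALSE][, , 1],
                              what = paste0("covariance of component ", k))
  }
  structure(list(G = G, d = d, weights = weights, means = means, covs = covs),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("<mixture_params: G = %d components in %d dimensions>\n", x$G, x$d))
  cat("weights:", format(x$weights, digits = 4), "\n")
  invisible(x)
}

# validate an n x G membership (responsibility) matrix
.check_membership <- function(z, n = NULL, G = NULL, tol = 1e-10) {
  z <- as.matrix(z)
  if (!is.null(n) && nrow(z) != n) stop("membership matrix has wrong number of rows")
  if (!is.null(G) && ncol(z) != G) stop("membership matrix has wrong number of columns")
  if (any(z < -tol) || any(z > 1 + tol)) stop("membership probabilities must lie in [0, 1]")
  if (any(abs(rowSums(z) - 1) > tol)) {
    stop("membership rows must sum to 1 (max deviation ",
         format(max(abs(rowSums(z) - 1))), ")")
  }
  z
}

# one-hot membership matrix from integer labels 1..G
.labels_to_z <- function(labels, G) {
  n <- length(labels)
  z <- matrix(0, n, G)
  z[cbind(seq_len(n), labels)] <- 1
  z
}

# argmax with deterministic tie-break toward the lowest index
.hard_labels <- function(z) {
  apply(z, 1L, which.max)
}
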