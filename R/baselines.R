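#' Fit the error-free Gaussian mixture baseline
#'
#' Standard unconstrained-covariance Gaussian mixture EM: every observation's
#' error covariance is set to zero, so the M step has the familiar closed
#' forms (weighted means and weighted sample covariances). This is the model
#' the error-aware fit reduces to when all error covariances vanish, and it
#' runs through the same EM loop, E step, and convergence logic as
#' [errmix_fit()] — only the M step differs.
#'
#' @inheritParams errmix_fit
#' @return An `errmix_fit` object with `method = "gmm"`. Error covariance
#'   columns in `data`, if present, are ignored.
#' @export
gmm_fit <- function(data, G = 2, init = c("hierarchical", "kmeans", "labels", "params"),
                    labels = NULL, params = NULL, tol = 1e-6, max_iter = 500,
                    seed = NULL) {
  data <- as_error_dataset(data)
  init <- match.arg(init)
  data0 <- error_dataset(data$points, diag(0, ncol(data$points)), ids = data$ids)
  z0 <- em_init(data0, G, method = init, labels = labels, params = params, seed = seed)
  fit <- .em_run(data0, G, z0, tol = tol, max_iter = max_iter, closed_form = TRUE)
  fit$method <- "gmm"
  fit$init <- init
  fit
}

#' Precision-weighted cluster center (kError)
#'
#' Weighted average of the observations in one cluster, with each observation
#' weighted by the inverse of its total covariance, together with the
#' covariance of that center estimate:
#' `mu = (sum_i P_i)^-1 sum_i P_i y_i`, `Psi = (sum_i P_i)^-1` with
#' `P_i = Lambda_i^-1`.
#'
#' @param points `m x d` matrix of the cluster's observations.
#' @param errs `d x d x m` array (or list of m matrices) of positive definite
#'   total covariances.
#' @return List with `center` (d-vector) and `psi` (`d x d` matrix).
#' @export
kerror_center <- function(points, errs) {
  points <- rbind(points)
  m <- nrow(points)
  d <- ncol(points)
  errs <- .as_cov_array(errs, n = m, d = d)
  prec <- matrix(0, d, d)
  pw <- numeric(d)
  for (i in seq_len(m)) {
    P <- tryCatch(chol2inv(chol(errs[, , i])),
                  error = function(e) stop("singular covariance for observation ", i))
    prec <- prec + P
    pw <- pw + P %*% points[i, ]
  }
  psi <- chol2inv(chol(prec))
  list(center = drop(psi %*% pw), psi = (psi + t(psi)) / 2)
}

#' kError point-to-center distance
#'
#' The squared Mahalanobis distance `(y - mu)^T Lambda^-1 (y - mu)` used by
#' the kError assignment step.
#'
#' @param y Observation (d-vector).
#' @param lam_tilde Positive definite `d x d` covariance for the distance.
#' @param center Cluster center (d-vector).
#' @return Nonnegative scalar.
#' @export
kerror_distance <- function(y, lam_tilde, center) {
  r <- as.numeric(y) - as.numeric(center)
  R <- tryCatch(chol(lam_tilde), error = function(e) stop("singular covariance in kerror_distance"))
  sum(backsolve(R, r, transpose = TRUE)^2)
}

#' Inter-cluster distance between precision-weighted centers
#'
#' `(mu_k - mu_l)^T (Psi_k + Psi_l)^-1 (mu_k - mu_l)`: the squared distance
#' between two cluster centers scaled by the combined covariance of the two
#' center estimates. Exposed as a standalone statistic (the hierarchical
#' merging algorithm built on it is out of scope here).
#'
#' @param center_k,center_l Cluster centers (d-vectors).
#' @param psi_k,psi_l Center covariance matrices from [kerror_center()].
#' @return Nonnegative scalar.
#' @export
kerror_cluster_distance <- function(center_k, psi_k, center_l, psi_l) {
  r <- as.numeric(center_k) - as.numeric(center_l)
  drop(t(r) %*% solve(psi_k + psi_l, r))
}

#' Fit clusters by the kError algorithm
#'
#' A k-means-style comparator for errorful data: centers are precision-
#' weighted means ([kerror_center()]) and each point is assigned to the
#' nearest center under its own Mahalanobis distance ([kerror_distance()]).
#' The two steps alternate until the hard labels stop changing or `max_iter`
#' is reached. Note the model behind kError treats each observation's matrix
#' as its *total* covariance around the cluster center; driving it with
#' estimation-error covariances (as done here) makes it a comparator rather
#' than a faithful model.
#'
#' @param data A wide data frame or [error_dataset()]; all error covariances
#'   must be positive definite.
#' @param G Number of clusters.
#' @param labels Initial hard labels with `G` non-empty clusters.
#' @param max_iter Iteration cap.
#' @return Object of class `kerror_fit`: list with `labels`, `centers`
#'   (`G x d`), `center_covs` (`d x d x G`), `objective` (sum of assigned
#'   distances), `objective_trace`, `converged`, `n_iter`.
#' @export
kerror_fit <- function(data, G = 2, labels, max_iter = 100) {
  data <- as_error_dataset(data)
  n <- nrow(data$points)
  d <- ncol(data$points)
  if (length(labels) != n) stop("`labels` must have one entry per observation")
  u <- sort(unique(labels))
  if (length(u) != G) stop("initial labels must contain exactly G distinct values")
  lab <- match(labels, u)

  prec <- array(0, dim = c(d, d, n))
  for (i in seq_len(n)) {
    prec[, , i] <- tryCatch(chol2inv(chol(data$covs[, , i])),
                            error = function(e) stop("singular error covariance for observation ", i))
  }

  centers <- matrix(0, G, d)
  psis <- array(0, dim = c(d, d, G))
  obj_trace <- numeric(0)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    for (k in seq_len(G)) {
      idx <- which(lab == k)
      if (length(idx) == 0L) stop("cluster ", k, " became empty during kError")
      kc <- kerror_center(data$points[idx, , drop = FALSE],
                          data$covs[, , idx, drop = FALSE])
      centers[k, ] <- kc$center
      psis[, , k] <- kc$psi
    }
    D <- matrix(0, n, G)
    for (k in seq_len(G)) {
      r <- t(data$points) - centers[k, ]
      for (i in seq_len(n)) D[i, k] <- drop(t(r[, i]) %*% prec[, , i] %*% r[, i])
    }
    new_lab <- max.col(-D, ties.method = "first")
    obj_trace <- c(obj_trace, sum(D[cbind(seq_len(n), new_lab)]))
    if (all(new_lab == lab)) {
      converged <- TRUE
      break
    }
    lab <- new_lab
    if (iter >= max_iter) break
  }
  structure(
    list(labels = lab, centers = centers, center_covs = psis,
         objective = obj_trace[length(obj_trace)], objective_trace = obj_trace,
         converged = converged, n_iter = iter, data = data),
    class = "kerror_fit")
}

#' @export
print.kerror_fit <- function(x, ...) {
  cat(sprintf("<kerror_fit: G = %d, n = %d, objective %.4f after %d iterations (%s)>\n",
              nrow(x$centers), length(x$labels), x$objective, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}
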