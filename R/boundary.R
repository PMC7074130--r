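#' Two-group classification score
#'
#' For a fitted two-component mixture, the log-ratio
#' `log(tau_1 g_1(t)) - log(tau_2 g_2(t))` with both component densities
#' evaluated at error covariance `lam`. Positive values classify `t` into
#' cluster 1; the zero level set is that error covariance's decision
#' boundary, exactly where the posterior membership probability equals 1/2.
#' Every distinct error covariance has its own boundary; observations sharing
#' a covariance share a boundary.
#'
#' @param t Point (d-vector) or `m x d` matrix of points.
#' @param lam Error covariance (`d x d` PSD) at which to evaluate.
#' @param params Fitted [mixture_params()] with exactly two components.
#' @return Numeric score(s).
#' @export
classification_score <- function(t, lam, params) {
  stopifnot(inherits(params, "mixture_params"))
  if (params$G != 2) stop("classification scores are defined for G = 2 only")
  t <- rbind(t)
  l1 <- log(params$weights[1]) +
    component_density(t, params$means[1, ], params$covs[, , 1], lam, log = TRUE)
  l2 <- log(params$weights[2]) +
    component_density(t, params$means[2, ], params$covs[, , 2], lam, log = TRUE)
  drop(l1 - l2)
}

#' Conic coefficients of a 2-D decision boundary
#'
#' In two dimensions, the boundary `{t : score(t) = 0}` is the zero set of the
#' quadratic `t' M t + b' t + c` with `A_k = Sigma_k + lam`:
#' `M = (A_2^-1 - A_1^-1)/2`, `b = A_1^-1 mu_1 - A_2^-1 mu_2`, and
#' `c = log(tau_1/tau_2) - (1/2) log(det A_1 / det A_2)
#'      - (1/2)(mu_1' A_1^-1 mu_1 - mu_2' A_2^-1 mu_2)`.
#' When `A_1 = A_2` the quadratic term vanishes and the boundary is a
#' straight line; otherwise it is a conic section.
#'
#' @inheritParams classification_score
#' @return List with `M` (2x2 matrix), `b` (length-2), `c` (scalar).
#' @export
conic_coefficients <- function(lam, params) {
  stopifnot(inherits(params, "mixture_params"))
  if (params$G != 2) stop("boundaries are defined for G = 2 only")
  if (params$d != 2) stop("conic coefficients are defined for d = 2 only")
  lam <- as.matrix(lam)
  A1 <- params$covs[, , 1] + lam
  A2 <- params$covs[, , 2] + lam
  P1 <- chol2inv(chol(A1))
  P2 <- chol2inv(chol(A2))
  mu1 <- params$means[1, ]
  mu2 <- params$means[2, ]
  M <- (P2 - P1) / 2
  b <- drop(P1 %*% mu1 - P2 %*% mu2)
  c0 <- log(params$weights[1] / params$weights[2]) -
    0.5 * (determinant(A1, logarithm = TRUE)$modulus -
           determinant(A2, logarithm = TRUE)$modulus) -
    0.5 * (drop(t(mu1) %*% P1 %*% mu1) - drop(t(mu2) %*% P2 %*% mu2))
  list(M = (M + t(M)) / 2, b = b, c = as.numeric(c0))
}

#' Trace a 2-D decision boundary
#'
#' Contours the classification score at level zero over a rectangular window
#' and refines every contour vertex by Newton steps along the exact score
#' gradient (the score is a quadratic, so refinement converges in a handful
#' of steps) until `|score| < 1e-6`. Grid contouring is used rather than
#' closed-form conic plotting so degenerate conics (lines, near-parabolic
#' cases) are handled uniformly.
#'
#' @inheritParams classification_score
#' @param window Numeric `c(xmin, xmax, ymin, ymax)` bounding box.
#' @param resolution Grid points per axis.
#' @return A tibble with columns `piece` (polyline id), `y_1`, `y_2`,
#'   `score`. Zero rows (with a message) when the score does not change sign
#'   in the window.
#' @export
trace_boundary_2d <- function(lam, params, window, resolution = 201) {
  stopifnot(inherits(params, "mixture_params"))
  if (params$d != 2) stop("boundary tracing is defined for d = 2 only")
  if (params$G != 2) stop("boundary tracing is defined for G = 2 only")
  window <- as.numeric(window)
  if (length(window) != 4) stop("`window` must be c(xmin, xmax, ymin, ymax)")
  xs <- seq(window[1], window[2], length.out = resolution)
  ys <- seq(window[3], window[4], length.out = resolution)
  grid <- as.matrix(expand.grid(y_1 = xs, y_2 = ys))
  sc <- matrix(classification_score(grid, lam, params), resolution, resolution)
  if (all(sc > 0) || all(sc < 0)) {
    rlang::inform("classification score does not change sign in the window; no boundary to trace")
    return(tibble::tibble(piece = integer(0), y_1 = numeric(0),
                          y_2 = numeric(0), score = numeric(0)))
  }
  cl <- grDevices::contourLines(xs, ys, sc, levels = 0)
  cc <- conic_coefficients(lam, params)
  pieces <- purrr::imap(cl, function(piece, idx) {
    pts <- cbind(piece$x, piece$y)
    for (r in seq_len(nrow(pts))) {
      pts[r, ] <- .refine_root(pts[r, ], cc)
    }
    tibble::tibble(piece = idx, y_1 = pts[, 1], y_2 = pts[, 2],
                   score = classification_score(pts, lam, params))
  })
  dplyr::bind_rows(pieces)
}

# Newton refinement of a near-boundary point onto score(t) = 0 along the
# exact quadratic gradient 2 M t + b
.refine_root <- function(t0, cc, tol = 1e-10, max_steps = 50) {
  t <- t0
  for (s in seq_len(max_steps)) {
    f <- drop(t %*% cc$M %*% t) + sum(cc$b * t) + cc$c
    if (abs(f) < tol) break
    g <- drop(2 * cc$M %*% t) + cc$b
    gn <- sum(g^2)
    if (gn < 1e-300) break
    t <- t - f * g / gn
  }
  t
}

#' Decision boundaries of a fitted two-group model
#'
#' Convenience wrapper around [trace_boundary_2d()]: extracts the boundary
#' for each distinct error covariance in the fitted data (or for covariances
#' supplied in `lams`), over the data bounding box padded by 20%.
#'
#' @param fit An `errmix_fit` with `G = 2` on 2-D data.
#' @param lams Optional list of error covariance matrices; defaults to the
#'   distinct error covariances present in the fitted data.
#' @param resolution Grid points per axis for [trace_boundary_2d()].
#' @return A tibble with columns `lam_id`, `piece`, `y_1`, `y_2`, `score`.
#' @export
decision_boundary <- function(fit, lams = NULL, resolution = 201) {
  stopifnot(inherits(fit, "errmix_fit"))
  d <- fit$params$d
  if (d != 2 || fit$params$G != 2) stop("decision_boundary requires G = 2 and d = 2")
  if (is.null(lams)) {
    lams <- purrr::map(seq_len(dim(fit$data$group_covs)[3]),
                       ~ fit$data$group_covs[, , .x])
  }
  rng1 <- range(fit$data$points[, 1])
  rng2 <- range(fit$data$points[, 2])
  pad1 <- 0.2 * diff(rng1)
  pad2 <- 0.2 * diff(rng2)
  window <- c(rng1[1] - pad1, rng1[2] + pad1, rng2[1] - pad2, rng2[2] + pad2)
  out <- purrr::imap(lams, function(lam, i) {
    tb <- trace_boundary_2d(lam, fit$params, window, resolution)
    tb$lam_id <- rep(i, nrow(tb))
    tb
  })
  dplyr::relocate(dplyr::bind_rows(out), "lam_id")
}
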