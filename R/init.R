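#' Initial memberships for EM
#'
#' Produces a one-hot membership matrix to start EM (the algorithm's first
#' move is an M step). Strategies:
#'
#' * `"hierarchical"` — model-based greedy agglomeration: starting from
#'   singletons, repeatedly merge the pair of clusters that maximizes the
#'   unconstrained-Gaussian classification log-likelihood of the partition
#'   (error covariances ignored at this stage). A small fixed ridge keeps
#'   singleton covariances well defined.
#' * `"kmeans"` — [stats::kmeans()] with `nstart = 10`, seeded by `seed`.
#' * `"labels"` — user-supplied hard labels (used, e.g., to start from known
#'   ground truth in simulations); must contain exactly `G` distinct values.
#' * `"params"` — one E step at the supplied [mixture_params()], hardened to
#'   one-hot by the argmax rule.
#'
#' @param data A wide data frame or [error_dataset()].
#' @param G Number of clusters.
#' @param method One of `"hierarchical"`, `"kmeans"`, `"labels"`, `"params"`.
#' @param labels Hard labels for `method = "labels"`.
#' @param params [mixture_params()] for `method = "params"`.
#' @param seed RNG seed for `method = "kmeans"`.
#' @return `n x G` one-hot membership matrix.
#' @export
em_init <- function(data, G, method = c("hierarchical", "kmeans", "labels", "params"),
                    labels = NULL, params = NULL, seed = NULL) {
  data <- as_error_dataset(data)
  method <- match.arg(method)
  n <- nrow(data$points)
  if (G < 1) stop("G must be at least 1")
  lab <- switch(
    method,
    labels = {
      if (is.null(labels)) stop("`labels` required for init = 'labels'")
      if (length(labels) != n) stop("`labels` must have one entry per observation")
      u <- sort(unique(labels))
      if (length(u) < G) stop("label vector has fewer than G distinct values")
      if (length(u) > G) stop("label vector has more than G distinct values")
      match(labels, u)
    },
    kmeans = {
      if (!is.null(seed)) set.seed(seed)
      stats::kmeans(data$points, centers = G, nstart = 10)$cluster
    },
    hierarchical = hclust_classlik(data$points, G),
    params = {
      if (is.null(params)) stop("`params` required for init = 'params'")
      .hard_labels(e_step(data, params))
    })
  if (length(unique(lab)) < G) {
    stop("initialization produced fewer than G non-empty clusters")
  }
  .labels_to_z(lab, G)
}

#' Greedy model-based agglomerative clustering
#'
#' Agglomerates observations from singletons down to `G` clusters, at each
#' stage merging the pair of clusters whose merge maximizes the partition's
#' classification log-likelihood under unconstrained per-cluster Gaussians
#' (mean and covariance at their within-cluster maximum-likelihood values).
#' A fixed ridge of `1e-6` times the average marginal variance is added to
#' every cluster covariance so singletons and collinear clusters remain well
#' defined. Used as the default EM initialization.
#'
#' @param points `n x d` numeric matrix.
#' @param G Target number of clusters.
#' @return Integer label vector (values `1..G`, numbered by first occurrence).
#' @export
hclust_classlik <- function(points, G) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- ncol(points)
  if (G > n) stop("cannot form more clusters than observations")
  ridge <- 1e-6 * mean(apply(points, 2, stats::var))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-8

  # per-cluster sufficient statistics
  m <- rep(1, n)
  s <- points                        # cluster sums
  S <- array(0, dim = c(d, d, n))    # cluster sums of outer products
  for (i in seq_len(n)) S[, , i] <- tcrossprod(points[i, ])
  active <- rep(TRUE, n)
  member <- seq_len(n)               # cluster id of each observation

  clus_ll <- function(mi, si, Si) {
    mu <- si / mi
    M <- Si - mi * tcrossprod(mu)
    M <- (M + t(M)) / 2
    Sg <- M / mi + diag(ridge, d)
    R <- chol(Sg)
    -0.5 * mi * (d * log(2 * pi) + 2 * sum(log(diag(R)))) -
      0.5 * sum(chol2inv(R) * M)
  }
  ll <- vapply(seq_len(n), function(i) clus_ll(m[i], s[i, ], S[, , i]), 0)

  merge_gain <- function(i, j) {
    clus_ll(m[i] + m[j], s[i, ] + s[j, ], S[, , i] + S[, , j]) - ll[i] - ll[j]
  }
  gain <- matrix(-Inf, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) gain[i, j] <- merge_gain(i, j)
  }

  n_active <- n
  while (n_active > G) {
    best <- arrayInd(which.max(gain), dim(gain))
    i <- best[1]; j <- best[2]
    # absorb j into i
    m[i] <- m[i] + m[j]
    s[i, ] <- s[i, ] + s[j, ]
    S[, , i] <- S[, , i] + S[, , j]
    ll[i] <- clus_ll(m[i], s[i, ], S[, , i])
    member[member == j] <- i
    active[j] <- FALSE
    gain[j, ] <- -Inf
    gain[, j] <- -Inf
    for (k in which(active)) {
      if (k == i) next
      g <- merge_gain(min(i, k), max(i, k))
      gain[min(i, k), max(i, k)] <- g
    }
    n_active <- n_active - 1
  }

  match(member, unique(member))
}
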