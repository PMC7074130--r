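# Independent oracles used across tests. These deliberately avoid the
# package's internal code paths: densities go through solve()/det(),
# pair counts through explicit O(n^2) enumeration, and the agglomeration
# oracle recomputes every candidate merge from scratch.

dmvnorm_naive <- function(y, mu, S) {
  y <- as.numeric(y); mu <- as.numeric(mu)
  d <- length(mu)
  r <- y - mu
  exp(-0.5 * drop(t(r) %*% solve(S, r))) / sqrt(det(2 * pi * S))
}

# unstabilized observed log-likelihood by direct summation
loglik_naive <- function(points, covs, weights, means, comp_covs) {
  n <- nrow(points)
  G <- length(weights)
  total <- 0
  for (i in seq_len(n)) {
    mix <- 0
    for (k in seq_len(G)) {
      mix <- mix + weights[k] *
        dmvnorm_naive(points[i, ], means[k, ], comp_covs[[k]] + covs[, , i])
    }
    total <- total + log(mix)
  }
  total
}

# pair counts by explicit enumeration of all unordered pairs
pair_counts_naive <- function(r, q) {
  n <- length(r)
  a <- b <- cc <- d <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same_r <- r[i] == r[j]
    same_q <- q[i] == q[j]
    if (same_r && same_q) a <- a + 1
    else if (same_r && !same_q) b <- b + 1
    else if (!same_r && same_q) cc <- cc + 1
    else d <- d + 1
  }
  list(a = a, b = b, c = cc, d = d, n = n)
}

# from-scratch greedy classification-likelihood agglomeration: at each stage
# evaluate every candidate merge by recomputing the partition's classification
# log-likelihood directly from the points
greedy_merge_naive <- function(points, G, ridge) {
  n <- nrow(points)
  d <- ncol(points)
  clus <- as.list(seq_len(n))
  cl_ll <- function(idx) {
    Y <- points[idx, , drop = FALSE]
    m <- length(idx)
    mu <- colMeans(Y)
    M <- crossprod(sweep(Y, 2, mu))
    Sg <- M / m + diag(ridge, d)
    sum(log(vapply(seq_len(m), function(i) dmvnorm_naive(Y[i, ], mu, Sg), 0)))
  }
  while (length(clus) > G) {
    best <- c(NA, NA); best_gain <- -Inf
    for (i in seq_len(length(clus) - 1)) for (j in (i + 1):length(clus)) {
      gain <- cl_ll(c(clus[[i]], clus[[j]])) - cl_ll(clus[[i]]) - cl_ll(clus[[j]])
      if (gain > best_gain) { best_gain <- gain; best <- c(i, j) }
    }
    clus[[best[1]]] <- c(clus[[best[1]]], clus[[best[2]]])
    clus[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (k in seq_along(clus)) lab[clus[[k]]] <- k
  # renumber by first occurrence to match the implementation's convention
  match(lab, unique(lab))
}

# small deterministic 2-D dataset with heterogeneous diagonal error covariances
toy_dataset <- function(n = 8, seed = 100) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(n * 2, sd = 2), n, 2)
  covs <- array(0, dim = c(2, 2, n))
  for (i in seq_len(n)) covs[, , i] <- diag(stats::runif(2, 0.2, 2))
  error_dataset(pts, covs)
}

toy_params <- function() {
  mixture_params(c(0.4, 0.6), rbind(c(-1, 0), c(2, 1)),
                 list(matrix(c(2, 0.5, 0.5, 1.5), 2), diag(c(1, 3))))
}
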