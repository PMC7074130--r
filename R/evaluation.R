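#' Pair-agreement counts between two partitions
#'
#' Over all `n(n-1)/2` unordered pairs of observations, counts pairs placed
#' together in both partitions (`a`), together in the first only (`b`),
#' together in the second only (`c`), and apart in both (`d`). Computed from
#' the label cross-tabulation in `O(n + K^2)` rather than by pair
#' enumeration.
#'
#' @param labels_r,labels_q Label vectors of equal length (any atomic type).
#' @return A list of class `pair_counts` with elements `a`, `b`, `c`, `d`,
#'   and `n`.
#' @export
pair_counts <- function(labels_r, labels_q) {
  if (length(labels_r) != length(labels_q)) stop("label vectors must have equal length")
  n <- length(labels_r)
  tab <- table(labels_r, labels_q)
  ch2 <- function(x) x * (x - 1) / 2
  a <- sum(ch2(tab))
  b <- sum(ch2(rowSums(tab))) - a
  cc <- sum(ch2(colSums(tab))) - a
  d <- ch2(n) - a - b - cc
  structure(list(a = a, b = b, c = cc, d = d, n = n), class = "pair_counts")
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("<pair_counts over %d observations: a=%g b=%g c=%g d=%g>\n",
              x$n, x$a, x$b, x$c, x$d))
  invisible(x)
}

.as_pair_counts <- function(x, q = NULL) {
  if (inherits(x, "pair_counts")) return(x)
  if (is.null(q)) stop("supply either a pair_counts object or two label vectors")
  pair_counts(x, q)
}

#' Rand index
#'
#' Fraction of observation pairs on which two partitions agree:
#' `(a + d) / (a + b + c + d)`.
#'
#' @param x A `pair_counts` object, or the first label vector.
#' @param q The second label vector when `x` is a label vector.
#' @return Value in `[0, 1]`.
#' @export
rand_index <- function(x, q = NULL) {
  pc <- .as_pair_counts(x, q)
  (pc$a + pc$d) / (pc$a + pc$b + pc$c + pc$d)
}

#' Adjusted Rand index
#'
#' The Rand index rescaled to have expectation zero under random labelings
#' with the same cluster sizes: with `N = n(n-1)/2` total pairs,
#' `ARI = (N (a + d) - P) / (N^2 - P)` where
#' `P = (a+b)(a+c) + (c+d)(b+d)`. Equals 1 for identical partitions and is
#' close to 0 for independent ones.
#'
#' @inheritParams rand_index
#' @return Value in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(x, q = NULL) {
  pc <- .as_pair_counts(x, q)
  N <- pc$n * (pc$n - 1) / 2
  P <- (pc$a + pc$b) * (pc$a + pc$c) + (pc$c + pc$d) * (pc$b + pc$d)
  (N * (pc$a + pc$d) - P) / (N^2 - P)
}

#' Permutation test for a positive adjusted Rand index
#'
#' Tests whether the observed ARI between two partitions exceeds what random
#' labelings would give, by uniformly permuting one label vector (cluster
#' counts and sizes are preserved automatically) and recomputing the ARI.
#' The p-value uses the add-one convention `(1 + #{ARI* >= ARI_obs}) /
#' (n_perm + 1)`, so it is never exactly zero: the smallest attainable value
#' is `1/(n_perm+1)`.
#'
#' @param labels_r,labels_q Label vectors of equal length.
#' @param n_perm Number of permutations.
#' @param seed Optional RNG seed.
#' @return List with `ari` (observed), `p_value`, `n_perm`.
#' @export
ari_permutation_test <- function(labels_r, labels_q, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_perm < 1) stop("n_perm must be at least 1")
  obs <- adjusted_rand_index(labels_r, labels_q)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (adjusted_rand_index(labels_r, sample(labels_q)) >= obs) hits <- hits + 1L
  }
  list(ari = obs, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Paired permutation test for a difference in ARI
#'
#' Given matched ARI values from two clustering methods on the same
#' replicates, tests `H1: mean(ari_a - ari_b) > 0` by sign-flipping the
#' paired differences (the standard paired exchangeability test):
#' `p = (1 + #{mean* >= mean_obs}) / (n_perm + 1)`.
#'
#' @param ari_a,ari_b Equal-length numeric vectors of paired ARI values
#'   (length at least 2).
#' @param n_perm Number of sign-flip draws.
#' @param seed Optional RNG seed.
#' @return List with `mean_diff`, `p_value`, `n_perm`.
#' @export
paired_ari_test <- function(ari_a, ari_b, n_perm = 999, seed = NULL) {
  if (length(ari_a) != length(ari_b)) stop("paired vectors must have equal length")
  m <- length(ari_a)
  if (m < 2) stop("need at least two pairs")
  if (!is.null(seed)) set.seed(seed)
  diffs <- ari_a - ari_b
  obs <- mean(diffs)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    flip <- sample(c(-1, 1), m, replace = TRUE)
    if (mean(flip * diffs) >= obs) hits <- hits + 1L
  }
  list(mean_diff = obs, p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm)
}

#' Cross-tabulate the hard labels of two fits
#'
#' Side-by-side agreement table of two clusterings of the same data, plus
#' the count of observations the two methods assign differently (after
#' greedily matching cluster labels by maximal overlap).
#'
#' @param fit_a,fit_b Fits with `hard_labels` entries (e.g. `errmix_fit`,
#'   `kerror_fit`) or plain label vectors.
#' @return List with `table` (cross-tabulation), `n_disagree`, and
#'   `matching` (the label map applied to the second fit).
#' @export
label_crosstab <- function(fit_a, fit_b) {
  la <- if (is.list(fit_a)) fit_a$hard_labels %||% fit_a$labels else fit_a
  lb <- if (is.list(fit_b)) fit_b$hard_labels %||% fit_b$labels else fit_b
  if (length(la) != length(lb)) stop("fits cluster different numbers of observations")
  tab <- table(a = la, b = lb)
  # greedy label matching by overlap
  K <- min(nrow(tab), ncol(tab))
  map <- integer(ncol(tab))
  t2 <- tab
  for (s in seq_len(K)) {
    ij <- arrayInd(which.max(t2), dim(t2))
    map[ij[2]] <- ij[1]
    t2[ij[1], ] <- -1
    t2[, ij[2]] <- -1
  }
  map[map == 0] <- setdiff(seq_len(ncol(tab)), map)[seq_len(sum(map == 0))]
  lb_mapped <- map[match(lb, as.integer(colnames(tab)))]
  la_int <- match(la, as.integer(rownames(tab)))
  n_disagree <- sum(la_int != lb_mapped)
  list(table = tab, n_disagree = n_disagree, matching = map)
}
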