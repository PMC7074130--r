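test_that("component density matches closed forms and the quadratic-form oracle", {
  # univariate: standard normal at its mean, then error variance added on top
  expect_equal(component_density(0, 0, 1, 0), dnorm(0), tolerance = 1e-6)
  expect_equal(component_density(0, 0, 1, 3), dnorm(0, sd = 2), tolerance = 1e-6)
  # bivariate value against an independently coded inverse/determinant oracle
  y <- c(1, 1); mu <- c(0, 0)
  sig <- matrix(c(2, 1, 1, 2), 2); lam <- diag(2)
  expect_equal(component_density(y, mu, sig, lam),
               dmvnorm_naive(y, mu, sig + lam), tolerance = 1e-12)
  # log variant is the log of the linear-scale value
  expect_equal(component_density(y, mu, sig, lam, log = TRUE),
               log(component_density(y, mu, sig, lam)))
})

test_that("covariances add: density with error equals error-free density at Sigma+Lambda", {
  set.seed(42)
  for (r in 1:10) {
    mu <- rnorm(2)
    A <- crossprod(matrix(rnorm(4), 2)) + diag(0.1, 2)
    B <- crossprod(matrix(rnorm(4), 2))
    y <- rnorm(2, mu, 2)
    expect_identical(component_density(y, mu, A, B),
                     component_density(y, mu, A + B, matrix(0, 2, 2)))
  }
})

test_that("log component density is maximized exactly at the mean", {
  p <- toy_params()
  mu <- p$means[1, ]
  at_mu <- component_density(mu, mu, p$covs[, , 1], diag(0.3, 2), log = TRUE)
  set.seed(7)
  for (r in 1:20) {
    off <- mu + rnorm(2)
    expect_lt(component_density(off, mu, p$covs[, , 1], diag(0.3, 2), log = TRUE), at_mu)
  }
})

test_that("singular total covariance raises rather than regularizes", {
  expect_error(component_density(c(0, 0), c(0, 0), matrix(0, 2, 2), matrix(0, 2, 2)),
               "singular|positive")
})

test_that("mixture density reduces, sums term by term, and integrates to 1", {
  p <- toy_params()
  lam <- diag(0.4, 2)
  y <- c(0.3, -0.2)
  # G = 1 reduction
  p1 <- mixture_params(1, p$means[1, , drop = FALSE], p$covs[, , 1])
  expect_equal(mixture_density(y, lam, p1),
               component_density(y, p$means[1, ], p$covs[, , 1], lam))
  # identical components: mixture equals either component
  pid <- mixture_params(c(0.5, 0.5), rbind(c(1, 1), c(1, 1)),
                        list(diag(2), diag(2)))
  expect_equal(mixture_density(y, lam, pid),
               component_density(y, c(1, 1), diag(2), lam))
  # mixed case equals the hand-summed two-term oracle
  hand <- p$weights[1] * dmvnorm_naive(y, p$means[1, ], p$covs[, , 1] + lam) +
    p$weights[2] * dmvnorm_naive(y, p$means[2, ], p$covs[, , 2] + lam)
  expect_equal(mixture_density(y, lam, p), hand, tolerance = 1e-12)
  # Monte-Carlo integral over a wide box is 1 within 3 standard errors
  set.seed(11)
  lo <- c(-15, -15); hi <- c(15, 15)
  m <- 40000
  u <- cbind(runif(m, lo[1], hi[1]), runif(m, lo[2], hi[2]))
  vals <- mixture_density(u, lam, p)
  vol <- prod(hi - lo)
  est <- vol * mean(vals)
  se <- vol * sd(vals) / sqrt(m)
  expect_lt(abs(est - 1), 3 * se)
})

test_that("observed log-likelihood is additive, stabilized, and matches the naive oracle", {
  ds <- toy_dataset(n = 4, seed = 5)
  p <- toy_params()
  ll <- observed_loglik(ds, p)
  naive <- loglik_naive(ds$points, ds$covs, p$weights, p$means,
                        list(p$covs[, , 1], p$covs[, , 2]))
  expect_equal(ll, naive, tolerance = 1e-10)
  # duplicating every observation doubles the value
  ds2 <- error_dataset(rbind(ds$points, ds$points),
                       array(c(ds$covs, ds$covs), dim = c(2, 2, 8)))
  expect_equal(observed_loglik(ds2, p), 2 * ll, tolerance = 1e-10)
  # far-outlying points survive through log-sum-exp
  far <- error_dataset(matrix(c(500, 500), 1, 2), diag(0, 2))
  expect_true(is.finite(observed_loglik(far, p)))
})

test_that("complete-data log-likelihood obeys the EM decomposition", {
  ds <- toy_dataset(n = 6, seed = 21)
  p <- toy_params()
  # one-hot z with G = 1 equals the observed log-likelihood
  p1 <- mixture_params(1, p$means[1, , drop = FALSE], p$covs[, , 1])
  z1 <- matrix(1, 6, 1)
  expect_equal(complete_loglik(ds, p1, z1), observed_loglik(ds, p1))
  # with z from the E step: l_obs = l_complete + entropy(z)
  z <- e_step(ds, p)
  ent <- -sum(ifelse(z > 0, z * log(z), 0))
  expect_equal(observed_loglik(ds, p), complete_loglik(ds, p, z) + ent,
               tolerance = 1e-8)
  # hand-computed 2-point, 2-cluster four-term sum
  ds2 <- error_dataset(rbind(c(0, 0), c(2, 1)), diag(0.5, 2))
  zh <- rbind(c(0.3, 0.7), c(0.9, 0.1))
  hand <- 0
  for (i in 1:2) for (k in 1:2) {
    hand <- hand + zh[i, k] *
      log(p$weights[k] * dmvnorm_naive(ds2$points[i, ], p$means[k, ],
                                       p$covs[, , k] + diag(0.5, 2)))
  }
  expect_equal(complete_loglik(ds2, p, zh), hand, tolerance = 1e-10)
  # membership mass on a zero-weight component is an explicit error
  p0 <- mixture_params(c(1, 0), p$means, p$covs)
  expect_error(complete_loglik(ds2, p0, zh), "zero weight")
})
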