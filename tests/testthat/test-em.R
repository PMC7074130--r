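test_that("E step reproduces degenerate and limiting cases", {
  ds <- toy_dataset(n = 10, seed = 3)
  # identical components with uniform weights: all memberships 1/G
  pid <- mixture_params(rep(1 / 3, 3), rbind(c(0, 0), c(0, 0), c(0, 0)),
                        list(diag(2), diag(2), diag(2)))
  z <- e_step(ds, pid)
  expect_equal(z, matrix(1 / 3, 10, 3), tolerance = 1e-12)
  # degenerate weights give deterministic memberships
  p10 <- mixture_params(c(1, 0), rbind(c(0, 0), c(5, 5)), list(diag(2), diag(2)))
  z <- e_step(ds, p10)
  expect_equal(z[, 1], rep(1, 10))
  # rows always sum to 1
  p <- toy_params()
  expect_equal(rowSums(e_step(ds, p)), rep(1, 10), tolerance = 1e-10)
})

test_that("inflating an observation's error covariance drives memberships to the weights", {
  p <- toy_params()
  y <- c(0.5, 0.5)
  big <- error_dataset(matrix(y, 1, 2), diag(1e6, 2))
  z <- e_step(big, p)
  expect_equal(drop(z), p$weights, tolerance = 1e-3)
})

test_that("M-step weight update is the column mean", {
  z <- .row_to_z <- matrix(0, 4, 2)
  z[cbind(1:4, c(1, 1, 1, 2))] <- 1
  expect_equal(m_step_tau(z), c(0.75, 0.25))
  expect_equal(m_step_tau(matrix(0.5, 6, 2)), c(0.5, 0.5))
  set.seed(8)
  raw <- matrix(runif(30), 10, 3)
  zr <- raw / rowSums(raw)
  expect_equal(m_step_tau(zr), colMeans(zr))
})

test_that("M-step mean update solves the precision-weighted estimating equation", {
  ds <- toy_dataset(n = 12, seed = 13)
  z <- runif(12, 0.2, 1)
  sig <- matrix(c(1.5, 0.3, 0.3, 1), 2)
  # common error covariance: reduces to the plain weighted mean
  ds_eq <- error_dataset(ds$points, diag(0.7, 2))
  expect_equal(m_step_mu(ds_eq, z, sig),
               colSums(z * ds$points) / sum(z), tolerance = 1e-10)
  # all weights one and zero errors: the sample mean
  ds0 <- error_dataset(ds$points, diag(0, 2))
  expect_equal(m_step_mu(ds0, rep(1, 12), sig), colMeans(ds$points),
               tolerance = 1e-10)
  # heterogeneous covariances: dense linear-solve oracle
  mu <- m_step_mu(ds, z, sig)
  lhs <- matrix(0, 2, 2); rhs <- numeric(2)
  for (i in 1:12) {
    P <- solve(sig + ds$covs[, , i])
    lhs <- lhs + z[i] * P
    rhs <- rhs + z[i] * P %*% ds$points[i, ]
  }
  expect_equal(mu, drop(solve(lhs, rhs)), tolerance = 1e-10)
  # an all-zero weight vector is an empty cluster
  expect_error(m_step_mu(ds, rep(0, 12), sig), "empty cluster")
})

test_that("M-step covariance update recovers the closed form when errors vanish", {
  set.seed(31)
  Y <- matrix(rnorm(80 * 2), 80, 2) %*% chol(matrix(c(3, 1, 1, 2), 2))
  ds0 <- error_dataset(Y, diag(0, 2))
  z <- runif(80, 0.1, 1)
  shat <- m_step_sigma(ds0, z, diag(2), gtol = 1e-9)
  muw <- colSums(z * Y) / sum(z)
  s19 <- crossprod(sqrt(z) * sweep(Y, 2, muw)) / sum(z)
  expect_equal(matrix(as.numeric(shat), 2, 2), s19, tolerance = 1e-6)
})

test_that("M-step covariance update matches a 1-D grid-search oracle", {
  set.seed(17)
  y <- rnorm(40, sd = 2)
  covs <- array(runif(40, 0.1, 1.5), dim = c(1, 1, 40))
  ds <- error_dataset(matrix(y, ncol = 1), covs)
  z <- runif(40, 0.3, 1)
  shat <- m_step_sigma(ds, z, matrix(4, 1, 1), gtol = 1e-9)
  qfun <- function(s) {
    prec <- 1 / (s + covs[1, 1, ])
    mu <- sum(z * prec * y) / sum(z * prec)
    sum(z * dnorm(y, mu, sqrt(s + covs[1, 1, ]), log = TRUE))
  }
  grid <- seq(1e-3, 10 * var(y), length.out = 4000)
  s_grid <- grid[which.max(vapply(grid, qfun, 0))]
  expect_equal(as.numeric(shat), s_grid, tolerance = diff(grid[1:2]) * 2)
})

test_that("profiled objective is stationary at the returned covariance", {
  ds <- toy_dataset(n = 30, seed = 41)
  z <- runif(30, 0.2, 1)
  shat <- m_step_sigma(ds, z, diag(2, 2), gtol = 1e-9)
  shat <- matrix(as.numeric(shat), 2, 2)
  qfun <- function(svec) {
    s <- matrix(c(svec[1], svec[2], svec[2], svec[3]), 2, 2)
    mu <- m_step_mu(ds, z, s)
    sum(vapply(1:30, function(i) {
      z[i] * log(dmvnorm_naive(ds$points[i, ], mu, s + ds$covs[, , i]))
    }, 0))
  }
  v0 <- c(shat[1, 1], shat[1, 2], shat[2, 2])
  h <- 1e-5
  g <- vapply(1:3, function(j) {
    vp <- v0; vp[j] <- vp[j] + h
    vm <- v0; vm[j] <- vm[j] - h
    (qfun(vp) - qfun(vm)) / (2 * h)
  }, 0)
  expect_lt(sqrt(sum(g^2)), 1e-5)
})

test_that("EM fit ascends, assigns by argmax, and bounds two-group uncertainty", {
  sim <- sim_bernoulli_errors(n = 120, eta = 0.5, seed = 19)
  fit <- errmix_fit(sim$data, G = 2, init = "labels", labels = sim$truth$label)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6))
  expect_equal(fit$hard_labels, apply(fit$z, 1, which.max))
  expect_equal(fit$uncertainty, 1 - apply(fit$z, 1, max))
  expect_true(all(fit$uncertainty <= 0.5 + 1e-12))
  expect_equal(rowSums(fit$z), rep(1, 120), tolerance = 1e-10)
})

test_that("fits are equivariant under observation permutation and label swap", {
  sim <- sim_bernoulli_errors(n = 60, eta = 0.5, seed = 37)
  fit <- errmix_fit(sim$data, G = 2, init = "labels", labels = sim$truth$label)
  # permuting the observations permutes the outputs identically
  set.seed(1); perm <- sample(60)
  dperm <- sim$data[perm, ]
  fitp <- errmix_fit(dperm, G = 2, init = "labels", labels = sim$truth$label[perm])
  expect_equal(fitp$z, fit$z[perm, ], tolerance = 1e-6)
  expect_equal(fitp$loglik, fit$loglik, tolerance = 1e-8)
  # relabeling the initial clusters relabels the solution
  fits <- errmix_fit(sim$data, G = 2, init = "labels", labels = 3 - sim$truth$label)
  expect_equal(fits$loglik, fit$loglik, tolerance = 1e-8)
  expect_equal(fits$z[, c(2, 1)], fit$z, tolerance = 1e-6)
})

test_that("a point with larger error covariance sits closer to the weights", {
  sim <- sim_bernoulli_errors(n = 100, eta = 0.5, seed = 29)
  fit <- errmix_fit(sim$data, G = 2, init = "labels", labels = sim$truth$label)
  y <- fit$params$means[1, ] + c(2, 0.5)
  z_small <- e_step(error_dataset(matrix(y, 1, 2), diag(0.01, 2)), fit$params)
  z_large <- e_step(error_dataset(matrix(y, 1, 2), diag(50, 2)), fit$params)
  tau <- fit$params$weights
  if (max(z_small) > max(tau)) {
    expect_lt(sum(abs(z_large - tau)), sum(abs(z_small - tau)))
  }
})

test_that("an emptied cluster aborts with advice instead of reseeding", {
  set.seed(55)
  pts <- matrix(rnorm(40), 20, 2)
  ds <- error_dataset(pts, diag(0.1, 2))
  # a membership column with no mass is refused by the EM loop
  z0 <- matrix(0, 20, 3)
  z0[1:10, 1] <- 1
  z0[11:20, 2] <- 1
  expect_error(errmix:::.em_run(ds, 3, z0), "empty|initialization")
})
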