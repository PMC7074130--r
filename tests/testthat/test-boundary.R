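# configuration with exact reflection symmetry about the vertical axis:
# mirrored means, equal axis-aligned covariances
mirror_params <- function() {
  mixture_params(c(0.5, 0.5), rbind(c(-3, 0), c(3, 0)),
                 list(diag(c(2, 1.5)), diag(c(2, 1.5))))
}

test_that("classification score vanishes on symmetry axes and favors the near cluster", {
  p <- mirror_params()
  lam <- diag(0.5, 2)
  # mirrored configuration: any point on the vertical axis scores zero
  expect_equal(classification_score(c(0, 1.7), lam, p), 0, tolerance = 1e-12)
  expect_equal(classification_score(c(0, -4), lam, p), 0, tolerance = 1e-12)
  # each fitted center is classified into its own cluster
  expect_gt(classification_score(p$means[1, ], lam, p), 0)
  expect_lt(classification_score(p$means[2, ], lam, p), 0)
  pany <- toy_params()
  expect_error(classification_score(c(0, 0), lam,
                                    mixture_params(1, matrix(0, 1, 2), diag(2))),
               "G = 2")
})

test_that("conic coefficients reproduce the log score exactly", {
  p <- toy_params()
  lam <- matrix(c(0.8, 0.2, 0.2, 0.5), 2)
  cc <- conic_coefficients(lam, p)
  set.seed(107)
  for (r in 1:25) {
    t <- rnorm(2, sd = 4)
    quad <- drop(t %*% cc$M %*% t) + sum(cc$b * t) + cc$c
    expect_equal(quad, classification_score(t, lam, p), tolerance = 1e-10)
  }
  # equal component covariances and shared error: the boundary is a line
  pl <- mirror_params()
  ccl <- conic_coefficients(diag(0.3, 2), pl)
  expect_equal(max(abs(ccl$M)), 0, tolerance = 1e-14)
})

test_that("isotropic unequal variances give a circular boundary", {
  # completing the square: |t|^2 (1/b - 1/a) - 2 mu' t (...) ... oracle below
  a <- 2; b <- 6  # total variances of the two components
  p <- mixture_params(c(0.5, 0.5), rbind(c(0, 0), c(4, 0)),
                      list(diag(a - 1, 2), diag(b - 1, 2)))
  cc <- conic_coefficients(diag(1, 2), p)
  # M proportional to identity => circle; recover center and radius
  expect_equal(cc$M[1, 2], 0, tolerance = 1e-12)
  expect_equal(cc$M[1, 1], cc$M[2, 2], tolerance = 1e-12)
  ctr <- -cc$b / (2 * cc$M[1, 1])
  rad2 <- sum(ctr^2) - cc$c / cc$M[1, 1]
  # oracle by completing the square on the explicit log-ratio
  m <- cc$M[1, 1]
  expect_equal(m, (1 / b - 1 / a) / 2, tolerance = 1e-12)
  # linear term A1^-1 mu1 - A2^-1 mu2
  expect_equal(cc$b, c(0 - 4 / b, 0), tolerance = 1e-12)
  # every point at distance sqrt(rad2) from ctr is on the boundary
  for (ang in c(0, pi / 3, pi, 4)) {
    t <- ctr + sqrt(rad2) * c(cos(ang), sin(ang))
    expect_equal(classification_score(t, diag(1, 2), p), 0, tolerance = 1e-9)
  }
})

test_that("traced boundaries sit at membership one half", {
  p <- toy_params()
  lam <- diag(0.6, 2)
  bd <- trace_boundary_2d(lam, p, window = c(-8, 8, -8, 8), resolution = 101)
  expect_gt(nrow(bd), 10)
  expect_lt(max(abs(bd$score)), 1e-6)
  z <- e_step(error_dataset(as.matrix(bd[, c("y_1", "y_2")]), lam), p)
  expect_lt(max(abs(z[, 1] - 0.5)), 1e-4)
})

test_that("mirrored symmetric case traces the vertical midline", {
  p <- mirror_params()
  bd <- trace_boundary_2d(diag(0.5, 2), p, window = c(-6, 6, -5, 5), resolution = 81)
  expect_lt(max(abs(bd$y_1)), 1e-6)
})

test_that("boundaries depend on the error covariance only through its value", {
  p <- toy_params()
  lam <- matrix(c(0.9, 0.1, 0.1, 0.7), 2)
  b1 <- trace_boundary_2d(lam, p, window = c(-7, 7, -7, 7), resolution = 81)
  b2 <- trace_boundary_2d(lam, p, window = c(-7, 7, -7, 7), resolution = 81)
  expect_identical(b1, b2)
  # swapping cluster labels negates the score but keeps the zero set
  pswap <- mixture_params(p$weights[c(2, 1)], p$means[c(2, 1), ],
                          list(p$covs[, , 2], p$covs[, , 1]))
  set.seed(109)
  for (r in 1:10) {
    t <- rnorm(2, sd = 3)
    expect_equal(classification_score(t, lam, p),
                 -classification_score(t, lam, pswap), tolerance = 1e-10)
  }
})

test_that("a window without sign change yields an empty result with a notice", {
  p <- mirror_params()
  expect_message(
    bd <- trace_boundary_2d(diag(0.5, 2), p, window = c(2, 5, -1, 1),
                            resolution = 31),
    "does not change sign")
  expect_equal(nrow(bd), 0L)
})

test_that("decision_boundary extracts one boundary per distinct error covariance", {
  sim <- sim_bernoulli_errors(n = 80, eta = 0.5, seed = 113)
  fit <- errmix_fit(sim$data, G = 2, init = "labels", labels = sim$truth$label)
  bd <- decision_boundary(fit, resolution = 81)
  expect_true(all(sort(unique(bd$lam_id)) %in% 1:2))
  expect_lt(max(abs(bd$score)), 1e-6)
})
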