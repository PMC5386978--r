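test_that("RVR handles degenerate and exact targets", {
  set.seed(2)
  x <- matrix(rnorm(60), 20, 3)

  # constant target: predictions are identically that constant
  fit_c <- rvr(x, rep(7.5, 20))
  expect_equal(fitted(fit_c), rep(7.5, 20))
  expect_equal(predict(fit_c, matrix(rnorm(9), 3, 3)), rep(7.5, 3))

  # noiseless linear target recovered within 1e-3
  y <- 3 + 2 * x[, 1]
  fit_l <- rvr(x, y)
  expect_lt(max(abs(fitted(fit_l) - y)), 1e-3)

  # deterministic: same inputs, identical fits
  fit_l2 <- rvr(x, y)
  expect_identical(coef(fit_l), coef(fit_l2))

  expect_error(rvr(x[1:2, ], y[1:2]), "at least 3")
  expect_error(rvr(x, c(y[-1], NA)), "finite")
})

test_that("fixed-hyperparameter RVR equals the kernel ridge oracle", {
  # with beta fixed and no updates, the posterior mean must equal ridge
  # regression on the kernel design with per-basis penalties alpha/beta
  set.seed(3)
  n <- 20
  x <- matrix(rnorm(n * 4), n, 4)
  y <- 1.5 + x %*% c(1, -2, 0.5, 0) + rnorm(n, 0, 0.3)
  alpha0 <- 0.37
  beta0 <- 4.2
  fit <- rvr(x, y, max_iter = 0, alpha0 = alpha0, beta0 = beta0,
             update_beta = FALSE, prune_threshold = Inf)

  Phi <- cbind(1, x %*% t(x))
  w_ridge <- solve(crossprod(Phi) + diag(rep(alpha0 / beta0, n + 1)),
                   crossprod(Phi, y))
  expect_lt(max(abs(fit$weights - w_ridge)), 1e-6)
  expect_lt(max(abs(fitted(fit) - Phi %*% w_ridge)), 1e-6)
})

test_that("prediction is linear and consistent with training", {
  set.seed(4)
  x <- matrix(rnorm(36), 12, 3)
  y <- 10 + x %*% c(0.5, 1, -1) + rnorm(12, 0, 0.1)
  fit <- rvr(x, y)

  # a training subject's own features return its fitted value
  expect_equal(predict(fit, x[3, , drop = FALSE]), fitted(fit)[3],
               tolerance = 1e-10)

  # linearity: prediction of a convex combination equals the combination
  z <- 0.3 * x[1, ] + 0.7 * x[2, ]
  expect_equal(predict(fit, matrix(z, 1)),
               0.3 * predict(fit, x[1, , drop = FALSE]) +
                 0.7 * predict(fit, x[2, , drop = FALSE]),
               tolerance = 1e-9)

  # zero feature vector returns the bias term
  expect_equal(predict(fit, matrix(0, 1, 3)), unname(fit$bias),
               tolerance = 1e-12)

  expect_error(predict(fit, matrix(0, 1, 5)), "dimension mismatch")

  # posterior predictive machinery
  pr <- predict(fit, x, se.fit = TRUE)
  expect_true(all(pr$se.fit >= 0))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(12L, 3L))
})

test_that("RVR is sparse on noisy data and matches kernlab's RVM", {
  skip_if_not_installed("kernlab")
  set.seed(6)
  sparse_count <- 0L
  for (s in 1:5) {
    n <- 30
    x <- matrix(rnorm(n * 2), n, 2)
    y <- 5 + x[, 1] + rnorm(n, 0, 0.3)
    fit <- rvr(x, y)
    if (length(fit$relevance_index) < n) sparse_count <- sparse_count + 1L
    # independent implementation agrees on held-out predictions (kernlab's
    # RVM carries no intercept, so it is fitted on the centred response)
    km <- suppressWarnings(kernlab::rvm(x, y - mean(y),
                                        kernel = "vanilladot",
                                        kpar = list(), scaled = FALSE))
    xt <- matrix(rnorm(10), 5, 2)
    expect_lt(mean(abs(predict(fit, xt) -
                         (kernlab::predict(km, xt) + mean(y)))), 0.5)
  }
  # Tipping sparsity: fewer relevance vectors than training points
  expect_gte(sparse_count, 4L)
})
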