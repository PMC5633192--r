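test_that("the RBF kernel follows its closed form and symmetry", {
  expect_equal(rbf_kernel(c(1, 2, 3), c(1, 2, 3), sigma = 0.7), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), sigma = 1), exp(-1))
  expect_equal(rbf_kernel(c(0, 0), c(3, 4), sigma = 5), exp(-1))  # ||d||^2 = sigma^2
  expect_equal(rbf_kernel(c(1, 5), c(2, -1), 2), rbf_kernel(c(2, -1), c(1, 5), 2))
  # widening the kernel drives the value towards 1 monotonically
  vals <- sapply(c(1, 2, 4, 8, 16), function(s) rbf_kernel(0, 3, s))
  expect_true(all(diff(vals) > 0) && vals[5] > 0.9)
  expect_error(rbf_kernel(1, 1, sigma = 0), "sigma")
  expect_error(rbf_kernel(c(1, 2), 1, 1), "length")
})

test_that("Gram matrices are symmetric, unit-diagonal and positive semidefinite", {
  expect_equal(gram_matrix(matrix(3.7), 1), matrix(1))
  set.seed(11)
  x <- matrix(runif(15), 5)
  K <- gram_matrix(x, 0.8)
  expect_equal(K, t(K))
  expect_equal(diag(K), rep(1, 5))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  # duplicated point gives identical rows
  K2 <- gram_matrix(x[c(1, 1, 2), ], 0.8)
  expect_equal(K2[1, ], K2[2, ])
})

test_that("flat targets inside the tube give the all-zero dual solution", {
  x <- matrix(runif(10), 5)
  K <- gram_matrix(x, 1)
  sol <- solve_dual(rep(0.4, 5), K, svr_config(C = 1, epsilon = 0.05, sigma = 1))
  expect_true(sol$converged)
  expect_equal(sol$beta, rep(0, 5))
  expect_equal(sol$iterations, 0L)
})

test_that("the two-point dual matches an exhaustive grid search of the feasible set", {
  # with sum(beta) = 0 the 2-point dual is one-dimensional: beta = (a, -a)
  x <- matrix(c(0, 1), 2)
  K <- gram_matrix(x, 1)
  y <- c(0.3, 0.9)  # symmetric about 0.6
  C <- 1
  eps <- 0.05
  sol <- solve_dual(y, K, svr_config(C = C, epsilon = eps, sigma = 1,
                                     kkt_tolerance = 1e-10))
  a_grid <- seq(-C, C, by = 1e-4)
  obj <- 0.5 * (K[1, 1] + K[2, 2] - 2 * K[1, 2]) * a_grid^2 +
    2 * eps * abs(a_grid) - (y[1] - y[2]) * a_grid
  expect_lte(sol$objective, min(obj) + 1e-6)
  expect_gte(sol$objective, min(obj) - 1e-6)
})

test_that("the SMO solver matches the exact enumeration oracle on random small instances", {
  set.seed(101)
  for (rep in 1:12) {
    inst <- random_svr_instance()
    K <- gram_matrix(inst$x, inst$sigma)
    cfg <- svr_config(C = inst$C, epsilon = inst$epsilon, sigma = inst$sigma,
                      kkt_tolerance = 1e-8)
    sol <- solve_dual(inst$y, K, cfg)
    oracle <- qp_enum_oracle(inst$y, K, inst$C, inst$epsilon)
    expect_true(sol$converged)
    expect_equal(sol$objective, oracle$objective, tolerance = 1e-6)
    # dual feasibility, equality constraint, complementarity
    expect_true(all(sol$alpha >= 0 & sol$alpha <= inst$C + 1e-9))
    expect_true(all(sol$alpha_star >= 0 & sol$alpha_star <= inst$C + 1e-9))
    expect_lt(abs(sum(sol$beta)), 1e-9)
    expect_equal(sol$alpha * sol$alpha_star, rep(0, length(inst$y)))
  }
})

test_that("non-convergence within the update cap is flagged", {
  set.seed(5)
  x <- matrix(runif(40), 20)
  y <- runif(20)
  K <- gram_matrix(x, 0.5)
  cfg <- svr_config(C = 100, epsilon = 0.001, sigma = 0.5, max_passes = 2L)
  expect_warning(sol <- solve_dual(y, K, cfg), "did not converge")
  expect_false(sol$converged)
  expect_gt(sol$max_violation, 0)
})

test_that("the bias averages the standard-support-vector boundary conditions consistently", {
  # symmetric two-point problem: the fitted bias is the target mean
  x <- matrix(c(0, 1), 2)
  K <- gram_matrix(x, 1)
  y <- c(0.2, 1.0)
  cfg <- svr_config(C = 10, epsilon = 0.05, sigma = 1, kkt_tolerance = 1e-10)
  sol <- solve_dual(y, K, cfg)
  bias <- compute_bias(sol, K, y, cfg$epsilon, cfg$C)
  expect_equal(bias$b, mean(y), tolerance = 1e-8)
  oracle <- qp_enum_oracle(y, K, cfg$C, cfg$epsilon)
  expect_equal(sol$objective, oracle$objective, tolerance = 1e-9)

  # all standard support vectors' individual estimates agree within 10 * tol
  set.seed(77)
  x <- matrix(runif(30), 15)
  y <- sin(4 * x[, 1]) + 0.4 * x[, 2]
  cfg <- svr_config(C = 5, epsilon = 0.02, sigma = 0.7, kkt_tolerance = 1e-8)
  K <- gram_matrix(x, cfg$sigma)
  sol <- solve_dual(y, K, cfg)
  beta <- sol$beta
  d <- y - as.numeric(K %*% beta)
  margin <- 1e-10 * cfg$C
  est <- c(d[beta > margin & beta < cfg$C - margin] - cfg$epsilon,
           d[beta < -margin & beta > -cfg$C + margin] + cfg$epsilon)
  expect_gt(length(est), 0)
  expect_lt(max(est) - min(est), 10 * cfg$kkt_tolerance)

  # no standard support vectors (flat data): fallback midpoint with warning
  yflat <- rep(0.5, 5)
  Kf <- gram_matrix(matrix(1:5 / 5), 1)
  solf <- solve_dual(yflat, Kf, svr_config(C = 1, epsilon = 0.1, sigma = 1))
  expect_warning(bf <- compute_bias(solf, Kf, yflat, 0.1, 1), "no standard")
  expect_equal(bf$b, 0.5)
  expect_identical(bf$n_standard_sv, 0L)
})

test_that("prediction is the kernel expansion over support vectors", {
  # hand-built model with one support vector
  m <- structure(list(x_sv = matrix(c(0, 0), 1), beta_sv = 1, b = 0, sigma = 1,
                      config = svr_config(sigma = 1), scaling = NULL,
                      diagnostics = list()),
                 class = "welan_svr")
  expect_equal(predict(m, matrix(c(1, 0), 1)), exp(-1))
  expect_equal(predict(m, matrix(c(0, 0), 1)), 1)
  expect_error(predict(m, matrix(1, 1, 3)), "columns")

  # no support vectors: constant b (the flat fit warns about the bias fallback)
  mflat <- suppressWarnings(
    svr_fit(matrix(1:6 / 6), rep(0.3, 6), svr_config(epsilon = 0.05)))
  expect_equal(mflat$diagnostics$n_sv, 0L)
  expect_equal(predict(mflat, matrix(c(0.1, 0.9))), c(0.3, 0.3))
})

test_that("free support vectors sit exactly on the tube boundary", {
  set.seed(31)
  for (rep in 1:5) {
    x <- matrix(runif(30), 15)
    y <- cos(3 * x[, 1]) * x[, 2] + rnorm(15, 0, 0.1)
    cfg <- svr_config(C = 8, epsilon = 0.05, sigma = 0.8, kkt_tolerance = 1e-8)
    m <- svr_fit(x, y, cfg)
    sol <- solve_dual(y, gram_matrix(x, cfg$sigma), cfg)
    resid <- predict(m, x) - y
    margin <- 1e-10 * cfg$C
    free <- (sol$beta > margin & sol$beta < cfg$C - margin) |
      (sol$beta < -margin & sol$beta > -cfg$C + margin)
    expect_gt(sum(free), 0)
    expect_lt(max(abs(abs(resid[free]) - cfg$epsilon)), 10 * cfg$kkt_tolerance)
  }
})

test_that("fitting is deterministic and matches oracle predictions on a toy set", {
  set.seed(13)
  x <- matrix(runif(10), 5)
  y <- runif(5)
  cfg <- svr_config(C = 2, epsilon = 0.03, sigma = 1, kkt_tolerance = 1e-9)
  m1 <- svr_fit(x, y, cfg)
  m2 <- svr_fit(x, y, cfg)
  expect_identical(m1$beta_sv, m2$beta_sv)
  expect_identical(m1$b, m2$b)

  oracle <- qp_enum_oracle(y, gram_matrix(x, cfg$sigma), cfg$C, cfg$epsilon)
  K <- gram_matrix(x, cfg$sigma)
  pred_oracle <- as.numeric(K %*% oracle$beta) + m1$b
  expect_equal(predict(m1, x), pred_oracle, tolerance = 1e-5)

  # targets within epsilon of a constant: the model predicts inside the tube
  y2 <- 0.5 + runif(5, -0.01, 0.01)
  m3 <- suppressWarnings(svr_fit(x, y2, svr_config(C = 1, epsilon = 0.05, sigma = 1)))
  expect_true(all(abs(predict(m3, x) - y2) <= 0.05 + 1e-8))
})

test_that("widening the tube never recruits more support vectors", {
  set.seed(19)
  x <- matrix(runif(40), 20)
  y <- sin(5 * x[, 1]) + rnorm(20, 0, 0.05)
  n_sv <- sapply(c(0.005, 0.02, 0.05, 0.1, 0.2), function(eps) {
    svr_fit(x, y, svr_config(C = 5, epsilon = eps, sigma = 0.7))$diagnostics$n_sv
  })
  expect_true(all(diff(n_sv) <= 0))
})

test_that("duplicating a non-support training point leaves predictions unchanged", {
  set.seed(23)
  x <- matrix(runif(24), 12)
  y <- x[, 1] + 0.3 * x[, 2] + rnorm(12, 0, 0.02)
  cfg <- svr_config(C = 5, epsilon = 0.1, sigma = 1, kkt_tolerance = 1e-9)
  m <- svr_fit(x, y, cfg)
  sol <- solve_dual(y, gram_matrix(x, cfg$sigma), cfg)
  non_sv <- which(abs(sol$beta) <= 1e-8)
  expect_gt(length(non_sv), 0)
  i <- non_sv[1]
  m_dup <- svr_fit(rbind(x, x[i, ]), c(y, y[i]), cfg)
  grid <- matrix(runif(20), 10)
  expect_equal(predict(m_dup, grid), predict(m, grid), tolerance = 1e-6)
})

test_that("models survive the JSON round trip bit-identically", {
  set.seed(3)
  x <- matrix(runif(20), 10)
  y <- runif(10)
  sc <- make_scaling(stats::setNames(rep(0, 10), c(condition_names(), "production")),
                     stats::setNames(rep(1, 10), c(condition_names(), "production")))
  m <- svr_fit(x, y, svr_config(C = 3, epsilon = 0.02, sigma = 0.9), scaling = sc)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  got <- read_model(path)
  expect_equal(got$beta_sv, m$beta_sv)
  expect_equal(got$b, m$b)
  expect_equal(predict(got, x), predict(m, x))
})
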