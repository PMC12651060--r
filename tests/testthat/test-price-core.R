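test_that("delta_mean evaluates the change in the weighted mean", {
  pop <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.25, 0.75))
  expect_equal(delta_mean(pop), 0.25)

  pop0 <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.5, 0.5))
  expect_equal(delta_mean(pop0), 0)

  pop2 <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.25, 0.75),
                     updated_traits = c(0.2, 1.0))
  expect_equal(delta_mean(pop2), 0.30)
})

test_that("population constructor enforces its invariants", {
  expect_error(population(c(0.5, 0.4), c(0, 1), fitness = c(1, 1)), "sum to 1")
  expect_error(population(c(0.5, 0.5), c(0, 1), fitness = c(0.2, 1.2)), "mean fitness")
  expect_error(population(c(0.5, 0.5, 0), c(0, 1, 2), fitness = rep(1, 3)),
               "strictly positive")
  expect_error(population(c(0.5, 0.5), c(0, 1), fitness = c(0.5, 1.5),
                          updated_weights = c(0.3, 0.7)), "inconsistent")
  # raw performance values are accepted with normalize and kept as attribute
  pop <- population(c(0.5, 0.5), c(0, 1), fitness = c(2, 6), normalize = TRUE)
  expect_equal(sum(pop$weights * pop$fitness), 1)
  expect_equal(attr(pop, "raw_fitness"), c(2, 6))
})

test_that("price_partition splits mean change into selection and transmission", {
  pop <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.25, 0.75),
                    updated_traits = c(0.2, 1.0))
  pp <- price_partition(pop)
  expect_equal(pp$selection, 0.25)
  expect_equal(pp$transmission, 0.05)

  # no selection when fitness is flat
  flat <- population(c(0.3, 0.7), c(1, 4), fitness = c(1, 1),
                     updated_traits = c(2, 5))
  expect_equal(price_partition(flat)$selection, 0)

  # no transmission when traits do not change
  sel <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.25, 0.75))
  expect_equal(price_partition(sel)$transmission, 0)
})

test_that("exact Price partition holds over random populations with transmission", {
  set.seed(101)
  for (i in 1:200) {
    m <- sample(3:30, 1)
    n <- sample(1:4, 1)
    pop <- generate_population(m, n, fitness_model = "linear",
                               delta = sample(c("none", "gamma", "correlated"), 1))
    pp <- price_partition(pop)
    total <- delta_mean(pop)
    expect_equal(pp$selection + pp$transmission, total, tolerance = 1e-10)
  }
})

test_that("weighted regression solves the q-weighted normal equations", {
  fit <- weighted_regression(c(0.5, 1.5), c(0, 1), c(0.5, 0.5))
  expect_equal(fit$coefficients, 1.0)
  expect_false(fit$singular)

  # constant response carries no slope
  fitc <- weighted_regression(rep(2, 5), matrix(rnorm(10), 5, 2), rand_simplex(5))
  expect_equal(fitc$coefficients, c(0, 0), tolerance = 1e-12)

  # residual orthogonality to centered predictors, random cases
  set.seed(42)
  for (i in 1:20) {
    m <- sample(5:40, 1); n <- sample(1:3, 1)
    q <- rand_simplex(m)
    X <- matrix(rnorm(m * n), m, n)
    y <- rnorm(m)
    fit <- weighted_regression(y, X, q)
    xbar <- as.numeric(crossprod(q, X))
    for (j in seq_len(n)) {
      expect_lt(abs(sum(q * fit$residuals * (X[, j] - xbar[j]))), 1e-10)
    }
  }
})

test_that("rank-deficient predictors take the pseudoinverse path but keep the Mf identity", {
  set.seed(7)
  m <- 20
  q <- rand_simplex(m)
  x <- rnorm(m)
  X <- cbind(x, x)                       # duplicated column
  w <- exp(0.5 * x); w <- w / sum(q * w)
  fit <- weighted_regression(w, X, q)
  expect_true(fit$singular)
  Cxx <- covariance_from_deviations(population(q, X, fitness = w))
  cov_wx <- sapply(1:2, function(j) sum(q * (w - 1) * X[, j]))
  expect_equal(as.numeric(Cxx %*% fit$coefficients), cov_wx, tolerance = 1e-8)
})

test_that("fmb_decompose reproduces both Price terms as metric-force and bias", {
  pop <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.25, 0.75))
  d <- fmb_decompose(pop)
  expect_equal(as.numeric(d$metric), 0.25)
  expect_equal(d$force, 1.0)
  expect_equal(d$transmission_term, 0)

  # constant trait shift: pure intrinsic bias, no fitness-covariant part
  popc <- population(c(0.4, 0.6), c(0, 1), updated_weights = c(0.3, 0.7),
                     updated_traits = c(0, 1) + 0.5)
  dc <- fmb_decompose(popc)
  expect_equal(as.numeric(dc$bias_metric), 0)
  expect_equal(dc$intrinsic_bias, 0.5)
  expect_equal(as.numeric(dc$bias_metric %*% dc$bias_slope) + dc$intrinsic_bias,
               dc$transmission_term, tolerance = 1e-10)

  # random population: Mf + C beta + gamma equals the direct mean change
  set.seed(11)
  pop3 <- generate_population(50, 3, fitness_model = "linear", delta = "correlated")
  d3 <- fmb_decompose(pop3)
  Mf <- as.numeric(d3$metric %*% d3$force)
  Cb <- as.numeric(d3$bias_metric %*% d3$bias_slope)
  expect_equal(Mf, d3$selection_term, tolerance = 1e-8)
  expect_equal(Cb + d3$intrinsic_bias, d3$transmission_term, tolerance = 1e-8)
  expect_equal(Mf + Cb + d3$intrinsic_bias, delta_mean(pop3), tolerance = 1e-8)

  s <- summary(d3)
  expect_lt(s$residual_selection, 1e-10)
  expect_lt(s$residual_transmission, 1e-10)
})

test_that("expected_gain is the quadratic form in the force", {
  expect_equal(expected_gain(matrix(0.25), 1), 0.25)
  expect_equal(expected_gain(diag(3), c(0, 0, 0)), 0)
  f <- c(1, -2, 3)
  expect_equal(expected_gain(diag(3), f), sum(f^2))
  expect_error(expected_gain(matrix(c(1, 2, 0, 1), 2, 2), c(1, 1)), "symmetric")
})

test_that("deviation-form covariance equals the direct weighted covariance", {
  pop <- population(c(0.5, 0.5), c(0, 1), updated_weights = c(0.25, 0.75))
  expect_equal(as.numeric(covariance_from_deviations(pop)), 0.25)

  # identical rows give the zero matrix
  same <- population(rand_simplex(4), matrix(2, 4, 2), fitness = rep(1, 4))
  expect_equal(covariance_from_deviations(same), matrix(0, 2, 2))

  set.seed(12)
  pop2 <- generate_population(20, 4, fitness_model = "boltzmann")
  direct <- fmb_decompose(pop2)$metric
  expect_equal(covariance_from_deviations(pop2), direct, tolerance = 1e-10)
})

test_that("using fitness as the trait links the selection term to Var(w) and F", {
  set.seed(13)
  for (i in 1:20) {
    q <- rand_simplex(sample(3:15, 1))
    w <- rgamma(length(q), 3) + 0.1
    w <- w / sum(q * w)
    pop <- population(q, matrix(w, ncol = 1), fitness = w)
    sel <- price_partition(pop)$selection
    varw <- sum(q * w^2) - 1
    dq <- q * w - q
    expect_equal(sel, varw, tolerance = 1e-10)
    expect_equal(sel, sum(dq^2 / q), tolerance = 1e-10)
  }
})

test_that("rescaling one trait column leaves the metric-force product invariant", {
  set.seed(14)
  pop <- generate_population(30, 3, fitness_model = "linear", noise_sd = 0.05)
  d <- fmb_decompose(pop)
  k <- 7
  theta2 <- pop$traits; theta2[, 2] <- k * theta2[, 2]
  pop2 <- population(pop$weights, theta2, fitness = pop$fitness)
  d2 <- fmb_decompose(pop2)
  expect_equal(d2$force[2], d$force[2] / k, tolerance = 1e-8)
  expect_equal(d2$metric[2, ], d$metric[2, ] * c(k, k^2, k), tolerance = 1e-8)
  expect_equal(as.numeric(d2$metric %*% d2$force),
               as.numeric(d$metric %*% d$force) * c(1, k, 1), tolerance = 1e-8)
})
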