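test_that("every optimizer step reproduces itself from its FMB fields", {
  set.seed(41)
  A <- rand_spd(3)
  s <- quad_surface(A)
  th <- rnorm(3)
  steps <- list(
    gd_step(s, th, 0.1),
    newton_step(s, th),
    natural_gradient_step(s, th, rand_spd(3)),
    mirror_step_first_order(s, abs(th) + 0.5, mirror_potential("entropy"), 0.2),
    regularized_gd_step(s, th, 0.1, 0.5),
    sgld_step(s, th, rand_spd(3), 0.05)
  )
  st <- optimizer_state(th)
  steps <- c(steps, list(polyak_step(st, s, 0.1, 0.9)$step,
                         adam_paper_step(st, s, 0.1, 0.9, 0.999)$step))
  for (stp in steps) {
    recon <- as.numeric(stp$metric %*% stp$force) + stp$bias_metric_part +
      stp$intrinsic_bias + stp$noise
    expect_equal(stp$step, recon, tolerance = 1e-12)
  }
  # a forged step is rejected by the audit
  expect_error(fmb_step(diag(2), c(1, 1), step = c(2, 2)), "audit")
})

test_that("gradient step follows the orientation and scales with eta", {
  s <- quad_surface(diag(2))
  expect_equal(gd_step(s, c(0, 0), 0.1)$step, c(0, 0))
  expect_equal(gd_step(s, c(1, 0), 0.1)$step, c(-0.1, 0))
  smin <- performance_surface(s$evaluate, s$gradient, s$hessian,
                              orientation = "minimize")
  expect_equal(gd_step(smin, c(1, 0), 0.1)$step, c(0.1, 0))
})

test_that("Newton lands on the maximizer of a concave quadratic in one step", {
  # U = -1/2 t't + a't, maximizer a
  a <- c(3, -1)
  s <- performance_surface(function(t) -0.5 * sum(t^2) + sum(a * t),
                           function(t) -t + a,
                           function(t) -diag(2))
  ns <- newton_step(s, c(0, 0))
  expect_equal(ns$step, a)
  expect_equal(newton_step(s, a)$step, c(0, 0))
  # indefinite curvature in the maximize orientation is refused without damping
  convex <- performance_surface(function(t) 0.5 * sum(t^2),
                                function(t) t, function(t) diag(2))
  expect_error(newton_step(convex, c(1, 1)), class = "MetricNotPD")
  expect_silent(newton_step(convex, c(1, 1), lambda = 2))
})

test_that("the Newton direction maximizes the second-order model at fixed metric length", {
  set.seed(42)
  for (rep in 1:3) {
    A <- rand_spd(3)
    s <- quad_surface(A)
    th <- rnorm(3)
    newton <- newton_step(s, th)$step
    gain_n <- quadratic_model_gain(s, th, newton)
    # exactness on the quadratic itself
    expect_equal(gain_n, s$evaluate(th + newton) - s$evaluate(th),
                 tolerance = 1e-10)
    expect_equal(quadratic_model_gain(s, th, numeric(3)), 0)
    len <- as.numeric(crossprod(newton, A %*% newton))
    for (i in 1:200) {
      d <- rnorm(3)
      d <- d * sqrt(len / as.numeric(crossprod(d, A %*% d)))
      expect_lte(quadratic_model_gain(s, th, d), gain_n + 1e-10)
    }
  }
})

test_that("BFGS secant updates recover the true inverse curvature on quadratics", {
  set.seed(43)
  A <- rand_spd(3)
  s <- quad_surface(A)
  st <- optimizer_state(rep(0, 3))
  th <- c(1, 2, -1)
  for (i in 1:3) {
    g <- s$gradient(th)
    d <- as.numeric(st$inverse_metric_estimate %*% g)
    alpha <- sum(d * g) / as.numeric(crossprod(d, A %*% d))  # exact line search
    stp <- alpha * d
    th2 <- th + stp
    st <- bfgs_metric_update(st, stp, s$gradient(th2) - g)
    # secant equation holds for the most recent pair
    y <- -(s$gradient(th2) - g)
    expect_equal(as.numeric(st$inverse_metric_estimate %*% y), stp,
                 tolerance = 1e-10)
    ev <- eigen(st$inverse_metric_estimate, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    th <- th2
  }
  expect_equal(st$inverse_metric_estimate, solve(A), tolerance = 1e-6)
  expect_equal(th, rep(0, 3), tolerance = 1e-8)

  # flat direction: update skipped, state unchanged
  before <- st$inverse_metric_estimate
  st2 <- bfgs_metric_update(st, c(1, 0, 0), c(0, 0, 0))
  expect_true(st2$skipped_update)
  expect_equal(st2$inverse_metric_estimate, before)
})

test_that("natural gradient reduces to gradient and Newton in the limiting metrics", {
  set.seed(44)
  A <- rand_spd(2)
  s <- quad_surface(A)
  th <- c(1, -1)
  expect_equal(natural_gradient_step(s, th, diag(2))$step,
               gd_step(s, th, 1)$step)
  # diagonal metric scales each force component by its inverse
  expect_equal(natural_gradient_step(quad_surface(diag(2)), c(1, 1),
                                     diag(c(2, 0.5)))$step,
               c(-0.5, -2))
  # Boltzmann Fisher of a quadratic is the constant negative Hessian, so the
  # natural-gradient step equals the Newton step
  grid <- as.matrix(expand.grid(seq(-3, 3, 0.5), seq(-3, 3, 0.5)))
  G <- boltzmann_fisher(s, grid)
  expect_equal(G, A, tolerance = 1e-12)
  expect_equal(natural_gradient_step(s, th, G)$step, newton_step(s, th)$step,
               tolerance = 1e-6)
  expect_error(natural_gradient_step(s, th, matrix(c(1, 2, 2, 1), 2, 2)),
               "positive definite")
})

test_that("Boltzmann-weighted Fisher matrix converges in the grid and temperature limits", {
  # 1-D quartic: grid refinement agreement
  s <- generate_surface("quartic1d", a = 1)
  g1 <- boltzmann_fisher(s, seq(-4, 4, by = 0.02))
  g2 <- boltzmann_fisher(s, seq(-4, 4, by = 0.01))
  expect_equal(as.numeric(g1), as.numeric(g2), tolerance = 1e-4)
  # large inverse temperature concentrates at the maximizer (0), where -H = a
  ghot <- boltzmann_fisher(s, seq(-4, 4, by = 0.005), inv_temp = 200)
  expect_equal(as.numeric(ghot), 1, tolerance = 0.05)
})

test_that("mirror steps match their closed forms and differ at second order", {
  surf <- const_grad_surface(c(0.1, -0.1))
  pot <- mirror_potential("entropy")
  expect_equal(mirror_step_first_order(surf, c(1, 2), pot, 1)$step, c(0.1, -0.2))
  expect_equal(mirror_step_exact(surf, c(1, 2), pot, 1),
               c(1, 2) * exp(c(0.1, -0.1)), tolerance = 1e-12)
  # quadratic potential: linear mirror map, first order is exact for all eta
  potq <- mirror_potential("quadratic")
  for (eta in c(0.1, 1, 3)) {
    expect_equal(mirror_step_exact(surf, c(1, 2), potq, eta),
                 c(1, 2) + mirror_step_first_order(surf, c(1, 2), potq, eta)$step)
  }
  # eta ladder: discrepancy between exact and first-order shrinks ~4x per halving
  disc <- sapply(c(0.2, 0.1, 0.05), function(eta) {
    ex <- mirror_step_exact(surf, c(1, 2), pot, eta)
    fo <- c(1, 2) + mirror_step_first_order(surf, c(1, 2), pot, eta)$step
    max(abs(ex - fo))
  })
  expect_equal(disc[1] / disc[2], 4, tolerance = 0.3)
  expect_equal(disc[2] / disc[3], 4, tolerance = 0.3)
})

test_that("regularized steps balance the gradient force against prior shrinkage", {
  flat <- const_grad_surface(c(0, 0))
  th <- c(2, -1)
  expect_equal(regularized_gd_step(flat, th, 0.1, 0.5)$step, -0.05 * th)
  # U = -1/2 (t - 2)^2 with lambda = 1, prior 0: fixed point at t = 1
  s <- performance_surface(function(t) -0.5 * (t - 2)^2,
                           function(t) -(t - 2),
                           function(t) matrix(-1, 1, 1))
  t <- 0
  for (i in 1:500) t <- t + regularized_gd_step(s, t, 0.1, 1)$step
  expect_equal(t, 1, tolerance = 1e-8)
})

test_that("momentum step splits into fresh-gradient force and coasting bias", {
  s <- const_grad_surface(c(1, 0))
  st <- optimizer_state(c(0, 0), momentum = c(0, 1))
  out <- polyak_step(st, s, 0.1, 0.9)
  expect_equal(out$step$step, c(0.01, 0.09))
  expect_equal(as.numeric(out$step$metric %*% out$step$force), c(0.01, 0))
  expect_equal(out$step$intrinsic_bias, c(0, 0.09))
  # u = 0: plain gradient step
  out0 <- polyak_step(optimizer_state(c(0, 0)), s, 0.1, 0)
  expect_equal(out0$step$step, c(0.1, 0))
  # zero gradient, nonzero momentum: pure coasting
  sz <- const_grad_surface(c(0, 0))
  outc <- polyak_step(optimizer_state(c(0, 0), momentum = c(2, -2)), sz, 0.1, 0.5)
  expect_equal(outc$step$step, 0.1 * 0.5 * c(2, -2))
})

test_that("adaptive-metric momentum decomposition equals its closed form", {
  s1 <- const_grad_surface(1)
  out <- adam_paper_step(optimizer_state(0), s1, eta = 0.1, u = 0.9,
                         s = 0.999, c = 1e-8)
  expect_equal(out$step$step, 0.1 * 0.1 / ((0.001 + 1e-8) * 0.1),
               tolerance = 1e-12)
  # zero gradient, zero momentum: no step
  out0 <- adam_paper_step(optimizer_state(0), const_grad_surface(0),
                          eta = 0.1, u = 0.9, s = 0.9)
  expect_equal(out0$step$step, 0)
  # u = 0: metric-only adaptive gradient
  outm <- adam_paper_step(optimizer_state(0, second_moment = 0.5), s1,
                          eta = 0.1, u = 0, s = 0.5, c = 0.01)
  expect_equal(outm$step$step, 0.1 * 1 / (0.5 * 1 + 0.5 * 0.5 + 0.01))
  # 1000 random tuples: decomposed step equals the closed form
  set.seed(45)
  for (i in 1:1000) {
    g <- rnorm(2); m0 <- rnorm(2); v0 <- rgamma(2, 2)
    eta <- runif(1, 0.01, 1); u <- runif(1, 0, 0.99)
    sq <- runif(1, 0, 0.999); cc <- 10^runif(1, -8, -2)
    st <- optimizer_state(c(0, 0), momentum = m0, second_moment = v0)
    out <- adam_paper_step(st, const_grad_surface(g), eta, u, sq, cc)
    m1 <- (1 - u) * g + u * m0
    v1 <- (1 - sq) * g^2 + sq * v0
    expect_equal(out$step$step, eta * m1 / ((v1 + cc) * (1 - u)),
                 tolerance = 1e-12)
  }
})

test_that("Langevin noise is seed-reproducible with the documented covariance scale", {
  s <- quad_surface(diag(2))
  expect_equal(sgld_step(s, c(1, 1), diag(2), 0)$step, c(0, 0))
  set.seed(46)
  a <- sgld_step(s, c(1, 1), diag(2), 0.05)
  set.seed(46)
  b <- sgld_step(s, c(1, 1), diag(2), 0.05)
  expect_identical(a$noise, b$noise)
  expect_equal(a$step - a$noise, as.numeric(0.05 * diag(2) %*% s$gradient(c(1, 1))))
  # moderate-sample covariance check (the full-scale one runs in the
  # acceptance suite)
  set.seed(47)
  M <- diag(c(1, 4)); eta <- 0.05
  draws <- t(replicate(20000, sgld_step(s, c(0, 0), M, eta)$noise))
  emp <- cov(draws)
  se <- sqrt(2 / nrow(draws)) * diag(2 * eta * M)
  expect_true(all(abs(diag(emp) - diag(2 * eta * M)) < 4 * se))
  expect_error(sgld_step(s, c(0, 0), matrix(c(1, 2, 2, 1), 2, 2), 0.1),
               "positive definite")
})

test_that("minibatch gradients split into full-data signal plus zero-mean noise", {
  set.seed(48)
  G <- matrix(rnorm(500 * 2), 500, 2)
  full <- sgd_split(G, 1:500)
  expect_equal(full$noise, c(0, 0))
  expect_equal(full$signal, colMeans(G))
  one <- sgd_split(G, 7)
  expect_equal(one$noise, G[7, ] - colMeans(G))
  expect_error(sgd_split(G, integer(0)), "empty")
  # variance halves as batch size doubles (up to the finite-population factor)
  vb <- sapply(c(10, 40), function(B) {
    reps <- replicate(3000, sgd_split(G, sample.int(500, B))$noise[1])
    var(reps)
  })
  fpc <- function(B, N = 500) (1 / B) * (N - B) / (N - 1)
  expect_equal(vb[1] / vb[2], fpc(10) / fpc(40), tolerance = 0.2)
})
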