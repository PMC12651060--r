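test_that("bayes_update normalizes the likelihood to a fitness and forms the posterior", {
  db <- bayes_update(c(0.5, 0.5), c(2, 1))
  expect_equal(db$posterior, c(2 / 3, 1 / 3))
  expect_equal(db$log_evidence, log(1.5))
  expect_equal(sum(db$prior * db$norm_likelihood), 1, tolerance = 1e-12)

  flat <- bayes_update(c(0.2, 0.8), c(3, 3))
  expect_equal(flat$posterior, flat$prior)

  conc <- bayes_update(c(0.99, 0.01), c(1, 100))
  expect_equal(conc$posterior, c(0.99, 1) / 1.99, tolerance = 1e-12)
  expect_equal(conc$posterior, c(0.4975, 0.5025), tolerance = 1e-3)

  expect_error(bayes_update(c(0.5, 0.5), c(0, 0)), "strictly positive")
})

test_that("direct likelihood gain equals the squared Fisher-Rao step", {
  db <- bayes_update(c(0.5, 0.5), c(2, 1))
  expect_equal(likelihood_gain(db), 1 / 9, tolerance = 1e-12)
  expect_equal(likelihood_gain(bayes_update(c(0.3, 0.7), c(1, 1))), 0)
  set.seed(31)
  for (i in 1:25) {
    db <- rand_bayes(sample(2:12, 1))
    fc <- frequency_change(db$prior, db$posterior)
    expect_equal(likelihood_gain(db), fisher_rao_sq(fc), tolerance = 1e-12)
  }
})

test_that("sequential updates compose multiplicatively in the likelihood", {
  set.seed(32)
  for (i in 1:10) {
    q <- rand_simplex(8)
    L1 <- rgamma(8, 2) + 0.1
    L2 <- rgamma(8, 2) + 0.1
    two_step <- bayes_update(bayes_update(q, L1)$posterior, L2)$posterior
    one_step <- bayes_update(q, L1 * L2)$posterior
    expect_equal(two_step, one_step, tolerance = 1e-12)
  }
})

test_that("ELBO equals log evidence minus divergence from the posterior", {
  db <- bayes_update(c(0.5, 0.5), c(2, 1))
  at_post <- elbo(db, db$posterior)
  expect_equal(at_post$elbo, log(1.5), tolerance = 1e-12)
  expect_equal(at_post$free_energy, 0, tolerance = 1e-12)

  at_prior <- elbo(db, db$prior)
  expect_equal(at_prior$elbo, 0.5 * log(2), tolerance = 1e-12)

  set.seed(33)
  for (i in 1:25) {
    db <- rand_bayes(6)
    cand <- rand_simplex(6)
    st <- elbo(db, cand)
    expect_equal(st$elbo + st$kl_to_posterior, db$log_evidence, tolerance = 1e-10)
    expect_lte(st$elbo, db$log_evidence + 1e-12)
  }
})

test_that("ELBO change splits into direct data force and prior context cost", {
  db <- bayes_update(c(0.5, 0.5), c(2, 1))
  dec <- elbo_price_decomposition(db, db$posterior)
  expect_equal(dec$direct, log(2) / 6, tolerance = 1e-12)
  expect_equal(dec$direct, 0.1155, tolerance = 1e-3)
  expect_equal(dec$context, -0.0566, tolerance = 1e-3)
  expect_equal(dec$total, log(1.5) - 0.5 * log(2), tolerance = 1e-12)

  at_prior <- elbo_price_decomposition(db, db$prior)
  expect_equal(c(at_prior$direct, at_prior$context), c(0, 0))

  set.seed(34)
  for (i in 1:20) {
    db <- rand_bayes(8)
    cand <- rand_simplex(8)
    dec <- elbo_price_decomposition(db, cand)
    expect_equal(dec$total, elbo(db, cand)$elbo - elbo(db, db$prior)$elbo,
                 tolerance = 1e-10)
  }
})

test_that("free-energy change is minus the ELBO change and signs correctly", {
  db <- bayes_update(c(0.5, 0.5), c(2, 1))
  expect_equal(free_energy_change(db, db$posterior),
               -(log(1.5) - 0.5 * log(2)), tolerance = 1e-12)
  expect_equal(free_energy_change(db, db$prior), 0)
  expect_lt(free_energy_change(db, db$posterior), 0)
  # moving mass against the likelihood raises free energy: grid over 2-state
  # candidates with less mass on the favored state than the prior
  for (a in seq(0.05, 0.45, by = 0.05)) {
    expect_gt(free_energy_change(db, c(a, 1 - a)), 0)
  }
})

test_that("virtual work of the balanced forces vanishes for zero-sum displacements", {
  set.seed(35)
  db <- rand_bayes(6)
  cand <- rand_simplex(6)
  disp <- lapply(1:10, function(i) { d <- rnorm(6); d - mean(d) })
  expect_lt(dalembert_balance(db, cand, disp), 1e-10)
  expect_equal(dalembert_balance(db, cand, list(numeric(6))), 0)
  # with pre-normalized likelihoods the bracket vector is identically zero
  dbn <- bayes_update(db$prior, db$norm_likelihood)
  bracket <- log(dbn$unnorm_likelihood) - log(cand / dbn$prior) -
    log(dbn$posterior / cand)
  expect_equal(bracket, numeric(6) + 0, tolerance = 1e-12)
  expect_error(dalembert_balance(db, cand, list(rep(1, 6))), "sum to zero")
})

test_that("mean-field projection recovers factorable posteriors and never lowers the ELBO", {
  # independent true posterior on a 2x2 grid: the family contains the truth
  lik <- as.vector(outer(c(2, 1), c(1, 3)))
  db <- bayes_update(rep(0.25, 4), lik)
  fit <- variational_project(db, dims = c(2, 2))
  expect_lt(fit$free_energy, 1e-8)

  # correlated posterior: monotone ELBO trace, bounded by log evidence
  likc <- c(5, 1, 1, 5)
  dbc <- bayes_update(rep(0.25, 4), likc)
  fitc <- variational_project(dbc, dims = c(2, 2))
  expect_true(all(diff(fitc$elbo_trace) >= -1e-12))
  expect_lte(max(fitc$elbo_trace), dbc$log_evidence + 1e-12)
  # no worse than the product of the true posterior marginals
  # (first factor fastest in the state order)
  m1 <- c(dbc$posterior[1] + dbc$posterior[3], dbc$posterior[2] + dbc$posterior[4])
  m2 <- c(dbc$posterior[1] + dbc$posterior[2], dbc$posterior[3] + dbc$posterior[4])
  cand <- as.vector(outer(m1, m2))
  expect_gte(fitc$elbo, elbo(dbc, cand)$elbo - 1e-10)

  # single factor: exact posterior
  db1 <- bayes_update(c(0.5, 0.5), c(2, 1))
  fit1 <- variational_project(db1, dims = 2)
  expect_equal(fit1$candidate, db1$posterior, tolerance = 1e-10)

  expect_error(variational_project(db, dims = c(3, 2)), "factor")
})
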