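# The reparameterization, conjugate updates, and integrated minute
# likelihood that everything else builds on.

test_that("mean/correlation and beta shapes convert exactly both ways", {
  expect_equal(beta_from_mean_corr(0.5, 1 / 3), list(alpha = 1, beta = 1))
  expect_equal(beta_from_mean_corr(0.5, 0.2), list(alpha = 2, beta = 2))
  expect_equal(mean_corr_from_beta(1, 1), list(mean_p = 0.5, rho = 1 / 3))
  expect_equal(mean_corr_from_beta(2, 2), list(mean_p = 0.5, rho = 0.2))
  expect_equal(mean_corr_from_beta(9, 1), list(mean_p = 0.9, rho = 1 / 11))

  grid <- expand.grid(mean_p = seq(0.05, 0.95, length.out = 20),
                      rho = seq(0.05, 0.95, length.out = 20))
  ab <- beta_from_mean_corr(grid$mean_p, grid$rho)
  expect_true(all(ab$alpha > 0) && all(ab$beta > 0))
  back <- mean_corr_from_beta(ab$alpha, ab$beta)
  expect_equal(back$mean_p, grid$mean_p, tolerance = 1e-12)
  expect_equal(back$rho, grid$rho, tolerance = 1e-12)
})

test_that("boundary and invalid reparameterization arguments error", {
  expect_error(beta_from_mean_corr(0, 0.3), "strictly inside")
  expect_error(beta_from_mean_corr(0.5, 1), "strictly inside")
  expect_error(mean_corr_from_beta(0, 1), "strictly positive")
  expect_error(mean_corr_from_beta(1, -2), "strictly positive")
})

test_that("minute-level conjugate update follows beta-Bernoulli arithmetic", {
  expect_equal(minute_posterior(1, 1, k_detect = 0, s_active = 0),
               list(alpha = 1, beta = 1))
  expect_equal(minute_posterior(2, 3, k_detect = 2, s_active = 5),
               list(alpha = 4, beta = 6))
  expect_error(minute_posterior(1, 1, k_detect = 3, s_active = 2),
               "excluded or nonexistent")
})

test_that("augmented-row inclusion probability matches its closed form", {
  expect_equal(inclusion_probability(0.5, 0.5), 1 / 3)
  expect_equal(inclusion_probability(0.37, numeric()), 0.37)
  expect_equal(inclusion_probability(0.37, c(0, 0, 0)), 0.37)
  expect_equal(inclusion_probability(0.5, c(0.9, 0.9)),
               0.005 / (0.005 + 0.5), tolerance = 1e-12)
  expect_equal(inclusion_probability(0, c(0.3, 0.4)), 0)
  # monotone in omega and in q (i.e. decreasing in each p)
  omegas <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(omegas, inclusion_probability, numeric(1), p = c(0.3, 0.6))
  expect_true(all(diff(vals) > 0))
  ps <- seq(0.05, 0.95, by = 0.05)
  vals_q <- vapply(ps, function(p) inclusion_probability(0.4, p), numeric(1))
  expect_true(all(diff(vals_q) < 0))
})

test_that("inclusion-probability and omega updates validate their inputs", {
  expect_error(inclusion_probability(1.2, 0.5), "0, 1")
  expect_error(inclusion_probability(0.5, c(0.5, 2)), "0, 1")
  expect_equal(omega_posterior(c(1, 1), 30, 100), list(alpha = 31, beta = 71))
  expect_equal(omega_posterior(c(1, 1), 0, 0), list(alpha = 1, beta = 1))
  expect_equal(omega_posterior(c(2, 5), 10, 40), list(alpha = 12, beta = 35))
  expect_error(omega_posterior(c(1, 1), 5, 3), "n_included")
  expect_error(omega_posterior(c(-1, 1), 1, 3), "hyperpair")
})

test_that("hyperparameter log density matches direct special-function sums", {
  expect_equal(hyper_loglik(1, 1, runif(17)), 0)
  expect_equal(hyper_loglik(2, 2, 0.5), log(1.5))
  set.seed(11)
  for (i in 1:50) {
    a <- runif(1, 0.2, 8); b <- runif(1, 0.2, 8)
    p <- runif(sample(1:20, 1), 0.01, 0.99)
    direct <- sum((a - 1) * log(p) + (b - 1) * log(1 - p) - lbeta(a, b))
    expect_equal(hyper_loglik(a, b, p), direct, tolerance = 1e-10)
  }
  expect_error(hyper_loglik(1, 1, c(0.5, 1)), "strictly inside")
})

test_that("integrated minute likelihood agrees with quadrature", {
  expect_equal(beta_binomial_loglik(1, 1, 1, 1), log(1 / 2))
  expect_equal(beta_binomial_loglik(1, 1, 2, 1), log(1 / 6))
  expect_identical(beta_binomial_loglik(3.2, 0.7, 0, 0), 0)
  set.seed(7)
  for (i in 1:100) {
    a <- runif(1, 0.3, 10); b <- runif(1, 0.3, 10)
    s <- sample(0:20, 1); k <- if (s > 0) sample(0:s, 1) else 0
    expect_equal(exp(beta_binomial_loglik(a, b, s, k)),
                 quadrature_minute_lik(a, b, s, k), tolerance = 1e-10)
  }
  expect_error(beta_binomial_loglik(1, 1, 2, 3), "k_detect")
})

test_that("beta-binomial pmf built from the integrated likelihood normalizes", {
  set.seed(21)
  for (i in 1:100) {
    a <- runif(1, 0.2, 15); b <- runif(1, 0.2, 15)
    s <- sample(1:30, 1)
    total <- sum(choose(s, 0:s) *
                   exp(beta_binomial_loglik(a, b, s, 0:s)))
    expect_equal(total, 1, tolerance = 1e-10)
  }
})

test_that("prior specification validates hyperpairs", {
  pr <- bbcmr_priors()
  expect_s3_class(pr, "bbcmr_priors")
  expect_equal(pr$omega, c(1, 1))
  expect_error(bbcmr_priors(omega = c(1, -1)), "omega")
  expect_error(bbcmr_priors(rho = 1), "rho")
})
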