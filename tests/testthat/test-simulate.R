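# The synthetic survey generator: structure, limits, moment checks, and the
# closure-violation hook.

test_that("zero-abundance sites yield zero-row histories", {
  sim <- simulate_survey(survey_design("v1", "s1", 10, A = 50),
                         mean_p = 0.4, rho = 0.2, N = 0, seed = 1)
  expect_equal(n_observed(sim$histories$histories[[1]]), 0L)
  expect_equal(sim$truth$N$N, 0L)
})

test_that("near-perfect detection observes every individual", {
  sim <- simulate_survey(survey_design("v1", "s1", 10, A = 50),
                         mean_p = 0.999, rho = 0.05, N = 20, seed = 2)
  expect_equal(n_observed(sim$histories$histories[[1]]), 20L)
})

test_that("observed counts never exceed the simulated truth", {
  sim <- refuge_preset(seed = 7)
  tab <- as.data.frame(sim$histories)
  expect_true(all(tab$n_obs <= sim$truth$N$N))
})

test_that("shared minute-level probabilities induce the nominal correlation", {
  # two individuals observed over many minutes: their detection indicators
  # have correlation rho under the model
  set.seed(12)
  ab <- beta_from_mean_corr(0.4, 0.2)
  n_min <- 10000
  p <- rbeta(n_min, ab$alpha, ab$beta)
  y1 <- rbinom(n_min, 1, p)
  y2 <- rbinom(n_min, 1, p)
  expect_lt(abs(cor(y1, y2) - 0.2), 0.045)
  expect_lt(abs(mean(p) - 0.4), 0.02)
  # and the generator itself reproduces it across simulated minutes
  sim <- simulate_survey(survey_design(paste0("v", 1), "s1", 10, A = 100),
                         mean_p = 0.4, rho = 0.2, N = 60, seed = 12)
  y <- sim$truth$y_full[[1]]
  k <- colSums(y)  # detections per minute among 60 individuals
  # overdispersion relative to independent binomial reflects rho > 0
  p_hat <- mean(k) / 60
  binom_var <- 60 * p_hat * (1 - p_hat)
  expect_gt(var(k), binom_var)
})

test_that("with rho near zero minute counts match binomial dispersion", {
  set.seed(13)
  reps <- 400
  counts <- replicate(reps, {
    sim <- simulate_survey(survey_design("v1", "s1", 1, A = 100),
                           mean_p = 0.4, rho = 0.001, N = 50)
    sum(sim$truth$y_full[[1]])
  })
  p_hat <- mean(counts) / 50
  ratio <- var(counts) / (50 * p_hat * (1 - p_hat))
  expect_lt(abs(ratio - 1), 0.35)
})

test_that("simulation is reproducible given a seed", {
  s1 <- simulate_survey(survey_design(c("v1", "v2"), "s1", 10, A = 50),
                        mean_p = 0.4, rho = 0.2, N = c(10, 5), seed = 99)
  s2 <- simulate_survey(survey_design(c("v1", "v2"), "s1", 10, A = 50),
                        mean_p = 0.4, rho = 0.2, N = c(10, 5), seed = 99)
  expect_identical(s1$truth, s2$truth)
  expect_identical(lapply(s1$histories$histories, `[[`, "y"),
                   lapply(s2$histories$histories, `[[`, "y"))
  p1 <- refuge_preset(seed = 5); p2 <- refuge_preset(seed = 5)
  expect_identical(p1$truth, p2$truth)
})

test_that("abundance can be drawn through the inclusion probability", {
  sim <- simulate_survey(survey_design(rep("v1", 40), paste0("s", 1:40),
                                       6, A = 100),
                         mean_p = 0.5, rho = 0.2, omega = 0.3, seed = 3)
  N <- sim$truth$N$N
  expect_true(all(N >= 0 & N <= 100))
  expect_equal(mean(N), 30, tolerance = 3)
  expect_error(
    simulate_survey(survey_design("v1", "s1", 6, A = 10),
                    mean_p = 0.5, rho = 0.2, N = 11),
    "raise the design")
})

test_that("the refuge preset reproduces the intended study layout", {
  sim <- refuge_preset(seed = 1)
  d <- sim$design
  expect_equal(length(unique(d$visit)), 4L)
  expect_equal(length(unique(d$site)), 15L)
  expect_equal(nrow(d), 14 * 4 + 1)
  expect_equal(d$visit[d$site == "preserve"], "visit_4")
  expect_true(all(sim$truth$mean_p >= 0.29 & sim$truth$mean_p <= 0.54))
  expect_true(all(sim$truth$rho >= 0.11 & sim$truth$rho <= 0.28))
  expect_true(all(sim$truth$N$N >= 0 & sim$truth$N$N <= 47))
  expect_true(any(sim$truth$N$N == 0))          # structural zeros
  expect_true(all(d$duration %in% c(6L, 10L)))
  expect_true(all(d$duration[sim$truth$N$N == 0] == 6L))
})

test_that("closure-violation hook removes detections after departure", {
  sim <- simulate_survey(survey_design("v1", "s1", 10, A = 60),
                         mean_p = 0.5, rho = 0.15, N = 25, seed = 8)
  same <- inject_closure_violation(sim, departure_rate = 0, seed = 9)
  expect_identical(same, sim)

  gone <- inject_closure_violation(sim, departure_rate = 1, seed = 9,
                                   departure_minute = 1)
  expect_equal(n_observed(gone$histories$histories[[1]]), 0L)
  expect_true(all(gone$truth$y_full[[1]] == 0))

  set.seed(10)
  half <- inject_closure_violation(sim, departure_rate = 0.5, seed = 10)
  expect_lte(sum(half$truth$y_full[[1]]), sum(sim$truth$y_full[[1]]))
  dep <- half$truth$departures[[1]]
  expect_true(any(!is.na(dep)))
  # erased exactly from the departure minute on
  for (i in which(!is.na(dep))) {
    expect_true(all(half$truth$y_full[[1]][i, dep[i]:10] == 0))
  }
})

test_that("closure violations push abundance estimates down, not up", {
  sim <- simulate_survey(survey_design(rep("v1", 4), paste0("s", 1:4),
                                       10, A = 60),
                         mean_p = 0.45, rho = 0.2, N = 20, seed = 14)
  bad <- inject_closure_violation(sim, departure_rate = 0.6, seed = 15)
  fit_clean <- bbcmr(sim, A = 60, chains = 2, iter = 1500, burnin = 750,
                     seed = 1, store_p = FALSE)
  fit_bad <- bbcmr(bad, A = 60, chains = 2, iter = 1500, burnin = 750,
                   seed = 1, store_p = FALSE)
  err_clean <- mean(fit_clean$summary$N$mean - 20)
  err_bad <- mean(fit_bad$summary$N$mean - 20)
  expect_lt(err_bad, err_clean)
  expect_gte(abs(err_bad), abs(err_clean) - 0.5)
})
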