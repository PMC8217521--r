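# Sampler behavior: reproducibility, conjugate correctness, invariants on
# retained draws, and adaptation.

small_fit <- function(...) {
  sim <- simulate_survey(
    survey_design(c("v1", "v1", "v2"), c("a", "b", "a"),
                  duration = c(6, 6, 10), A = 40),
    mean_p = c(0.45, 0.35), rho = 0.2, N = c(10, 0, 15), seed = 100)
  bbcmr(sim, A = 40, chains = 2, iter = 800, burnin = 400, seed = 7, ...)
}

small_fit_seed_differs <- function() {
  sim <- simulate_survey(
    survey_design(c("v1", "v1", "v2"), c("a", "b", "a"),
                  duration = c(6, 6, 10), A = 40),
    mean_p = c(0.45, 0.35), rho = 0.2, N = c(10, 0, 15), seed = 100)
  bbcmr(sim, A = 40, chains = 2, iter = 800, burnin = 400, seed = 8)
}

test_that("the same master seed reproduces draws bit for bit", {
  f1 <- small_fit()
  f2 <- small_fit()
  expect_identical(f1$draws[[1]]$N, f2$draws[[1]]$N)
  expect_identical(f1$draws[[2]]$omega, f2$draws[[2]]$omega)
  expect_identical(f1$seeds, f2$seeds)
  f3 <- small_fit_seed_differs()
  expect_false(identical(f1$draws[[1]]$N, f3$draws[[1]]$N))
})

test_that("chain bookkeeping matches the requested configuration", {
  sim <- simulate_survey(survey_design("v1", "s1", 6, A = 20),
                         mean_p = 0.4, rho = 0.2, N = 5, seed = 1)
  fit <- bbcmr(sim, A = 20, chains = 1, iter = 10, burnin = 0, seed = 1)
  expect_equal(nrow(fit$draws[[1]]$N), 10L)
  expect_equal(length(fit$draws), 1L)
  expect_error(
    bbcmr(sim, A = 20, chains = 1, iter = 0, burnin = 10, seed = 1),
    "retained")
})

test_that("with everything fixed the p-update samples its conjugate posterior", {
  # one site, no augmented rows (A = n_obs), fixed hyperparameters and
  # omega: the sampler draws each minute's p from Beta(a + k, b + s - k)
  y <- rbind(c(1, 0), c(1, 1), c(0, 1))
  h <- capture_history(y, "v1", "s1")
  aug <- list(augment_history(h, A = 3))
  a <- 2; b <- 3
  run <- bbcmr:::bbcmr_engine(aug, chains = 1, iter = 10000, burnin = 100,
                              seed = 3, store_p = TRUE,
                              fixed = list(alpha = a, beta = b, omega = 0.5))
  p <- run$chains[[1]]$p
  k <- colSums(y); s <- 3
  for (t in 1:2) {
    post_mean <- (a + k[t]) / (a + b + s)
    post_var <- post_mean * (1 - post_mean) / (a + b + s + 1)
    se <- sqrt(post_var / nrow(p))  # draws are iid here given fixed rest
    expect_lt(abs(mean(p[, t]) - post_mean), 4 * se)
  }
})

test_that("impossible augmented inclusions stay at the observed count", {
  # all-zero augmented rows with detection probability pinned near 1:
  # q ~ 0 so no pseudo-individual is ever included
  y <- matrix(1, 4, 6)
  h <- capture_history(y, "v1", "s1")
  aug <- list(augment_history(h, A = 12))
  run <- bbcmr:::bbcmr_engine(aug, chains = 1, iter = 2000, burnin = 100,
                              seed = 4, store_p = FALSE,
                              fixed = list(alpha = 500, beta = 1,
                                           omega = 0.5))
  expect_true(all(run$chains[[1]]$N[, 1] == 4))
})

test_that("retained draws satisfy the hard model invariants", {
  fit <- small_fit()
  sv <- fit$prep$sv
  for (ch in fit$draws) {
    for (j in seq_len(nrow(sv))) {
      expect_true(all(ch$N[, j] >= sv$n_obs[j]))   # observed z stay included
      expect_true(all(ch$N[, j] <= sv$A[j]))
    }
    expect_true(all(ch$p > 0 & ch$p < 1))
    expect_true(all(ch$pstar >= 0 & ch$pstar <= 1))
    expect_true(all(ch$omega > 0 & ch$omega < 1))
    expect_true(all(ch$mean_p > 0 & ch$mean_p < 1))
    expect_true(all(ch$rho > 0 & ch$rho < 1))
  }
})

test_that("proposal adaptation lands in a sane acceptance window", {
  sim <- refuge_preset(seed = 21)
  fit <- bbcmr(sim, A = 100, chains = 1, iter = 1500, burnin = 1500,
               seed = 2, store_p = FALSE)
  acc <- fit$draws[[1]]$accept_rate
  expect_true(all(acc >= 0.15 & acc <= 0.5))
})

test_that("posterior mass at the augmentation cap triggers a warning", {
  y <- matrix(1, 3, 2)
  h <- capture_history(y, "v1", "s1")
  sim_set <- capture_history_set(list(h))
  expect_warning(
    bbcmr(sim_set, A = 3, chains = 1, iter = 200, burnin = 50, seed = 1),
    "augmentation cap")
})

test_that("credible intervals for N cover the simulated truth", {
  # many independent single-visit sites at moderate detection; interval
  # coverage of the 95% CI should be near (and not far below) nominal
  set.seed(61)
  sim <- simulate_survey(
    survey_design(rep("v1", 25), paste0("s", 1:25), 10, A = 60),
    mean_p = 0.4, rho = 0.2, N = sample(5:25, 25, replace = TRUE),
    seed = 61)
  fit <- bbcmr(sim, A = 60, chains = 2, iter = 2000, burnin = 1000,
               seed = 6, store_p = FALSE)
  tab <- fit$summary$N
  truth <- sim$truth$N$N
  covered <- mean(truth >= tab$q2.5 & truth <= tab$q97.5)
  expect_gte(covered, 0.8)
})
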