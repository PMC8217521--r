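# Derived posterior functionals: abundance tables, visit totals, detection
# summaries, and duration comparisons.

shared_fit <- local({
  fit <- NULL
  function() {
    if (is.null(fit)) {
      sim <- simulate_survey(
        survey_design(c("v1", "v1", "v1", "v2"), c("a", "b", "c", "a"),
                      duration = c(10, 10, 6, 10), A = 50),
        mean_p = c(0.45, 0.35), rho = 0.2, N = c(12, 6, 0, 15), seed = 201)
      fit <<- bbcmr(sim, A = 50, chains = 2, iter = 1200, burnin = 600,
                    seed = 11)
    }
    fit
  }
})

test_that("visit totals equal the per-draw sum of their site abundances", {
  fit <- shared_fit()
  draws <- bbcmr:::visit_total_draws(fit)
  sv <- fit$prep$sv
  for (ci in seq_along(fit$draws)) {
    for (v in seq_along(fit$prep$visits)) {
      cols <- which(sv$vidx == v)
      expect_identical(draws[[ci]][, v],
                       rowSums(fit$draws[[ci]]$N[, cols, drop = FALSE]))
    }
  }
  tot <- visit_totals(fit)
  expect_equal(tot$visit, c("v1", "v2"))
  expect_equal(tot$mean,
               vapply(seq_along(fit$prep$visits), function(v) {
                 mean(unlist(lapply(draws, function(d) d[, v])))
               }, numeric(1)))
})

test_that("site exclusions drop sites from every total", {
  fit <- shared_fit()
  tot_all <- visit_totals(fit)
  tot_ex <- visit_totals(fit, exclude = c("b", "c"))
  # v2 only surveyed site a, so its total is untouched
  expect_equal(tot_ex$mean[2], tot_all$mean[2])
  expect_lt(tot_ex$mean[1], tot_all$mean[1])
  expect_error(visit_totals(fit, exclude = "nope"), "unknown site")
  # excluding the only site in a visit gives a zero total
  tot_none <- visit_totals(fit, exclude = c("a", "b", "c"))
  expect_equal(tot_none$mean, c(0, 0))
})

test_that("cumulative detection matches its closed form per draw", {
  fit <- shared_fit()
  prep <- fit$prep
  for (ci in seq_along(fit$draws)) {
    ch <- fit$draws[[ci]]
    for (j in c(1, 4)) {
      cols <- which(prep$minute_site == j)
      manual <- 1 - apply(1 - ch$p[, cols, drop = FALSE], 1, prod)
      expect_equal(ch$pstar[, j], manual, tolerance = 1e-12)
    }
  }
  cd <- cumulative_detection(fit)
  expect_true(all(cd$mean >= 0 & cd$mean <= 1))
})

test_that("predicted cumulative detection grows with duration", {
  fit <- shared_fit()
  p6 <- predict(fit, duration = 6)
  p10 <- predict(fit, duration = 10)
  expect_true(all(p10$mean >= p6$mean - 1e-12))
  # closed-form sanity: all p = 0.5 for one minute gives p* = 0.5
  expect_equal(1 - prod(1 - rep(0.5, 6)), 0.984375)
})

test_that("fixed hyperparameters propagate exactly into detection summaries", {
  sim <- simulate_survey(survey_design("v1", "s1", 4, A = 20),
                         mean_p = 0.5, rho = 1 / 3, N = 6, seed = 202)
  fit <- bbcmr(sim, A = 20, chains = 2, iter = 300, burnin = 100, seed = 12,
               fixed = list(alpha = 1, beta = 1))
  dm <- detection_means(fit)
  expect_equal(dm$visit$mean, 0.5)
  expect_equal(dm$visit$rho_mean, 1 / 3)
})

test_that("site-level mean detection pools minutes across visits", {
  fit <- shared_fit()
  dm <- detection_means(fit)
  expect_equal(sort(dm$site$site), c("a", "b", "c"))
  a_row <- dm$site[dm$site$site == "a", ]
  expect_equal(a_row$n_minutes, 20L)  # 10 min in each of two visits
  # pooled mean equals the minute-count-weighted average of per-draw means
  prep <- fit$prep
  cols <- which(prep$sv$site[prep$minute_site] == "a")
  manual <- mean(unlist(lapply(fit$draws, function(ch) {
    rowMeans(ch$p[, cols, drop = FALSE])
  })))
  expect_equal(a_row$mean, manual, tolerance = 1e-12)
})

test_that("count-versus-estimate differences behave as defined", {
  fit <- shared_fit()
  cve <- count_vs_estimate(fit)
  expect_true(all(cve$estimate >= cve$count))
  zero_row <- cve[cve$site == "c", ]
  expect_equal(zero_row$difference, zero_row$estimate)
  expect_equal(attr(cve, "mean_diff"), mean(cve$difference))
  expect_equal(attr(cve, "max_diff"), max(cve$difference))
})

test_that("duration comparison aligns rosters and aggregates differences", {
  fit <- shared_fit()
  same <- compare_durations(fit, fit)
  expect_equal(same$mean_abs_diff, 0)
  expect_equal(same$ci_width_ratio, 1)
  expect_true(all(same$table$diff == 0))

  # hand-check of the aggregate on three synthetic rows
  a <- fit
  expect_equal(compare_durations(fit, fit)$mean_abs_diff,
               mean(abs(fit$summary$N$mean - fit$summary$N$mean)))

  other <- bbcmr(simulate_survey(survey_design("v9", "x", 6, A = 20),
                                 mean_p = 0.4, rho = 0.2, N = 3, seed = 9),
                 A = 20, chains = 1, iter = 100, burnin = 50, seed = 1)
  expect_error(compare_durations(fit, other), "different")
})

test_that("near-perfect detection pins estimates to the counts", {
  sim <- simulate_survey(
    survey_design(rep("v1", 3), paste0("s", 1:3), 10, A = 40),
    mean_p = 0.95, rho = 0.1, N = c(10, 5, 18), seed = 203)
  fit <- bbcmr(sim, A = 40, chains = 2, iter = 1000, burnin = 500,
               seed = 13, store_p = FALSE)
  cve <- count_vs_estimate(fit)
  expect_lt(attr(cve, "mean_diff"), 0.1)
})
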