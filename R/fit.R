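# The user-facing fitting function and methods on the fitted-model object.

#' Fit the beta-binomial capture-mark-recapture model
#'
#' Fits the hierarchical closed-population model to per-minute capture
#' histories.  For each visit v, site l, minute t and individual i,
#' \deqn{y_{v,l,t,i} \sim \mathrm{Bern}(z_{v,l,i} \, p_{v,l,t}), \qquad
#'       p_{v,l,t} \sim \mathrm{Beta}(\alpha_v, \beta_v),}
#' with the visit-level shapes parameterized by the mean detection
#' probability \eqn{\bar p_v} and within-minute detection correlation
#' \eqn{\rho_v} (see [beta_from_mean_corr()]).  Each capture history is
#' padded with all-zero rows to `A` rows, and the latent inclusion
#' indicators follow \eqn{z_{v,l,i} \sim \mathrm{Bern}(\Omega)}; site/visit
#' abundance is \eqn{N_{v,l} = \sum_i z_{v,l,i}}.
#'
#' Sampling is Metropolis-within-Gibbs: conjugate updates for every
#' \eqn{p_{v,l,t}} and for \eqn{\Omega}, exchangeable binomial updates for
#' the included augmented rows, and a joint logit-scale random-walk
#' Metropolis update of \eqn{(\bar p_v, \rho_v)} whose scale is adapted
#' during burn-in only.
#'
#' @param data Detection data: a long-format records data frame (columns
#'   `visit`, `site`, `individual`, `minute`, `detected`), a
#'   `capture_history_set`, or a simulated survey from [simulate_survey()].
#' @param durations Optional declared-durations data frame (see
#'   [build_history_set()]); ignored when `data` already is a history set.
#' @param A Augmentation cap: total rows per site/visit after padding
#'   (default 100).
#' @param truncate Optionally truncate all histories to this many minutes
#'   before fitting (e.g. 6 to analyze only the first 6 minutes).
#' @param priors A [bbcmr_priors()] object.
#' @param chains Number of MCMC chains (default 3).
#' @param iter Retained iterations per chain after burn-in (default 120000).
#' @param burnin Burn-in iterations per chain (default 60000).
#' @param thin Thinning interval (default 1).
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @param store_p Keep the minute-level detection draws (needed for
#'   minute/site-level detection summaries, posterior-predictive simulation
#'   and `predict`; default `TRUE`).
#' @param fixed Optional list fixing parameters instead of sampling them:
#'   `alpha`/`beta` (per visit, recycled) and/or `omega`.  Used for sampler
#'   validation against the enumeration oracle.
#' @param adapt Adapt the Metropolis proposal scale during burn-in
#'   (default `TRUE`; adaptation is always frozen after burn-in).
#' @return An object of class `bbcmr_fit`.
#' @seealso [site_abundance()], [visit_totals()], [cumulative_detection()],
#'   [detection_means()], [count_vs_estimate()], [compare_durations()]
#' @examples
#' sim <- simulate_survey(survey_design(c("v1", "v1"), c("a", "b"), 6, A = 30),
#'                        mean_p = 0.4, rho = 0.2, N = c(8, 5), seed = 1)
#' fit <- bbcmr(sim, A = 30, chains = 2, iter = 500, burnin = 250, seed = 1)
#' fit
#' @export
bbcmr <- function(data, durations = NULL, A = 100, truncate = NULL,
                  priors = bbcmr_priors(), chains = 3, iter = 120000,
                  burnin = 60000, thin = 1, seed = 1L, store_p = TRUE,
                  fixed = NULL, adapt = TRUE) {
  cl <- match.call()
  hset <- as_history_set(data, durations)
  if (!is.null(truncate)) hset <- truncate_minutes(hset, truncate)
  aug <- augment_set(hset, A = A)
  run <- bbcmr_engine(aug, priors = priors, chains = chains, iter = iter,
                      burnin = burnin, thin = thin, seed = seed,
                      store_p = store_p, fixed = fixed, adapt = adapt)
  fit <- structure(list(
    call = cl, data = hset, prep = run$prep, draws = run$chains,
    config = list(A = A, chains = chains, iter = iter, burnin = burnin,
                  thin = thin, seed = seed, store_p = store_p,
                  fixed = fixed, adapt = adapt, priors = priors,
                  truncate = truncate),
    seeds = run$seeds
  ), class = "bbcmr_fit")
  fit$summary <- fit_summary(fit)
  check_augmentation_mass(fit)
  fit
}

as_history_set <- function(data, durations = NULL) {
  if (inherits(data, "capture_history_set")) return(data)
  if (inherits(data, "bbcmr_sim")) return(data$histories)
  if (is.data.frame(data)) return(build_history_set(data, durations))
  stop("`data` must be detection records, a capture_history_set, ",
       "or a simulated survey", call. = FALSE)
}

# Warn when posterior mass piles up at the augmentation cap.
check_augmentation_mass <- function(fit, threshold = 0.01) {
  sv <- fit$prep$sv
  for (j in seq_len(nrow(sv))) {
    at_cap <- mean(unlist(lapply(fit$draws, function(ch) ch$N[, j] == sv$A[j])))
    if (at_cap > threshold) {
      warning(sprintf(
        "posterior mass %.1f%% at the augmentation cap A = %d for (%s, %s); raise A",
        100 * at_cap, sv$A[j], sv$visit[j], sv$site[j]), call. = FALSE)
    }
  }
  invisible(fit)
}

# Per-scalar summary tables for the monitored nodes.
fit_summary <- function(fit, ess_warn = 100) {
  sv <- fit$prep$sv
  ch <- fit$draws
  blk <- function(name) lapply(ch, `[[`, name)

  N <- cbind(sv[c("visit", "site", "n_obs")], summarize_block(blk("N")))
  pstar <- cbind(sv[c("visit", "site", "duration")],
                 summarize_block(blk("pstar")))
  mean_p <- cbind(data.frame(visit = fit$prep$visits,
                             stringsAsFactors = FALSE),
                  summarize_block(blk("mean_p")))
  rho <- cbind(data.frame(visit = fit$prep$visits, stringsAsFactors = FALSE),
               summarize_block(blk("rho")))
  omega <- summarize_draws(lapply(ch, `[[`, "omega"))
  low_ess <- c(
    if (any(mean_p$ess < ess_warn, na.rm = TRUE)) "mean_p",
    if (any(rho$ess < ess_warn, na.rm = TRUE)) "rho"
  )
  list(N = N, pstar = pstar, mean_p = mean_p, rho = rho, omega = omega,
       low_ess = low_ess)
}

#' @export
print.bbcmr_fit <- function(x, ...) {
  cfg <- x$config
  cat("Beta-binomial capture-mark-recapture fit\n")
  cat(sprintf("  %d visits, %d site/visit combinations, A = %d\n",
              x$prep$V, x$prep$J, cfg$A))
  cat(sprintf("  %d chain(s) x %d retained (burn-in %d, thin %d), seed %d\n",
              cfg$chains, cfg$iter, cfg$burnin, cfg$thin, cfg$seed))
  om <- x$summary$omega
  cat(sprintf("  inclusion probability Omega: %.3f (%.3f-%.3f)\n",
              om$mean, om$q2.5, om$q97.5))
  mp <- x$summary$mean_p
  for (i in seq_len(nrow(mp))) {
    cat(sprintf("  visit %s: mean_p %.3f (%.3f-%.3f), rho %.3f (%.3f-%.3f)\n",
                mp$visit[i], mp$mean[i], mp$q2.5[i], mp$q97.5[i],
                x$summary$rho$mean[i], x$summary$rho$q2.5[i],
                x$summary$rho$q97.5[i]))
  }
  cat("Use summary() for site-level abundance and detection tables.\n")
  invisible(x)
}

#' Summarize a fitted model
#'
#' @param object A `bbcmr_fit`.
#' @param ... Unused.
#' @return An object of class `summary.bbcmr_fit`: a list of summary tables
#'   (`N`, `pstar`, `mean_p`, `rho`, `omega`), each with posterior mean,
#'   2.5%/97.5% quantiles, split-chain R-hat and effective sample size.
#' @export
summary.bbcmr_fit <- function(object, ...) {
  s <- object$summary
  structure(s, class = "summary.bbcmr_fit")
}

#' @export
print.summary.bbcmr_fit <- function(x, digits = 3, ...) {
  cat("Site/visit abundance (N):\n")
  print(format_summary_df(x$N, digits))
  cat("\nCumulative detection probability (p*):\n")
  print(format_summary_df(x$pstar, digits))
  cat("\nVisit-level mean detection (mean_p):\n")
  print(format_summary_df(x$mean_p, digits))
  cat("\nVisit-level detection correlation (rho):\n")
  print(format_summary_df(x$rho, digits))
  cat("\nInclusion probability (Omega):\n")
  print(format_summary_df(x$omega, digits))
  if (length(x$low_ess)) {
    cat(sprintf("\nNote: effective sample size below 100 for: %s.\n",
                paste(x$low_ess, collapse = ", ")))
    cat("Weak identification is expected for rho when a visit has very few minutes.\n")
  }
  invisible(x)
}

format_summary_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Posterior means of the visit-level parameters
#'
#' @param object A `bbcmr_fit`.
#' @param ... Unused.
#' @return Named numeric vector: `mean_p[<visit>]`, `rho[<visit>]`, `omega`.
#' @export
coef.bbcmr_fit <- function(object, ...) {
  s <- object$summary
  out <- c(setNames(s$mean_p$mean, paste0("mean_p[", s$mean_p$visit, "]")),
           setNames(s$rho$mean, paste0("rho[", s$rho$visit, "]")),
           omega = s$omega$mean)
  out
}

#' Abundance plot for a fitted model
#'
#' Posterior means and 95% credible intervals of site/visit abundance, with
#' the raw observed counts overlaid, grouped by visit.
#'
#' @param x A `bbcmr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.bbcmr_fit <- function(x, ...) {
  tab <- x$summary$N
  idx <- seq_len(nrow(tab))
  plot(idx, tab$mean, ylim = c(0, max(tab$q97.5) * 1.05 + 1),
       pch = 17, xaxt = "n", xlab = "", ylab = "Abundance (N)",
       main = "Posterior abundance by site and visit", ...)
  segments(idx, tab$q2.5, idx, tab$q97.5)
  points(idx, tab$n_obs, pch = 1)
  axis(1, at = idx, labels = paste(tab$site, tab$visit, sep = "\n"),
       las = 2, cex.axis = 0.6)
  legend("topright", pch = c(17, 1),
         legend = c("posterior mean (95% CI)", "observed count"), bty = "n")
  invisible(x)
}

#' Posterior-predictive survey simulation
#'
#' Draws new capture histories from the posterior: for each replicate a
#' retained draw is selected at random (pooled across chains) and a survey is
#' generated from its abundances and realized per-minute detection
#' probabilities.
#'
#' @param object A `bbcmr_fit` fitted with `store_p = TRUE`.
#' @param nsim Number of replicate surveys.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `capture_history_set` objects of length `nsim`.
#' @export
simulate.bbcmr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$config$store_p) {
    stop("posterior-predictive simulation needs `store_p = TRUE`",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  prep <- object$prep
  n_chain <- length(object$draws)
  n_iter <- nrow(object$draws[[1]]$N)
  out <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    ci <- sample.int(n_chain, 1)
    it <- sample.int(n_iter, 1)
    ch <- object$draws[[ci]]
    histories <- vector("list", prep$J)
    for (j in seq_len(prep$J)) {
      Tj <- prep$sv$duration[j]
      pj <- ch$p[it, prep$minute_site == j]
      Nj <- ch$N[it, j]
      y <- matrix(rbinom(Nj * Tj, 1, rep(pj, each = Nj)),
                  nrow = Nj, ncol = Tj)
      y <- y[rowSums(y) > 0, , drop = FALSE]
      histories[[j]] <- capture_history(
        y, visit = prep$sv$visit[j], site = prep$sv$site[j], duration = Tj,
        labels = if (nrow(y)) sprintf("pp%03d", seq_len(nrow(y))) else
          character())
    }
    out[[r]] <- capture_history_set(histories)
  }
  out
}

#' Cumulative detection at an arbitrary survey duration
#'
#' Computes, per posterior draw, the probability of detecting an individual
#' at least once within the first `duration` minutes,
#' \eqn{p^* = 1 - \prod_{t \le d} (1 - p_{v,l,t})}, and summarizes it.
#'
#' @param object A `bbcmr_fit` fitted with `store_p = TRUE`.
#' @param duration Number of minutes to accumulate; defaults to each site's
#'   full surveyed duration.  Sites surveyed for fewer minutes use all their
#'   minutes.
#' @param ... Unused.
#' @return Data frame per (visit, site): duration used, posterior mean and
#'   95% CI of p*.
#' @export
predict.bbcmr_fit <- function(object, duration = NULL, ...) {
  prep <- object$prep
  if (is.null(duration)) {
    tab <- object$summary$pstar
    names(tab)[names(tab) == "duration"] <- "duration_used"
    return(tab[c("visit", "site", "duration_used", "mean", "q2.5", "q97.5")])
  }
  if (!object$config$store_p) {
    stop("`predict` at a non-default duration needs `store_p = TRUE`",
         call. = FALSE)
  }
  out <- vector("list", prep$J)
  for (j in seq_len(prep$J)) {
    d <- min(duration, prep$sv$duration[j])
    cols <- which(prep$minute_site == j & prep$minute_index <= d)
    draws <- lapply(object$draws, function(ch) {
      as.matrix(1 - exp(rowSums(log1p(-ch$p[, cols, drop = FALSE]))))
    })
    out[[j]] <- cbind(
      data.frame(visit = prep$sv$visit[j], site = prep$sv$site[j],
                 duration_used = d, stringsAsFactors = FALSE),
      summarize_block(draws)[c("mean", "q2.5", "q97.5")]
    )
  }
  do.call(rbind, out)
}
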