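# Exact enumeration posterior for tiny instances with fixed hyperparameters,
# used to validate the sampler.  All weight arithmetic is in log space with a
# log-sum-exp normalization, since beta-function ratios underflow quickly.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Exact posterior of abundance on a tiny instance
#'
#' With the visit-level beta shapes and the inclusion probability held fixed,
#' the posterior of N for a single capture history can be enumerated in
#' closed form.  All-zero augmented rows are exchangeable, so it suffices to
#' sum over the number m of included pseudo-rows:
#' \deqn{w(m) = \binom{A-n}{m} \Omega^{n+m} (1-\Omega)^{A-n-m}
#'   \prod_t \frac{B(\alpha + k_t,\; \beta + n + m - k_t)}{B(\alpha, \beta)},}
#' where n is the observed count and k_t the observed column sum at minute t;
#' the pmf is w normalized over m = 0..A-n.
#'
#' @param history A `capture_history`.
#' @param alpha,beta Fixed beta shape parameters.
#' @param omega Fixed inclusion probability, strictly in (0, 1).
#' @param A Augmentation cap.  Tractability bounds `A <= 12` and
#'   `duration <= 6` are enforced.
#' @return An object of class `bbcmr_oracle`: list with `N` (support
#'   n..A), `pmf`, `log_normalizer`, and the echoed inputs.
#' @export
enumerate_posterior_N <- function(history, alpha, beta, omega, A = 12) {
  stopifnot(inherits(history, "capture_history"))
  if (A > 12 || history$duration > 6) {
    stop("enumeration is restricted to A <= 12 and duration <= 6",
         call. = FALSE)
  }
  if (omega <= 0 || omega >= 1) {
    stop("`omega` must lie strictly in (0, 1)", call. = FALSE)
  }
  n <- n_observed(history)
  if (A < n) stop("A is smaller than the observed count; raise A",
                  call. = FALSE)
  k_t <- if (n) colSums(history$y) else rep(0, history$duration)
  m <- 0:(A - n)
  lw <- lchoose(A - n, m) + (n + m) * log(omega) +
    (A - n - m) * log1p(-omega)
  for (t in seq_along(k_t)) {
    lw <- lw + beta_binomial_loglik(alpha, beta, s_active = n + m,
                                    k_detect = k_t[t])
  }
  lz <- logsumexp(lw)
  structure(list(N = n + m, pmf = exp(lw - lz), log_normalizer = lz,
                 inputs = list(alpha = alpha, beta = beta, omega = omega,
                               A = A, n_obs = n, k_t = k_t)),
            class = "bbcmr_oracle")
}

#' @export
print.bbcmr_oracle <- function(x, digits = 4, ...) {
  cat("exact posterior of N (fixed hyperparameters)\n")
  print(setNames(round(x$pmf, digits), x$N))
  invisible(x)
}

#' Total-variation distance between the sampler and the exact posterior
#'
#' Runs the Gibbs sampler on a single augmented history with the
#' hyperparameters and the inclusion probability held fixed, and compares the
#' empirical pmf of N against [enumerate_posterior_N()].
#'
#' @param history A `capture_history` within the oracle's tractability
#'   bounds.
#' @param alpha,beta,omega Fixed model parameters.
#' @param A Augmentation cap.
#' @param sweeps Retained sweeps (default 200000).
#' @param burnin Burn-in sweeps (default 1000).
#' @param seed Seed for the sampler.
#' @return List with `tv` (total-variation distance), `mc_se` (its rough
#'   Monte-Carlo standard error under an independence approximation),
#'   `pmf_mcmc`, and the `oracle` result.
#' @export
oracle_vs_mcmc <- function(history, alpha, beta, omega, A = 12,
                           sweeps = 200000, burnin = 1000, seed = 1L) {
  oracle <- enumerate_posterior_N(history, alpha, beta, omega, A = A)
  aug <- list(augment_history(history, A = A))
  run <- bbcmr_engine(aug, chains = 1, iter = sweeps, burnin = burnin,
                      thin = 1, seed = seed, store_p = FALSE,
                      fixed = list(alpha = alpha, beta = beta, omega = omega))
  N_draws <- run$chains[[1]]$N[, 1]
  emp <- tabulate(N_draws + 1L, nbins = A + 1L)[oracle$N + 1L] / sweeps
  tv <- 0.5 * sum(abs(emp - oracle$pmf))
  mc_se <- 0.5 * sqrt(sum(emp * (1 - emp)) / sweeps)
  list(tv = tv, mc_se = mc_se, pmf_mcmc = setNames(emp, oracle$N),
       oracle = oracle)
}
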