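# Core model arithmetic: the beta mean/correlation reparameterization, the
# conjugate full conditionals used by the Gibbs sweeps, and the integrated
# (beta-marginalized) minute likelihood shared with the enumeration oracle.

#' Beta shape parameters from mean and correlation
#'
#' The correlated-detection model draws each minute's detection probability
#' from a visit-level beta distribution.  Rather than working with the shape
#' parameters directly, the model is parameterized by the mean detection
#' probability \eqn{\bar p = \alpha/(\alpha+\beta)} and the intraclass
#' correlation of detections within a minute,
#' \eqn{\rho = 1/(\alpha+\beta+1)}.  This function inverts that map.
#'
#' @param mean_p Mean per-minute detection probability, strictly in (0, 1).
#' @param rho Within-minute detection correlation, strictly in (0, 1).
#'   Both arguments may be vectors and are recycled.
#' @return A list with components `alpha` and `beta`, both strictly positive.
#' @seealso [mean_corr_from_beta()] for the forward map.
#' @examples
#' beta_from_mean_corr(0.5, 1/3)  # the uniform distribution, alpha = beta = 1
#' @export
beta_from_mean_corr <- function(mean_p, rho) {
  if (!all(is.finite(mean_p)) || !all(is.finite(rho)) ||
      any(mean_p <= 0 | mean_p >= 1) || any(rho <= 0 | rho >= 1)) {
    stop("`mean_p` and `rho` must lie strictly inside (0, 1)", call. = FALSE)
  }
  nu <- (1 - rho) / rho           # alpha + beta
  list(alpha = mean_p * nu, beta = (1 - mean_p) * nu)
}

#' Mean and correlation of a beta detection distribution
#'
#' Forward map of the reparameterization: given beta shape parameters, returns
#' the mean detection probability and the induced within-minute correlation.
#'
#' @param alpha,beta Positive beta shape parameters (vectors recycled).
#' @return A list with components `mean_p` and `rho`.
#' @seealso [beta_from_mean_corr()]
#' @export
mean_corr_from_beta <- function(alpha, beta) {
  if (!all(is.finite(alpha)) || !all(is.finite(beta)) ||
      any(alpha <= 0) || any(beta <= 0)) {
    stop("`alpha` and `beta` must be strictly positive", call. = FALSE)
  }
  list(mean_p = alpha / (alpha + beta), rho = 1 / (alpha + beta + 1))
}

#' Conjugate full conditional for a minute's detection probability
#'
#' Given the visit-level beta hyperparameters and the detection outcome of one
#' minute -- `k_detect` detections among `s_active` currently included
#' individuals -- the full conditional of that minute's detection probability
#' is Beta(alpha + k, beta + s - k).  Only included (z = 1) individuals count
#' toward `s_active`; excluded augmented rows contribute nothing.
#'
#' @param alpha,beta Positive visit-level beta shape parameters.
#' @param k_detect Number of detections in the minute.
#' @param s_active Number of currently included individuals.
#' @return A list with the updated `alpha` and `beta`.
#' @export
minute_posterior <- function(alpha, beta, k_detect, s_active) {
  if (any(k_detect < 0) || any(s_active < 0) || any(k_detect > s_active)) {
    stop("need 0 <= k_detect <= s_active: a detection was recorded for an ",
         "excluded or nonexistent individual", call. = FALSE)
  }
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("`alpha` and `beta` must be strictly positive", call. = FALSE)
  }
  list(alpha = alpha + k_detect, beta = beta + s_active - k_detect)
}

#' Inclusion probability of an all-zero augmented row
#'
#' Under data augmentation, a pseudo-individual with an all-zero detection
#' history is included (z = 1) with conditional probability
#' \deqn{\Omega q / (\Omega q + 1 - \Omega), \quad q = \prod_t (1 - p_t),}
#' where the product runs over the surveyed minutes.  Rows with at least one
#' detection are included with probability one and must not be passed here.
#'
#' @param omega Inclusion probability \eqn{\Omega} in \[0, 1\].
#' @param p Vector of per-minute detection probabilities in \[0, 1\]; may be
#'   empty, in which case the empty product gives q = 1 and the result is
#'   `omega`.
#' @return The conditional inclusion probability.
#' @export
inclusion_probability <- function(omega, p = numeric()) {
  if (!is.finite(omega) || omega < 0 || omega > 1) {
    stop("`omega` must lie in [0, 1]", call. = FALSE)
  }
  if (length(p) && (any(!is.finite(p)) || any(p < 0 | p > 1))) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  q <- exp(sum(log1p(-p)))
  num <- omega * q
  den <- num + 1 - omega
  if (den == 0) return(1)  # omega = 1 and q = 0: row is included a.s.
  num / den
}

#' Conjugate full conditional for the inclusion probability
#'
#' With a Beta(a, b) prior on \eqn{\Omega} and independent Bernoulli inclusion
#' indicators over all augmented rows in all site/visit combinations, the full
#' conditional is Beta(a + included, b + total - included).
#'
#' @param prior Length-2 positive numeric: the Beta(a, b) prior hyperpair.
#' @param n_included Number of rows currently included (z = 1).
#' @param n_total_rows Total number of augmented rows across the design.
#' @return A list with the updated `alpha` and `beta`.
#' @export
omega_posterior <- function(prior, n_included, n_total_rows) {
  if (length(prior) != 2 || any(!is.finite(prior)) || any(prior <= 0)) {
    stop("`prior` must be a positive beta hyperpair (a, b)", call. = FALSE)
  }
  if (n_included < 0 || n_total_rows < 0 || n_included > n_total_rows) {
    stop("need 0 <= n_included <= n_total_rows", call. = FALSE)
  }
  list(alpha = prior[[1]] + n_included,
       beta = prior[[2]] + n_total_rows - n_included)
}

#' Log density of detection probabilities under the visit-level beta
#'
#' Sum of log Beta(alpha, beta) densities over a vector of realized per-minute
#' detection probabilities.  This is the data term driving the Metropolis
#' update of the visit-level mean and correlation.
#'
#' @param alpha,beta Positive beta shape parameters.
#' @param p Vector of probabilities strictly inside (0, 1).
#' @return The summed log density (finite).
#' @export
hyper_loglik <- function(alpha, beta, p) {
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("`alpha` and `beta` must be strictly positive", call. = FALSE)
  }
  if (length(p) && (any(!is.finite(p)) || any(p <= 0 | p >= 1))) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  sum(dbeta(p, alpha, beta, log = TRUE))
}

#' Integrated (beta-marginalized) minute log likelihood
#'
#' Marginal log likelihood of observing `k_detect` detections among `s_active`
#' included individuals in one minute, with the minute's detection probability
#' integrated out against its Beta(alpha, beta) distribution:
#' \deqn{\log B(\alpha + k, \beta + s - k) - \log B(\alpha, \beta).}
#' This is the (unnormalized, order-specific) beta-binomial likelihood used by
#' the exact enumeration oracle; it equals 0 when `s_active` is 0.
#'
#' @param alpha,beta Positive beta shape parameters.
#' @param s_active Number of included individuals exposed in the minute.
#' @param k_detect Number of detections among them.
#' @return Log marginal likelihood; vectorized over `s_active`/`k_detect`.
#' @export
beta_binomial_loglik <- function(alpha, beta, s_active, k_detect) {
  if (any(k_detect < 0) || any(s_active < 0) || any(k_detect > s_active)) {
    stop("need 0 <= k_detect <= s_active", call. = FALSE)
  }
  if (any(alpha <= 0) || any(beta <= 0)) {
    stop("`alpha` and `beta` must be strictly positive", call. = FALSE)
  }
  lbeta(alpha + k_detect, beta + s_active - k_detect) - lbeta(alpha, beta)
}

#' Prior specification for the hierarchical detection model
#'
#' Beta hyperpairs for the inclusion probability \eqn{\Omega}, the visit-level
#' mean detection probability \eqn{\bar p_v}, and the within-minute detection
#' correlation \eqn{\rho_v}.  Defaults are flat Beta(1, 1) on each
#' interpretable scale.
#'
#' @param omega,mean_p,rho Length-2 positive numeric hyperpairs.
#' @return An object of class `bbcmr_priors`.
#' @export
bbcmr_priors <- function(omega = c(1, 1), mean_p = c(1, 1), rho = c(1, 1)) {
  for (nm in c("omega", "mean_p", "rho")) {
    h <- get(nm)
    if (length(h) != 2 || any(!is.finite(h)) || any(h <= 0)) {
      stop("prior hyperpair `", nm, "` must be two positive numbers",
           call. = FALSE)
    }
  }
  structure(list(omega = as.numeric(omega), mean_p = as.numeric(mean_p),
                 rho = as.numeric(rho)),
            class = "bbcmr_priors")
}

#' @export
print.bbcmr_priors <- function(x, ...) {
  cat("bbcmr priors:\n")
  cat(sprintf("  omega  ~ Beta(%g, %g)\n", x$omega[1], x$omega[2]))
  cat(sprintf("  mean_p ~ Beta(%g, %g)  (per visit)\n",
              x$mean_p[1], x$mean_p[2]))
  cat(sprintf("  rho    ~ Beta(%g, %g)  (per visit)\n", x$rho[1], x$rho[2]))
  invisible(x)
}
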