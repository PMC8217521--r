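# Independent oracles and small fixture builders used across the suite.
# These re-derive quantities by a different route than the package code
# (explicit enumeration, quadrature, direct formulas) so agreement is a
# genuine cross-check.

# Naive posterior of N: enumerate every z-configuration of the augmented
# rows explicitly (2^(A - n_obs) terms), integrating each minute's detection
# probability against its beta prior by the marginal beta-function ratio.
naive_posterior_N <- function(history, alpha, beta, omega, A) {
  n <- nrow(history$y)
  k_t <- if (n) colSums(history$y) else rep(0, history$duration)
  n_aug <- A - n
  stopifnot(n_aug >= 0, n_aug <= 14)
  pmf <- numeric(A - n + 1)  # over N = n .. A
  configs <- if (n_aug > 0) {
    as.matrix(expand.grid(rep(list(0:1), n_aug)))
  } else {
    matrix(0, 1, 0)
  }
  for (r in seq_len(nrow(configs))) {
    z_extra <- sum(configs[r, ])
    s <- n + z_extra
    w <- omega^(n + z_extra) * (1 - omega)^(n_aug - z_extra)
    for (t in seq_along(k_t)) {
      w <- w * exp(lbeta(alpha + k_t[t], beta + s - k_t[t]) -
                     lbeta(alpha, beta))
    }
    pmf[z_extra + 1] <- pmf[z_extra + 1] + w
  }
  pmf / sum(pmf)
}

# Direct-formula split-chain potential scale reduction factor, written
# independently of the package implementation.
reference_split_rhat <- function(chains) {
  halves <- list()
  for (x in chains) {
    h <- floor(length(x) / 2)
    halves <- c(halves, list(x[1:h]), list(x[(length(x) - h + 1):length(x)]))
  }
  n <- length(halves[[1]])
  m <- length(halves)
  chain_means <- sapply(halves, mean)
  grand <- mean(chain_means)
  B <- n / (m - 1) * sum((chain_means - grand)^2)
  W <- mean(sapply(halves, function(x) sum((x - mean(x))^2) / (n - 1)))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Beta-binomial marginal likelihood by adaptive quadrature.
quadrature_minute_lik <- function(alpha, beta, s, k) {
  stats::integrate(function(p) {
    p^k * (1 - p)^(s - k) * stats::dbeta(p, alpha, beta)
  }, 0, 1, rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# Random small capture history with at least-once-detected rows only.
random_history <- function(n_ind, t_min, visit = "v1", site = "s1",
                           p = 0.5) {
  repeat {
    y <- matrix(rbinom(n_ind * t_min, 1, p), nrow = n_ind, ncol = t_min)
    y <- y[rowSums(y) > 0, , drop = FALSE]
    if (!n_ind || nrow(y) > 0 || n_ind == 0) break
  }
  capture_history(y, visit = visit, site = site, duration = t_min)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Records data frame for a tiny hand-built example.
tiny_records <- function() {
  data.frame(
    visit = c("v1", "v1", "v1"),
    site = c("s1", "s1", "s1"),
    individual = c("A", "A", "B"),
    minute = c(1L, 2L, 2L),
    detected = c(1L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}
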