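# Convergence diagnostics and posterior summaries.

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain variant: each chain is halved (an odd middle element is
#' dropped), and the PSRF is computed from the between- and within-half
#' variances, \eqn{\hat R = \sqrt{((n-1)/n \, W + B/n) / W}}.  Values near 1
#' indicate mixing; chains that have not mixed give values well above 1.1.
#'
#' @param chains A list of two or more numeric vectors (equal length), one
#'   per chain, or a matrix with one column per chain.
#' @param split Halve each chain before computing (default `TRUE`).  With
#'   `split = FALSE` the classic multi-chain PSRF (without the
#'   degrees-of-freedom correction) is returned.
#' @return The potential scale reduction factor.  `Inf` when the within-chain
#'   variance is zero but chains differ; `NaN` when all draws are identical.
#' @export
gelman_rubin <- function(chains, split = TRUE) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (!is.list(chains) || length(chains) < 2) {
    stop("need at least two chains for the Gelman-Rubin diagnostic",
         call. = FALSE)
  }
  len <- vapply(chains, length, integer(1))
  if (any(len < 2) || length(unique(len)) != 1) {
    stop("all chains must have equal length >= 2", call. = FALSE)
  }
  if (split) {
    half <- floor(len[1] / 2)
    if (half < 2) stop("chains too short to split", call. = FALSE)
    chains <- unlist(lapply(chains, function(x) {
      list(x[seq_len(half)], x[seq.int(length(x) - half + 1, length(x))])
    }), recursive = FALSE)
  }
  n <- length(chains[[1]])
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, var, numeric(1))
  W <- mean(vars)
  B_over_n <- var(means)                      # = B/n
  var_plus <- (n - 1) / n * W + B_over_n
  sqrt(var_plus / W)
}

# Effective sample size via Geyer's initial positive sequence, computed per
# chain and summed.  Conservative truncation at the first negative paired
# autocorrelation sum.
ess_one <- function(x, max_lag = 200L) {
  n <- length(x)
  if (n < 4 || var(x) == 0) return(NA_real_)
  max_lag <- min(max_lag, n - 2L)
  rho <- as.vector(acf(x, lag.max = max_lag, plot = FALSE,
                       demean = TRUE)$acf)[-1]
  npairs <- floor(length(rho) / 2)
  ssum <- 0
  for (k in seq_len(npairs)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g < 0) break
    ssum <- ssum + g
  }
  n / (1 + 2 * ssum)
}

ess_chains <- function(chains, max_lag = 200L) {
  v <- vapply(chains, ess_one, numeric(1), max_lag = max_lag)
  if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
}

#' Summarize posterior draws of one scalar across chains
#'
#' Pools the chains for the point estimate (posterior mean) and the 2.5% and
#' 97.5% quantiles, and reports the split-chain Gelman-Rubin statistic and an
#' effective sample size (Geyer initial positive sequence, summed over
#' chains).
#'
#' @param chains List of numeric vectors (one per chain, equal length) or a
#'   single numeric vector (one chain; R-hat is then `NA`).
#' @return A one-row data frame: `mean`, `q2.5`, `q97.5`, `rhat`, `ess`.
#' @export
summarize_draws <- function(chains) {
  if (is.numeric(chains)) chains <- list(chains)
  if (!length(chains) || !length(chains[[1]])) {
    stop("empty draws", call. = FALSE)
  }
  pooled <- unlist(chains, use.names = FALSE)
  qs <- unname(quantile(pooled, c(0.025, 0.975), names = FALSE))
  rhat <- if (length(chains) >= 2 && length(chains[[1]]) >= 4) {
    suppressWarnings(gelman_rubin(chains))
  } else {
    NA_real_
  }
  data.frame(mean = mean(pooled), q2.5 = qs[1], q97.5 = qs[2],
             rhat = rhat, ess = ess_chains(chains))
}

# Summarize one monitored block: `draws` is a list (per chain) of matrices
# with a common column layout.  Returns a data frame with one row per column.
summarize_block <- function(draws) {
  K <- ncol(draws[[1]])
  out <- vector("list", K)
  for (k in seq_len(K)) {
    out[[k]] <- summarize_draws(lapply(draws, function(d) d[, k]))
  }
  do.call(rbind, out)
}
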