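# Metropolis-within-Gibbs sampler for the hierarchical beta-binomial
# capture-mark-recapture model with data augmentation.
#
# Scan order per sweep (fixed, for deterministic replay under a seed):
#   1. every per-minute detection probability p_{v,l,t} from its conjugate
#      beta full conditional (only included individuals count);
#   2. the number of included all-zero augmented rows per (visit, site).
#      All-zero rows are exchangeable, so their common conditional inclusion
#      probability c = Omega*q / (Omega*q + 1 - Omega) makes the included
#      count Binomial(A - n_obs, c) -- identical in distribution to per-row
#      Bernoulli draws, with nothing downstream depending on row identity.
#      Observed rows have z = 1 always and are never touched;
#   3. Omega from its conjugate beta full conditional over all rows;
#   4. per visit, a joint random-walk Metropolis proposal on
#      (logit mean_p_v, logit rho_v), accepted by the beta log density of the
#      realized p's plus priors plus logit Jacobians (proposals for all
#      visits are drawn and evaluated in one vectorized block).  Proposal
#      scale is adapted during burn-in only (target acceptance ~0.3).

# Flatten a list of augmented histories into index vectors the sweep loop
# can address with single vectorized calls.  Minutes are laid out site-major
# (site 1's minutes, then site 2's, ...), so per-site sums are contiguous
# segment sums.
bbcmr_prep <- function(aug_list) {
  stopifnot(length(aug_list) > 0)
  base <- lapply(aug_list, `[[`, "base")
  visit <- vapply(base, `[[`, character(1), "visit")
  site <- vapply(base, `[[`, character(1), "site")
  if (anyDuplicated(ch_key(visit, site))) {
    stop("duplicate (visit, site) combinations", call. = FALSE)
  }
  visits <- unique(visit)
  vidx <- match(visit, visits)
  n_obs <- vapply(base, function(h) nrow(h$y), integer(1))
  dur <- vapply(base, `[[`, integer(1), "duration")
  A <- vapply(aug_list, `[[`, integer(1), "A")
  k_obs <- lapply(base, function(h) {
    if (nrow(h$y)) colSums(h$y) else rep(0, h$duration)
  })
  minute_site <- rep(seq_along(base), dur)
  # 0/1 incidence of sites in visits, for visit-level segment sums
  vs_mat <- matrix(0, nrow = length(visits), ncol = length(base))
  vs_mat[cbind(vidx, seq_along(base))] <- 1
  list(
    J = length(base), V = length(visits), P = sum(dur),
    visits = visits,
    sv = data.frame(visit = visit, site = site, vidx = vidx,
                    n_obs = n_obs, duration = dur, A = A,
                    stringsAsFactors = FALSE),
    minute_site = minute_site,
    minute_visit = vidx[minute_site],
    minute_index = unlist(lapply(dur, seq_len), use.names = FALSE),
    k_flat = unlist(k_obs, use.names = FALSE),
    n_minutes_visit = as.vector(vs_mat %*% dur),
    site_ends = cumsum(dur),
    vs_mat = vs_mat,
    A_minus_n = A - n_obs
  )
}

# Contiguous segment sums: site-level totals of a minute-level vector.
segment_sums <- function(x, ends) {
  cs <- cumsum(x)
  diff(c(0, cs[ends]))
}

# Deterministic per-chain seed derivation (kept below 2^31).
chain_seed <- function(master_seed, chain) {
  s <- (as.double(master_seed) %% 2147483647) + 104729 * chain
  as.integer(s %% 2147483647) + 1L
}

# log prior density of (mean_p, rho) on the logit scale, including the
# logit Jacobians; vectorized over visits.  Normalizing beta-function
# constants cancel in the Metropolis ratio and are dropped.
logit_prior_kernel <- function(mean_p, rho, priors) {
  priors$mean_p[1] * log(mean_p) + priors$mean_p[2] * log1p(-mean_p) +
    priors$rho[1] * log(rho) + priors$rho[2] * log1p(-rho)
}

# Run one chain.  Returns retained draws and tuning metadata.
bbcmr_chain <- function(prep, priors, iter, burnin, thin, seed, store_p,
                        fixed = NULL, adapt = TRUE, init_proposal_sd = 0.4) {
  set.seed(seed)
  J <- prep$J; V <- prep$V; P <- prep$P
  ms <- prep$minute_site
  mv <- prep$minute_visit
  k_flat <- prep$k_flat
  n_obs <- prep$sv$n_obs
  Acap <- prep$A_minus_n
  n_total_rows <- sum(prep$sv$A)
  nv <- prep$n_minutes_visit
  ends <- prep$site_ends
  vs_mat <- prep$vs_mat
  sum_n_obs <- sum(n_obs)
  eps <- 1e-12

  fix_hyper <- !is.null(fixed$alpha)
  fix_omega <- !is.null(fixed$omega)

  # --- initialization (deterministic given seed) ---
  p <- (k_flat + 0.5) / (n_obs[ms] + 1)
  p <- pmin(pmax(p, 0.01), 0.99)
  if (fix_hyper) {
    alpha <- rep_len(fixed$alpha, V)
    beta <- rep_len(fixed$beta, V)
    mc <- mean_corr_from_beta(alpha, beta)
    mean_p <- mc$mean_p; rho <- mc$rho
  } else {
    mean_p <- as.vector(vs_mat %*% segment_sums(p, ends)) / nv
    mean_p <- pmin(pmax(mean_p, 0.01), 0.99)
    rho <- rep(0.2, V)
    ab <- beta_from_mean_corr(mean_p, rho)
    alpha <- ab$alpha; beta <- ab$beta
  }
  omega <- if (fix_omega) fixed$omega else {
    (sum_n_obs + 1) / (n_total_rows + 2)
  }
  m <- rbinom(J, Acap, 0.5)

  lsd <- rep(log(init_proposal_sd), V)
  acc_batch <- rep(0, V); batch_len <- 50L; batch_no <- 0L
  acc_post <- rep(0, V); post_updates <- 0L
  n_overflow <- 0L

  n_keep <- as.integer(iter)
  total <- burnin + n_keep * thin
  N_draw <- matrix(0L, n_keep, J)
  pstar_draw <- matrix(0, n_keep, J)
  mp_draw <- matrix(0, n_keep, V)
  rho_draw <- matrix(0, n_keep, V)
  om_draw <- numeric(n_keep)
  p_draw <- if (store_p) matrix(0, n_keep, P) else NULL
  keep <- 0L

  oa <- priors$omega[1]; ob <- priors$omega[2]
  theta1 <- qlogis(mean_p); theta2 <- qlogis(rho)

  for (it in seq_len(total)) {
    s_act <- n_obs + m
    # (1) conjugate update of every minute-level p
    p <- rbeta(P, alpha[mv] + k_flat, beta[mv] + s_act[ms] - k_flat)
    p[p < eps] <- eps
    p[p > 1 - eps] <- 1 - eps
    l1 <- log1p(-p)
    lq <- segment_sums(l1, ends)
    q <- exp(lq)
    # (2) included augmented rows per site (exchangeable all-zero rows)
    num <- omega * q
    cc <- num / (num + 1 - omega)
    m <- rbinom(J, Acap, cc)
    # (3) conjugate update of Omega
    if (!fix_omega) {
      inc <- sum_n_obs + sum(m)
      omega <- rbeta(1, oa + inc, ob + n_total_rows - inc)
      omega <- min(max(omega, eps), 1 - eps)
    }
    # (4) joint logit-scale Metropolis update of (mean_p_v, rho_v),
    #     proposals for all visits drawn and scored in one block
    if (!fix_hyper) {
      Slp <- as.vector(vs_mat %*% segment_sums(log(p), ends))
      Sl1 <- as.vector(vs_mat %*% lq)
      step <- exp(lsd)
      prop1 <- theta1 + rnorm(V, 0, step)
      prop2 <- theta2 + rnorm(V, 0, step)
      mpn <- plogis(prop1); rhn <- plogis(prop2)
      bad <- !is.finite(prop1) | !is.finite(prop2) |
        mpn <= 0 | mpn >= 1 | rhn <= 0 | rhn >= 1
      n_overflow <- n_overflow + sum(bad)
      mpn[bad] <- 0.5; rhn[bad] <- 0.5  # placeholder; rejected below
      nun <- (1 - rhn) / rhn
      an <- mpn * nun; bn <- (1 - mpn) * nun
      ll_new <- -nv * lbeta(an, bn) + (an - 1) * Slp + (bn - 1) * Sl1 +
        logit_prior_kernel(mpn, rhn, priors)
      ll_cur <- -nv * lbeta(alpha, beta) + (alpha - 1) * Slp +
        (beta - 1) * Sl1 + logit_prior_kernel(mean_p, rho, priors)
      accept <- !bad & is.finite(ll_new) &
        log(runif(V)) < ll_new - ll_cur
      if (any(accept)) {
        mean_p[accept] <- mpn[accept]; rho[accept] <- rhn[accept]
        alpha[accept] <- an[accept]; beta[accept] <- bn[accept]
        theta1[accept] <- prop1[accept]; theta2[accept] <- prop2[accept]
      }
      if (it <= burnin) {
        acc_batch <- acc_batch + accept
        if (adapt && it %% batch_len == 0L) {
          batch_no <- batch_no + 1L
          lsd <- lsd + (acc_batch / batch_len - 0.3) / sqrt(batch_no)
          acc_batch[] <- 0
        }
      } else {
        acc_post <- acc_post + accept
        post_updates <- post_updates + 1L
      }
    }
    # retain
    if (it > burnin && (it - burnin) %% thin == 0L) {
      keep <- keep + 1L
      N_draw[keep, ] <- n_obs + m
      pstar_draw[keep, ] <- -expm1(lq)
      mp_draw[keep, ] <- mean_p
      rho_draw[keep, ] <- rho
      om_draw[keep] <- omega
      if (store_p) p_draw[keep, ] <- p
    }
  }

  list(N = N_draw, pstar = pstar_draw, mean_p = mp_draw, rho = rho_draw,
       omega = om_draw, p = p_draw, seed = seed,
       accept_rate = if (post_updates > 0) acc_post / post_updates else
         rep(NA_real_, V),
       proposal_sd = exp(lsd), n_overflow = n_overflow)
}

# Run several chains with deterministically derived seeds.
bbcmr_engine <- function(aug_list, priors = bbcmr_priors(), chains = 3,
                         iter = 120000, burnin = 60000, thin = 1,
                         seed = 1L, store_p = TRUE, fixed = NULL,
                         adapt = TRUE, init_proposal_sd = 0.4) {
  if (chains < 1) stop("`chains` must be >= 1", call. = FALSE)
  if (iter < 1) stop("no retained iterations: `iter` must be >= 1",
                     call. = FALSE)
  if (burnin < 0 || thin < 1) stop("invalid `burnin`/`thin`", call. = FALSE)
  prep <- bbcmr_prep(aug_list)
  seeds <- vapply(seq_len(chains), chain_seed, integer(1),
                  master_seed = seed)
  runs <- lapply(seeds, function(s) {
    bbcmr_chain(prep, priors, iter = iter, burnin = burnin, thin = thin,
                seed = s, store_p = store_p, fixed = fixed, adapt = adapt,
                init_proposal_sd = init_proposal_sd)
  })
  overflow <- sum(vapply(runs, `[[`, integer(1), "n_overflow"))
  if (overflow > 0) {
    warning(sprintf(
      "%d hyperparameter proposal(s) rejected for logit-scale overflow",
      overflow), call. = FALSE)
  }
  list(prep = prep, chains = runs, seeds = seeds)
}
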