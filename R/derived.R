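# Posterior functionals of a fitted model: abundance tables, visit totals,
# detection summaries, count-vs-estimate and survey-duration comparisons.

#' Site/visit abundance estimates
#'
#' @param fit A `bbcmr_fit`.
#' @return Data frame per (visit, site): observed count `n_obs`, posterior
#'   mean of N, 95% credible interval, R-hat and effective sample size.
#' @export
site_abundance <- function(fit) {
  stopifnot(inherits(fit, "bbcmr_fit"))
  fit$summary$N
}

# Per-chain draw matrices of visit totals M_v over non-excluded sites.
visit_total_draws <- function(fit, exclude = character()) {
  sv <- fit$prep$sv
  unknown <- setdiff(exclude, sv$site)
  if (length(unknown)) {
    stop("exclusion list names unknown site(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  visits <- fit$prep$visits
  lapply(fit$draws, function(ch) {
    M <- matrix(0, nrow(ch$N), length(visits),
                dimnames = list(NULL, visits))
    for (v in seq_along(visits)) {
      cols <- which(sv$vidx == v & !(sv$site %in% exclude))
      if (length(cols)) {
        M[, v] <- rowSums(ch$N[, cols, drop = FALSE])
      }
    }
    M
  })
}

#' Visit-level total abundance
#'
#' Sums site abundances within each visit per posterior draw, so the credible
#' interval reflects the joint posterior rather than a sum of site-level
#' intervals.  Sites surveyed in only some visits can be excluded from every
#' total to keep the totals comparable across visits.
#'
#' @param fit A `bbcmr_fit`.
#' @param exclude Character vector of site ids to leave out of all totals.
#' @return Data frame per visit: total observed count, posterior mean of
#'   M_v, 95% CI, R-hat, ESS.
#' @export
visit_totals <- function(fit, exclude = character()) {
  stopifnot(inherits(fit, "bbcmr_fit"))
  draws <- visit_total_draws(fit, exclude)
  sv <- fit$prep$sv
  visits <- fit$prep$visits
  counts <- vapply(seq_along(visits), function(v) {
    sum(sv$n_obs[sv$vidx == v & !(sv$site %in% exclude)])
  }, numeric(1))
  cbind(data.frame(visit = visits, count = counts, stringsAsFactors = FALSE),
        summarize_block(draws))
}

#' Cumulative detection probability by site and visit
#'
#' Probability of detecting an individual at least once over the surveyed
#' minutes, computed per posterior draw from the realized per-minute
#' detection probabilities, \eqn{p^* = 1 - \prod_t (1 - p_{v,l,t})}.
#'
#' @param fit A `bbcmr_fit`.
#' @return Data frame per (visit, site): duration, posterior mean and 95% CI
#'   of p*, R-hat, ESS.
#' @export
cumulative_detection <- function(fit) {
  stopifnot(inherits(fit, "bbcmr_fit"))
  fit$summary$pstar
}

#' Detection-probability summaries at visit, site and minute level
#'
#' Visit-level mean detection \eqn{\bar p_v} and correlation \eqn{\rho_v}
#' are summarized from the hyperparameter draws.  Site-level mean detection
#' is computed per draw as the average of the realized per-minute
#' probabilities over all minutes surveyed at that site, pooled across
#' visits weighted by surveyed-minute counts (the per-visit breakdown is in
#' the minute table).  Minute-level summaries cover every
#' (visit, site, minute).
#'
#' @param fit A `bbcmr_fit`; site and minute tables need `store_p = TRUE`.
#' @return A list of data frames: `visit`, `site`, `minute`.
#' @export
detection_means <- function(fit) {
  stopifnot(inherits(fit, "bbcmr_fit"))
  visit <- cbind(fit$summary$mean_p[c("visit", "mean", "q2.5", "q97.5",
                                      "rhat", "ess")],
                 rho_mean = fit$summary$rho$mean,
                 rho_q2.5 = fit$summary$rho$q2.5,
                 rho_q97.5 = fit$summary$rho$q97.5)
  if (!fit$config$store_p) {
    message("minute-level draws were not stored; returning visit-level table only")
    return(list(visit = visit, site = NULL, minute = NULL))
  }
  prep <- fit$prep
  minute <- cbind(
    data.frame(visit = prep$sv$visit[prep$minute_site],
               site = prep$sv$site[prep$minute_site],
               minute = prep$minute_index, stringsAsFactors = FALSE),
    summarize_block(lapply(fit$draws, `[[`, "p"))
  )
  sites <- prep$sv$site
  site_ids <- unique(sites)
  site_rows <- lapply(site_ids, function(s) {
    cols <- which(sites[prep$minute_site] == s)
    draws <- lapply(fit$draws, function(ch) {
      as.matrix(rowMeans(ch$p[, cols, drop = FALSE]))
    })
    cbind(data.frame(site = s, n_minutes = length(cols),
                     stringsAsFactors = FALSE),
          summarize_block(draws))
  })
  list(visit = visit, site = do.call(rbind, site_rows), minute = minute)
}

#' Observed counts versus abundance estimates
#'
#' @param fit A `bbcmr_fit`.
#' @return Data frame per (visit, site): observed count, posterior mean N,
#'   and their difference, with attributes `mean_diff` and `max_diff`
#'   aggregating over all rows (also returned as the list columns of the
#'   `aggregate` attribute).
#' @export
count_vs_estimate <- function(fit) {
  stopifnot(inherits(fit, "bbcmr_fit"))
  tab <- fit$summary$N
  out <- data.frame(visit = tab$visit, site = tab$site, count = tab$n_obs,
                    estimate = tab$mean, difference = tab$mean - tab$n_obs,
                    stringsAsFactors = FALSE)
  attr(out, "mean_diff") <- mean(out$difference)
  attr(out, "max_diff") <- max(out$difference)
  out
}

#' Compare fits at two survey durations
#'
#' Compares abundance estimates from two fits of the same survey data
#' analyzed at different durations (e.g. the full 10-minute histories and
#' their 6-minute truncation): per (visit, site), both posterior means, both
#' 95% CI widths, and their differences, plus aggregate mean absolute
#' difference in N and the ratio of mean CI widths.
#'
#' @param fit_short Fit at the shorter duration.
#' @param fit_long Fit at the longer duration.
#' @return An object of class `bbcmr_duration_comparison`: a list with the
#'   per-site `table`, `mean_abs_diff`, and `ci_width_ratio`
#'   (mean short-duration width / mean long-duration width).
#' @export
compare_durations <- function(fit_short, fit_long) {
  stopifnot(inherits(fit_short, "bbcmr_fit"), inherits(fit_long, "bbcmr_fit"))
  a <- fit_short$summary$N
  b <- fit_long$summary$N
  if (nrow(a) != nrow(b) ||
      !all(a$visit == b$visit) || !all(a$site == b$site)) {
    stop("the two fits cover different (visit, site) combinations; ",
         "fit the same survey at both durations", call. = FALSE)
  }
  tab <- data.frame(
    visit = a$visit, site = a$site,
    mean_short = a$mean, mean_long = b$mean,
    diff = a$mean - b$mean,
    width_short = a$q97.5 - a$q2.5,
    width_long = b$q97.5 - b$q2.5,
    stringsAsFactors = FALSE
  )
  tab$width_diff <- tab$width_short - tab$width_long
  structure(list(
    table = tab,
    mean_abs_diff = mean(abs(tab$diff)),
    ci_width_ratio = if (mean(tab$width_long) > 0) {
      mean(tab$width_short) / mean(tab$width_long)
    } else {
      NA_real_
    }
  ), class = "bbcmr_duration_comparison")
}

#' @export
print.bbcmr_duration_comparison <- function(x, digits = 3, ...) {
  cat("Survey-duration comparison (short vs long analysis window)\n")
  cat(sprintf("  mean |difference in N|: %.3f\n", x$mean_abs_diff))
  cat(sprintf("  mean CI width ratio (short/long): %.3f\n", x$ci_width_ratio))
  print(format_summary_df(x$table, digits))
  invisible(x)
}
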