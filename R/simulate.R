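# Synthetic survey generation with the exact statistical structure the model
# assumes: visit-level beta-distributed per-minute detection shared by all
# individuals within a minute (which is what induces the within-minute
# correlation), plus an optional closure-violation hook.

#' Define a survey design
#'
#' @param visit,site Character vectors (recycled against each other) listing
#'   the (visit, site) combinations surveyed; the design may be ragged.
#' @param duration Surveyed minutes per combination (recycled; typically 6
#'   or 10).
#' @param A Augmentation cap intended for the analysis (default 100); used
#'   to validate simulated abundances.
#' @return A data frame of class `survey_design` with columns `visit`,
#'   `site`, `duration` and attribute `A`.
#' @export
survey_design <- function(visit, site, duration = 10, A = 100) {
  n <- max(length(visit), length(site), length(duration))
  df <- data.frame(visit = as.character(rep_len(visit, n)),
                   site = as.character(rep_len(site, n)),
                   duration = as.integer(rep_len(duration, n)),
                   stringsAsFactors = FALSE)
  if (any(df$duration < 1)) stop("durations must be >= 1", call. = FALSE)
  if (anyDuplicated(ch_key(df$visit, df$site))) {
    stop("duplicate (visit, site) combinations in design", call. = FALSE)
  }
  attr(df, "A") <- as.integer(A)
  class(df) <- c("survey_design", "data.frame")
  df
}

#' Simulate a survey from the detection model
#'
#' Generates capture histories exactly as the model assumes: per visit the
#' beta shapes are derived from `mean_p` and `rho`; each (site, minute) draws
#' one detection probability from that beta; every individual present is
#' detected that minute as an independent Bernoulli with the *same* shared
#' probability (this sharing induces the within-minute correlation `rho`).
#' Individuals never detected are recorded in the truth but absent from the
#' observed histories.  Output individual labels are anonymized and
#' shuffled.
#'
#' @param design A [survey_design()].
#' @param mean_p,rho Visit-level mean detection probability and within-minute
#'   correlation: scalars or vectors named by / aligned with the design's
#'   unique visits.
#' @param N True abundance per design row (recycled), or `NULL` to draw each
#'   row's abundance as Binomial(A, `omega`).
#' @param omega Inclusion probability used when `N` is `NULL`.
#' @param seed Optional seed; the simulation is fully reproducible given it.
#' @return An object of class `bbcmr_sim`: list with `design`, `truth`
#'   (true N, mean_p, rho, alpha, beta, realized p, full detection matrices,
#'   omega, seed) and `histories` (a `capture_history_set` of observed
#'   individuals only).
#' @export
simulate_survey <- function(design, mean_p, rho, N = NULL, omega = NULL,
                            seed = NULL) {
  stopifnot(inherits(design, "survey_design"))
  if (!is.null(seed)) set.seed(seed)
  A <- attr(design, "A")
  visits <- unique(design$visit)
  V <- length(visits)
  mean_p <- align_visit_param(mean_p, visits, "mean_p")
  rho <- align_visit_param(rho, visits, "rho")
  ab <- beta_from_mean_corr(mean_p, rho)

  if (is.null(N)) {
    if (is.null(omega) || omega <= 0 || omega >= 1) {
      stop("supply true `N` or an `omega` in (0, 1) to draw it",
           call. = FALSE)
    }
    N <- rbinom(nrow(design), A, omega)
  } else {
    N <- as.integer(rep_len(N, nrow(design)))
  }
  if (any(N < 0) || any(N > A)) {
    stop("true abundances must lie in [0, A]; raise the design's A",
         call. = FALSE)
  }

  histories <- vector("list", nrow(design))
  p_real <- vector("list", nrow(design))
  y_full <- vector("list", nrow(design))
  for (j in seq_len(nrow(design))) {
    v <- match(design$visit[j], visits)
    Tj <- design$duration[j]
    p <- rbeta(Tj, ab$alpha[v], ab$beta[v])
    y <- matrix(rbinom(N[j] * Tj, 1, rep(p, each = N[j])),
                nrow = N[j], ncol = Tj)
    p_real[[j]] <- p
    y_full[[j]] <- y
    histories[[j]] <- observed_history(y, design$visit[j], design$site[j], Tj)
  }
  structure(list(
    design = design,
    truth = list(N = cbind(design[c("visit", "site", "duration")], N = N),
                 mean_p = setNames(mean_p, visits),
                 rho = setNames(rho, visits),
                 alpha = setNames(ab$alpha, visits),
                 beta = setNames(ab$beta, visits),
                 p = p_real, y_full = y_full, omega = omega, seed = seed),
    histories = capture_history_set(histories)
  ), class = "bbcmr_sim")
}

align_visit_param <- function(x, visits, what) {
  if (!is.null(names(x))) {
    if (!all(visits %in% names(x))) {
      stop("`", what, "` must name every visit", call. = FALSE)
    }
    x <- x[visits]
  } else {
    x <- rep_len(x, length(visits))
  }
  unname(x)
}

# Keep only ever-detected rows, anonymize and shuffle labels.
observed_history <- function(y, visit, site, duration) {
  y <- y[rowSums(y) > 0, , drop = FALSE]
  if (nrow(y) > 1) y <- y[sample.int(nrow(y)), , drop = FALSE]
  rownames(y) <- if (nrow(y)) sprintf("ind%03d", seq_len(nrow(y))) else NULL
  capture_history(y, visit = visit, site = site, duration = duration)
}

#' @export
print.bbcmr_sim <- function(x, ...) {
  cat("simulated survey\n")
  cat(sprintf("  true total N = %d over %d site/visit combinations\n",
              sum(x$truth$N$N), nrow(x$design)))
  cat(sprintf("  observed individuals = %d\n",
              sum(vapply(x$histories$histories, n_observed, integer(1)))))
  invisible(x)
}

#' Long-format annotation records of a simulated survey
#'
#' Emits the observed capture histories in the same long CSV shape that
#' [read_annotations()] ingests: one row per observed individual x minute
#' with a 0/1 `detected` flag, so the full pipeline can be exercised
#' end-to-end from simulated data alone.
#'
#' @param sim A `bbcmr_sim`.
#' @return Data frame of detection records.
#' @export
sim_annotations <- function(sim) {
  stopifnot(inherits(sim, "bbcmr_sim"))
  out <- lapply(sim$histories$histories, function(h) {
    n <- nrow(h$y)
    if (!n) return(NULL)
    data.frame(visit = h$visit, site = h$site,
               individual = rep(rownames(h$y), h$duration),
               minute = rep(seq_len(h$duration), each = n),
               detected = as.integer(h$y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(visit = character(), site = character(),
                      individual = character(), minute = integer(),
                      detected = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Durations table of a simulated survey
#'
#' @param sim A `bbcmr_sim`.
#' @return Data frame with `visit`, `site`, `duration` (for
#'   [build_history_set()]; needed because zero-detection sites cannot have
#'   their duration inferred from records).
#' @export
sim_durations <- function(sim) {
  stopifnot(inherits(sim, "bbcmr_sim"))
  as.data.frame(sim$design[c("visit", "site", "duration")])
}

#' Preset survey emulating a winter thermal-refuge monitoring study
#'
#' A fixed study layout: 4 winter visits over 15 site labels -- 12 canals, a
#' set of mitigation pools, a pond, and a preserve site surveyed only on the
#' last visit.  Visit-level mean detection is drawn uniformly in
#' \[0.29, 0.54\] and the detection correlation in \[0.11, 0.28\]; true
#' site/visit abundances range 0-47 with one heavily used canal (30-47),
#' several consistently used sites, occasional users, structural zeros, and
#' pools that stay nearly empty until the final visit.  Sites with no
#' animals present are surveyed for 6 minutes (the hover is cut short when
#' nothing is seen), all others for 10.
#'
#' @param seed Optional seed.
#' @return A `bbcmr_sim` (see [simulate_survey()]).
#' @export
refuge_preset <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  visits <- paste0("visit_", 1:4)
  canals <- sprintf("canal_%02d", 1:12)
  sites <- c(canals, "pools", "pond", "preserve")

  N <- matrix(0L, nrow = 4, ncol = length(sites),
              dimnames = list(visits, sites))
  N[, "canal_02"] <- sample(30:47, 4, replace = TRUE)   # heavy, consistent
  N[, "canal_03"] <- sample(8:25, 4, replace = TRUE)    # consistent
  N[, "canal_07"] <- sample(3:18, 4, replace = TRUE)    # consistent
  N[, "pond"] <- sample(4:15, 4, replace = TRUE)        # consistent
  for (s in c("canal_04", "canal_05", "canal_06", "canal_10")) {
    use <- runif(4) < 0.5                               # occasional
    N[use, s] <- sample(1:8, sum(use), replace = TRUE)
  }
  for (s in c("canal_01", "canal_09", "canal_12")) {
    N[, s] <- sample(0:12, 4, replace = TRUE)           # variable
  }
  # canal_08 and canal_11 stay structural zeros; pools nearly empty until
  # the last visit, when use jumps.
  N[1:3, "pools"] <- sample(0:2, 3, replace = TRUE)
  N[4, "pools"] <- sample(20:30, 1)
  N[4, "preserve"] <- sample(5:15, 1)

  rows <- expand.grid(site = sites, visit = visits,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[rows$site != "preserve" | rows$visit == "visit_4", ]
  Nvec <- N[cbind(rows$visit, rows$site)]
  design <- survey_design(rows$visit, rows$site,
                          duration = ifelse(Nvec > 0, 10L, 6L), A = 100)
  simulate_survey(design,
                  mean_p = runif(4, 0.29, 0.54),
                  rho = runif(4, 0.11, 0.28),
                  N = Nvec, seed = NULL)
}

#' Inject a closure violation into a simulated survey
#'
#' The closed-population model assumes no movement in or out of a site
#' during the hover.  This hook makes each true individual independently
#' depart with probability `departure_rate`; a departing individual leaves
#' at the start of a uniformly drawn minute d (so it is present only for
#' minutes 1..d-1) and all its detections from minute d on are erased.
#' Only departures are modeled; arrivals are not.
#'
#' @param sim A `bbcmr_sim`.
#' @param departure_rate Probability in \[0, 1\] that an individual departs.
#' @param seed Optional seed.
#' @param departure_minute Optional fixed departure minute applied to every
#'   departing individual (otherwise uniform on 1..duration).
#' @return A modified `bbcmr_sim` whose truth records the departure minutes
#'   (`NA` for individuals that stay).
#' @export
inject_closure_violation <- function(sim, departure_rate, seed = NULL,
                                     departure_minute = NULL) {
  stopifnot(inherits(sim, "bbcmr_sim"))
  if (departure_rate < 0 || departure_rate > 1) {
    stop("`departure_rate` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (departure_rate == 0) return(sim)
  design <- sim$design
  departures <- vector("list", nrow(design))
  for (j in seq_len(nrow(design))) {
    y <- sim$truth$y_full[[j]]
    Tj <- design$duration[j]
    n <- nrow(y)
    dep <- rep(NA_integer_, n)
    if (n) {
      leaves <- runif(n) < departure_rate
      dep[leaves] <- if (is.null(departure_minute)) {
        sample.int(Tj, sum(leaves), replace = TRUE)
      } else {
        rep(min(as.integer(departure_minute), Tj), sum(leaves))
      }
      for (i in which(leaves)) y[i, dep[i]:Tj] <- 0
    }
    sim$truth$y_full[[j]] <- y
    departures[[j]] <- dep
    sim$histories$histories[[j]] <- observed_history(
      y, design$visit[j], design$site[j], Tj)
  }
  sim$truth$departures <- departures
  sim
}
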