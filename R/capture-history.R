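# Capture-history containers: per-(visit, site) binary detection matrices,
# ragged sets of them, truncation to a shorter survey window, and data
# augmentation with all-zero pseudo-individual rows.

ch_key <- function(visit, site) paste(visit, site, sep = "::")

#' Construct a capture history
#'
#' A capture history holds the binary detection matrix for one site on one
#' visit: one row per observed individual, one column per surveyed minute.
#' Every observed individual must have been detected at least once; matrices
#' with zero rows are valid and represent sites where nothing was seen.
#'
#' @param y Binary matrix (entries 0/1), rows = individuals, columns =
#'   minutes.  A zero-row matrix is allowed; pass `duration` explicitly then
#'   if `y` has no columns.
#' @param visit,site Identifiers for the visit and the site.
#' @param duration Survey duration in minutes; must equal `ncol(y)`.
#' @param labels Optional individual row labels (defaults to rownames or
#'   generated labels).
#' @return An object of class `capture_history`.
#' @export
capture_history <- function(y, visit, site, duration = ncol(y),
                            labels = rownames(y)) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  duration <- as.integer(duration)
  if (is.na(duration) || duration < 1) {
    stop("`duration` must be a positive integer number of minutes",
         call. = FALSE)
  }
  if (ncol(y) != duration) {
    stop("`y` must have exactly `duration` columns", call. = FALSE)
  }
  if (nrow(y) && !all(y %in% c(0, 1))) {
    stop("all detection entries must be 0 or 1", call. = FALSE)
  }
  if (nrow(y) && any(rowSums(y) == 0)) {
    stop("every observed individual must have at least one detection; ",
         "all-zero rows are not valid observed histories", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- if (nrow(y)) sprintf("ind%03d", seq_len(nrow(y))) else character()
  }
  rownames(y) <- labels
  colnames(y) <- seq_len(duration)
  structure(list(visit = as.character(visit), site = as.character(site),
                 duration = duration, y = y),
            class = "capture_history")
}

#' Number of observed individuals in a capture history
#' @param history A `capture_history` (or `augmented_history`).
#' @return Integer count of observed rows.
#' @export
n_observed <- function(history) {
  if (inherits(history, "augmented_history")) history <- history$base
  nrow(history$y)
}

#' @export
print.capture_history <- function(x, ...) {
  cat(sprintf("capture history: visit %s, site %s (%d min, %d observed)\n",
              x$visit, x$site, x$duration, nrow(x$y)))
  if (nrow(x$y)) print(x$y)
  invisible(x)
}

#' Construct a set of capture histories
#'
#' Bundles capture histories keyed by (visit, site).  The design may be
#' ragged: a site can be absent from some visits, and no missing combinations
#' are imputed.
#'
#' @param histories A list of `capture_history` objects with unique
#'   (visit, site) keys.
#' @return An object of class `capture_history_set` with the histories plus
#'   ordered visit and site rosters (order of first appearance).
#' @export
capture_history_set <- function(histories) {
  if (!length(histories)) {
    stop("`histories` must contain at least one capture history", call. = FALSE)
  }
  ok <- vapply(histories, inherits, logical(1), what = "capture_history")
  if (!all(ok)) stop("all elements must be capture_history objects",
                     call. = FALSE)
  visits <- vapply(histories, `[[`, character(1), "visit")
  sites <- vapply(histories, `[[`, character(1), "site")
  keys <- ch_key(visits, sites)
  if (anyDuplicated(keys)) {
    stop("duplicate (visit, site) combinations in history set", call. = FALSE)
  }
  names(histories) <- keys
  structure(list(histories = histories,
                 visits = unique(visits), sites = unique(sites)),
            class = "capture_history_set")
}

#' @export
print.capture_history_set <- function(x, ...) {
  n <- vapply(x$histories, n_observed, integer(1))
  d <- vapply(x$histories, `[[`, integer(1), "duration")
  cat(sprintf("capture history set: %d visits, %d sites, %d site/visit combinations\n",
              length(x$visits), length(x$sites), length(x$histories)))
  cat(sprintf("  observed individuals: %d total; durations %s min\n",
              sum(n), paste(sort(unique(d)), collapse = "/")))
  invisible(x)
}

#' Tabulate a capture history set
#'
#' @param x A `capture_history_set`.
#' @param ... Unused.
#' @return A data frame with one row per (visit, site): visit, site,
#'   duration, and the observed count `n_obs`.
#' @export
as.data.frame.capture_history_set <- function(x, ...) {
  data.frame(
    visit = vapply(x$histories, `[[`, character(1), "visit"),
    site = vapply(x$histories, `[[`, character(1), "site"),
    duration = vapply(x$histories, `[[`, integer(1), "duration"),
    n_obs = vapply(x$histories, n_observed, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Build a capture history set from long-format detection records
#'
#' Converts validated long-format records (one row per individual x minute,
#' as returned by [read_annotations()] or emitted by the survey simulator)
#' into per-(visit, site) detection matrices.  Minutes without a record are
#' filled with 0.  Individuals that appear in the records but are never
#' scored detected are dropped with a warning (an annotated-but-never-seen
#' individual is treated as an annotation slip, not an error).
#'
#' @param records Data frame with columns `visit`, `site`, `individual`,
#'   `minute`, `detected`.
#' @param durations Optional data frame with columns `visit`, `site`,
#'   `duration` declaring the survey length of every (visit, site); site/visit
#'   combinations declared here but absent from `records` become zero-row
#'   histories.  When `NULL`, each duration is inferred as the largest minute
#'   present for that combination (with a notice; inference is unsafe for
#'   sites with no detections, so declared durations are recommended).
#' @return A `capture_history_set`.
#' @export
build_history_set <- function(records, durations = NULL) {
  records <- validate_records(records)
  if (!is.null(durations)) {
    durations <- as.data.frame(durations)
    need <- c("visit", "site", "duration")
    if (!all(need %in% names(durations))) {
      stop("`durations` must have columns visit, site, duration", call. = FALSE)
    }
    durations$visit <- as.character(durations$visit)
    durations$site <- as.character(durations$site)
    durations$duration <- as.integer(durations$duration)
    if (any(is.na(durations$duration)) || any(durations$duration < 1)) {
      stop("all declared durations must be positive integers", call. = FALSE)
    }
    if (anyDuplicated(ch_key(durations$visit, durations$site))) {
      stop("duplicate (visit, site) rows in `durations`", call. = FALSE)
    }
  } else if (nrow(records)) {
    durations <- aggregate_durations(records)
    message("survey durations inferred as the largest minute present per ",
            "(visit, site); declare durations explicitly for zero-detection sites")
  } else {
    stop("no records and no declared durations: nothing to build", call. = FALSE)
  }

  rec_keys <- ch_key(records$visit, records$site)
  dur_keys <- ch_key(durations$visit, durations$site)
  missing_dur <- setdiff(unique(rec_keys), dur_keys)
  if (length(missing_dur)) {
    stop("no duration declared for: ", paste(missing_dur, collapse = ", "),
         call. = FALSE)
  }

  dropped <- 0L
  histories <- vector("list", nrow(durations))
  for (i in seq_len(nrow(durations))) {
    v <- durations$visit[i]; s <- durations$site[i]
    tmax <- durations$duration[i]
    sub <- records[rec_keys == dur_keys[i], , drop = FALSE]
    if (nrow(sub) && max(sub$minute) > tmax) {
      stop(sprintf("record at minute %d exceeds declared duration %d for (%s, %s)",
                   max(sub$minute), tmax, v, s), call. = FALSE)
    }
    if (nrow(sub)) {
      inds <- sort(unique(sub$individual))
      y <- matrix(0, nrow = length(inds), ncol = tmax,
                  dimnames = list(inds, seq_len(tmax)))
      y[cbind(match(sub$individual, inds), sub$minute)] <- sub$detected
      keep <- rowSums(y) > 0
      dropped <- dropped + sum(!keep)
      y <- y[keep, , drop = FALSE]
    } else {
      y <- matrix(0, nrow = 0, ncol = tmax)
    }
    histories[[i]] <- capture_history(y, visit = v, site = s, duration = tmax)
  }
  if (dropped > 0) {
    warning(sprintf(
      "%d individual(s) annotated but never scored detected were dropped",
      dropped), call. = FALSE)
  }
  capture_history_set(histories)
}

aggregate_durations <- function(records) {
  agg <- stats::aggregate(minute ~ visit + site, data = records, FUN = max)
  names(agg)[names(agg) == "minute"] <- "duration"
  agg
}

#' Truncate capture histories to a shorter survey window
#'
#' Keeps only the first `t_new` minutes of each history, emulating analysis of
#' a shorter hover.  Individuals first seen after the truncation point become
#' unobserved and their (now all-zero) rows are removed.  Histories no longer
#' than `t_new` pass through unchanged.
#'
#' @param x A `capture_history` or `capture_history_set`.
#' @param t_new Positive integer number of minutes to keep.
#' @return An object of the same class as `x`.
#' @export
truncate_minutes <- function(x, t_new) {
  UseMethod("truncate_minutes")
}

#' @export
truncate_minutes.capture_history <- function(x, t_new) {
  t_new <- as.integer(t_new)
  if (is.na(t_new) || t_new < 1) stop("`t_new` must be >= 1", call. = FALSE)
  if (x$duration <= t_new) return(x)
  y <- x$y[, seq_len(t_new), drop = FALSE]
  y <- y[rowSums(y) > 0, , drop = FALSE]
  capture_history(y, visit = x$visit, site = x$site, duration = t_new)
}

#' @export
truncate_minutes.capture_history_set <- function(x, t_new) {
  capture_history_set(lapply(x$histories, truncate_minutes, t_new = t_new))
}

#' Augment a capture history with all-zero pseudo-individuals
#'
#' Pads the observed detection matrix with all-zero rows up to a fixed cap
#' `A`, the parameter-expanded data augmentation used for abundance
#' estimation.  The observed block is preserved bit-identically.
#'
#' @param history A `capture_history`.
#' @param A Augmentation cap: total number of rows after padding
#'   (default 100).
#' @return An object of class `augmented_history` with elements `base`
#'   (the input), `A`, and `y_aug` (the A-row matrix).
#' @export
augment_history <- function(history, A = 100) {
  stopifnot(inherits(history, "capture_history"))
  A <- as.integer(A)
  n <- nrow(history$y)
  if (is.na(A) || A < n) {
    stop(sprintf(
      "augmentation cap A = %d is smaller than the %d observed individuals; raise A",
      A, n), call. = FALSE)
  }
  y_aug <- rbind(history$y,
                 matrix(0, nrow = A - n, ncol = history$duration))
  rownames(y_aug) <- c(rownames(history$y),
                       if (A > n) sprintf("aug%03d", seq_len(A - n)))
  structure(list(base = history, A = A, y_aug = y_aug),
            class = "augmented_history")
}

#' @export
print.augmented_history <- function(x, ...) {
  cat(sprintf(
    "augmented history: visit %s, site %s (%d min, %d observed + %d all-zero rows)\n",
    x$base$visit, x$base$site, x$base$duration, nrow(x$base$y),
    x$A - nrow(x$base$y)))
  invisible(x)
}

# Augment every history in a set to a common cap.
augment_set <- function(hset, A = 100) {
  stopifnot(inherits(hset, "capture_history_set"))
  lapply(hset$histories, augment_history, A = A)
}
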