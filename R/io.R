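# Reading and writing the plain-text interchange formats: long-format
# annotation CSVs (the shape of tabular exports from video-annotation tools),
# per-site detection-matrix CSVs, and a JSON manifest for a history set.

canonical_columns <- c(visit = "visit", site = "site",
                       individual = "individual", minute = "minute",
                       detected = "detected")

#' Read long-format detection annotations
#'
#' Reads a comma-delimited file with one row per (visit, site, individual,
#' minute) scoring whether that individual was detected in that minute --
#' the long format produced when per-minute resighting histories are scored
#' from survey video.  Column names can be remapped to tolerate export
#' variants.
#'
#' @param path Path to a CSV file with a header.
#' @param columns Named character vector mapping the canonical names
#'   (`visit`, `site`, `individual`, `minute`, `detected`) to the column
#'   names used in the file.  Unnamed entries default to the canonical names.
#' @return A validated data frame of detection records with the canonical
#'   column names.  Duplicated records that agree are dropped with a warning;
#'   duplicates with conflicting `detected` values are an error.
#' @export
read_annotations <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  map <- canonical_columns
  if (!is.null(columns)) {
    if (is.null(names(columns)) || !all(names(columns) %in% names(map))) {
      stop("`columns` must be named with a subset of: ",
           paste(names(map), collapse = ", "), call. = FALSE)
    }
    map[names(columns)] <- columns
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unname(map), names(raw))
  if (length(missing)) {
    stop("annotation file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rec <- data.frame(
    visit = as.character(raw[[map[["visit"]]]]),
    site = as.character(raw[[map[["site"]]]]),
    individual = as.character(raw[[map[["individual"]]]]),
    minute = raw[[map[["minute"]]]],
    detected = raw[[map[["detected"]]]],
    stringsAsFactors = FALSE
  )
  validate_records(rec)
}

# Shared validation for annotation records (file-read or simulator-emitted).
validate_records <- function(records) {
  records <- as.data.frame(records)
  need <- names(canonical_columns)
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  records <- records[need]
  if (!nrow(records)) return(records)
  records$visit <- as.character(records$visit)
  records$site <- as.character(records$site)
  records$individual <- as.character(records$individual)
  minute <- suppressWarnings(as.numeric(records$minute))
  if (any(!is.finite(minute)) || any(minute != as.integer(minute)) ||
      any(minute < 1)) {
    stop("`minute` must be an integer >= 1", call. = FALSE)
  }
  records$minute <- as.integer(minute)
  det <- suppressWarnings(as.numeric(records$detected))
  if (any(!is.finite(det)) || !all(det %in% c(0, 1))) {
    stop("`detected` must be 0 or 1", call. = FALSE)
  }
  records$detected <- as.integer(det)

  key <- paste(records$visit, records$site, records$individual,
               records$minute, sep = "\r")
  if (anyDuplicated(key)) {
    full <- paste(key, records$detected, sep = "\r")
    if (length(unique(full)) > length(unique(key))) {
      stop("duplicate (visit, site, individual, minute) records with ",
           "conflicting `detected` values", call. = FALSE)
    }
    warning(sprintf("%d exactly duplicated record(s) dropped",
                    sum(duplicated(key))), call. = FALSE)
    records <- records[!duplicated(key), , drop = FALSE]
    rownames(records) <- NULL
  }
  records
}

#' Write long-format detection annotations
#'
#' @param records Data frame of detection records (canonical columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  records <- validate_records(records)
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write one capture history as a delimited detection matrix
#'
#' One row per observed individual, a leading `individual` label column, and
#' one `min_<t>` column per surveyed minute.  A zero-row history writes a
#' header-only file.  Round-trips exactly with [read_history_matrix()].
#'
#' @param history A `capture_history`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history_matrix <- function(history, path) {
  stopifnot(inherits(history, "capture_history"))
  header <- c("individual", paste0("min_", seq_len(history$duration)))
  if (nrow(history$y) == 0) {
    writeLines(paste(header, collapse = ","), path)
    return(invisible(path))
  }
  df <- data.frame(individual = rownames(history$y),
                   history$y, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- header
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a detection matrix written by [write_history_matrix()]
#'
#' @param path CSV path.
#' @param visit,site Identifiers to attach (the matrix file itself only
#'   stores labels and minutes).
#' @return A `capture_history`.
#' @export
read_history_matrix <- function(path, visit = "v", site = "s") {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mcols <- grep("^min_", names(df), value = TRUE)
  if (!length(mcols) || names(df)[1] != "individual") {
    stop("not a detection-matrix file: expected `individual` + `min_<t>` columns",
         call. = FALSE)
  }
  ord <- order(as.integer(sub("^min_", "", mcols)))
  y <- as.matrix(df[, mcols[ord], drop = FALSE])
  rownames(y) <- df$individual
  capture_history(y, visit = visit, site = site, duration = length(mcols),
                  labels = df$individual)
}

#' Write a capture history set to a directory
#'
#' Writes one detection-matrix CSV per (visit, site) plus a `manifest.json`
#' recording the rosters, durations, observed counts, and file names.
#'
#' @param hset A `capture_history_set`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_history_set <- function(hset, dir) {
  stopifnot(inherits(hset, "capture_history_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- as.data.frame(hset)
  tab$file <- sprintf("history_%03d_%s.csv", seq_len(nrow(tab)),
                      gsub("[^A-Za-z0-9_-]", "_",
                           paste(tab$visit, tab$site, sep = "_")))
  for (i in seq_len(nrow(tab))) {
    write_history_matrix(hset$histories[[i]], file.path(dir, tab$file[i]))
  }
  manifest <- list(visits = hset$visits, sites = hset$sites, entries = tab)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a capture history set written by [write_history_set()]
#'
#' @param dir Directory containing `manifest.json` and the matrix CSVs.
#' @return A `capture_history_set`.
#' @export
read_history_set <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir, call. = FALSE)
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- manifest$entries
  histories <- lapply(seq_len(nrow(tab)), function(i) {
    h <- read_history_matrix(file.path(dir, tab$file[i]),
                             visit = tab$visit[i], site = tab$site[i])
    if (h$duration != tab$duration[i] || n_observed(h) != tab$n_obs[i]) {
      stop("manifest does not match matrix file ", tab$file[i], call. = FALSE)
    }
    h
  })
  capture_history_set(histories)
}

#' Read a declared-durations table
#'
#' @param path CSV with columns `visit`, `site`, `duration`.
#' @return Data frame suitable for [build_history_set()]'s `durations`.
#' @export
read_durations <- function(path) {
  if (!file.exists(path)) stop("durations file not found: ", path,
                               call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("visit", "site", "duration") %in% names(df))) {
    stop("durations file must have columns visit, site, duration",
         call. = FALSE)
  }
  df$visit <- as.character(df$visit)
  df$site <- as.character(df$site)
  df$duration <- as.integer(df$duration)
  df
}
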