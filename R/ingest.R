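# Reading and validation of the three field data streams:
# photo-identification sightings, daily acoustic presence calls, and
# scan-sampled focal-follow behavioural records.

#' Default resting-bay identifiers
#'
#' The four sheltered bays along the Kona coast of Hawaii Island in which the
#' monitoring programme operated. Any analysis may substitute its own set of
#' bay identifiers; these are merely the defaults used throughout.
#'
#' @return character vector of four bay names.
#' @export
kona_bays <- function() c("Makako", "Kealakekua", "Honaunau", "Kauhako")

#' Sentinel stratum for time spent outside all bays
#'
#' Reserved identifier for the outside-bays stratum. Never a valid value in a
#' sighting or acoustic table; valid as a scan location and as a budget
#' stratum.
#'
#' @export
OUTSIDE <- "OUTSIDE"

activity_states <- function() c("REST", "SOCIAL", "TRAVEL")
acoustic_statuses <- function() c("PRESENT", "ABSENT", "MISSING")
platforms <- function() c("BOAT", "LAND")

## ---- sighting table ---------------------------------------------------

#' Construct and validate a sighting table
#'
#' One record per (individual, date, bay) photographic sighting-day. Duplicate
#' records are collapsed to one with a warning: a dolphin photographed twice
#' in the same bay on the same day is a single sighting-day.
#'
#' @param df data.frame with columns `individual_id`, `date` (Date or ISO
#'   string), `bay`.
#' @param bays character vector of valid bay identifiers.
#' @return a `sighting_table` (data.frame) sorted by individual, date, bay,
#'   with a `bays` attribute.
#' @export
as_sighting_table <- function(df, bays = kona_bays()) {
  check_columns(df, c("individual_id", "date", "bay"), "sighting table")
  df$individual_id <- as.character(df$individual_id)
  if (!inherits(df$date, "Date")) df$date <- parse_iso_date(as.character(df$date), "sighting table")
  df$bay <- as.character(df$bay)
  bad <- which(!df$bay %in% bays)
  if (length(bad)) {
    abort_validation(sprintf(
      "sighting table: unknown bay '%s' (row %d); valid bays: %s",
      df$bay[bad[1]], bad[1], paste(bays, collapse = ", ")
    ))
  }
  dup <- duplicated(df[, c("individual_id", "date", "bay")])
  if (any(dup)) {
    warning(sprintf("collapsed %d duplicate sighting record(s)", sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$individual_id, df$date, df$bay), c("individual_id", "date", "bay")]
  rownames(df) <- NULL
  structure(df, bays = bays, class = c("sighting_table", "data.frame"))
}

#' Read photo-identification sightings from CSV
#'
#' @param path CSV file with header `individual_id,date,bay`.
#' @inheritParams as_sighting_table
#' @return a `sighting_table`.
#' @export
read_sightings <- function(path, bays = kona_bays()) {
  if (!file.exists(path)) abort_config(sprintf("sightings file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  as_sighting_table(df, bays)
}

#' Write a sighting table to CSV
#' @param x a `sighting_table`.
#' @param path output file.
#' @export
write_sightings <- function(x, path) {
  out <- data.frame(
    individual_id = x$individual_id,
    date = format(x$date, "%Y-%m-%d"),
    bay = x$bay
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- occurrence matrix ------------------------------------------------

#' Per-individual bay occurrence counts and allocation probabilities
#'
#' Tallies the number of sighting-days of each individual in each bay and
#' normalises each individual's counts into allocation probabilities
#' (count / total count for that individual). These probabilities drive the
#' daily bay allocation in the cumulative-budget simulation.
#'
#' @param sightings a `sighting_table`.
#' @param bays bay identifiers; defaults to the table's `bays` attribute.
#' @return an `occurrence_matrix`: list with `counts` and `probs`
#'   (individuals x bays matrices), `individuals` and `bays`.
#' @export
occurrence_matrix <- function(sightings, bays = attr(sightings, "bays")) {
  if (nrow(sightings) == 0L) abort_validation("occurrence_matrix: empty sighting table")
  tab <- table(
    factor(sightings$individual_id),
    factor(sightings$bay, levels = bays)
  )
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  probs <- counts / rowSums(counts)
  structure(
    list(counts = counts, probs = probs,
         individuals = rownames(counts), bays = bays),
    class = "occurrence_matrix"
  )
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("Occurrence matrix: %d individuals x %d bays (%s)\n",
              length(x$individuals), length(x$bays), paste(x$bays, collapse = ", ")))
  cat(sprintf("Total sighting-days: %d\n", sum(x$counts)))
  invisible(x)
}

#' Percentage of individuals documented in each bay
#'
#' For each bay, the percentage of catalogued individuals with at least one
#' sighting-day there. Individuals use several bays, so percentages need not
#' sum to 100. Reported both unrounded and rounded half-up to the nearest
#' integer (the convention for whole-number reporting).
#'
#' @param matrix an `occurrence_matrix`.
#' @return data.frame with `bay`, `n_documented`, `n_total`, `pct`,
#'   `pct_rounded`.
#' @export
bay_use_summary <- function(matrix) {
  n_total <- length(matrix$individuals)
  n_doc <- colSums(matrix$counts >= 1L)
  pct <- 100 * n_doc / n_total
  data.frame(
    bay = matrix$bays,
    n_documented = as.integer(n_doc),
    n_total = n_total,
    pct = as.numeric(pct),
    pct_rounded = as.integer(round_half_up(pct)),
    row.names = NULL
  )
}

## ---- acoustic table ---------------------------------------------------

#' Construct and validate an acoustic presence table
#'
#' One tri-state presence call per (bay, study day). Study-day coverage is
#' explicit: any (bay, day) pair absent from the input becomes `MISSING`
#' (recorder malfunction or servicing), to be imputed downstream by a
#' Bernoulli draw at the bay's observed presence rate.
#'
#' @param df data.frame with columns `bay`, `date`, `status`
#'   (PRESENT/ABSENT/MISSING).
#' @param bays valid bay identifiers.
#' @param study_days Date vector of all study days.
#' @return an `acoustic_table` (data.frame) with one row per (bay, study day).
#' @export
as_acoustic_table <- function(df, bays = kona_bays(), study_days) {
  stopifnot(inherits(study_days, "Date"), length(study_days) > 0L)
  check_columns(df, c("bay", "date", "status"), "acoustic table")
  df$bay <- as.character(df$bay)
  if (!inherits(df$date, "Date")) df$date <- parse_iso_date(as.character(df$date), "acoustic table")
  df$status <- toupper(as.character(df$status))
  bad <- which(!df$bay %in% bays)
  if (length(bad)) {
    abort_validation(sprintf("acoustic table: unknown bay '%s' (row %d)", df$bay[bad[1]], bad[1]))
  }
  bad <- which(!df$status %in% acoustic_statuses())
  if (length(bad)) {
    abort_validation(sprintf(
      "acoustic table: status '%s' (row %d) not one of %s",
      df$status[bad[1]], bad[1], paste(acoustic_statuses(), collapse = "/")
    ))
  }
  if (anyDuplicated(df[, c("bay", "date")])) {
    abort_validation("acoustic table: more than one record for the same (bay, date)")
  }
  outside <- !df$date %in% study_days
  if (any(outside)) {
    warning(sprintf("dropped %d acoustic record(s) outside the study period", sum(outside)))
    df <- df[!outside, , drop = FALSE]
  }
  grid <- expand.grid(date = study_days, bay = bays,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(b, d) paste(b, format(d, "%Y-%m-%d"))
  idx <- match(key(grid$bay, grid$date), key(df$bay, df$date))
  grid$status <- ifelse(is.na(idx), "MISSING", df$status[idx])
  grid <- grid[order(grid$bay, grid$date), c("bay", "date", "status")]
  rownames(grid) <- NULL
  structure(grid, bays = bays, study_days = study_days,
            class = c("acoustic_table", "data.frame"))
}

#' Read daily acoustic presence calls from CSV
#'
#' @param path CSV file with header `bay,date,status`.
#' @inheritParams as_acoustic_table
#' @return an `acoustic_table` covering every (bay, study day).
#' @export
read_acoustic <- function(path, bays = kona_bays(), study_days) {
  if (!file.exists(path)) abort_config(sprintf("acoustic file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  as_acoustic_table(df, bays, study_days)
}

#' Write an acoustic table to CSV
#' @param x an `acoustic_table`.
#' @param path output file.
#' @export
write_acoustic <- function(x, path) {
  out <- data.frame(bay = x$bay, date = format(x$date, "%Y-%m-%d"), status = x$status)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Observed daily presence probability for a bay
#'
#' The fraction of non-missing monitoring days on which dolphins were
#' acoustically present: `#PRESENT / (#PRESENT + #ABSENT)`. Used to impute
#' presence on `MISSING` days via a Bernoulli draw.
#'
#' @param acoustic an `acoustic_table`.
#' @param bay a single bay identifier.
#' @return presence probability in `[0, 1]`.
#' @export
presence_probability <- function(acoustic, bay) {
  st <- acoustic$status[acoustic$bay == bay]
  if (!length(st)) abort_validation(sprintf("presence_probability: no records for bay '%s'", bay))
  n_obs <- sum(st != "MISSING")
  if (n_obs == 0L) {
    abort_config(sprintf(
      "presence_probability: bay '%s' has no non-missing monitoring days; supply a prior presence probability via configuration", bay
    ))
  }
  sum(st == "PRESENT") / n_obs
}

#' Presence probabilities for all bays of an acoustic table
#' @param acoustic an `acoustic_table`.
#' @return named numeric vector, one probability per bay.
#' @export
presence_probabilities <- function(acoustic) {
  bays <- attr(acoustic, "bays")
  vapply(bays, function(b) presence_probability(acoustic, b), numeric(1))
}

## ---- scan table -------------------------------------------------------

#' Construct and validate a scan-sample table
#'
#' Instantaneous scan samples taken at a nominal 10-min cadence during group
#' focal follows. Each record carries the follow id, timestamp, observation
#' platform (BOAT/LAND), location (a bay or `OUTSIDE`), the predominant group
#' activity (REST/SOCIAL/TRAVEL), and counts of boats, kayaks and swimmers
#' within 100 m of the focal group.
#'
#' Records are sorted by (follow, timestamp); tied timestamps within a follow
#' are an error. Follows with a single scan are retained (with a message).
#'
#' @param df data.frame with columns `follow_id`, `timestamp`, `platform`,
#'   `location`, `activity`, `n_boats`, `n_kayaks`, `n_swimmers`.
#' @param bays valid bay identifiers.
#' @return a `scan_table` (data.frame).
#' @export
as_scan_table <- function(df, bays = kona_bays()) {
  cols <- c("follow_id", "timestamp", "platform", "location", "activity",
            "n_boats", "n_kayaks", "n_swimmers")
  check_columns(df, cols, "scan table")
  df$follow_id <- as.character(df$follow_id)
  if (!inherits(df$timestamp, "POSIXct")) {
    df$timestamp <- parse_iso_datetime(as.character(df$timestamp), "scan table")
  }
  df$platform <- toupper(as.character(df$platform))
  df$location <- as.character(df$location)
  df$activity <- toupper(as.character(df$activity))
  for (cc in c("n_boats", "n_kayaks", "n_swimmers")) {
    v <- suppressWarnings(as.integer(df[[cc]]))
    if (anyNA(v)) abort_validation(sprintf("scan table: non-integer %s", cc))
    if (any(v < 0L)) abort_validation(sprintf("scan table: negative %s", cc))
    df[[cc]] <- v
  }
  bad <- which(!df$platform %in% platforms())
  if (length(bad)) {
    abort_validation(sprintf("scan table: platform '%s' (row %d) not BOAT/LAND",
                             df$platform[bad[1]], bad[1]))
  }
  bad <- which(!df$location %in% c(bays, OUTSIDE))
  if (length(bad)) {
    abort_validation(sprintf("scan table: unknown location '%s' (row %d)",
                             df$location[bad[1]], bad[1]))
  }
  bad <- which(!df$activity %in% activity_states())
  if (length(bad)) {
    abort_validation(sprintf("scan table: activity '%s' (row %d) not one of %s",
                             df$activity[bad[1]], bad[1],
                             paste(activity_states(), collapse = "/")))
  }
  df <- df[order(df$follow_id, df$timestamp), cols]
  rownames(df) <- NULL
  # strictly increasing timestamps within a follow
  same <- df$follow_id[-1] == df$follow_id[-nrow(df)]
  if (nrow(df) > 1L) {
    dt <- diff(as.numeric(df$timestamp))
    if (any(same & dt <= 0)) {
      abort_validation("scan table: non-increasing timestamps within a follow")
    }
  }
  singles <- names(which(table(df$follow_id) == 1L))
  if (length(singles)) {
    message(sprintf("scan table: %d follow(s) have a single scan (retained)", length(singles)))
  }
  structure(df, bays = bays, class = c("scan_table", "data.frame"))
}

#' Read focal-follow scan samples from CSV
#'
#' @param path CSV file with header
#'   `follow_id,timestamp,platform,location,activity,n_boats,n_kayaks,n_swimmers`.
#' @inheritParams as_scan_table
#' @return a `scan_table`, sorted by (follow, timestamp).
#' @export
read_scans <- function(path, bays = kona_bays()) {
  if (!file.exists(path)) abort_config(sprintf("scans file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  as_scan_table(df, bays)
}

#' Write a scan table to CSV
#' @param x a `scan_table`.
#' @param path output file.
#' @export
write_scans <- function(x, path) {
  out <- data.frame(
    follow_id = x$follow_id,
    timestamp = format_iso_datetime(x$timestamp),
    platform = x$platform,
    location = x$location,
    activity = x$activity,
    n_boats = x$n_boats,
    n_kayaks = x$n_kayaks,
    n_swimmers = x$n_swimmers
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
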