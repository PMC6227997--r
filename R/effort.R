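# Published field-effort summaries of the monitoring programme, bundled as
# plain CSV so reports and checks can recompute programme totals.

effort_file <- function(name) {
  path <- system.file("extdata", name, package = "spinnerbudget")
  if (!nzchar(path)) abort_config(sprintf("bundled effort table '%s' not found", name))
  path
}

#' Per-bay survey and monitoring effort table
#'
#' Photo-identification survey days and hours, acoustic recording days, and
#' the number of catalogued individuals documented, per resting bay, as
#' published for the 2010-2012 Kona coast monitoring programme.
#'
#' @return data.frame with columns `bay`, `survey_days`, `survey_hours`,
#'   `recording_days`, `n_individuals_documented`.
#' @export
survey_effort <- function() {
  utils::read.csv(effort_file("survey_effort.csv"), stringsAsFactors = FALSE)
}

#' Focal-follow effort table
#'
#' Number of group focal follows and follow hours per platform and location.
#'
#' @return data.frame with columns `platform`, `location`, `n_follows`,
#'   `hours`.
#' @export
follow_effort <- function() {
  utils::read.csv(effort_file("focal_follow_effort.csv"), stringsAsFactors = FALSE)
}

#' Programme-level effort totals
#'
#' Sums the per-bay and per-platform effort tables into programme totals:
#' total survey days and hours, total acoustic recording days, and total
#' number of focal follows.
#'
#' @param survey data.frame as returned by [survey_effort()].
#' @param follows data.frame as returned by [follow_effort()].
#' @return named list of the four totals.
#' @export
effort_summary <- function(survey = survey_effort(), follows = follow_effort()) {
  list(
    survey_days_total = sum(survey$survey_days),
    survey_hours_total = sum(survey$survey_hours),
    recording_days_total = sum(survey$recording_days),
    n_follows_total = sum(follows$n_follows)
  )
}

#' Reconstruct a minimal sighting table from per-bay documented counts
#'
#' Builds a sighting table over a catalogue of `n_total` individuals whose
#' per-bay "documented" tallies (number of individuals with >= 1 sighting in
#' the bay) equal the given counts, while every catalogue member appears at
#' least once. Bay membership overlaps are assigned greedily (largest count
#' first, uncovered individuals first); which individuals overlap is
#' immaterial to [bay_use_summary()], which only counts memberships. One
#' sighting-day per membership, all on `date`.
#'
#' @param counts named integer vector: documented individuals per bay.
#' @param n_total catalogue size; requires `sum(counts) >= n_total` and
#'   `max(counts) <= n_total`.
#' @param date the nominal sighting date (default 2011-01-01).
#' @return a `sighting_table` whose [bay_use_summary()] reproduces `counts`.
#' @export
reconstruct_sightings_from_counts <- function(counts, n_total,
                                              date = as.Date("2011-01-01")) {
  if (sum(counts) < n_total) {
    abort_validation("reconstruct_sightings_from_counts: counts cannot cover the catalogue")
  }
  if (max(counts) > n_total) {
    abort_validation("reconstruct_sightings_from_counts: a count exceeds the catalogue size")
  }
  ids <- sprintf("IND%03d", seq_len(n_total))
  uncovered <- seq_len(n_total)
  rows <- list()
  for (b in names(sort(counts, decreasing = TRUE))) {
    k <- counts[[b]]
    take <- utils::head(uncovered, k)
    if (length(take) < k) {
      covered <- setdiff(seq_len(n_total), uncovered)
      take <- c(take, utils::head(covered, k - length(take)))
    }
    uncovered <- setdiff(uncovered, take)
    if (k > 0L) rows[[b]] <- data.frame(individual_id = ids[take], date = date, bay = b)
  }
  if (length(uncovered)) {
    abort_validation("reconstruct_sightings_from_counts: could not cover every individual")
  }
  as_sighting_table(do.call(rbind, rows), bays = names(counts))
}
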