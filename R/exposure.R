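# Human-exposure analysis from scan samples.
#
# A scan is APPROACHED when any boat, kayak or swimmer is within 100 m of
# the focal group, UNAPPROACHED otherwise (the control condition). Maximal
# runs of identical exposure state within a follow form exposure intervals;
# each scan stands for its 10-min sampling window, so a run of k scans lasts
# 10k minutes.

#' Classify scans as approached or unapproached
#'
#' `APPROACHED` iff at least one boat, kayak or swimmer is within 100 m
#' (i.e. the three counts sum to >= 1). Vectorised.
#'
#' @param n_boats,n_kayaks,n_swimmers non-negative integer counts, or
#'   `n_boats` may be a `scan_table` (the other arguments are then ignored).
#' @return character vector, `"APPROACHED"` / `"UNAPPROACHED"`.
#' @export
classify_scan <- function(n_boats, n_kayaks = NULL, n_swimmers = NULL) {
  if (is.data.frame(n_boats)) {
    scans <- n_boats
    n_kayaks <- scans$n_kayaks
    n_swimmers <- scans$n_swimmers
    n_boats <- scans$n_boats
  }
  if (any(c(n_boats, n_kayaks, n_swimmers) < 0)) {
    abort_validation("classify_scan: counts must be non-negative")
  }
  ifelse(n_boats + n_kayaks + n_swimmers >= 1L, "APPROACHED", "UNAPPROACHED")
}

run_lengths_one_follow <- function(scans_f, gap_factor, scan_minutes) {
  state <- classify_scan(scans_f)
  n <- length(state)
  gap_break <- if (n > 1L) {
    diff(as.numeric(scans_f$timestamp)) / 60 > gap_factor * scan_minutes
  } else {
    logical(0)
  }
  # a new interval starts at a state change or after an observation gap
  new_run <- c(TRUE, state[-1] != state[-n] | gap_break)
  run_id <- cumsum(new_run)
  starts <- which(new_run)
  ends <- c(starts[-1] - 1L, n)
  n_runs <- length(starts)
  # censoring: follow boundaries, plus both sides of a gap break
  left <- logical(n_runs)
  right <- logical(n_runs)
  left[1] <- TRUE
  right[n_runs] <- TRUE
  if (n > 1L && any(gap_break)) {
    after_gap <- which(gap_break) + 1L          # scan index opening a piece
    gap_runs <- run_id[after_gap]
    left[gap_runs] <- TRUE
    right[gap_runs - 1L] <- TRUE
  }
  data.frame(
    follow_id = scans_f$follow_id[1],
    platform = scans_f$platform[starts],
    state = state[starts],
    n_scans = ends - starts + 1L,
    duration_minutes = scan_minutes * (ends - starts + 1L),
    left_censored = left,
    right_censored = right
  )
}

#' Extract continuous exposure intervals (run-length encoding)
#'
#' Maximal runs of identical exposure state within each follow, in timestamp
#' order. The first and last interval of a follow are flagged censored (they
#' abut an observation boundary). Observation gaps longer than
#' `gap_factor` x the nominal scan cadence break a run into censored pieces
#' rather than fabricating continuity across a dropout.
#'
#' @param scans a `scan_table`.
#' @param follow_id optional single follow to extract; default all follows.
#' @param gap_factor multiple of the nominal cadence above which a gap breaks
#'   a run (default 1.5).
#' @param scan_minutes nominal scan cadence in minutes (default 10).
#' @return data.frame of intervals: `follow_id`, `platform`, `state`,
#'   `n_scans`, `duration_minutes`, `left_censored`, `right_censored`.
#' @export
extract_runs <- function(scans, follow_id = NULL, gap_factor = 1.5, scan_minutes = 10L) {
  if (!is.null(follow_id)) {
    scans <- scans[scans$follow_id %in% follow_id, , drop = FALSE]
    if (!nrow(scans)) abort_validation(sprintf("extract_runs: no such follow '%s'", follow_id))
  }
  pieces <- lapply(split(seq_len(nrow(scans)), scans$follow_id), function(ix) {
    run_lengths_one_follow(scans[ix, , drop = FALSE], gap_factor, scan_minutes)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Overall proportion of scans in the approached condition
#'
#' @param scans a `scan_table`.
#' @param platform optional `"BOAT"` or `"LAND"` filter.
#' @return proportion in `[0, 1]`.
#' @export
exposure_proportion <- function(scans, platform = NULL) {
  if (!is.null(platform)) scans <- scans[scans$platform == platform, , drop = FALSE]
  if (!nrow(scans)) abort_validation("exposure_proportion: no scans in selection")
  mean(classify_scan(scans) == "APPROACHED")
}

#' Fraction of control (unapproached) scans on a platform
#'
#' @param scans a `scan_table`.
#' @param platform `"BOAT"` or `"LAND"`.
#' @return proportion of the platform's scans with no human activity within
#'   100 m.
#' @export
control_fraction <- function(scans, platform) {
  sel <- scans$platform == platform
  if (!any(sel)) abort_validation(sprintf("control_fraction: no scans on platform '%s'", platform))
  mean(classify_scan(scans[sel, , drop = FALSE]) == "UNAPPROACHED")
}

#' Median durations and duration histograms of exposure intervals
#'
#' Medians per (state, platform) cell with the even-count convention (mean of
#' the two middle values), and histogram counts of interval durations in
#' 10-min bins (`bin_start_min` = the duration value; durations are exact
#' multiples of the cadence). Empty cells are absent from the output, not
#' reported as zero.
#'
#' @param intervals data.frame from [extract_runs()].
#' @param include_censored include boundary-censored intervals (default
#'   `TRUE`); set `FALSE` to drop any interval abutting a follow boundary or
#'   observation gap.
#' @return list with `medians` (state, platform, n, median_minutes) and
#'   `histogram` (state, platform, bin_start_min, count).
#' @export
interval_summary <- function(intervals, include_censored = TRUE) {
  if (!include_censored) {
    intervals <- intervals[!(intervals$left_censored | intervals$right_censored), , drop = FALSE]
  }
  if (!nrow(intervals)) abort_validation("interval_summary: no intervals in selection")
  grp <- interaction(intervals$state, intervals$platform, drop = TRUE, sep = ":")
  med <- do.call(rbind, lapply(levels(grp), function(g) {
    d <- intervals$duration_minutes[grp == g]
    parts <- strsplit(g, ":", fixed = TRUE)[[1]]
    data.frame(state = parts[1], platform = parts[2],
               n = length(d), median_minutes = stats::median(d))
  }))
  hist <- as.data.frame(table(state = intervals$state, platform = intervals$platform,
                              bin_start_min = intervals$duration_minutes),
                        stringsAsFactors = FALSE)
  names(hist)[names(hist) == "Freq"] <- "count"
  hist <- hist[hist$count > 0, , drop = FALSE]
  hist$bin_start_min <- as.integer(hist$bin_start_min)
  hist <- hist[order(hist$state, hist$platform, hist$bin_start_min), ]
  rownames(hist) <- NULL
  list(medians = med, histogram = hist)
}

#' Per-activity-type exposure fractions
#'
#' Descriptive table: the fraction of scans with at least one boat, kayak or
#' swimmer within 100 m, per location stratum.
#'
#' @param scans a `scan_table`.
#' @return data.frame with `location`, `n_scans` and the three per-type
#'   fractions.
#' @export
exposure_by_type <- function(scans) {
  locs <- sort(unique(scans$location))
  do.call(rbind, lapply(locs, function(l) {
    s <- scans[scans$location == l, , drop = FALSE]
    data.frame(location = l, n_scans = nrow(s),
               frac_boats = mean(s$n_boats >= 1L),
               frac_kayaks = mean(s$n_kayaks >= 1L),
               frac_swimmers = mean(s$n_swimmers >= 1L))
  }))
}
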