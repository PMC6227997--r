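# A deterministic toy dataset small enough to hand-check.

#' Toy fixture: three tiny input tables
#'
#' A fully deterministic, hand-written miniature of the three input streams:
#' 4 individuals, 2 bays (Makako, Kealakekua), 12 study days, 3 focal
#' follows (13 scans). Intended for unit tests, examples and quick smoke
#' runs; every derived quantity can be tallied by hand. Copies of these
#' tables ship as CSVs under `inst/extdata/` for exercising the readers.
#'
#' Hand tallies: occurrence counts are A = (3, 1), B = (2, 0), C = (1, 2),
#' D = (0, 1) over (Makako, Kealakekua); acoustic presence rates are 9/10
#' (Makako) and 3/10 (Kealakekua) with days 11-12 missing in both bays.
#'
#' @return list with `sightings`, `acoustic`, `scans`, `bays`, `study_days`.
#' @export
small_fixture <- function() {
  bays <- c("Makako", "Kealakekua")
  study_days <- seq(as.Date("2011-01-01"), by = "day", length.out = 12L)

  sightings <- as_sighting_table(data.frame(
    individual_id = c("A", "A", "A", "A", "B", "B", "C", "C", "C", "D"),
    date = as.Date(c("2011-01-01", "2011-01-03", "2011-01-05", "2011-01-07",
                     "2011-01-01", "2011-01-05",
                     "2011-01-02", "2011-01-07", "2011-01-09",
                     "2011-01-02")),
    bay = c("Makako", "Makako", "Makako", "Kealakekua",
            "Makako", "Makako",
            "Kealakekua", "Kealakekua", "Makako",
            "Kealakekua")
  ), bays)

  # days 1-10 recorded; days 11-12 have no record (-> MISSING via gap fill)
  acoustic <- as_acoustic_table(data.frame(
    bay = rep(bays, each = 10L),
    date = rep(study_days[1:10], 2L),
    status = c(
      c("PRESENT", "ABSENT", rep("PRESENT", 8L)),                 # Makako 9/10
      c("ABSENT", "PRESENT", "ABSENT", "ABSENT", "PRESENT",
        "ABSENT", "PRESENT", "ABSENT", "ABSENT", "ABSENT")        # Kealakekua 3/10
    )
  ), bays, study_days)

  ts <- function(day, hhmm) as.POSIXct(paste(day, hhmm), tz = "UTC")
  scans <- as_scan_table(data.frame(
    follow_id = c(rep("F01", 6L), rep("F02", 4L), rep("F03", 3L)),
    timestamp = c(
      ts("2011-01-01", sprintf("08:%02d", seq(0, 50, 10))),
      ts("2011-01-02", sprintf("09:%02d", seq(0, 30, 10))),
      ts("2011-01-03", sprintf("10:%02d", seq(0, 20, 10)))
    ),
    platform = c(rep("BOAT", 6L), rep("LAND", 4L), rep("BOAT", 3L)),
    location = c(rep("Makako", 4L), rep(OUTSIDE, 2L),
                 rep("Kealakekua", 4L), rep(OUTSIDE, 3L)),
    activity = c("REST", "REST", "REST", "SOCIAL", "TRAVEL", "TRAVEL",
                 "SOCIAL", "REST", "REST", "SOCIAL",
                 "TRAVEL", "TRAVEL", "SOCIAL"),
    # exposure patterns: F01 U,U,A,A,A,U; F02 A,A,U,U; F03 A,U,A
    n_boats = c(0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 2, 0, 1),
    n_kayaks = c(0, 0, 0, 2, 1, 0, 1, 0, 0, 0, 0, 0, 1),
    n_swimmers = c(0, 0, 0, 3, 0, 0, 0, 1, 0, 0, 1, 0, 1)
  ), bays)

  list(sightings = sightings, acoustic = acoustic, scans = scans,
       bays = bays, study_days = study_days)
}

#' Write the toy fixture to CSV files
#'
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
write_fixture <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- small_fixture()
  paths <- c(
    sightings = file.path(dir, "sightings_toy.csv"),
    acoustic = file.path(dir, "acoustic_toy.csv"),
    scans = file.path(dir, "scans_toy.csv")
  )
  write_sightings(fx$sightings, paths[["sightings"]])
  # write only the recorded acoustic rows; MISSING days are re-derived on read
  rec <- fx$acoustic[fx$acoustic$status != "MISSING", , drop = FALSE]
  write_acoustic(rec, paths[["acoustic"]])
  write_scans(fx$scans, paths[["scans"]])
  paths
}
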