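toy_path <- function(name) system.file("extdata", name, package = "spinnerbudget")

test_that("sighting reader validates, deduplicates and counts individuals", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,date,bay",
               "A,2011-01-01,Makako",
               "A,2011-01-02,Kealakekua",
               "B,2011-01-01,Makako"), tmp)
  st <- read_sightings(tmp)
  expect_equal(nrow(st), 3L)
  expect_equal(length(unique(st$individual_id)), 2L)

  # unknown bay is a hard error naming the offending value
  writeLines(c("individual_id,date,bay", "A,2011-01-01,Oahu"), tmp)
  expect_error(read_sightings(tmp), "Oahu")

  # unparseable date is a hard error
  writeLines(c("individual_id,date,bay", "A,01/02/2011,Makako"), tmp)
  expect_error(read_sightings(tmp), "date")

  # duplicate (id, date, bay) collapses to one record with a warning
  writeLines(c("individual_id,date,bay",
               "A,2011-01-01,Makako",
               "A,2011-01-01,Makako"), tmp)
  expect_warning(st <- read_sightings(tmp), "duplicate")
  expect_equal(nrow(st), 1L)
})

test_that("occurrence matrix normalises counts into allocation probabilities", {
  st <- as_sighting_table(data.frame(
    individual_id = rep("A", 4),
    date = as.Date("2011-01-01") + 0:3,
    bay = c("Makako", "Makako", "Makako", "Kealakekua")
  ))
  om <- occurrence_matrix(st)
  expect_equal(unname(om$probs["A", ]), c(0.75, 0.25, 0, 0))

  # degenerate: a single sighting gives probability 1 for that bay
  st1 <- as_sighting_table(data.frame(individual_id = "B",
                                      date = as.Date("2011-01-01"),
                                      bay = "Honaunau"))
  expect_equal(unname(occurrence_matrix(st1)$probs["B", ]), c(0, 0, 1, 0))
})

test_that("occurrence probabilities match a brute-force tally and sum to 1", {
  set.seed(101)
  for (rep in 1:5) {
    n_rec <- 40L
    df <- data.frame(
      individual_id = sample(sprintf("I%02d", 1:5), n_rec, replace = TRUE),
      date = as.Date("2011-01-01") + sample.int(60, n_rec, replace = TRUE),
      bay = sample(kona_bays(), n_rec, replace = TRUE)
    )
    df <- df[!duplicated(df), ]
    st <- as_sighting_table(df)
    om <- occurrence_matrix(st)
    # brute-force tally: double loop over (individual, bay)
    for (id in om$individuals) {
      tot <- sum(st$individual_id == id)
      for (b in om$bays) {
        cnt <- sum(st$individual_id == id & st$bay == b)
        expect_identical(om$counts[id, b], cnt)
        expect_equal(om$probs[id, b], cnt / tot)
        if (cnt == 0L) expect_identical(om$probs[id, b], 0)
      }
      expect_lt(abs(sum(om$probs[id, ]) - 1), 1e-12)
    }
  }
})

test_that("bay-use summary reports the documented percentage per bay", {
  fx <- small_fixture()
  bu <- bay_use_summary(occurrence_matrix(fx$sightings))
  # hand tally: A, B, C use Makako; A, C, D use Kealakekua
  expect_equal(bu$n_documented, c(3L, 3L))
  expect_equal(bu$pct, c(75, 75))
  expect_true(all(bu$pct >= 0 & bu$pct <= 100))

  # all individuals in a single bay: 100% there, 0% elsewhere
  st <- as_sighting_table(data.frame(
    individual_id = c("A", "B"), date = as.Date("2011-01-01"), bay = "Makako"))
  bu <- bay_use_summary(occurrence_matrix(st))
  expect_equal(bu$pct, c(100, 0, 0, 0))
})

test_that("acoustic reader fills gaps as MISSING and validates the vocabulary", {
  days <- seq(as.Date("2011-01-01"), by = "day", length.out = 12L)
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- expand.grid(bay = kona_bays(), date = format(days[1:10], "%Y-%m-%d"),
                    stringsAsFactors = FALSE)
  df$status <- "PRESENT"
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  ac <- read_acoustic(tmp, study_days = days)
  expect_equal(nrow(ac), 4L * 12L)
  for (b in kona_bays()) {
    expect_equal(sum(ac$status[ac$bay == b] == "MISSING"), 2L)
    expect_equal(presence_probability(ac, b), 1)
  }

  df$status[1] <- "MAYBE"
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_acoustic(tmp, study_days = days), "MAYBE")
})

test_that("tri-state acoustic counts match an independent line count", {
  set.seed(202)
  days <- seq(as.Date("2011-03-01"), by = "day", length.out = 30L)
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- expand.grid(bay = kona_bays(), date = format(days, "%Y-%m-%d"),
                    stringsAsFactors = FALSE)
  df$status <- sample(c("PRESENT", "ABSENT", "MISSING"), nrow(df), replace = TRUE)
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  ac <- read_acoustic(tmp, study_days = days)
  lines <- readLines(tmp)[-1]
  for (b in kona_bays()) {
    for (s in c("PRESENT", "ABSENT", "MISSING")) {
      expect_equal(sum(ac$bay == b & ac$status == s),
                   sum(grepl(sprintf("^%s,.*,%s$", b, s), lines)))
    }
    # presence rate equals brute-force count over the table
    st <- ac$status[ac$bay == b]
    expect_equal(presence_probability(ac, b),
                 sum(st == "PRESENT") / sum(st != "MISSING"))
  }
})

test_that("presence probability handles boundary cases and full missingness", {
  days <- seq(as.Date("2011-01-01"), by = "day", length.out = 10L)
  ac <- as_acoustic_table(data.frame(
    bay = "Makako", date = days,
    status = c(rep("PRESENT", 9), "ABSENT")
  ), bays = c("Makako", "Kealakekua"), study_days = days)
  expect_equal(presence_probability(ac, "Makako"), 0.9)
  # the other bay has no records at all -> all MISSING -> config error
  expect_error(presence_probability(ac, "Kealakekua"),
               class = "spinnerbudget_config_error")

  ac0 <- as_acoustic_table(data.frame(
    bay = "Makako", date = days, status = rep("ABSENT", 10)
  ), bays = "Makako", study_days = days)
  expect_equal(presence_probability(ac0, "Makako"), 0)
})

test_that("scan reader sorts, validates and is idempotent under shuffling", {
  scans <- read_scans(toy_path("scans_toy.csv"), bays = c("Makako", "Kealakekua"))
  expect_equal(nrow(scans), 13L)
  expect_false(is.unsorted(order(scans$follow_id, scans$timestamp)))

  # shuffled input produces the identical sorted table
  tmp <- withr::local_tempfile(fileext = ".csv")
  raw <- utils::read.csv(toy_path("scans_toy.csv"), colClasses = "character")
  set.seed(7)
  utils::write.csv(raw[sample.int(nrow(raw)), ], tmp, row.names = FALSE, quote = FALSE)
  expect_equal(read_scans(tmp, bays = c("Makako", "Kealakekua")), scans)

  raw2 <- raw; raw2$activity[3] <- "MILL"
  utils::write.csv(raw2, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_scans(tmp, bays = c("Makako", "Kealakekua")), "MILL")

  raw3 <- raw; raw3$n_boats[1] <- "-1"
  utils::write.csv(raw3, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_scans(tmp, bays = c("Makako", "Kealakekua")), "negative")

  raw4 <- raw; raw4$timestamp[2] <- raw4$timestamp[1]  # tied within follow
  utils::write.csv(raw4, tmp, row.names = FALSE, quote = FALSE)
  expect_error(read_scans(tmp, bays = c("Makako", "Kealakekua")), "timestamps")
})

test_that("write then re-read round-trips all three tables", {
  fx <- small_fixture()
  dir <- withr::local_tempdir()
  write_sightings(fx$sightings, file.path(dir, "s.csv"))
  write_acoustic(fx$acoustic, file.path(dir, "a.csv"))
  write_scans(fx$scans, file.path(dir, "sc.csv"))
  expect_equal(read_sightings(file.path(dir, "s.csv"), fx$bays), fx$sightings)
  expect_equal(read_acoustic(file.path(dir, "a.csv"), fx$bays, fx$study_days),
               fx$acoustic)
  expect_equal(read_scans(file.path(dir, "sc.csv"), fx$bays), fx$scans)
})
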