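test_that("read/write round-trips a synthetic dataset field for field", {
  d <- simulate_dataset(small_sim_config(seed = 11))
  dir <- withr::local_tempdir()
  write_events(d, dir)
  d2 <- read_events(file.path(dir, "events.csv"), file.path(dir, "sessions.csv"))
  expect_equal(d2$sessions, d$sessions)
  expect_equal(d2$events, d$events)
})

test_that("schema and row-level validation errors are explicit", {
  dir <- withr::local_tempdir()
  ev <- make_event("S1", 305, "A", "B", "contact")
  se <- make_session_row("S1")
  write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(se, file.path(dir, "sessions.csv"), row.names = FALSE)
  expect_error(
    read_events(file.path(dir, "events.csv"), file.path(dir, "sessions.csv")),
    "row 1.*t outside \\[0, 300\\)")

  write.csv(ev[, -2], file.path(dir, "events.csv"), row.names = FALSE)
  expect_error(
    read_events(file.path(dir, "events.csv"), file.path(dir, "sessions.csv")),
    "schema error.*'t'")

  expect_error(validate_events(make_event("S1", 10, "A", "B", "waving")),
               "unknown behavior")
  expect_error(validate_events(make_event("S1", 10, "A", "B", "vocalization",
                                          oriented = TRUE, dist = NA)),
               "missing distance_m")
})

test_that("header-only event file yields an empty event set with a warning", {
  dir <- withr::local_tempdir()
  write.csv(no_events(), file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(make_session_row("S1"), file.path(dir, "sessions.csv"),
            row.names = FALSE)
  expect_warning(
    d <- read_events(file.path(dir, "events.csv"),
                     file.path(dir, "sessions.csv")),
    "empty")
  expect_identical(nrow(d$events), 0L)
})

test_that("PC-MC pairing applies the 1-14 day and 2 h rules", {
  mk <- function(id, kind, dt) make_session_row(id, kind, date_time = dt)
  pc <- mk("PC1", "PC", "2013-06-01T10:00:00")
  good <- pair_pc_mc(rbind(pc, mk("MC1", "MC", "2013-06-03T10:30:00")))
  expect_equal(good$pairs$mc, "MC1")
  expect_length(good$unmatched, 0)

  late <- pair_pc_mc(rbind(pc, mk("MC1", "MC", "2013-06-21T10:00:00")))
  expect_equal(nrow(late$pairs), 0L)
  expect_setequal(late$unmatched, c("PC1", "MC1"))

  offtime <- pair_pc_mc(rbind(pc, mk("MC1", "MC", "2013-06-04T14:30:00")))
  expect_equal(nrow(offtime$pairs), 0L)

  early <- pair_pc_mc(rbind(pc, mk("MC1", "MC", "2013-05-30T10:00:00")))
  expect_equal(nrow(early$pairs), 0L)
  expect_match(early$issues$problem, "not later than PC")
})

test_that("duplicate eligible MCs resolve to the earliest, with a warning", {
  mk <- function(id, kind, dt) make_session_row(id, kind, date_time = dt)
  sess <- rbind(mk("PC1", "PC", "2013-06-01T10:00:00"),
                mk("MC2", "MC", "2013-06-05T10:00:00"),
                mk("MC1", "MC", "2013-06-03T10:00:00"))
  expect_warning(res <- pair_pc_mc(sess), "2 eligible MCs")
  expect_equal(res$pairs$mc, "MC1")
  expect_equal(res$unmatched, "MC2")
})

test_that("pairing is stable under input permutation and partitions sessions", {
  d <- simulate_dataset(small_sim_config(seed = 3))
  base <- pair_pc_mc(d$sessions)
  for (s in 1:3) {
    perm <- d$sessions[sample(nrow(d$sessions)), ]
    res <- pair_pc_mc(perm)
    expect_equal(res$pairs[order(res$pairs$pc), c("pc", "mc")],
                 base$pairs[order(base$pairs$pc), c("pc", "mc")],
                 ignore_attr = TRUE)
    expect_setequal(c(res$pairs$pc, res$pairs$mc, res$unmatched),
                    d$sessions$session_id)
    expect_false(anyDuplicated(c(res$pairs$pc, res$pairs$mc,
                                 res$unmatched)) > 0)
  }
})

test_that("postponement rule: renewed aggression within 30 s postpones", {
  expect_false(validate_postponement(0, 20))
  expect_true(validate_postponement(0, 45))
  expect_true(validate_postponement(0, numeric(0)))
  expect_false(validate_postponement(100, c(50, 125))) # 25 s after the end
})

test_that("deposited-style layout round-trips losslessly (CSV sheets)", {
  d <- simulate_dataset(small_sim_config(seed = 5))
  dir <- withr::local_tempdir()
  write_deposited_dataset(d, dir)
  got <- suppressWarnings(read_deposited_dataset(dir))
  expect_equal(got$data$sessions, d$sessions)
  expect_equal(got$data$events, d$events)
  # pairing recovered from metadata alone covers the same session universe
  # (when two conflicts of one dyad have interchangeable MCs the matcher may
  # legitimately swap them, so the mapping is checked as PC and MC sets)
  expect_setequal(got$pairs$pc, d$pairs$pc)
  expect_setequal(got$pairs$mc, d$pairs$mc)
  expect_equal(nrow(got$covariates), nrow(d$pairs))
})

test_that("deposited adapter names the offending column, never partial-loads", {
  d <- simulate_dataset(small_sim_config(seed = 5))
  dir <- withr::local_tempdir()
  write_deposited_dataset(d, dir)
  se <- read.csv(file.path(dir, "sessions.csv"))
  names(se)[names(se) == "focal"] <- "subject_name"
  write.csv(se, file.path(dir, "sessions.csv"), row.names = FALSE)
  expect_error(read_deposited_dataset(dir), "sheet 'sessions'.*'focal'")
  expect_error(read_deposited_dataset(withr::local_tempdir()),
               "missing sheet 'sessions'")
})

test_that("deposited adapter reads a real XLSX workbook", {
  d <- simulate_dataset(small_sim_config(seed = 5))
  dir <- withr::local_tempdir()
  write_deposited_dataset(d, dir)
  xlsx <- file.path(dir, "synthetic_deposited.xlsx")
  script <- sprintf("
import pandas as pd
with pd.ExcelWriter(%s) as w:
    for sheet in ['sessions', 'events', 'census']:
        pd.read_csv('%s/' + sheet + '.csv').to_excel(w, sheet_name=sheet, index=False)
", shQuote(xlsx), dir)
  status <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  got <- suppressWarnings(read_deposited_dataset(xlsx))
  expect_equal(got$data$sessions$focal, d$sessions$focal)
  expect_equal(got$data$events$t, d$events$t, tolerance = 1e-9)
  expect_equal(nrow(got$pairs), nrow(d$pairs))
})
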