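test_that("scaled totals map the instrument range onto 0-100", {
  phq9 <- phq9_spec()
  expect_equal(scale_rm_instance(rep(0, 9), phq9), 0)
  expect_equal(scale_rm_instance(rep(3, 9), phq9), 100)
  # raw sum 13 scaled by the PHQ-9 multiplier 100/27
  expect_equal(scale_rm_total(13, phq9), 13 * 100 / 27)
  expect_equal(scale_rm_total(13, phq9), 48.148148, tolerance = 1e-6)
  expect_true(is.na(scale_rm_instance(c(NA, rep(1, 8)), phq9)))
  expect_error(scale_rm_instance(rep(1, 5), phq9), "expected 9")
  # prescaled instruments pass through unmodified
  vas <- instrument_spec("VAS", 1, 0, 100, 7, prescaled_0_100 = TRUE)
  expect_equal(scale_rm_instance(73.5, vas), 73.5)
})

test_that("rescaling is invariant to relabelling the item range", {
  a <- instrument_spec("A", 5, 0, 3, 14)
  b <- instrument_spec("B", 5, 1, 4, 14)  # same items shifted by +1
  scores <- c(0, 1, 3, 2, 2)
  expect_equal(scale_rm_instance(scores, a), scale_rm_instance(scores + 1, b))
})

test_that("the recall window keeps the up-to-7 days closest to administration", {
  jan <- function(d) as.Date(sprintf("2020-01-%02d", d))
  # full daily data across a 14-day recall answered Jan 14 -> Jan 8..14
  expect_equal(select_dm_window(jan(1:14), jan(14), 14),
               jan(8:14))
  # fewer than 7 observed days -> all of them
  expect_equal(select_dm_window(jan(c(2, 5, 9)), jan(14), 14),
               jan(c(2, 5, 9)))
  # gaps: Jan 11 and 13 missing -> the 7 most recent observed dates
  expect_equal(select_dm_window(jan(setdiff(1:14, c(11, 13))), jan(14), 14),
               jan(c(6, 7, 8, 9, 10, 12, 14)))
  # data outside the recall period is never used
  expect_equal(select_dm_window(jan(1:31), jan(20), 3), jan(18:20))
  expect_error(select_dm_window(jan(1:5), jan(5), 0), "positive")
})

test_that("daily RM values align to the window with missing markers", {
  jan <- function(d) as.Date(sprintf("2020-01-%02d", d))
  win <- jan(8:14)
  vals <- select_daily_rm(jan(8:12), 10 * (8:12), win)
  expect_equal(vals, c(80, 90, 100, 110, 120, NA, NA))
  expect_equal(select_daily_rm(as.Date(character()), numeric(), win),
               rep(NA_real_, 7))
})

test_that("window means average observed values and propagate all-missing", {
  expect_equal(aggregate_window_mean(c(4, 4, 4)), 4)
  expect_equal(aggregate_window_mean(c(1, NA, 2, NA, 6)), 3)
  expect_true(is.na(aggregate_window_mean(numeric())))
  expect_true(is.na(aggregate_window_mean(c(NA_real_, NA_real_))))
  # shuffling observations changes nothing
  set.seed(3)
  x <- c(rnorm(5), NA, NA)
  expect_equal(aggregate_window_mean(sample(x)), aggregate_window_mean(x))
})

test_that("aligned records carry window bounds, means and completeness flags", {
  study <- tiny_study(sprintf("2020-01-%02d", 1:14), item_scores = rep(1, 9))
  al <- build_aligned_dataset(study, "steps", "PHQ-9")
  expect_s3_class(al, "avtk_aligned")
  expect_equal(nrow(al), 1L)
  expect_equal(al$window_start, as.Date("2020-01-01"))
  expect_equal(al$window_end, as.Date("2020-01-14"))
  expect_equal(al$n_dm_days, 7L)
  # dm values were 1..14 by date; selected days Jan 8..14 -> values 8..14
  expect_equal(unlist(al[paste0("dm_d", 1:7)], use.names = FALSE), 8:14)
  expect_equal(al$dm_mean, mean(8:14))
  expect_equal(al$rm_scaled, 9 * 100 / 27)
  expect_true(al$rm_complete)
})

test_that("instances without DM data are retained and flagged, not dropped", {
  study <- tiny_study("2019-06-01")  # DM data far outside the recall period
  al <- build_aligned_dataset(study, "steps", "PHQ-9")
  expect_equal(nrow(al), 1L)
  expect_equal(al$n_dm_days, 0L)
  expect_true(is.na(al$dm_mean))
  expect_true(all(is.na(unlist(al[paste0("dm_d", 1:7)]))))
})

test_that("every RM administration instance yields one aligned record", {
  sim <- generate_study(sim_config(n_participants = 2,
                                   instances_per_participant = 2, seed = 5))
  al <- build_aligned_dataset(sim$study, "dm", "SIM-RM")
  expect_equal(nrow(al), 4L)
  expect_equal(al$window_end, sim$truth$admin_date[order(sim$truth$participant_id,
                                                         sim$truth$instance)])
  # windows of successive instances do not overlap
  by_pid <- split(al, al$participant_id)
  for (b in by_pid)
    expect_true(all(diff(as.numeric(b$window_end)) >= 14))
  expect_error(build_aligned_dataset(sim$study, "nope", "SIM-RM"), "unknown DM")
  expect_error(build_aligned_dataset(sim$study, "dm", "nope"), "unknown RM")
})
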