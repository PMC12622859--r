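# A study with two multiday RMs: the simulated RM plus a copy under a
# second instrument name with reversed item order (same information).
two_rm_study <- function(n = 120, seed = 13) {
  sim <- generate_study(sim_config(n_participants = n, seed = seed))
  st <- sim$study
  inst2 <- instrument_spec("SIM-RM2", 9, 0, 3, 14)
  rm2 <- st$rm
  rm2$instrument <- "SIM-RM2"
  rm2$instance_id <- sub("^SIM-RM", "SIM-RM2", rm2$instance_id)
  items2 <- st$rm_items
  items2$instance_id <- sub("^SIM-RM", "SIM-RM2", items2$instance_id)
  items2$item <- 10L - items2$item
  study_data(dm = st$dm, rm = rbind(st$rm, rm2),
             rm_items = rbind(st$rm_items, items2),
             daily_rm = st$daily_rm,
             instruments = c(st$instruments, list("SIM-RM2" = inst2)))
}

test_that("one DM crossed with two RMs yields two agreement rows", {
  study <- two_rm_study()
  rep <- run_av_analysis(study, daily_rm_instrument = "SIM-DAILY")
  expect_s3_class(rep, "avtk_report")
  expect_equal(nrow(rep$agreement), 2L)
  expect_setequal(rep$agreement$rm_instrument, c("SIM-RM", "SIM-RM2"))
  expect_true(all(is.finite(rep$agreement$pearson_r)))
  expect_true(all(is.finite(rep$agreement$cfa_phi)))
  # regression predictor sets: each RM, all RMs, and the two daily variants
  expect_setequal(rep$regressions$predictor_set,
                  c("SIM-RM", "SIM-RM2", "all multiday RMs",
                    "all + daily (mean values)", "all + daily (individual days)"))
  expect_error(run_av_analysis(study, pairings = data.frame()), "no pairings")
})

test_that("pass/fail flags in the report equal evaluate_fit on its own indices", {
  rep <- run_av_analysis(two_rm_study(), thresholds = fit_thresholds())
  for (i in seq_len(nrow(rep$agreement))) {
    row <- rep$agreement[i, ]
    ev <- evaluate_fit(as.list(row[c("cfi", "tli", "rmsea", "srmr")]),
                       rep$thresholds)
    expect_equal(row$cfi_pass, ev$cfi_pass)
    expect_equal(row$tli_pass, ev$tli_pass)
    expect_equal(row$rmsea_pass, ev$rmsea_pass)
    expect_equal(row$srmr_pass, ev$srmr_pass)
    expect_equal(row$verdict, ev$verdict)
  }
})

test_that("a failing CFA is recorded in the row while PCC and R2 survive", {
  # only 12 instances: fewer complete rows than the 16 indicators need
  sim <- generate_study(sim_config(n_participants = 12, seed = 2))
  rep <- run_av_analysis(sim$study)
  expect_equal(nrow(rep$agreement), 1L)
  expect_true(is.finite(rep$agreement$pearson_r))
  expect_true(is.finite(rep$agreement$slr_r2))
  expect_true(is.na(rep$agreement$cfa_phi))
  expect_match(rep$agreement$cfa_error, "complete rows")
})

test_that("identical runs produce identical reports", {
  study <- two_rm_study(n = 80, seed = 44)
  r1 <- run_av_analysis(study, daily_rm_instrument = "SIM-DAILY")
  r2 <- run_av_analysis(study, daily_rm_instrument = "SIM-DAILY")
  expect_identical(r1, r2)
})

test_that("completeness fractions match hand counts", {
  sim <- generate_study(sim_config(n_participants = 50, seed = 3))
  al <- build_aligned_dataset(sim$study, "dm", "SIM-RM",
                              daily_rm_instrument = "SIM-DAILY")
  cm <- completeness_metrics(al)
  expect_equal(cm$dm_day_completeness, 1)
  expect_equal(cm$rm_instance_completeness, 1)
  expect_equal(cm$daily_rm_completeness, 1)

  # knock out exactly one DM day per instance
  st <- sim$study
  drop_dates <- sim$truth$admin_date  # the newest window day of each instance
  keep <- !(paste(st$dm$participant_id, st$dm$date) %in%
              paste(sim$truth$participant_id, drop_dates))
  st$dm <- st$dm[keep, ]
  al2 <- build_aligned_dataset(st, "dm", "SIM-RM")
  cm2 <- completeness_metrics(al2)
  expect_equal(cm2$dm_day_completeness, 6 / 7)
  # no daily RM aligned -> fraction is missing, not zero
  expect_true(is.na(cm2$daily_rm_completeness))
})

test_that("reports round-trip through csv and json", {
  rep <- run_av_analysis(two_rm_study(n = 60, seed = 21),
                         daily_rm_instrument = "SIM-DAILY")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, csv, format = "csv")
  back <- read_report(csv, format = "csv")
  expect_equal(back$pearson_r, rep$agreement$pearson_r)
  expect_equal(back$cfa_phi, rep$agreement$cfa_phi)
  expect_equal(back$srmr, rep$agreement$srmr)

  js <- withr::local_tempfile(fileext = ".json")
  write_report(rep, js, format = "json")
  back_js <- read_report(js, format = "json")
  expect_equal(back_js$agreement$cfa_phi, rep$agreement$cfa_phi)
  expect_equal(back_js$regressions$adj_r2, rep$regressions$adj_r2)
  expect_equal(back_js$thresholds$cfi_min, 0.9)
})

test_that("empty-report serialisation writes headers only", {
  rep <- structure(list(agreement = run_av_analysis(two_rm_study(n = 60,
                                                                 seed = 21))$agreement[0, ],
                        regressions = NULL, completeness = NULL,
                        thresholds = fit_thresholds()),
                   class = "avtk_report")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, csv, format = "csv")
  lines <- readLines(csv)
  expect_length(lines, 1L)
  expect_match(lines, "pearson_r")
})
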