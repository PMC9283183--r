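# Six-month management measures: stays, LOS, readmission, window edges.

reg <- load_registry()
cfg <- analysis_config()
idx0 <- as.Date("2016-06-01")
hip_dx <- names(reg$fracture_dx)[unname(reg$fracture_dx) == "hip"][1]

test_that("the index stay is found, with nights-based LOS and a same-day minimum", {
  b <- mini_bundle()  # inpatient admission idx..idx+3
  cb <- build_cohort(b, reg, cfg)
  hosp <- find_index_hospitalization(cb$cohort, b, reg, cfg)
  expect_equal(nrow(hosp), 1L)
  expect_identical(hosp$los_days, 3L)

  same_day <- mc_row("X1", idx0, "inpatient", dx = hip_dx,
                     admission = idx0, discharge = idx0)
  b2 <- claims_bundle(b$members, b$enrollment, same_day, b$pharmacy_claims)
  cb2 <- build_cohort(b2, reg, cfg)
  hosp2 <- find_index_hospitalization(cb2$cohort, b2, reg, cfg)
  expect_identical(hosp2$los_days, 1L)

  out_only <- mini_bundle(id = "O1", setting = "outpatient")
  cbo <- build_cohort(out_only, reg, cfg)
  expect_equal(nrow(find_index_hospitalization(cbo$cohort, out_only, reg, cfg)), 0L)
})

test_that("abutting inpatient stays merge into one stay", {
  mc <- rbindlist(list(
    mc_row("X1", idx0, "inpatient", dx = hip_dx, admission = idx0,
           discharge = idx0 + 3),
    mc_row("X1", idx0 + 4, "inpatient", admission = idx0 + 4,
           discharge = idx0 + 6)))
  b <- mini_bundle(extra_mc = mc[2])  # first claim comes from mini_bundle... rebuild
  b <- claims_bundle(b$members, b$enrollment, mc, b$pharmacy_claims)
  cb <- build_cohort(b, reg, cfg)
  hosp <- find_index_hospitalization(cb$cohort, b, reg, cfg)
  expect_equal(nrow(hosp), 1L)
  expect_identical(hosp$discharge_date, idx0 + 6)
  expect_identical(hosp$los_days, 6L)
  # and a merged continuation is not a readmission
  expect_false(detect_readmission(hosp, b, reg, cfg))
})

test_that("readmission window is [discharge+1, discharge+30]", {
  mk <- function(gap_days) {
    re <- idx0 + 3 + gap_days
    b <- mini_bundle(extra_mc = mc_row("X1", re, "inpatient", dx = "GEN_1",
                                       admission = re, discharge = re + 1))
    cb <- build_cohort(b, reg, cfg)
    hosp <- find_index_hospitalization(cb$cohort, b, reg, cfg)
    detect_readmission(hosp, b, reg, cfg)
  }
  expect_true(mk(22))    # admission 25 days after discharge
  expect_false(mk(31))   # outside the 30-day window
  expect_false(mk(0))    # same-day rebill is not a readmission
  expect_true(mk(30))    # boundary day 30 counts
})

test_that("readmission is NA for members never hospitalized for the index", {
  b <- mini_bundle(setting = "outpatient")
  cb <- build_cohort(b, reg, cfg)
  mg <- summarize_management(cb$cohort, b, reg, cfg)
  expect_false(mg$hospitalized_for_index)
  expect_true(is.na(mg$readmit_30d))
})

test_that("post-index windows are closed: day 0 and day 183 count, 184 does not", {
  surg <- reg$ortho_surgery_proc[1]
  b <- mini_bundle(setting = "outpatient",
                   extra_mc = mc_row("X1", idx0, proc = surg))
  cb <- build_cohort(b, reg, cfg)
  mg <- summarize_management(cb$cohort, b, reg, cfg)
  expect_true(mg$ortho_surgery_6mo)  # surgery on the index date itself

  fx <- make_adversarial_fixtures(reg, cfg)
  for (case in c("dme_d183", "dme_d184")) {
    bb <- fx[[case]]$bundle
    cbb <- build_cohort(bb, reg, cfg)
    mgg <- summarize_management(cbb$cohort, bb, reg, cfg)
    expect_identical(mgg$dme_6mo, fx[[case]]$expected$dme_6mo, info = case)
  }
})

test_that("DXA timing and SNF timing are measured from index", {
  b <- mini_bundle(setting = "outpatient", extra_mc = rbindlist(list(
    mc_row("X1", idx0 + 75, proc = reg$dxa_proc[1]),
    mc_row("X1", idx0 + 90, proc = reg$dxa_proc[1]),  # later scan ignored
    mc_row("X1", idx0 + 12, "snf"))))
  cb <- build_cohort(b, reg, cfg)
  mg <- summarize_management(cb$cohort, b, reg, cfg)
  expect_true(mg$dxa_6mo)
  expect_identical(mg$days_to_first_dxa, 75L)
  expect_true(mg$snf_6mo)
  expect_identical(mg$days_index_to_snf, 12L)
})

test_that("rehabilitation counts rehab codes or home-health claims", {
  b1 <- mini_bundle(extra_mc = mc_row("X1", idx0 + 30, proc = reg$rehab[1]))
  b2 <- mini_bundle(extra_mc = mc_row("X1", idx0 + 30, "home_health"))
  for (b in list(b1, b2)) {
    cb <- build_cohort(b, reg, cfg)
    expect_true(summarize_management(cb$cohort, b, reg, cfg)$rehab_6mo)
  }
})

test_that("stratified aggregation uses the hospitalized denominator for readmission", {
  gen <- generate_population(scenario_config(n_members = 40, seed = 3), reg, cfg)
  cb <- build_cohort(gen$bundle, reg, cfg)
  mg <- summarize_management(cb$cohort, gen$bundle, reg, cfg)
  bl <- build_baseline(cb$cohort, gen$bundle, reg, cfg)
  t3 <- aggregate_table3(mg, cb$cohort, bl)
  r <- t3[stratum == "overall" & measure == "readmit_30d"]
  expect_identical(r$denominator, sum(mg$hospitalized_for_index))
  h <- t3[stratum == "overall" & measure == "hospitalized_for_index"]
  expect_identical(h$denominator, nrow(mg))
  expect_true(all(t3$numerator <= t3$denominator, na.rm = TRUE))
  expect_true(all(t3[kind == "pct" & denominator > 0, value >= 0 & value <= 100]))
})

test_that("empty strata report NA percentages, not zero", {
  b <- mini_bundle()  # hip index only: vertebral stratum is empty
  cb <- build_cohort(b, reg, cfg)
  mg <- summarize_management(cb$cohort, b, reg, cfg)
  bl <- build_baseline(cb$cohort, b, reg, cfg)
  t3 <- aggregate_table3(mg, cb$cohort, bl)
  expect_true(all(is.na(t3[stratum == "vertebral" & kind == "pct", value])))
  expect_true(all(t3[stratum == "vertebral", denominator] == 0L))
})
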