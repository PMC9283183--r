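# Pre-index baseline profiling: CCI, interval bands, window conventions.

reg <- load_registry()
cfg <- analysis_config()
idx0 <- as.Date("2016-06-01")

test_that("CCI sums weights over distinct categories only", {
  expect_equal(compute_cci(character(0), reg$cci_map), 0)
  expect_equal(compute_cci("ZZZ", reg$cci_map), 0)
  mi <- reg$cci_map[category == "myocardial_infarction", code][1]
  renal <- reg$cci_map[category == "renal_disease", code][1]
  expect_equal(compute_cci(c(mi, renal), reg$cci_map), 3)
  expect_equal(compute_cci(rep(renal, 5), reg$cci_map), 2)
})

test_that("interval banding is half-open with an out_of_range marker", {
  expect_identical(interval_band(c(0, 30, 31, 60, 61, 180, 181, 360)),
                   c("<=30", "<=30", ">30-60", ">30-60", ">60-180", ">60-180",
                     ">180-360", ">180-360"))
  expect_identical(interval_band(361), "out_of_range")
  expect_error(interval_band(-1), "negative")
})

test_that("baseline flags respect the [index-365, index-1] window", {
  dxa <- reg$dxa_proc[1]
  extra <- rbindlist(list(
    mc_row("X1", idx0 - 10, proc = dxa),           # in window, 10 days out
    mc_row("X1", idx0, dx = reg$op_dx[1])))        # index-day claim: NOT baseline
  b <- mini_bundle(extra_mc = extra)
  cb <- build_cohort(b, reg, cfg)
  bl <- build_baseline(cb$cohort, b, reg, cfg)
  expect_true(bl$dxa)
  expect_identical(bl$dxa_days_before_index, 10L)
  expect_identical(bl$dxa_band, "<=30")
  expect_false(bl$op_dx)
})

test_that("a claim exactly 365 days before index is in the window; 366 is not", {
  for (d in c(365L, 366L)) {
    b <- mini_bundle(extra_mc = mc_row("X1", idx0 - d, dx = reg$op_dx[1]),
                     enroll_start = idx0 - 500L)
    cb <- build_cohort(b, reg, cfg)
    bl <- build_baseline(cb$cohort, b, reg, cfg)
    expect_identical(bl$op_dx, d == 365L, info = d)
  }
})

test_that("pre-index OP fills set use flags and the supergroup split", {
  teri <- names(reg$drug_class)[unname(reg$drug_class) == "teriparatide"][1]
  b <- mini_bundle(extra_rx = rx_row("X1", idx0 - 90, teri))
  cb <- build_cohort(b, reg, cfg)
  bl <- build_baseline(cb$cohort, b, reg, cfg)
  expect_true(bl$op_med_use)
  expect_true(bl$anabolic_use)
  expect_false(bl$antiresorptive_use)
  expect_true(bl$op_dx_or_tx)
  expect_true(bl$rx_teriparatide)
})

test_that("corticosteroid look-back is 183 days, not the full year", {
  cort <- names(reg$drug_class)[unname(reg$drug_class) == "corticosteroid"][1]
  for (d in c(183L, 184L)) {
    b <- mini_bundle(extra_rx = rx_row("X1", idx0 - d, cort))
    cb <- build_cohort(b, reg, cfg)
    bl <- build_baseline(cb$cohort, b, reg, cfg)
    expect_identical(bl$corticosteroid_6mo, d == 183L, info = d)
    expect_true(bl$rx_corticosteroid)  # full-year flag still set
  }
})

test_that("op_dx_or_tx dominates both of its components on generated cohorts", {
  gen <- generate_population(scenario_config(n_members = 800, seed = 5), reg, cfg)
  cb <- build_cohort(gen$bundle, reg, cfg)
  bl <- build_baseline(cb$cohort, gen$bundle, reg, cfg)
  expect_gte(sum(bl$op_dx_or_tx), max(sum(bl$op_dx), sum(bl$op_med_use)))
  expect_true(all(bl$op_dx_or_tx == (bl$op_dx | bl$op_med_use)))
  expect_true(all((bl$anabolic_use | bl$antiresorptive_use) <= bl$op_med_use))
})

test_that("baseline flags equal a brute-force claim scan on random members", {
  gen <- generate_population(scenario_config(n_members = 500, seed = 23), reg, cfg)
  cb <- build_cohort(gen$bundle, reg, cfg)
  bl <- build_baseline(cb$cohort, gen$bundle, reg, cfg)
  mc <- gen$bundle$medical_claims
  rx <- gen$bundle$pharmacy_claims
  op_set <- reg$op_dx
  dxa_set <- reg$dxa_proc
  op_codes <- names(reg$drug_class)[unname(reg$drug_class) %in% op_med_classes()]
  for (k in sample(nrow(bl), min(120, nrow(bl)))) {
    m <- bl$member_id[k]
    i <- bl$index_date[k]
    mm <- mc[member_id == m & service_date >= i - 365 & service_date <= i - 1]
    dxs <- unlist(strsplit(mm$dx_codes, "|", fixed = TRUE))
    pxs <- unlist(strsplit(mm$proc_codes, "|", fixed = TRUE))
    rr <- rx[member_id == m & fill_date >= i - 365 & fill_date <= i - 1]
    expect_identical(bl$op_dx[k], any(dxs %in% op_set), info = m)
    expect_identical(bl$dxa[k], any(pxs %in% dxa_set), info = m)
    expect_identical(bl$op_med_use[k], any(rr$drug_code %in% op_codes), info = m)
    expect_identical(bl$cci[k], compute_cci(dxs, reg$cci_map), info = m)
    if (bl$dxa[k]) {
      dxa_dates <- mm$service_date[vapply(strsplit(mm$proc_codes, "|", fixed = TRUE),
                                          function(p) any(p %in% dxa_set), NA)]
      expect_identical(bl$dxa_days_before_index[k],
                       as.integer(i - max(dxa_dates)), info = m)
    }
  }
})
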