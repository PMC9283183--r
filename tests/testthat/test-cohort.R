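# Fracture identification, index assignment, eligibility, attrition.

reg <- load_registry()
cfg <- analysis_config()
idx0 <- as.Date("2016-06-01")
hip_dx <- names(reg$fracture_dx)[unname(reg$fracture_dx) == "hip"][1]
hip_px <- names(reg$fracture_proc)[unname(reg$fracture_proc) == "hip"][1]
ver_dx <- names(reg$fracture_dx)[unname(reg$fracture_dx) == "vertebral"][1]
rad_dx <- names(reg$fracture_dx)[unname(reg$fracture_dx) == "radius_ulna"][1]

test_that("the three identification rules fire and non-qualifying claims do not", {
  mc <- rbindlist(list(
    mc_row("A", idx0, "inpatient", dx = hip_dx, admission = idx0,
           discharge = idx0 + 2),           # (a) inpatient dx
    mc_row("B", idx0, "outpatient", dx = rad_dx),  # outpatient dx, no proc
    mc_row("C", idx0, "outpatient", dx = ver_dx,
           proc = reg$em_proc[1]),          # (c) vertebral dx + E&M
    mc_row("D", idx0, "outpatient", dx = hip_dx),  # (b) dx and proc 5 days apart
    mc_row("D", idx0 + 5, "outpatient", proc = hip_px),
    mc_row("E", idx0, "outpatient", dx = hip_dx),  # proc outside pairing window
    mc_row("E", idx0 + 8, "outpatient", proc = hip_px)))
  ev <- identify_fracture_events(mc, reg, cfg)
  expect_identical(ev[member_id == "A", rule], "inpatient_dx")
  expect_identical(ev[member_id == "A", setting], "inpatient")
  expect_equal(nrow(ev[member_id == "B"]), 0L)
  expect_identical(ev[member_id == "C", rule], "vertebral_dx_plus_em")
  expect_identical(ev[member_id == "C", site], "vertebral")
  expect_identical(ev[member_id == "D", rule], "outpatient_dx_plus_proc")
  expect_identical(ev[member_id == "D", event_date], idx0)  # dated at the dx
  expect_equal(nrow(ev[member_id == "E"]), 0L)
})

test_that("inpatient events are dated at admission when present", {
  mc <- mc_row("A", idx0 + 4, "inpatient", dx = hip_dx,
               admission = idx0, discharge = idx0 + 6)
  ev <- identify_fracture_events(mc, reg, cfg)
  expect_identical(ev$event_date, idx0)
})

test_that("earliest date beats hierarchy; same-day ties resolve by rank", {
  mc <- rbindlist(list(
    mc_row("A", idx0, "inpatient", dx = ver_dx, admission = idx0,
           discharge = idx0 + 1),
    mc_row("A", idx0 + 40, "inpatient", dx = hip_dx, admission = idx0 + 40,
           discharge = idx0 + 41)))
  idx <- assign_index_fracture(identify_fracture_events(mc, reg, cfg), reg, cfg)
  expect_identical(idx$site, "vertebral")
  expect_identical(idx$index_date, idx0)

  tib_dx <- names(reg$fracture_dx)[unname(reg$fracture_dx) == "tibia_fibula"][1]
  ank_dx <- names(reg$fracture_dx)[unname(reg$fracture_dx) == "ankle"][1]
  mc2 <- mc_row("B", idx0, "inpatient", dx = paste(ank_dx, tib_dx, sep = "|"),
                admission = idx0, discharge = idx0 + 1)
  idx2 <- assign_index_fracture(identify_fracture_events(mc2, reg, cfg), reg, cfg)
  expect_identical(idx2$site, "tibia_fibula")
  expect_identical(idx2$competing_sites_same_day, "ankle")
})

test_that("index assignment is invariant to claim order", {
  mc <- rbindlist(list(
    mc_row("A", idx0 + 10, "inpatient", dx = hip_dx, admission = idx0 + 10,
           discharge = idx0 + 12),
    mc_row("A", idx0, "outpatient", dx = ver_dx, proc = reg$em_proc[1]),
    mc_row("A", idx0 + 3, "outpatient", dx = rad_dx),
    mc_row("A", idx0 + 4, "outpatient", proc = names(reg$fracture_proc)[
      unname(reg$fracture_proc) == "radius_ulna"][1])))
  ref <- assign_index_fracture(identify_fracture_events(mc, reg, cfg), reg, cfg)
  set.seed(7)
  for (i in 1:5) {
    perm <- mc[sample(.N)]
    got <- assign_index_fracture(identify_fracture_events(perm, reg, cfg), reg, cfg)
    expect_equal(as.data.frame(got), as.data.frame(ref))
  }
})

test_that("events outside the index period cannot be the index", {
  mc <- mc_row("A", as.Date("2014-06-01"), "inpatient", dx = hip_dx,
               admission = as.Date("2014-06-01"),
               discharge = as.Date("2014-06-03"))
  ev <- identify_fracture_events(mc, reg, cfg)
  expect_equal(nrow(ev), 1L)  # identified within the study period
  expect_equal(nrow(assign_index_fracture(ev, reg, cfg)), 0L)  # but not indexable
})

test_that("hierarchy resolution is exact over all 36 same-day site pairs", {
  fx <- make_adversarial_fixtures(reg, cfg)$hierarchy_allpairs
  cb <- build_cohort(fx$bundle, reg, cfg)
  got <- setNames(cb$cohort$index_site, cb$cohort$member_id)
  want <- fx$expected$winner
  expect_identical(got[names(want)], want)
  expect_false(any(got == fx$expected$loser[names(got)]))
})

test_that("eligibility boundary fixtures resolve as engineered", {
  fx <- make_adversarial_fixtures(reg, cfg)
  for (case in c("enroll_hole_1day", "trauma_index_day", "cancer_excluded",
                 "nmsc_carveout", "fu_183", "fu_182")) {
    cb <- build_cohort(fx[[case]]$bundle, reg, cfg)
    exp_el <- fx[[case]]$expected$eligible
    expect_equal(nrow(cb$cohort) == 1L, exp_el, info = case)
    if (!exp_el) {
      expect_identical(cb$eligibility$exclusion_reason,
                       fx[[case]]$expected$exclusion_reason, info = case)
    }
  }
})

test_that("a qualified pre-index fracture excludes, with reason prior_fracture", {
  pre <- mc_row("X1", as.Date("2014-09-01"), "inpatient", dx = rad_dx,
                admission = as.Date("2014-09-01"),
                discharge = as.Date("2014-09-02"))
  b <- mini_bundle(extra_mc = pre, enroll_start = as.Date("2014-01-01"))
  cb <- build_cohort(b, reg, cfg)
  expect_equal(nrow(cb$cohort), 0L)
  expect_identical(cb$eligibility$exclusion_reason, "prior_fracture")
})

test_that("attrition decrements one per engineered failure and ends at cohort size", {
  idx <- idx0
  mk <- function(id, ...) mini_bundle(id = id, idx = idx, ...)
  bundles <- list(
    mk("ok1"), mk("ok2"), mk("ok3"),
    mk("m_sex", sex = "M"),
    mk("m_age", birth_year = 1970L),
    mk("m_pre", enroll_start = idx - 100L),
    mk("m_post", enroll_end = idx + 100L))
  b <- claims_bundle(
    rbindlist(lapply(bundles, function(x) x$members)),
    rbindlist(lapply(bundles, function(x) x$enrollment)),
    rbindlist(lapply(bundles, function(x) x$medical_claims)),
    rbindlist(lapply(bundles, function(x) x$pharmacy_claims)))
  cb <- build_cohort(b, reg, cfg)
  expect_equal(nrow(cb$cohort), 3L)
  expect_identical(cb$attrition$n_remaining, c(7L, 7L, 6L, 5L, 4L, 3L, 3L, 3L, 3L, 3L))
  expect_true(all(diff(cb$attrition$n_remaining) <= 0))
})

test_that("an empty bundle yields an empty cohort and an all-zero attrition", {
  empty <- claims_bundle(
    data.table(member_id = character(0), sex = character(0),
               birth_year = integer(0), region = character(0),
               payer = character(0), plan_type = character(0)),
    data.table(member_id = character(0), start_date = as.Date(character(0)),
               end_date = as.Date(character(0)), medical = logical(0),
               pharmacy = logical(0)),
    mc_row(character(0), as.Date(character(0))),
    rx_row(character(0), as.Date(character(0)), character(0), integer(0)))
  cb <- build_cohort(empty, reg, cfg)
  expect_equal(nrow(cb$cohort), 0L)
  expect_true(all(cb$attrition$n_remaining == 0L))
})

test_that("no cohort member has a qualified event before their index date", {
  gen <- generate_population(scenario_config(n_members = 600, seed = 11), reg, cfg)
  cb <- build_cohort(gen$bundle, reg, cfg)
  j <- merge(cb$events, cb$cohort[, .(member_id, index_date)], by = "member_id")
  expect_true(all(j$event_date >= j$index_date))
})
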