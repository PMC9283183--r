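# Label-first synthetic claims generator.
#
# The generator samples per-member ground-truth labels FIRST (eligibility
# category, index site/setting, hospitalization and LOS, readmission,
# post-index care, treatment episode shape, subsequent fracture), then
# writes claims that realize each label so that the corresponding pipeline
# rule is guaranteed to detect it; planted negatives violate exactly one
# clause of the relevant rule. This yields a decidable truth set for exact
# member-level recovery tests. All randomness flows from one seed.

.codes_for <- function(map, tag) names(map)[unname(map) == tag]
.code1 <- function(map, tag) .codes_for(map, tag)[1]

.empty_mc <- function() {
  data.table::data.table(
    member_id = character(0), service_date = as.Date(character(0)),
    setting = character(0), dx_codes = character(0), proc_codes = character(0),
    admission_date = as.Date(character(0)), discharge_date = as.Date(character(0)))
}

.mc_rows <- function(member_id, service_date, setting = "outpatient",
                     dx = "", proc = "", admission = NULL, discharge = NULL) {
  n <- length(member_id)
  if (!n) return(.empty_mc())
  data.table::data.table(
    member_id = member_id,
    service_date = service_date,
    setting = rep_len(setting, n),
    dx_codes = rep_len(dx, n),
    proc_codes = rep_len(proc, n),
    admission_date = if (is.null(admission)) as.Date(rep(NA, n)) else admission,
    discharge_date = if (is.null(discharge)) as.Date(rep(NA, n)) else discharge)
}

.empty_rx <- function() {
  data.table::data.table(member_id = character(0),
                         fill_date = as.Date(character(0)),
                         drug_code = character(0), days_supply = integer(0))
}

.rx_rows <- function(member_id, fill_date, drug_code, days_supply = 30L) {
  n <- length(member_id)
  if (!n) return(.empty_rx())
  data.table::data.table(member_id = member_id, fill_date = fill_date,
                         drug_code = rep_len(drug_code, n),
                         days_supply = as.integer(rep_len(days_supply, n)))
}

# group-level probability vector (hip/vertebral/NHNV) expanded per member
.by_group <- function(groups, v) unname(v[groups])

#' Simulation scenario configuration
#'
#' Builds a validated scenario: cohort size, seed, ineligibility mix, age
#' and site mixtures, per-site care probabilities, the treatment model
#' (initiation by window, class mix, discontinuation/re-initiation), the
#' subsequent-fracture model, and the enrollment model. Defaults are the
#' packaged calibration used by [scenario_paper()]; any element can be
#' overridden.
#'
#' @param n_members Number of members to simulate.
#' @param seed Integer seed; all generator randomness flows from it.
#' @param overrides Named list of elements to replace in the default
#'   scenario.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_members = 1000L, seed = 1L, overrides = list()) {
  sc <- list(
    n_members = as.integer(n_members),
    seed = as.integer(seed),
    # ineligibility mix: each failing member violates exactly one criterion
    p_fail = c(no_fracture = 0.02, sex = 0.01, age = 0.03, pre_enroll = 0.04,
               post_enroll = 0.03, trauma = 0.03, prior_fracture = 0.03,
               bone_disease = 0.01, cancer = 0.04),
    p_nmsc = 0.02,  # eligible members carrying a non-melanoma skin cancer dx
    age_band_probs = c("50-59" = 0.436, "60-64" = 0.287, "65-70" = 0.100,
                       "71-79" = 0.071, ">=80" = 0.106),
    site_mix = c(hip = 0.121, vertebral = 0.306, radius_ulna = 0.249,
                 humerus = 0.100, ankle = 0.080, tibia_fibula = 0.060,
                 pelvis = 0.044, femur = 0.024, clavicle = 0.016),
    region_probs = c(Northeast = 0.220, Midwest = 0.259, South = 0.350,
                     West = 0.171),
    payer_probs = c(Commercial = 0.872, MedicareRisk = 0.060,
                    Medicaid = 0.041, Unknown = 0.027),
    plan_probs = c(PPO = 0.751, HMO = 0.166, POS = 0.049,
                   ConsumerDirected = 0.001, Indemnity = 0.025, Other = 0.008),
    p_inpatient_by_group = c(hip = 0.967, vertebral = 0.213, NHNV = 0.289),
    los_nb = list(mu = 4.5, size = 1.645),  # LOS = 1 + NegBin: mean 5.5, SD 4.1
    p_readmit = 0.143,
    p_surgery_by_group = c(hip = 0.900, vertebral = 0.170, NHNV = 0.472),
    p_dxa_by_group = c(hip = 0.136, vertebral = 0.188, NHNV = 0.109),
    p_snf_by_group = c(hip = 0.414, vertebral = 0.082, NHNV = 0.085),
    p_dme_by_group = c(hip = 0.381, vertebral = 0.094, NHNV = 0.168),
    p_rehab_by_group = c(hip = 0.663, vertebral = 0.398, NHNV = 0.632),
    dme_subtype_probs = c(walker = 0.70, wheelchair = 0.20, other = 0.10),
    p_op_dx_post_given_tx = 0.723,
    p_op_dx_post_given_no_tx = 0.141,
    # one-year pre-index baseline prevalences
    p_pre = c(op_dx = 0.108, dxa = 0.097, op_med = 0.073, surgery = 0.018,
              smoking = 0.082, falls = 0.024, osteoarthritis = 0.199,
              depression = 0.180, cardiovascular = 0.296,
              corticosteroid_6mo = 0.219, narcotic = 0.325,
              antidepressant = 0.294),
    pre_anabolic_share = 0.028,  # of pre-index OP med users
    cci_k_probs = c(0.587, 0.217, 0.130, 0.066),  # 0/1/2/3 distinct categories
    # treatment model: initiation by window (6mo marginal; conditional
    # increments for (6,12] and (12,24] within the landmark denominators)
    p_treat6_by_group = c(hip = 0.142, vertebral = 0.187, NHNV = 0.065),
    p_treat12_new_by_group = c(hip = 0.0618, vertebral = 0.0504, NHNV = 0.0246),
    p_treat24_new_by_group = c(hip = 0.0584, vertebral = 0.0570, NHNV = 0.0285),
    class_mix = c(teriparatide = 0.054, abaloparatide = 0.009,
                  romosozumab = 0.000, oral_BP = 0.607, IV_BP = 0.045,
                  calcitonin = 0.116, denosumab = 0.116, SERM = 0.053),
    days_supply = 30L,
    # discontinuation by landmark, conditional on initiation window
    disc_probs = list(w1 = c(by6 = 0.098, by12 = 0.098, by24 = 0.090),
                      w2 = c(by12 = 0.129, by24 = 0.129),
                      w3 = c(by24 = 0.391)),
    p_reinit = 0.45,
    # subsequent-fracture model
    p_sub6_by_group = c(hip = 0.100, vertebral = 0.125, NHNV = 0.040),
    p_sub12_new_by_group = c(hip = 0.0311, vertebral = 0.0594, NHNV = 0.0135),
    p_sub24_new_by_group = c(hip = 0.0528, vertebral = 0.0705, NHNV = 0.0190),
    p_sub_same_site = 0.30,
    sub_group_mix = c(hip = 0.095, vertebral = 0.486, NHNV = 0.419),
    # enrollment model
    pre_slack_max = 200L,
    post_disenroll_rate = 8.545e-4
  )
  for (nm in names(overrides)) sc[[nm]] <- overrides[[nm]]
  validate_scenario(sc)
  class(sc) <- "scenario_config"
  sc
}

validate_scenario <- function(sc) {
  probs <- c(sc$p_fail, sc$p_nmsc, sc$age_band_probs, sc$site_mix,
             sc$p_inpatient_by_group, sc$p_readmit, sc$p_surgery_by_group,
             sc$p_dxa_by_group, sc$p_snf_by_group, sc$p_dme_by_group,
             sc$p_rehab_by_group, sc$p_pre, sc$class_mix,
             unlist(sc$disc_probs), sc$p_reinit, sc$p_sub6_by_group,
             sc$sub_group_mix)
  if (any(probs < 0 | probs > 1)) stop_input("scenario probabilities must be in [0,1]")
  if (sum(sc$p_fail) >= 1) stop_input("ineligibility probabilities sum to >= 1")
  if (abs(sum(sc$site_mix) - 1) > 1e-8) stop_input("site_mix must sum to 1")
  if (abs(sum(sc$age_band_probs) - 1) > 1e-8) stop_input("age_band_probs must sum to 1")
  if (abs(sum(sc$class_mix) - 1) > 1e-8) stop_input("class_mix must sum to 1")
  if (sc$n_members < 0) stop_input("n_members must be >= 0")
  invisible(sc)
}

#' The packaged paper-calibrated scenario
#'
#' [scenario_config()] with its defaults: the generator parameters are
#' calibrated to published headline values for post-fracture management in
#' commercially insured women (index-site mix 30.6/24.9/12.1...% for
#' vertebral/radius-ulna/hip, 34.8% inpatient ascertainment, 96.7%
#' hip-fracture hospitalization with mean LOS 5.5 days, 14.3% 30-day
#' readmission, 43.1%/90.0% overall/hip surgery, 41.4% hip SNF, 13.6% DXA,
#' 11.2/14.3/17.6% treated by 6/12/24 months, 7.4/9.9/13.2% subsequent
#' fracture). These values are calibration INPUTS to the simulation, not
#' independent reproductions of proprietary-database results.
#'
#' @param n_members Number of members (50,000 in the packaged evaluation).
#' @param seed Integer seed.
#' @return A `scenario_config`.
#' @export
scenario_paper <- function(n_members = 50000L, seed = 20150101L) {
  scenario_config(n_members = n_members, seed = seed)
}

#' Generate a synthetic claims population with planted ground truth
#'
#' Samples member-level labels from the scenario and writes claims
#' realizing them (see the source header for the label-first design).
#' Deterministic given the scenario seed.
#'
#' @param scenario A [scenario_config()].
#' @param registry A [load_registry()] object (codes to emit).
#' @param config An [analysis_config()].
#' @return A list with `bundle` (a `claims_bundle`) and `truth` (data.table
#'   of per-member planted labels: eligibility category and reason, index
#'   site/date/setting, follow-up days, hospitalization/LOS/readmission,
#'   six-month care flags, treatment episode labels by landmark, and
#'   subsequent-fracture day).
#' @export
generate_population <- function(scenario, registry = load_registry(),
                                config = analysis_config()) {
  sc <- scenario
  set.seed(sc$seed)
  n <- sc$n_members
  if (n == 0L) {
    empty_members <- data.table::data.table(
      member_id = character(0), sex = character(0), birth_year = integer(0),
      region = character(0), payer = character(0), plan_type = character(0))
    empty_enroll <- data.table::data.table(
      member_id = character(0), start_date = as.Date(character(0)),
      end_date = as.Date(character(0)), medical = logical(0), pharmacy = logical(0))
    b <- claims_bundle(empty_members, empty_enroll, .empty_mc(), .empty_rx())
    return(list(bundle = b, truth = data.table::data.table(member_id = character(0))))
  }

  id <- sprintf("M%07d", seq_len(n))
  cats <- c("eligible", names(sc$p_fail))
  cat_probs <- c(1 - sum(sc$p_fail), unname(sc$p_fail))
  category <- sample(cats, n, replace = TRUE, prob = cat_probs)
  has_fx <- category != "no_fracture"
  eligible <- category == "eligible"

  # index date: uniform over the index period; planted prior-fracture
  # exclusions index early so the earlier event predates the index period
  idx_span <- as.integer(config$index_end - config$index_start)
  index_date <- config$index_start + sample.int(idx_span + 1L, n, replace = TRUE) - 1L
  early <- category == "prior_fracture"
  index_date[early] <- config$index_start +
    sample.int(100L, sum(early), replace = TRUE) - 1L
  index_date[!has_fx] <- as.Date(NA)

  site <- sample(names(sc$site_mix), n, replace = TRUE, prob = sc$site_mix)
  grp <- site_group(site)
  site[!has_fx] <- NA_character_
  grp[!has_fx] <- NA_character_

  band <- sample(names(sc$age_band_probs), n, replace = TRUE,
                 prob = sc$age_band_probs)
  age <- integer(n)
  age[band == "50-59"] <- sample(50:59, sum(band == "50-59"), replace = TRUE)
  age[band == "60-64"] <- sample(60:64, sum(band == "60-64"), replace = TRUE)
  age[band == "65-70"] <- sample(65:70, sum(band == "65-70"), replace = TRUE)
  age[band == "71-79"] <- sample(71:79, sum(band == "71-79"), replace = TRUE)
  age[band == ">=80"] <- sample(80:94, sum(band == ">=80"), replace = TRUE)
  age[category == "age"] <- sample(45:49, sum(category == "age"), replace = TRUE)
  ref_year <- data.table::fifelse(has_fx, date_year(index_date),
                                  date_year(config$index_start))
  birth_year <- ref_year - age
  sex <- data.table::fifelse(category == "sex", "M", "F")

  members <- data.table::data.table(
    member_id = id, sex = sex, birth_year = birth_year,
    region = sample(names(sc$region_probs), n, TRUE, sc$region_probs),
    payer = sample(names(sc$payer_probs), n, TRUE, sc$payer_probs),
    plan_type = sample(names(sc$plan_probs), n, TRUE, sc$plan_probs))

  # --- enrollment ---------------------------------------------------------
  anchor <- data.table::fifelse(has_fx, index_date,
                                config$index_start + 200L)
  start <- pmax(config$study_start,
                anchor - config$pre_index_days -
                  sample.int(sc$pre_slack_max + 1L, n, TRUE) + 1L)
  fu_extra <- round(stats::rexp(n, rate = sc$post_disenroll_rate))
  end <- pmin(config$study_end,
              anchor + config$post_index_min_days + fu_extra)
  short <- category == "post_enroll"
  end[short] <- anchor[short] + sample(30:182, sum(short), replace = TRUE)

  holey <- category == "pre_enroll"
  hole_start <- anchor - sample(60:300, n, replace = TRUE)
  hole_len <- sample(1:20, n, replace = TRUE)
  enroll <- data.table::rbindlist(list(
    data.table::data.table(member_id = id[!holey], start_date = start[!holey],
                           end_date = end[!holey]),
    data.table::data.table(member_id = id[holey], start_date = start[holey],
                           end_date = hole_start[holey] - 1L),
    data.table::data.table(member_id = id[holey],
                           start_date = hole_start[holey] + hole_len[holey],
                           end_date = end[holey])))
  enroll[, `:=`(medical = TRUE, pharmacy = TRUE)]

  follow_up <- as.integer(end - anchor)
  follow_up[!has_fx] <- NA_integer_

  # --- index event realization -------------------------------------------
  hosp <- has_fx & stats::runif(n) < .by_group(grp, sc$p_inpatient_by_group)
  hosp[!has_fx] <- FALSE
  los <- 1L + as.integer(stats::rnbinom(n, size = sc$los_nb$size, mu = sc$los_nb$mu))
  los[!hosp] <- NA_integer_

  site_dx_code <- vapply(fracture_sites(), function(s)
    .code1(registry$fracture_dx, s), "")
  site_px_code <- vapply(fracture_sites(), function(s)
    .code1(registry$fracture_proc, s), "")
  dme_code <- vapply(c("walker", "wheelchair", "other"), function(s)
    .code1(registry$dme, s), "")
  dx_of_site <- function(ss) unname(site_dx_code[ss])
  px_of_site <- function(ss) unname(site_px_code[ss])

  mc_parts <- list()
  w <- which(hosp)
  mc_parts$index_ip <- .mc_rows(id[w], index_date[w], "inpatient",
                                dx = dx_of_site(site[w]),
                                admission = index_date[w],
                                discharge = index_date[w] + los[w])
  w <- which(has_fx & !hosp)
  use_em <- site[w] == "vertebral" & stats::runif(length(w)) < 0.5
  proc_out <- ifelse(use_em, registry$em_proc[1], px_of_site(site[w]))
  mc_parts$index_op <- .mc_rows(id[w], index_date[w], "outpatient",
                                dx = dx_of_site(site[w]), proc = proc_out)
  index_setting <- ifelse(hosp, "inpatient", "outpatient")
  index_setting[!has_fx] <- NA_character_

  # --- planted ineligibility claims --------------------------------------
  w <- which(category == "trauma")
  mc_parts$trauma <- .mc_rows(id[w], index_date[w], "outpatient",
                              dx = registry$trauma_dx[1])
  w <- which(category == "prior_fracture")
  prior_gap <- sample(100:300, length(w), replace = TRUE)
  prior_date <- pmax(config$study_start, index_date[w] - prior_gap)
  # must predate the index period so it cannot itself become the index
  prior_date <- pmin(prior_date, config$index_start - 1L)
  mc_parts$prior_fx <- .mc_rows(id[w], prior_date, "inpatient",
                                dx = dx_of_site(rep("radius_ulna", length(w))),
                                admission = prior_date,
                                discharge = prior_date + 2L)
  w <- which(category == "bone_disease")
  bone_codes <- names(registry$exclusion_dx)[
    registry$exclusion_dx != "cancer"]
  mc_parts$bone <- .mc_rows(id[w],
                            index_date[w] - sample(30:364, length(w), TRUE),
                            "outpatient",
                            dx = sample(bone_codes, length(w), TRUE))
  w <- which(category == "cancer")
  cancer_codes <- setdiff(
    names(registry$exclusion_dx)[registry$exclusion_dx == "cancer"],
    registry$nonmelanoma_skin_cancer_dx)
  mc_parts$cancer <- .mc_rows(id[w],
                              index_date[w] - sample(30:300, length(w), TRUE),
                              "outpatient",
                              dx = sample(cancer_codes, length(w), TRUE))
  nmsc <- eligible & stats::runif(n) < sc$p_nmsc
  w <- which(nmsc)
  mc_parts$nmsc <- .mc_rows(id[w],
                            index_date[w] - sample(30:300, length(w), TRUE),
                            "outpatient",
                            dx = registry$nonmelanoma_skin_cancer_dx[1])

  # --- baseline (pre-index) claims for all indexed members ----------------
  pre_day <- function(w, lo, hi) index_date[w] - sample(lo:hi, length(w), TRUE)
  bern <- function(p, base = has_fx) base & stats::runif(n) < p

  pre_op_dx <- bern(sc$p_pre[["op_dx"]])
  w <- which(pre_op_dx)
  mc_parts$pre_opdx <- .mc_rows(id[w], pre_day(w, 30, 364), "outpatient",
                                dx = registry$op_dx[1])
  pre_dxa <- bern(sc$p_pre[["dxa"]])
  pre_dxa_day <- sample(5:360, n, replace = TRUE)
  w <- which(pre_dxa)
  mc_parts$pre_dxa <- .mc_rows(id[w], index_date[w] - pre_dxa_day[w],
                               "outpatient", proc = registry$dxa_proc[1])
  pre_surg <- bern(sc$p_pre[["surgery"]])
  w <- which(pre_surg)
  mc_parts$pre_surg <- .mc_rows(id[w], pre_day(w, 1, 360), "outpatient",
                                proc = registry$ortho_surgery_proc[1])
  com_map <- registry$comorbidity_dx
  for (flag in c("smoking", "falls", "osteoarthritis", "depression")) {
    grp_name <- if (flag == "falls") "falls" else flag
    p <- sc$p_pre[[if (flag == "falls") "falls" else flag]]
    on <- bern(p)
    w <- which(on)
    mc_parts[[paste0("pre_", flag)]] <-
      .mc_rows(id[w], pre_day(w, 1, 364), "outpatient",
               dx = .code1(com_map, grp_name))
  }
  on <- bern(sc$p_pre[["cardiovascular"]])
  w <- which(on)
  mc_parts$pre_cvd <- .mc_rows(id[w], pre_day(w, 1, 364), "outpatient",
                               dx = .code1(com_map, "cardiovascular_disease"))
  # CCI: k distinct categories, one claim each
  cci_k <- sample(0:3, n, replace = TRUE, prob = sc$cci_k_probs)
  cci_k[!has_fx] <- 0L
  cci_cats <- unique(registry$cci_map$category)
  cci_cat_code <- registry$cci_map$code[match(cci_cats, registry$cci_map$category)]
  w <- which(cci_k > 0L)
  if (length(w)) {
    reps <- cci_k[w]
    mem <- rep(id[w], reps)
    mem_idx <- rep(w, reps)
    pick <- unlist(lapply(reps, function(k) sample(seq_along(cci_cats), k)))
    codes <- cci_cat_code[pick]
    mc_parts$pre_cci <- .mc_rows(mem, index_date[mem_idx] -
                                   sample(1:364, length(mem), TRUE),
                                 "outpatient", dx = codes)
  }
  # one generic unmapped claim per member (robustness noise)
  noise_day <- pmin(pmax(config$study_start + 30L +
                           sample.int(1500L, n, TRUE), config$study_start),
                    config$study_end)
  mc_parts$noise <- .mc_rows(id, noise_day, "outpatient", dx = "GEN_1")

  # --- post-index care for eligible members ------------------------------
  L6 <- config$post_index_min_days
  surgery6 <- eligible & stats::runif(n) < .by_group(grp, sc$p_surgery_by_group)
  w <- which(surgery6)
  mc_parts$surg <- .mc_rows(id[w], index_date[w] + sample(0:L6, length(w), TRUE),
                            "outpatient", proc = registry$ortho_surgery_proc[1])
  dxa6 <- eligible & stats::runif(n) < .by_group(grp, sc$p_dxa_by_group)
  dxa_day <- pmin(L6, pmax(0L, round(stats::rnorm(n, 75, 50))))
  w <- which(dxa6)
  mc_parts$dxa <- .mc_rows(id[w], index_date[w] + dxa_day[w], "outpatient",
                           proc = registry$dxa_proc[1])
  snf6 <- eligible & stats::runif(n) < .by_group(grp, sc$p_snf_by_group)
  snf_day <- pmin(L6, 1L + stats::rnbinom(n, size = 1, mu = 13))
  w <- which(snf6)
  mc_parts$snf <- .mc_rows(id[w], index_date[w] + snf_day[w], "snf")
  dme6 <- eligible & stats::runif(n) < .by_group(grp, sc$p_dme_by_group)
  dme_sub <- sample(names(sc$dme_subtype_probs), n, TRUE, sc$dme_subtype_probs)
  w <- which(dme6)
  mc_parts$dme <- .mc_rows(id[w], index_date[w] + sample(0:L6, length(w), TRUE),
                           "outpatient", proc = unname(dme_code[dme_sub[w]]))
  rehab6 <- eligible & stats::runif(n) < .by_group(grp, sc$p_rehab_by_group)
  rehab_hh <- stats::runif(n) < 0.2
  w <- which(rehab6 & !rehab_hh)
  mc_parts$rehab <- .mc_rows(id[w], index_date[w] + sample(0:L6, length(w), TRUE),
                             "outpatient", proc = registry$rehab[1])
  w <- which(rehab6 & rehab_hh)
  mc_parts$rehab_hh <- .mc_rows(id[w],
                                index_date[w] + sample(0:L6, length(w), TRUE),
                                "home_health")

  # --- treatment model ----------------------------------------------------
  treat <- .plant_treatment(sc, id, eligible, grp, follow_up, registry, config)
  op_dx_post <- eligible & stats::runif(n) <
    ifelse(treat$treated6, sc$p_op_dx_post_given_tx, sc$p_op_dx_post_given_no_tx)
  w <- which(op_dx_post)
  mc_parts$post_opdx <- .mc_rows(id[w], index_date[w] + sample(1:L6, length(w), TRUE),
                                 "outpatient", dx = registry$op_dx[1])

  # --- readmission --------------------------------------------------------
  readmit <- eligible & hosp & stats::runif(n) < sc$p_readmit
  w <- which(readmit)
  re_adm <- index_date[w] + los[w] + sample(2:30, length(w), replace = TRUE)
  mc_parts$readmit <- .mc_rows(id[w], re_adm, "inpatient", dx = "GEN_1",
                               admission = re_adm,
                               discharge = re_adm + sample(1:5, length(w), TRUE))
  readmit_lbl <- data.table::fifelse(hosp & eligible, readmit, NA)

  # --- subsequent fracture ------------------------------------------------
  subs <- .plant_subsequent(sc, id, eligible, site, grp, follow_up)
  w <- which(!is.na(subs$day))
  mc_parts$subsequent <- .mc_rows(id[w], index_date[w] + subs$day[w],
                                  "outpatient",
                                  dx = dx_of_site(subs$site[w]),
                                  proc = px_of_site(subs$site[w]))

  medical_claims <- data.table::rbindlist(mc_parts, use.names = TRUE)

  # --- pharmacy claims ----------------------------------------------------
  rx_parts <- list()
  pre_op_med <- bern(sc$p_pre[["op_med"]])
  w <- which(pre_op_med)
  pre_ana <- stats::runif(length(w)) < sc$pre_anabolic_share
  pre_class <- ifelse(pre_ana, "teriparatide", "oral_BP")
  pre_last <- index_date[w] - sample(40:200, length(w), replace = TRUE)
  n_pre_fills <- sample(1:3, length(w), replace = TRUE)
  pre_mem <- rep(seq_along(w), n_pre_fills)
  pre_off <- unlist(lapply(n_pre_fills, function(k) (seq_len(k) - 1L) * 30L))
  cls_code <- vapply(unique(unname(registry$drug_class)), function(cl)
    .code1(registry$drug_class, cl), "")
  rx_parts$pre_op <- .rx_rows(id[w][pre_mem], pre_last[pre_mem] - pre_off,
                              unname(cls_code[pre_class[pre_mem]]),
                              sc$days_supply)
  for (cl in c("corticosteroid", "narcotic", "antidepressant")) {
    p <- switch(cl, corticosteroid = sc$p_pre[["corticosteroid_6mo"]],
                narcotic = sc$p_pre[["narcotic"]],
                antidepressant = sc$p_pre[["antidepressant"]])
    on <- bern(p)
    w <- which(on)
    hi <- if (cl == "corticosteroid") 183L else 364L
    rx_parts[[paste0("pre_", cl)]] <- .rx_rows(
      id[w], index_date[w] - sample(1:hi, length(w), TRUE),
      .code1(registry$drug_class, cl), 30L)
  }
  rx_parts$treatment <- treat$fills[, .(member_id,
                                        fill_date = index_date[match(member_id, id)] + day,
                                        drug_code, days_supply)]
  pharmacy_claims <- data.table::rbindlist(rx_parts, use.names = TRUE)

  bundle <- claims_bundle(members, enroll, medical_claims, pharmacy_claims)

  reason_map <- c(no_fracture = "no_index", sex = "sex", age = "age_lt_min",
                  pre_enroll = "pre_index_enrollment",
                  post_enroll = "post_index_enrollment",
                  trauma = "trauma_same_day", prior_fracture = "prior_fracture",
                  bone_disease = "bone_disease_dx", cancer = "cancer_dx")
  truth <- data.table::data.table(
    member_id = id, category = category, eligible = eligible,
    exclusion_reason = ifelse(eligible, "", reason_map[category]),
    index_date = index_date, index_site = site, index_setting = index_setting,
    follow_up_days = follow_up,
    hospitalized = ifelse(eligible, hosp, NA),
    los = ifelse(eligible & hosp, los, NA_integer_),
    readmitted = ifelse(eligible, readmit_lbl, NA),
    surgery_6mo = ifelse(eligible, surgery6, NA),
    dxa_6mo = ifelse(eligible, dxa6, NA),
    snf_6mo = ifelse(eligible, snf6, NA),
    dme_6mo = ifelse(eligible, dme6, NA),
    rehab_6mo = ifelse(eligible, rehab6, NA),
    op_dx_post_6mo = ifelse(eligible, op_dx_post, NA),
    naive = ifelse(eligible, !pre_op_med, NA),
    first_class = treat$first_class,
    first_fill_day = treat$first_fill_day,
    run1_end = treat$run1_end,
    reinit_day = treat$reinit_day,
    sub_day = subs$day, sub_site = subs$site)
  for (nm in names(config$landmark_days)) {
    L <- config$landmark_days[[nm]]
    truth[, (paste0("treated_by_", nm)) := eligible & !is.na(first_fill_day) &
            first_fill_day <= L]
    truth[, (paste0("disc_by_", nm)) := eligible & !is.na(run1_end) &
            run1_end + config$discontinuation_gap_days + 1L <= L]
    truth[, (paste0("reinit_by_", nm)) := get(paste0("disc_by_", nm)) &
            !is.na(reinit_day) & reinit_day <= L]
    truth[, (paste0("subsequent_by_", nm)) := eligible & !is.na(sub_day) &
            sub_day <= L]
    truth[, (paste0("op_tx_by_", nm)) := get(paste0("treated_by_", nm))]
  }
  truth[, op_dx_or_tx_6mo := ifelse(eligible, op_dx_post_6mo | treated_by_6mo, NA)]

  list(bundle = bundle, truth = truth)
}

# Plant the treatment episode labels and realize fills.
# Returns per-member vectors plus the long fills table (day relative to index).
.plant_treatment <- function(sc, id, eligible, grp, follow_up, registry, config) {
  n <- length(id)
  lands <- config$landmark_days
  L6 <- lands[["6mo"]]; L12 <- lands[["12mo"]]; L24 <- lands[["24mo"]]
  g1 <- config$discontinuation_gap_days + 1L  # 61: gap observability offset

  u <- stats::runif(n)
  t6 <- eligible & u < .by_group(grp, sc$p_treat6_by_group)
  t12new <- eligible & !t6 & follow_up >= L12 &
    stats::runif(n) < .by_group(grp, sc$p_treat12_new_by_group)
  t24new <- eligible & !t6 & !t12new & follow_up >= L24 &
    stats::runif(n) < .by_group(grp, sc$p_treat24_new_by_group)
  window <- ifelse(t6, 1L, ifelse(t12new, 2L, ifelse(t24new, 3L, 0L)))

  # initiation day
  d <- rep(NA_integer_, n)
  w1 <- which(window == 1L)
  d[w1] <- as.integer(pmin(L6, pmax(1L, round(stats::rgamma(length(w1), shape = 2,
                                                            scale = 35)))))
  w2 <- which(window == 2L)
  d[w2] <- sample((L6 + 1L):L12, length(w2), replace = TRUE)
  w3 <- which(window == 3L)
  d[w3] <- sample((L12 + 1L):L24, length(w3), replace = TRUE)

  cls <- rep(NA_character_, n)
  treated <- window > 0L
  cls[treated] <- sample(names(sc$class_mix), sum(treated), replace = TRUE,
                         prob = sc$class_mix)

  # discontinuation landmark category (0 = none, else landmark days)
  disc_L <- rep(0L, n)
  pr <- sc$disc_probs
  r1 <- stats::runif(n)
  i1 <- window == 1L
  disc_L[i1 & r1 < pr$w1[["by6"]]] <- L6
  disc_L[i1 & r1 >= pr$w1[["by6"]] &
           r1 < pr$w1[["by6"]] + pr$w1[["by12"]]] <- L12
  disc_L[i1 & r1 >= pr$w1[["by6"]] + pr$w1[["by12"]] &
           r1 < sum(pr$w1)] <- L24
  i2 <- window == 2L
  disc_L[i2 & r1 < pr$w2[["by12"]]] <- L12
  disc_L[i2 & r1 >= pr$w2[["by12"]] & r1 < sum(pr$w2)] <- L24
  i3 <- window == 3L
  disc_L[i3 & r1 < pr$w3[["by24"]]] <- L24
  # a discontinuation is only plantable if the member is enrolled through it
  disc_L[disc_L > 0L & follow_up < disc_L] <- 0L

  # realize number of 30-day fills k: run end e = d + 30k - 1 must satisfy
  # prevL - 60 <= e <= discL - 61 (observable at discL, not before)
  s <- sc$days_supply
  prevL <- ifelse(disc_L == L6, 0L, ifelse(disc_L == L12, L6,
           ifelse(disc_L == L24, L12, NA_integer_)))
  lo_e <- pmax(d + s - 1L, prevL - config$discontinuation_gap_days)
  hi_e <- disc_L - g1
  lo_k <- pmax(1L, ceiling((lo_e - d + 1L) / s))
  hi_k <- floor((hi_e - d + 1L) / s)
  infeasible <- disc_L > 0L & (hi_k < lo_k)
  disc_L[infeasible] <- 0L

  k <- rep(NA_integer_, n)
  wd <- which(disc_L > 0L)
  if (length(wd)) {
    k[wd] <- as.integer(lo_k[wd] +
                          floor(stats::runif(length(wd)) * (hi_k[wd] - lo_k[wd] + 1L)))
  }
  # persistent members: fills continue through min(follow_up, 731)
  wp <- which(treated & disc_L == 0L)
  horizon <- pmin(follow_up, L24 + 1L)
  k[wp] <- as.integer(pmax(1L, floor((horizon[wp] - d[wp]) / s) + 1L))

  run1_end <- as.integer(ifelse(treated, d + s * k - 1L, NA_integer_))

  # re-initiation after a planted discontinuation
  reinit_day <- rep(NA_integer_, n)
  wr <- which(disc_L > 0L & stats::runif(n) < sc$p_reinit)
  if (length(wr)) {
    r <- as.integer(run1_end[wr] + g1 + 1L + sample(0:60, length(wr), replace = TRUE))
    ok <- r <= pmin(follow_up[wr], L24)
    reinit_day[wr[ok]] <- r[ok]
  }

  # fills table
  cls_code <- vapply(unique(unname(registry$drug_class)), function(cl)
    .code1(registry$drug_class, cl), "")
  wt <- which(treated)
  reps <- k[wt]
  mem <- rep(id[wt], reps)
  day <- rep(d[wt], reps) + (sequence(reps) - 1L) * s
  code <- rep(unname(cls_code[cls[wt]]), reps)
  fills <- data.table::data.table(member_id = mem, day = day, drug_code = code,
                                  days_supply = s)
  wr2 <- which(!is.na(reinit_day))
  if (length(wr2)) {
    fills <- data.table::rbindlist(list(fills, data.table::data.table(
      member_id = id[wr2], day = reinit_day[wr2],
      drug_code = unname(cls_code[cls[wr2]]),
      days_supply = s)))
  }

  list(first_class = cls, first_fill_day = d, run1_end = run1_end,
       reinit_day = reinit_day, treated6 = t6, fills = fills)
}

# Plant at most one subsequent fracture per eligible member.
.plant_subsequent <- function(sc, id, eligible, site, grp, follow_up) {
  n <- length(id)
  L6 <- 183L; L12 <- 365L; L24 <- 730L
  s6 <- eligible & stats::runif(n) < .by_group(grp, sc$p_sub6_by_group)
  s12 <- eligible & !s6 & follow_up >= L12 &
    stats::runif(n) < .by_group(grp, sc$p_sub12_new_by_group)
  s24 <- eligible & !s6 & !s12 & follow_up >= L24 &
    stats::runif(n) < .by_group(grp, sc$p_sub24_new_by_group)
  day <- rep(NA_integer_, n)
  day[s6] <- sample(1:L6, sum(s6), replace = TRUE)
  day[s12] <- sample((L6 + 1L):L12, sum(s12), replace = TRUE)
  day[s24] <- sample((L12 + 1L):L24, sum(s24), replace = TRUE)

  has_sub <- !is.na(day)
  same <- has_sub & stats::runif(n) < sc$p_sub_same_site
  # a same-site repeat must sit strictly beyond the 90-day gap (day >= 91)
  same[same & day < 91L] <- FALSE
  sub_site <- rep(NA_character_, n)
  sub_site[same] <- site[same]
  w <- which(has_sub & !same)
  if (length(w)) {
    g <- sample(names(sc$sub_group_mix), length(w), replace = TRUE,
                prob = sc$sub_group_mix)
    pick <- character(length(w))
    pick[g == "hip"] <- "hip"
    pick[g == "vertebral"] <- "vertebral"
    nh <- which(g == "NHNV")
    if (length(nh)) {
      pick[nh] <- vapply(seq_along(nh), function(j) {
        sample(setdiff(NHNV_SITES, site[w[nh[j]]]), 1L)
      }, "")
    }
    # a "new site" must differ from the index site; hip/vertebral draws that
    # collide with the index site fall back to a different NHNV site
    coll <- which(pick == site[w])
    if (length(coll)) {
      pick[coll] <- vapply(coll, function(j)
        sample(setdiff(NHNV_SITES, site[w[j]]), 1L), "")
    }
    sub_site[w] <- pick
  }
  list(day = day, site = sub_site)
}

NHNV_SITES <- c("femur", "pelvis", "humerus", "radius_ulna", "tibia_fibula",
                "ankle", "clavicle")
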