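# Six-month post-index medical management measures: index hospitalization
# and length of stay, 30-day all-cause readmission, post-index OP
# diagnosis/treatment, DXA and time-to-DXA, orthopedic surgery,
# rehabilitation, SNF and time-to-SNF, DME subtypes.
#
# Post-index windows are CLOSED [index, index+183]: "on or within 6 months"
# includes the index day. LOS counts nights (discharge - admission) with a
# minimum of 1 for same-day stays. The readmission window is
# [discharge+1, discharge+30]: a same-day rebill or transfer is not a
# readmission, and a stay beginning the day after discharge merges into the
# index stay under the contiguity rule below.

# Build merged inpatient stays per member: contiguous or overlapping claims
# (admission <= prior discharge + 1) collapse into one stay carrying the
# union of fracture sites seen on its claims.
.inpatient_stays <- function(medical_claims, registry) {
  mc <- data.table::as.data.table(medical_claims)
  ip <- mc[setting == "inpatient"]
  if (!nrow(ip))
    return(data.table::data.table(member_id = character(0),
                                  admission_date = as.Date(character(0)),
                                  discharge_date = as.Date(character(0)),
                                  sites = character(0)))
  ip[, admission_date := data.table::fifelse(is.na(admission_date),
                                             service_date, admission_date)]
  ip[, discharge_date := data.table::fifelse(is.na(discharge_date),
                                             admission_date, discharge_date)]
  ip[, .claim := .I]
  dx <- .explode_codes(ip$dx_codes)
  dx[, site := unname(registry$fracture_dx[code])]
  claim_sites <- dx[!is.na(site), .(sites = paste(unique(site), collapse = "|")),
                    by = .claim]
  ip <- claim_sites[ip, on = ".claim"]
  ip[is.na(sites), sites := ""]

  data.table::setorder(ip, member_id, admission_date, discharge_date)
  ip[, prev_max := data.table::shift(cummax(as.integer(discharge_date))),
     by = member_id]
  ip[, new_stay := is.na(prev_max) | as.integer(admission_date) > prev_max + 1L]
  ip[, stay_id := cumsum(new_stay)]
  stays <- ip[, .(member_id = member_id[1],
                  admission_date = min(admission_date),
                  discharge_date = max(discharge_date),
                  sites = paste(unique(unlist(strsplit(sites[sites != ""], "|",
                                                       fixed = TRUE))),
                                collapse = "|")),
              by = stay_id]
  stays[, stay_id := NULL]
  stays[]
}

#' Find the index-fracture hospitalization
#'
#' The merged inpatient stay whose admission falls within
#' `[index, index + index_hosp_window_days]` and whose claims carry a
#' fracture diagnosis at the index site. Admission on the index date is
#' preferred; otherwise the earliest qualifying stay wins.
#'
#' @param cohort Cohort table (uses `member_id`, `index_date`, `index_site`).
#' @param bundle A `claims_bundle`.
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return data.table, one row per hospitalized member: `member_id`,
#'   `admission_date`, `discharge_date`, `los_days` (>= 1).
#' @export
find_index_hospitalization <- function(cohort, bundle, registry,
                                       config = analysis_config()) {
  co <- data.table::as.data.table(cohort)
  stays <- .inpatient_stays(bundle$medical_claims, registry)
  j <- merge(stays, co[, .(member_id, index_date, index_site)], by = "member_id")
  j <- j[admission_date >= index_date &
           admission_date <= index_date + config$index_hosp_window_days]
  if (nrow(j)) {
    hit <- mapply(function(s, target) target %in% strsplit(s, "|", fixed = TRUE)[[1]],
                  j$sites, j$index_site)
    j <- j[as.logical(hit)]
  }
  if (!nrow(j))
    return(data.table::data.table(member_id = character(0),
                                  admission_date = as.Date(character(0)),
                                  discharge_date = as.Date(character(0)),
                                  los_days = integer(0)))
  j[, on_index := admission_date == index_date]
  data.table::setorder(j, member_id, -on_index, admission_date)
  j <- j[, .SD[1], by = member_id]
  j[, los_days := pmax(1L, as.integer(discharge_date - admission_date))]
  j[, .(member_id, admission_date, discharge_date, los_days)]
}

#' Detect 30-day all-cause readmission
#'
#' `TRUE` iff any other merged inpatient stay (any cause) begins within
#' `[discharge + 1, discharge + 30]` of the index stay's discharge.
#'
#' @param stay One-or-many-row table of index stays
#'   (`member_id`, `discharge_date`).
#' @param bundle A `claims_bundle`.
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return Logical vector along the rows of `stay`.
#' @export
detect_readmission <- function(stay, bundle, registry, config = analysis_config()) {
  st <- data.table::as.data.table(stay)
  if (!nrow(st)) return(logical(0))
  stays <- .inpatient_stays(bundle$medical_claims, registry)
  j <- merge(st[, .(member_id, discharge_date)],
             stays[, .(member_id, admission_date)],
             by = "member_id", allow.cartesian = TRUE)
  w <- config$readmission_window_days
  re_m <- unique(j[admission_date >= discharge_date + 1L &
                     admission_date <= discharge_date + w, member_id])
  st$member_id %in% re_m
}

#' Summarize six-month medical management per member
#'
#' Computes every management measure over the closed window
#' `[index, index + 183]`: index hospitalization (with LOS), 30-day
#' readmission (`NA` for members without an index hospitalization),
#' post-index OP diagnosis and OP-diagnosis-or-treatment, DXA with days to
#' first scan, orthopedic surgery, rehabilitation (rehab codes or a
#' home-health claim), SNF admission with days from index, and DME with
#' walker/wheelchair/other subtypes.
#'
#' @param cohort Cohort table from [build_cohort()].
#' @param bundle A `claims_bundle`.
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return data.table, one row per cohort member.
#' @export
summarize_management <- function(cohort, bundle, registry,
                                 config = analysis_config()) {
  co <- data.table::as.data.table(cohort)
  L <- config$post_index_min_days
  out <- co[, .(member_id, index_date, index_site, site_group)]
  data.table::setkey(out, member_id)

  hosp <- find_index_hospitalization(co, bundle, registry, config)
  out[, hospitalized_for_index := member_id %in% hosp$member_id]
  out[, los := hosp[out, on = "member_id", x.los_days]]
  readm <- hosp[detect_readmission(hosp, bundle, registry, config) == TRUE]
  out[, readmit_30d := data.table::fifelse(
    hospitalized_for_index, member_id %in% readm$member_id, NA)]

  mc <- merge(data.table::as.data.table(bundle$medical_claims),
              co[, .(member_id, index_date)], by = "member_id")
  mc_post <- mc[service_date >= index_date & service_date <= index_date + L]

  dx <- .explode_codes(mc_post$dx_codes)
  dx <- merge(dx, mc_post[, .(.claim = seq_len(.N), member_id, service_date,
                              setting, index_date)], by = ".claim")
  px <- .explode_codes(mc_post$proc_codes)
  px <- merge(px, mc_post[, .(.claim = seq_len(.N), member_id, service_date,
                              setting, index_date)], by = ".claim")

  out[, op_dx_6mo := member_id %in% dx[code %in% registry$op_dx, member_id]]

  dxa_first <- px[code %in% registry$dxa_proc,
                  .(d = min_day(service_date - index_date)), by = member_id]
  out[, dxa_6mo := member_id %in% dxa_first$member_id]
  out[, days_to_first_dxa := dxa_first[out, on = "member_id", x.d]]

  out[, ortho_surgery_6mo := member_id %in%
        px[code %in% registry$ortho_surgery_proc, member_id]]

  rehab_m <- union(px[code %in% registry$rehab, member_id],
                   mc_post[setting == "home_health", member_id])
  out[, rehab_6mo := member_id %in% rehab_m]

  snf_first <- mc_post[setting == "snf",
                       .(d = min_day(service_date - index_date)),
                       by = member_id]
  out[, snf_6mo := member_id %in% snf_first$member_id]
  out[, days_index_to_snf := snf_first[out, on = "member_id", x.d]]

  dme_px <- px[code %in% names(registry$dme)]
  dme_px[, subtype := unname(registry$dme[code])]
  out[, dme_6mo := member_id %in% dme_px$member_id]
  out[, dme_walker := member_id %in% dme_px[subtype == "walker", member_id]]
  out[, dme_wheelchair := member_id %in% dme_px[subtype == "wheelchair", member_id]]
  out[, dme_other := member_id %in% dme_px[subtype == "other", member_id]]

  rx <- merge(data.table::as.data.table(bundle$pharmacy_claims),
              co[, .(member_id, index_date)], by = "member_id")
  rx_post <- rx[fill_date >= index_date & fill_date <= index_date + L]
  rx_post[, class := unname(registry$drug_class[drug_code])]
  op_fill_m <- rx_post[class %in% op_med_classes(), member_id]
  out[, op_tx_6mo := member_id %in% op_fill_m]
  out[, op_dx_or_tx_6mo := op_dx_6mo | op_tx_6mo]
  out[]
}

TABLE3_STRATA <- c("overall", "hip", "vertebral", "NHNV",
                   "pre_op_dx", "pre_op_med", "pre_antiresorptive", "pre_anabolic")

.stratum_members <- function(stratum, cohort, baseline) {
  switch(stratum,
    overall = cohort$member_id,
    hip = cohort[site_group == "hip", member_id],
    vertebral = cohort[site_group == "vertebral", member_id],
    NHNV = cohort[site_group == "NHNV", member_id],
    pre_op_dx = baseline[op_dx == TRUE, member_id],
    pre_op_med = baseline[op_med_use == TRUE, member_id],
    pre_antiresorptive = baseline[antiresorptive_use == TRUE, member_id],
    pre_anabolic = baseline[anabolic_use == TRUE, member_id],
    stop_input("unknown stratum: ", stratum))
}

#' Aggregate six-month management measures by stratum
#'
#' Produces the stratified management report: percentages over the stratum
#' size (except readmission, whose denominator is the stratum's
#' hospitalized members) and mean (SD) for LOS, days to first DXA, and days
#' from index to SNF. Every percentage cell carries its numerator and
#' denominator; empty strata yield `NA` values, never `0`.
#'
#' @param mgmt Output of [summarize_management()].
#' @param cohort Cohort table.
#' @param baseline Output of [build_baseline()] (for the pre-index strata).
#' @param strata Character vector of strata (default: overall, the three
#'   fracture-type groups, and the four pre-index subgroups).
#' @return Long data.table: `stratum`, `measure`, `kind` (`pct`/`mean`),
#'   `numerator`, `denominator`, `value`, `sd`.
#' @export
aggregate_table3 <- function(mgmt, cohort, baseline, strata = TABLE3_STRATA) {
  mg <- data.table::as.data.table(mgmt)
  co <- data.table::as.data.table(cohort)
  bl <- data.table::as.data.table(baseline)
  pct_measures <- c("hospitalized_for_index", "op_dx_6mo", "op_dx_or_tx_6mo",
                    "dxa_6mo", "ortho_surgery_6mo", "rehab_6mo", "snf_6mo",
                    "dme_6mo", "dme_walker", "dme_wheelchair", "dme_other")
  rows <- list()
  for (s in strata) {
    ids <- .stratum_members(s, co, bl)
    sub <- mg[member_id %in% ids]
    n <- nrow(sub)
    for (m in pct_measures) {
      num <- sum(sub[[m]], na.rm = TRUE)
      rows[[length(rows) + 1]] <- data.table::data.table(
        stratum = s, measure = m, kind = "pct", numerator = num,
        denominator = n, value = pct_of(num, n), sd = NA_real_)
    }
    hosp <- sub[hospitalized_for_index == TRUE]
    rows[[length(rows) + 1]] <- data.table::data.table(
      stratum = s, measure = "readmit_30d", kind = "pct",
      numerator = sum(hosp$readmit_30d, na.rm = TRUE),
      denominator = nrow(hosp),
      value = pct_of(sum(hosp$readmit_30d, na.rm = TRUE), nrow(hosp)),
      sd = NA_real_)
    for (m in c("los", "days_to_first_dxa", "days_index_to_snf")) {
      v <- sub[[m]][!is.na(sub[[m]])]
      rows[[length(rows) + 1]] <- data.table::data.table(
        stratum = s, measure = m, kind = "mean", numerator = length(v),
        denominator = length(v),
        value = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_)
    }
  }
  data.table::rbindlist(rows)
}
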