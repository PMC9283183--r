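# One-year pre-index baseline profiling.
#
# All flags are computed over the closed window [index-365, index-1]:
# index-day claims belong to post-index context, never to baseline.
# Corticosteroid use looks back 183 days, consistent with the landmark
# arithmetic.

#' Charlson comorbidity index from diagnosis codes
#'
#' Sums the weights of the DISTINCT Charlson categories present among the
#' supplied codes; a category counts once no matter how many claims carry
#' it.
#'
#' @param dx_codes Character vector of diagnosis codes (one member's
#'   pre-index codes, duplicates allowed).
#' @param cci_map data.table(`code`, `category`, `weight`) as found in
#'   `registry$cci_map`.
#' @return Non-negative number.
#' @export
#' @examples
#' reg <- load_registry()
#' compute_cci(c("CCI_MI_1", "CCI_MI_1", "CCI_RENAL_1"), reg$cci_map)  # 1 + 2
compute_cci <- function(dx_codes, cci_map) {
  hit <- cci_map[cci_map$code %in% dx_codes]
  sum(hit$weight[!duplicated(hit$category)])
}

BASELINE_BANDS <- c("<=30", ">30-60", ">60-180", ">180-360", "out_of_range")

#' Band a days-since interval
#'
#' Half-open banding used for "days between last DXA/surgery and index":
#' `<=30`, `>30-60`, `>60-180`, `>180-360`. Values above 360 days are
#' reported as `out_of_range` rather than silently clipped, since the
#' look-back window (365 days) exceeds the last band.
#'
#' @param days Non-negative integer vector.
#' @return Character vector of band labels.
#' @export
interval_band <- function(days) {
  days <- as.integer(days)
  if (any(days < 0, na.rm = TRUE)) stop_input("interval_band: negative days")
  out <- ifelse(days <= 30, "<=30",
         ifelse(days <= 60, ">30-60",
         ifelse(days <= 180, ">60-180",
         ifelse(days <= 360, ">180-360", "out_of_range"))))
  out[is.na(days)] <- NA_character_
  out
}

AGE_BANDS <- c("50-59", "60-64", "65-70", "71-79", ">=80")

age_band <- function(age) {
  ifelse(age < 50, "<50",
  ifelse(age <= 59, "50-59",
  ifelse(age <= 64, "60-64",
  ifelse(age <= 70, "65-70",
  ifelse(age <= 79, "71-79", ">=80")))))
}

# latest pre-index day (distance to index) at which any of `codes` appears
# among proc codes; NA when absent.
.latest_proc_distance <- function(mc_window, codes) {
  px <- .explode_codes(mc_window$proc_codes)
  px <- px[code %in% codes]
  if (!nrow(px))
    return(data.table::data.table(member_id = character(0), dist = integer(0)))
  j <- merge(px, mc_window[, .(.claim = seq_len(.N), member_id, service_date,
                               index_date)], by = ".claim")
  j[, .(dist = min_day(index_date - service_date)), by = member_id]
}

#' Build pre-index baseline profiles
#'
#' Computes, for every cohort member, the demographic bands and the
#' clinical flags of the baseline characterization: osteoporosis diagnosis,
#' DXA (with days-before-index and band), prior orthopedic surgery (same),
#' osteoporosis medication use split into anabolic/antiresorptive and
#' per-class flags, smoking, falls history, DME use, comorbidity-group
#' flags, other drug-class flags, 6-month corticosteroid use, and the
#' Charlson comorbidity index.
#'
#' @param cohort Cohort table from [build_cohort()].
#' @param bundle A `claims_bundle`.
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return data.table, one row per cohort member. `op_dx_or_tx` is the
#'   union of `op_dx` and `op_med_use`.
#' @export
build_baseline <- function(cohort, bundle, registry, config = analysis_config()) {
  co <- data.table::as.data.table(cohort)
  out <- co[, .(member_id, index_date, index_site, site_group, age_at_index)]
  out[, age_band := age_band(age_at_index)]
  out <- merge(out, bundle$members[, .(member_id, region, payer, plan_type)],
               by = "member_id", sort = FALSE)
  data.table::setkey(out, member_id)

  mc <- merge(data.table::as.data.table(bundle$medical_claims),
              co[, .(member_id, index_date)], by = "member_id")
  mc_pre <- mc[service_date >= index_date - config$pre_index_days &
                 service_date <= index_date - 1L]

  dx <- .explode_codes(mc_pre$dx_codes)
  dx <- merge(dx, mc_pre[, .(.claim = seq_len(.N), member_id, service_date)],
              by = ".claim")
  px <- .explode_codes(mc_pre$proc_codes)
  px <- merge(px, mc_pre[, .(.claim = seq_len(.N), member_id, service_date)],
              by = ".claim")

  flag_members <- function(tbl, codes, min_claims = config$min_claims) {
    if (!nrow(tbl)) return(character(0))
    hits <- tbl[code %in% codes, .N, by = member_id]
    hits[N >= min_claims, member_id]
  }

  out[, op_dx := member_id %in% flag_members(dx, registry$op_dx)]
  out[, smoking := member_id %in% flag_members(dx, names(registry$comorbidity_dx)[registry$comorbidity_dx == "smoking"])]
  out[, falls_history := member_id %in% flag_members(dx, names(registry$comorbidity_dx)[registry$comorbidity_dx == "falls"])]
  for (grp in setdiff(sort(unique(unname(registry$comorbidity_dx))),
                      c("smoking", "falls"))) {
    out[, (paste0("com_", grp)) := member_id %in%
          flag_members(dx, names(registry$comorbidity_dx)[registry$comorbidity_dx == grp])]
  }
  out[, dme_use := member_id %in% flag_members(px, names(registry$dme))]

  dxa_tbl <- .latest_proc_distance(
    mc_pre[, .(member_id, service_date, proc_codes, index_date)], registry$dxa_proc)
  out[, dxa := member_id %in% dxa_tbl$member_id]
  out[, dxa_days_before_index := dxa_tbl[out, on = "member_id", x.dist]]
  out[, dxa_band := interval_band(dxa_days_before_index)]

  surg_tbl <- .latest_proc_distance(
    mc_pre[, .(member_id, service_date, proc_codes, index_date)],
    registry$ortho_surgery_proc)
  out[, prior_ortho_surgery := member_id %in% surg_tbl$member_id]
  out[, surgery_days_before_index := surg_tbl[out, on = "member_id", x.dist]]
  out[, surgery_band := interval_band(surgery_days_before_index)]

  cci_dx <- dx[code %in% registry$cci_map$code]
  cci_tbl <- if (nrow(cci_dx)) {
    j <- merge(cci_dx, registry$cci_map, by = "code", allow.cartesian = TRUE)
    j[, .(cci = sum(weight[!duplicated(category)])), by = member_id]
  } else data.table::data.table(member_id = character(0), cci = numeric(0))
  out[, cci := cci_tbl[out, on = "member_id", x.cci]]
  out[is.na(cci), cci := 0]

  rx <- merge(data.table::as.data.table(bundle$pharmacy_claims),
              co[, .(member_id, index_date)], by = "member_id")
  rx_pre <- rx[fill_date >= index_date - config$pre_index_days &
                 fill_date <= index_date - 1L]
  rx_pre[, class := unname(registry$drug_class[drug_code])]
  rx_pre[is.na(class), class := "non_op"]

  op_pre <- rx_pre[class %in% op_med_classes()]
  out[, op_med_use := member_id %in% op_pre$member_id]
  out[, anabolic_use := member_id %in% op_pre[class %in% anabolic_classes(), member_id]]
  out[, antiresorptive_use := member_id %in% op_pre[class %in% antiresorptive_classes(), member_id]]
  for (cl in sort(unique(unname(registry$drug_class)))) {
    out[, (paste0("rx_", cl)) := member_id %in% rx_pre[class == cl, member_id]]
  }
  out[, corticosteroid_6mo := member_id %in%
        rx_pre[class == "corticosteroid" &
                 fill_date >= index_date - 183L, member_id]]

  out[, op_dx_or_tx := op_dx | op_med_use]
  out[]
}
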