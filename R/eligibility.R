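# Cohort eligibility and attrition.
#
# Criteria are evaluated in a fixed order; the attrition table records the
# members remaining after each step:
#   1. female sex
#   2. age >= 50 (year arithmetic) at index
#   3. continuous medical+pharmacy enrollment over [index-365, index-1]
#   4. continuous medical+pharmacy enrollment over [index+1, index+183]
#   5. no trauma diagnosis on the index date
#   6. no qualified fracture event before the index date
#   7. no Paget's/other/metabolic bone-disease diagnosis pre-index
#      (all study-period data)
#   8. no cancer diagnosis in the 365-day pre-index window, excluding
#      non-melanoma skin cancer

.dx_claim_days <- function(medical_claims, codes) {
  mc <- medical_claims
  dx <- .explode_codes(mc$dx_codes)
  dx <- dx[code %in% codes]
  if (!nrow(dx))
    return(data.table::data.table(member_id = character(0),
                                  service_date = as.Date(character(0))))
  unique(merge(dx, mc[, .(.claim = seq_len(.N), member_id, service_date)],
               by = ".claim")[, .(member_id, service_date)])
}

#' Evaluate eligibility criteria for indexed members
#'
#' Returns per-criterion booleans, the first failed criterion, and the
#' overall eligibility flag for each member of `index_table`.
#'
#' @param index_table Output of [assign_index_fracture()] (one or many
#'   members).
#' @param bundle A `claims_bundle`.
#' @param events All qualified events from [identify_fracture_events()]
#'   (used for the prior-fracture criterion); recomputed from the bundle
#'   when `NULL`.
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return data.table with `member_id`, one logical column per criterion
#'   (`sex_f`, `age_ok`, `pre_enroll`, `post_enroll`, `no_trauma_same_day`,
#'   `no_prior_fracture`, `no_bone_disease`, `no_cancer`), `eligible`, and
#'   `exclusion_reason` (`""` when eligible).
#' @export
apply_eligibility <- function(index_table, bundle, registry,
                              config = analysis_config(), events = NULL) {
  idx <- data.table::as.data.table(index_table)
  if (!nrow(idx)) {
    return(data.table::data.table(
      member_id = character(0), sex_f = logical(0), age_ok = logical(0),
      pre_enroll = logical(0), post_enroll = logical(0),
      no_trauma_same_day = logical(0), no_prior_fracture = logical(0),
      no_bone_disease = logical(0), no_cancer = logical(0),
      eligible = logical(0), exclusion_reason = character(0)))
  }
  if (is.null(events))
    events <- identify_fracture_events(bundle$medical_claims, registry, config)

  res <- merge(idx[, .(member_id, index_date)],
               bundle$members[, .(member_id, sex, birth_year)],
               by = "member_id", sort = FALSE)

  res[, sex_f := sex == config$require_sex]
  res[, age_ok := (date_year(index_date) - birth_year) >= config$min_age]

  pre_w <- data.table::data.table(member_id = res$member_id,
                                  ws = res$index_date - config$pre_index_days,
                                  we = res$index_date - 1L)
  res[, pre_enroll := enrollment_covered(bundle$enrollment, pre_w,
                                         allowed_gap_days = config$allowed_gap_days)]
  post_w <- data.table::data.table(member_id = res$member_id,
                                   ws = res$index_date + 1L,
                                   we = res$index_date + config$post_index_min_days)
  res[, post_enroll := enrollment_covered(bundle$enrollment, post_w,
                                          allowed_gap_days = config$allowed_gap_days)]

  mc <- data.table::as.data.table(bundle$medical_claims)
  trauma <- .dx_claim_days(mc, registry$trauma_dx)
  trauma_m <- unique(merge(trauma, res[, .(member_id, index_date)],
                           by = "member_id")[service_date == index_date, member_id])
  res[, no_trauma_same_day := !member_id %in% trauma_m]

  ev <- data.table::as.data.table(events)
  prior_m <- if (nrow(ev)) {
    unique(merge(ev[, .(member_id, event_date)], res[, .(member_id, index_date)],
                 by = "member_id")[event_date < index_date, member_id])
  } else character(0)
  res[, no_prior_fracture := !member_id %in% prior_m]

  excl_codes <- names(registry$exclusion_dx)
  bone_codes <- excl_codes[registry$exclusion_dx[excl_codes] != "cancer"]
  cancer_codes <- setdiff(excl_codes[registry$exclusion_dx[excl_codes] == "cancer"],
                          registry$nonmelanoma_skin_cancer_dx)

  bone <- .dx_claim_days(mc, bone_codes)
  bone_m <- unique(merge(bone, res[, .(member_id, index_date)],
                         by = "member_id")[service_date < index_date &
                                             service_date >= config$study_start,
                                           member_id])
  res[, no_bone_disease := !member_id %in% bone_m]

  canc <- .dx_claim_days(mc, cancer_codes)
  canc_m <- unique(merge(canc, res[, .(member_id, index_date)],
                         by = "member_id")[service_date < index_date &
                                             service_date >= index_date - config$cancer_lookback_days,
                                           member_id])
  res[, no_cancer := !member_id %in% canc_m]

  crit <- c("sex_f", "age_ok", "pre_enroll", "post_enroll",
            "no_trauma_same_day", "no_prior_fracture", "no_bone_disease",
            "no_cancer")
  reasons <- c("sex", "age_lt_min", "pre_index_enrollment",
               "post_index_enrollment", "trauma_same_day", "prior_fracture",
               "bone_disease_dx", "cancer_dx")
  cm <- as.matrix(res[, crit, with = FALSE])
  first_fail <- apply(!cm, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  res[, eligible := !apply(!cm, 1, any)]
  res[, exclusion_reason := ifelse(is.na(first_fail), "", reasons[first_fail])]
  res[, c("sex", "birth_year", "index_date") := NULL]
  res[]
}

ATTRITION_STEPS <- c(
  "members in bundle",
  "qualified nontraumatic fracture in index period",
  "female",
  "age >= 50 at index",
  "continuous pre-index enrollment (365 d, medical+pharmacy)",
  "continuous post-index enrollment (183 d, medical+pharmacy)",
  "no trauma diagnosis on index date",
  "no prior nontraumatic fracture",
  "no Paget's/other/metabolic bone disease pre-index",
  "no pre-index cancer (non-melanoma skin cancer exempt)")

#' Build the study cohort and attrition table
#'
#' Runs fracture identification, index assignment and eligibility over the
#' whole bundle, producing the analysis cohort (with index metadata,
#' hip/vertebral/NHNV grouping, age at index, and continuous post-index
#' follow-up length) and the ordered attrition table.
#'
#' @param bundle A `claims_bundle`.
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return A list with `cohort` (one row per eligible member), `attrition`
#'   (data.table `step`, `n_remaining`, non-increasing), `events` (all
#'   qualified events), and `eligibility` (per-criterion detail for all
#'   indexed members).
#' @export
build_cohort <- function(bundle, registry, config = analysis_config()) {
  events <- identify_fracture_events(bundle$medical_claims, registry, config)
  idx <- assign_index_fracture(events, registry, config)
  elig <- apply_eligibility(idx, bundle, registry, config, events = events)

  counts <- integer(length(ATTRITION_STEPS))
  counts[1] <- nrow(bundle$members)
  counts[2] <- nrow(idx)
  crit <- c("sex_f", "age_ok", "pre_enroll", "post_enroll",
            "no_trauma_same_day", "no_prior_fracture", "no_bone_disease",
            "no_cancer")
  keep <- rep(TRUE, nrow(elig))
  for (k in seq_along(crit)) {
    keep <- keep & elig[[crit[k]]]
    counts[2 + k] <- sum(keep)
  }
  attrition <- data.table::data.table(step = ATTRITION_STEPS,
                                      n_remaining = counts)

  cohort <- merge(idx, elig[eligible == TRUE, .(member_id)], by = "member_id")
  data.table::setnames(cohort, c("site", "setting"),
                       c("index_site", "index_setting"))
  cohort <- merge(cohort, bundle$members, by = "member_id")
  if (nrow(cohort)) {
    cohort[, site_group := site_group(index_site)]
    cohort[, age_at_index := date_year(index_date) - birth_year]
    cohort[, follow_up_days := follow_up_days(
      bundle$enrollment,
      data.table::data.table(member_id = member_id, anchor = index_date),
      allowed_gap_days = config$allowed_gap_days)]
  } else {
    cohort[, `:=`(site_group = character(0), age_at_index = integer(0),
                  follow_up_days = integer(0))]
  }
  data.table::setorder(cohort, member_id)
  list(cohort = cohort[], attrition = attrition, events = events,
       eligibility = elig)
}

#' Landmark denominator membership
#'
#' A member enters the denominator of a landmark only with continuous
#' medical+pharmacy enrollment through that many days post-index
#' (6-month membership is guaranteed by eligibility).
#'
#' @param cohort Cohort table from [build_cohort()] (uses `follow_up_days`).
#' @param config An [analysis_config()].
#' @return The cohort with logical columns `in_denom_6mo`, `in_denom_12mo`,
#'   `in_denom_24mo` (per `config$landmark_days` names).
#' @export
landmark_denominators <- function(cohort, config = analysis_config()) {
  out <- data.table::as.data.table(cohort)
  for (nm in names(config$landmark_days)) {
    out[, (paste0("in_denom_", nm)) := follow_up_days >= config$landmark_days[[nm]]]
  }
  out[]
}
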