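# Nontraumatic fracture ascertainment and index assignment.
#
# A fracture event is one (member, site, date) satisfying any of:
#   (a) an inpatient claim carrying a fracture diagnosis for the site
#       (event date = admission date when present, else service date);
#   (b) an outpatient claim with a site diagnosis AND a fracture-treatment
#       procedure for the SAME site on an outpatient claim within the
#       pairing window (default +/- 7 days); the event is dated at the
#       diagnosis claim;
#   (c) vertebral only: an outpatient vertebral diagnosis with an
#       evaluation-and-management (E&M) procedure within the pairing window.

# split pipe-delimited code cells into a long table (.claim, code)
.explode_codes <- function(codes) {
  lst <- strsplit(codes, "|", fixed = TRUE)
  n <- lengths(lst)
  data.table::data.table(.claim = rep(seq_along(codes), n),
                         code = as.character(unlist(lst, use.names = FALSE)))
}

#' Identify qualified nontraumatic fracture events
#'
#' Applies the three-part identification rule (see source header) over a
#' medical-claims table of one or many members and returns at most one
#' event per member, site, and date. When an inpatient and an outpatient
#' rule both fire for the same member/site/date, the inpatient rule wins.
#'
#' @param medical_claims Medical-claims table (one or many members).
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()]; uses `pairing_window_days`.
#' @return data.table: `member_id`, `event_date`, `site`, `setting`
#'   (inpatient/outpatient), `rule` (`inpatient_dx`,
#'   `outpatient_dx_plus_proc`, `vertebral_dx_plus_em`), sorted by member,
#'   date, and site rank. Empty claims give an empty table.
#' @export
identify_fracture_events <- function(medical_claims, registry, config = analysis_config()) {
  empty <- data.table::data.table(
    member_id = character(0), event_date = as.Date(character(0)),
    site = character(0), setting = character(0), rule = character(0))
  mc <- data.table::as.data.table(medical_claims)
  if (!nrow(mc)) return(empty)
  mc <- mc[service_date >= config$study_start & service_date <= config$study_end]
  if (!nrow(mc)) return(empty)
  mc[, .claim := .I]
  mc[, event_date := data.table::fifelse(
    setting == "inpatient" & !is.na(admission_date), admission_date, service_date)]

  dx <- .explode_codes(mc$dx_codes)
  dx[, site := unname(registry$fracture_dx[code])]
  dx <- dx[!is.na(site)]
  dx <- merge(dx, mc[, .(.claim, member_id, setting, event_date)], by = ".claim")

  # (a) inpatient diagnosis
  ev_in <- unique(dx[setting == "inpatient",
                     .(member_id, event_date, site)])[, `:=`(
                       setting = "inpatient", rule = "inpatient_dx")]

  dx_out <- dx[setting == "outpatient"]
  out_claims <- mc[setting == "outpatient"]
  pw <- config$pairing_window_days

  # (b) outpatient diagnosis + same-site fracture-treatment procedure
  px <- .explode_codes(out_claims$proc_codes)
  px[, site := unname(registry$fracture_proc[code])]
  px_site <- px[!is.na(site)]
  px_site <- merge(px_site, out_claims[, .(.claim = seq_len(.N), member_id,
                                           proc_date = service_date)],
                   by = ".claim")
  ev_out <- if (nrow(dx_out) && nrow(px_site)) {
    j <- merge(dx_out[, .(member_id, site, event_date)],
               px_site[, .(member_id, site, proc_date)],
               by = c("member_id", "site"), allow.cartesian = TRUE)
    unique(j[abs(as.integer(proc_date) - as.integer(event_date)) <= pw,
             .(member_id, event_date, site)])[, `:=`(
               setting = "outpatient", rule = "outpatient_dx_plus_proc")]
  } else empty[0]

  # (c) outpatient vertebral diagnosis + E&M procedure
  em <- px[px$code %in% registry$em_proc]
  em <- merge(unique(em[, .(.claim)]),
              out_claims[, .(.claim = seq_len(.N), member_id,
                             proc_date = service_date)], by = ".claim")
  ev_em <- if (nrow(em) && nrow(dx_out[site == "vertebral"])) {
    j <- merge(dx_out[site == "vertebral", .(member_id, site, event_date)],
               em[, .(member_id, proc_date)],
               by = "member_id", allow.cartesian = TRUE)
    unique(j[abs(as.integer(proc_date) - as.integer(event_date)) <= pw,
             .(member_id, event_date, site)])[, `:=`(
               setting = "outpatient", rule = "vertebral_dx_plus_em")]
  } else empty[0]

  ev <- data.table::rbindlist(list(ev_in, ev_out, ev_em), use.names = TRUE)
  if (!nrow(ev)) return(empty)
  # dedupe per (member, site, date); rule precedence a > b > c
  ev[, .prio := match(rule, c("inpatient_dx", "outpatient_dx_plus_proc",
                              "vertebral_dx_plus_em"))]
  data.table::setorder(ev, member_id, event_date, site, .prio)
  ev <- ev[, .SD[1], by = .(member_id, event_date, site)]
  ev[, .prio := NULL]
  ev[, .rank := site_rank(site, registry)]
  data.table::setorder(ev, member_id, event_date, .rank)
  ev[, .rank := NULL]
  ev[]
}

#' Assign the index fracture
#'
#' The earliest qualified event inside the index period becomes the index;
#' among same-day events the site with the lowest hierarchy rank wins
#' (earliest date always beats hierarchy). Members with no event in the
#' index period get no row.
#'
#' @param events Output of [identify_fracture_events()].
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return data.table: `member_id`, `index_date`, `site`, `setting`,
#'   `rule`, `competing_sites_same_day` (pipe-delimited, possibly empty).
#' @export
assign_index_fracture <- function(events, registry, config = analysis_config()) {
  ev <- data.table::as.data.table(events)
  ev <- ev[event_date >= config$index_start & event_date <= config$index_end]
  if (!nrow(ev))
    return(data.table::data.table(
      member_id = character(0), index_date = as.Date(character(0)),
      site = character(0), setting = character(0), rule = character(0),
      competing_sites_same_day = character(0)))
  ev[, .rank := site_rank(site, registry)]
  data.table::setorder(ev, member_id, event_date, .rank)
  idx <- ev[, {
    first_day <- event_date[1]
    same_day <- site[event_date == first_day]
    .(index_date = first_day, site = site[1], setting = setting[1],
      rule = rule[1],
      competing_sites_same_day = paste(same_day[-1], collapse = "|"))
  }, by = member_id]
  idx[]
}
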