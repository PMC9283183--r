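# Subsequent-fracture detection.
#
# Scanning a member's qualified events after the index in date order, an
# event qualifies as a new (subsequent) fracture iff its site has never
# fractured before — relative to the index and previously ACCEPTED
# subsequents — or the gap from the most recent fracture at that site is
# strictly greater than 90 days. Accepted events update the per-site
# "most recent fracture" state; rejected events (continuing-care claims
# within 90 days of a same-site fracture) do not.

#' Identify subsequent nontraumatic fractures
#'
#' Events must themselves satisfy the full identification algorithm
#' (pass the output of [identify_fracture_events()]); only events strictly
#' after the index date are considered.
#'
#' @param events Qualified events (one or many members).
#' @param index_table Per-member index rows (`member_id`, `index_date`,
#'   `index_site` or `site`).
#' @param config An [analysis_config()].
#' @return data.table: `member_id`, `event_date`, `site`, `days_from_index`
#'   (>= 1), `qualifying_reason` (`new_site` / `same_site_gt90`).
#' @export
identify_subsequent <- function(events, index_table, config = analysis_config()) {
  ev <- data.table::as.data.table(events)
  idx <- data.table::as.data.table(index_table)
  if ("index_site" %in% names(idx)) {
    idx <- idx[, .(member_id, index_date, index_site)]
  } else {
    idx <- idx[, .(member_id, index_date, index_site = site)]
  }
  out_empty <- data.table::data.table(
    member_id = character(0), event_date = as.Date(character(0)),
    site = character(0), days_from_index = integer(0),
    qualifying_reason = character(0))
  if (!nrow(ev) || !nrow(idx)) return(out_empty)

  j <- merge(ev, idx, by = "member_id")
  j <- j[event_date > index_date]
  if (!nrow(j)) return(out_empty)
  data.table::setorder(j, member_id, event_date, site)  # site: deterministic same-day order
  gap <- config$subsequent_gap_days

  res <- j[, {
    last_seen <- stats::setNames(as.integer(index_date[1]), index_site[1])
    keep <- logical(.N)
    reason <- character(.N)
    d <- as.integer(event_date)
    for (k in seq_len(.N)) {
      s <- site[k]
      prev <- last_seen[s]
      if (is.na(prev)) {
        keep[k] <- TRUE
        reason[k] <- "new_site"
        last_seen[s] <- d[k]
      } else if (d[k] - prev > gap) {
        keep[k] <- TRUE
        reason[k] <- "same_site_gt90"
        last_seen[s] <- d[k]
      }
    }
    .(event_date = event_date[keep], site = site[keep],
      days_from_index = d[keep] - as.integer(index_date[1]),
      qualifying_reason = reason[keep])
  }, by = member_id]
  res[]
}

#' Aggregate subsequent-fracture occurrence by landmark and stratum
#'
#' Per landmark and stratum: the share of the landmark denominator with any
#' qualifying subsequent fracture, and the share with a subsequent fracture
#' in each site group (hip / vertebral / NHNV; a member counts once per
#' group row and once in "any").
#'
#' @param subsequent Output of [identify_subsequent()].
#' @param cohort Cohort table (with `follow_up_days`).
#' @param baseline Output of [build_baseline()].
#' @param config An [analysis_config()].
#' @param strata Strata names (default as in [aggregate_treatment()]).
#' @return Long data.table: `landmark`, `stratum`, `measure`, `numerator`,
#'   `denominator`, `value`.
#' @export
aggregate_subsequent <- function(subsequent, cohort, baseline,
                                 config = analysis_config(),
                                 strata = TREATMENT_STRATA) {
  co <- landmark_denominators(cohort, config)
  bl <- data.table::as.data.table(baseline)
  sub <- data.table::as.data.table(subsequent)
  if (nrow(sub)) sub[, grp := site_group(site)]
  rows <- list()
  for (nm in names(config$landmark_days)) {
    L <- config$landmark_days[[nm]]
    denom_ids <- co[get(paste0("in_denom_", nm)) == TRUE, member_id]
    within <- if (nrow(sub)) sub[days_from_index <= L] else sub
    for (s in strata) {
      ids <- intersect(.stratum_members(s, co, bl), denom_ids)
      n <- length(ids)
      w <- if (nrow(within)) within[member_id %in% ids] else within
      add_row <- function(measure, num) {
        rows[[length(rows) + 1]] <<- data.table::data.table(
          landmark = nm, stratum = s, measure = measure, numerator = num,
          denominator = n, value = pct_of(num, n))
      }
      add_row("any_subsequent", length(unique(w$member_id)))
      for (gname in c("hip", "vertebral", "NHNV")) {
        add_row(paste0("subsequent_", gname),
                if (nrow(w)) length(unique(w[grp == gname, member_id])) else 0L)
      }
    }
  }
  data.table::rbindlist(rows)
}
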