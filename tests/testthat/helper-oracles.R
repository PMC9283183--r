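# Independent day-grid oracles. These deliberately avoid the package's
# interval arithmetic: they materialize booleans over calendar days and
# read the answer off the grid.

library(data.table)

# Per-benefit enrollment oracle: every required benefit's spans must cover
# the window with no uncovered run longer than `gap` days.
oracle_enrolled <- function(spans, ws, we, med = TRUE, rx = TRUE, gap = 0L) {
  days <- seq(as.integer(as.Date(ws)), as.integer(as.Date(we)))
  ok_benefit <- function(benefit) {
    sp <- spans[spans[[benefit]] == TRUE, , drop = FALSE]
    covered <- rep(FALSE, length(days))
    for (i in seq_len(nrow(sp))) {
      covered <- covered | (days >= as.integer(sp$start_date[i]) &
                              days <= as.integer(sp$end_date[i]))
    }
    if (all(covered)) return(TRUE)
    if (!any(covered)) return(FALSE)
    r <- rle(covered)
    all(r$lengths[!r$values] <= gap)
  }
  out <- TRUE
  if (med) out <- out && ok_benefit("medical")
  if (rx) out <- out && ok_benefit("pharmacy")
  out
}

# Day-grid medication-episode oracle over days 0..horizon. Returns the
# quantities the coverage algebra must reproduce exactly.
oracle_episode <- function(day, supply, gap = 60L, horizon = 2000L,
                           landmarks = c(183L, 365L, 730L)) {
  covered <- rep(FALSE, horizon + 1L)
  for (i in seq_along(day)) {
    covered[seq(day[i], day[i] + supply[i] - 1L) + 1L] <- TRUE
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values] - 1L, end = ends[r$values] - 1L)
  # group covered intervals into runs: hole > gap breaks a run
  hole <- iv$start[-1] - iv$end[-nrow(iv)] - 1L
  runbreak <- c(FALSE, hole > gap)
  runid <- cumsum(runbreak) + 1L
  run1_end <- max(iv$end[runid == 1L])
  reinit_day <- if (any(runid > 1L)) min(day[day > run1_end]) else NA_integer_
  covered_by_landmark <- vapply(landmarks, function(L) sum(covered[seq_len(L + 1L)]),
                                integer(1))
  disc_by <- run1_end + gap + 1L <= landmarks
  rein_by <- disc_by & !is.na(reinit_day) & reinit_day <= landmarks
  list(intervals = iv, run1_end = run1_end, reinit_day = reinit_day,
       covered_by_landmark = covered_by_landmark,
       disc_by = disc_by, rein_by = rein_by)
}

random_fill_history <- function() {
  k <- sample(1:8, 1)
  data.frame(day = sort(sample(0:700, k, replace = TRUE)),
             supply = sample(c(7L, 14L, 30L, 60L, 90L), k, replace = TRUE))
}

random_spans <- function(member_id = "x") {
  k <- sample(1:4, 1)
  s <- sort(sample(0:2500, k, replace = TRUE))
  len <- sample(0:900, k, replace = TRUE)
  data.table(member_id = member_id,
             start_date = as.Date("2014-01-01") + s,
             end_date = as.Date("2014-01-01") + s + len,
             medical = sample(c(TRUE, TRUE, FALSE), k, replace = TRUE),
             pharmacy = sample(c(TRUE, TRUE, FALSE), k, replace = TRUE))
}

# Minimal single-member bundle: one eligible woman, hip index fracture on
# `idx`, inpatient unless stated. Extra claims/fills appended by callers.
mini_bundle <- function(id = "X1", idx = as.Date("2016-06-01"),
                        setting = "inpatient", site = "hip",
                        registry = load_registry(),
                        enroll_start = idx - 400L, enroll_end = idx + 750L,
                        extra_mc = NULL, extra_rx = NULL,
                        birth_year = 1950L, sex = "F") {
  dxc <- names(registry$fracture_dx)[unname(registry$fracture_dx) == site][1]
  pxc <- names(registry$fracture_proc)[unname(registry$fracture_proc) == site][1]
  members <- data.table(member_id = id, sex = sex, birth_year = birth_year,
                        region = "South", payer = "Commercial", plan_type = "PPO")
  enroll <- data.table(member_id = id, start_date = enroll_start,
                       end_date = enroll_end, medical = TRUE, pharmacy = TRUE)
  mc <- if (setting == "inpatient") {
    data.table(member_id = id, service_date = idx, setting = "inpatient",
               dx_codes = dxc, proc_codes = "",
               admission_date = idx, discharge_date = idx + 3L)
  } else {
    data.table(member_id = id, service_date = idx, setting = "outpatient",
               dx_codes = dxc, proc_codes = pxc,
               admission_date = as.Date(NA), discharge_date = as.Date(NA))
  }
  if (!is.null(extra_mc)) mc <- rbindlist(list(mc, extra_mc), use.names = TRUE)
  rx <- data.table(member_id = character(0), fill_date = as.Date(character(0)),
                   drug_code = character(0), days_supply = integer(0))
  if (!is.null(extra_rx)) rx <- rbindlist(list(rx, extra_rx), use.names = TRUE)
  claims_bundle(members, enroll, mc, rx)
}

mc_row <- function(id, date, setting = "outpatient", dx = "", proc = "",
                   admission = as.Date(NA), discharge = as.Date(NA)) {
  data.table(member_id = id, service_date = as.Date(date), setting = setting,
             dx_codes = dx, proc_codes = proc,
             admission_date = as.Date(admission),
             discharge_date = as.Date(discharge))
}

rx_row <- function(id, date, code, supply = 30L) {
  data.table(member_id = id, fill_date = as.Date(date), drug_code = code,
             days_supply = as.integer(supply))
}
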