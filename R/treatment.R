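# Osteoporosis-medication episode construction and landmark treatment
# metrics.
#
# Day arithmetic (all relative to index, day 0 = index date):
#   * a fill on day f with s days supply covers the closed run [f, f+s-1];
#   * overlapping or abutting coverage merges end-to-end (no stockpiling
#     shift unless config$stockpile);
#   * with current coverage-run end e, the refill gap to a fill on day f is
#     gap_days = f - e - 1; the run survives iff gap_days <= 60, i.e. a
#     fill on day e+61 (gap exactly 60) continues the run, a fill on day
#     e+62 starts a new run and the first run is discontinued at e (the
#     last covered day);
#   * discontinuation is observable at a landmark L only when the full
#     61-day gap fits before it: e + 61 <= L with no same-class fill in
#     between (censoring cannot create a false discontinuation);
#   * re-initiation is a same-class fill after the discontinuation day.

# Vectorized coverage/run construction over post-index fills of many
# (member, class) groups. `fills`: data.table(member_id, class, day, supply)
# with day >= 0. Returns one row per (member, class):
#   first_fill_day, n_fills, run1_end (end of first coverage run),
#   reinit_day (first fill after run 1, NA if none),
#   covered intervals retained long-form in attr "intervals".
.episode_core <- function(fills, gap_days = 60L, stockpile = FALSE) {
  f <- data.table::copy(fills)
  data.table::setorder(f, member_id, class, day, supply)
  if (stockpile) {
    # shift each fill to start after the previous supply ends
    f[, start := {
      st <- day
      if (.N > 1) for (k in 2:.N) st[k] <- max(st[k], st[k - 1] + supply[k - 1])
      st
    }, by = .(member_id, class)]
  } else {
    f[, start := day]
  }
  f[, end := start + supply - 1L]
  # run break: fill starts at least gap_days+2 after the running max end
  f[, prev_end := data.table::shift(cummax(end)), by = .(member_id, class)]
  f[, new_run := is.na(prev_end) | start > prev_end + gap_days + 1L]
  f[, run := cumsum(new_run), by = .(member_id, class)]
  # disjoint covered intervals: break when a true hole appears
  f[, new_iv := is.na(prev_end) | start > prev_end + 1L]
  f[, iv := cumsum(new_iv), by = .(member_id, class)]
  f
}

# per-(member,class) episode summary from .episode_core output
.episode_summary <- function(f) {
  f[, .(first_fill_day = day[1],
        n_fills = .N,
        run1_end = max(end[run == 1L]),
        reinit_day = if (any(run > 1L)) min(day[run > 1L]) else NA_integer_),
    by = .(member_id, class)]
}

#' Build a medication episode for one member and class
#'
#' Constructs coverage intervals, the first coverage run, discontinuation
#' and re-initiation state, and gap-excluded covered days by landmark from
#' one member's post-index fills of a single drug class. Pre-index fills
#' are excluded (pre-index use is baseline context).
#'
#' @param fills data.frame of one member's fills of one class: `fill_date`,
#'   `days_supply` (and optionally `member_id`, `drug_code`).
#' @param index Index date.
#' @param config An [analysis_config()].
#' @return A list of class `medication_episode`: `first_fill_day`,
#'   `coverage` (matrix of disjoint closed `[start, end]` day intervals),
#'   `discontinued` (a >60-day gap terminates the first run within the
#'   data), `discontinuation_day` (last covered day of the first run),
#'   `reinitiated`, `reinitiation_day`, `covered_days_by_landmark`. `NULL`
#'   when there is no post-index fill.
#' @export
#' @examples
#' fills <- data.frame(fill_date = as.Date("2016-01-01") + c(0, 30),
#'                     days_supply = 30L)
#' ep <- build_coverage(fills, as.Date("2016-01-01"))
#' ep$covered_days_by_landmark
build_coverage <- function(fills, index, config = analysis_config()) {
  fl <- data.table::as.data.table(fills)
  fl[, day := as.integer(as_date_strict(fill_date) - as_date_strict(index))]
  fl <- fl[day >= 0L]
  if (!nrow(fl)) return(NULL)
  fl[, `:=`(member_id = "x", class = "x", supply = as.integer(days_supply))]
  core <- .episode_core(fl[, .(member_id, class, day, supply)],
                        gap_days = config$discontinuation_gap_days,
                        stockpile = config$stockpile)
  sm <- .episode_summary(core)
  ivs <- core[, .(start = min(start), end = max(end)), by = iv]
  lands <- config$landmark_days
  covered <- vapply(lands, function(L) {
    sum(pmax(0L, pmin(ivs$end, L) - pmax(ivs$start, 0L) + 1L))
  }, numeric(1))
  # episode-level `discontinued` records an explicitly observed gap (a
  # second run exists); landmark-horizon discontinuation, where a run that
  # simply ends counts once the 61-day gap is observable, is answered by
  # detect_discontinuation_reinitiation().
  ep <- list(
    first_fill_day = sm$first_fill_day,
    coverage = as.matrix(ivs[, .(start, end)]),
    discontinued = !is.na(sm$reinit_day),
    discontinuation_day = sm$run1_end,
    reinitiated = !is.na(sm$reinit_day),
    reinitiation_day = sm$reinit_day,
    covered_days_by_landmark = covered
  )
  class(ep) <- "medication_episode"
  ep
}

#' Landmark discontinuation and re-initiation state of an episode
#'
#' Discontinued by landmark L iff the first coverage run has ended and its
#' qualifying gap is fully observable on or before L (`run1_end + 61 <= L`
#' with no same-class fill inside the gap). Re-initiated by L iff a
#' same-class fill follows the discontinuation day on or before L.
#'
#' @param episode A [build_coverage()] episode.
#' @param landmark_days Integer vector of landmark horizons (days).
#' @param config An [analysis_config()].
#' @return data.frame: `landmark_days`, `discontinued`, `reinitiated`.
#' @export
detect_discontinuation_reinitiation <- function(episode, landmark_days,
                                                config = analysis_config()) {
  g <- config$discontinuation_gap_days + 1L
  e <- episode$discontinuation_day
  r <- episode$reinitiation_day
  disc <- !is.na(e) & (e + g) <= landmark_days
  rein <- disc & !is.na(r) & r <= landmark_days
  data.frame(landmark_days = landmark_days, discontinued = disc,
             reinitiated = rein)
}

#' First post-index osteoporosis medication
#'
#' The earliest post-index OP-class fill; a same-day tie across classes is
#' broken anabolic-before-antiresorptive, then by canonical class order.
#' Members with any pre-index OP fill are flagged non-naive: time to
#' initiation is reported only among the treatment-naive.
#'
#' @param fills One member's pharmacy claims (`fill_date`, `drug_code`).
#' @param index Index date.
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return `NULL` if no post-index OP fill; else a list with `class`,
#'   `supergroup`, `day` (days from index) and `naive`.
#' @export
first_op_medication <- function(fills, index, registry,
                                config = analysis_config()) {
  fl <- data.table::as.data.table(fills)
  fl[, class := unname(registry$drug_class[drug_code])]
  fl <- fl[class %in% op_med_classes()]
  if (!nrow(fl)) return(NULL)
  index <- as_date_strict(index)
  fl[, day := as.integer(as_date_strict(fill_date) - index)]
  naive <- !any(fl$day < 0L & fl$day >= -config$pre_index_days)
  post <- fl[day >= 0L]
  if (!nrow(post)) return(NULL)
  post[, rank := match(class, op_med_classes())]
  data.table::setorder(post, day, rank)
  list(class = post$class[1],
       supergroup = classify_drug(post$drug_code[1], registry)$supergroup,
       day = post$day[1], naive = naive)
}

#' Months on treatment within a landmark
#'
#' Covered days (gap-excluded) inside the closed window `[index,
#' index+landmark]`, divided by the days-per-month constant (30.4375).
#'
#' @param episode A [build_coverage()] episode (or `NULL` for none).
#' @param landmark_days Landmark horizon in days.
#' @param config An [analysis_config()].
#' @return Non-negative months.
#' @export
months_on_treatment <- function(episode, landmark_days,
                                config = analysis_config()) {
  if (is.null(episode)) return(0)
  iv <- episode$coverage
  covered <- sum(pmax(0L, pmin(iv[, "end"], landmark_days) - pmax(iv[, "start"], 0L) + 1L))
  covered / config$days_per_month
}

# --- cohort-wide episode construction -------------------------------------

#' Build all post-index OP medication episodes for a cohort
#'
#' Vectorized episode construction over every (member, OP class) pair with
#' post-index fills, plus per-member first-agent resolution and naive
#' status.
#'
#' @param cohort Cohort table.
#' @param bundle A `claims_bundle`.
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return A list with `episodes` (one row per member x class:
#'   `first_fill_day`, `run1_end`, `reinit_day`, covered days per landmark)
#'   and `members` (one row per treated member: first agent `class`,
#'   `supergroup`, `first_fill_day`, `naive`, `run1_end`, `reinit_day` of
#'   the first agent's episode, union covered days per landmark).
#' @export
build_episodes <- function(cohort, bundle, registry, config = analysis_config()) {
  co <- data.table::as.data.table(cohort)
  lands <- config$landmark_days
  rx <- merge(data.table::as.data.table(bundle$pharmacy_claims),
              co[, .(member_id, index_date)], by = "member_id")
  rx[, class := unname(registry$drug_class[drug_code])]
  rx <- rx[class %in% op_med_classes()]
  rx[, day := as.integer(fill_date - index_date)]

  naive_not <- unique(rx[day < 0L & day >= -config$pre_index_days, member_id])
  post <- rx[day >= 0L]

  empty_ep <- data.table::data.table(
    member_id = character(0), class = character(0), first_fill_day = integer(0),
    n_fills = integer(0), run1_end = integer(0), reinit_day = integer(0))
  for (nm in names(lands)) empty_ep[, (paste0("covered_", nm)) := integer(0)]

  if (!nrow(post)) {
    members <- data.table::data.table(
      member_id = character(0), class = character(0), supergroup = character(0),
      first_fill_day = integer(0), naive = logical(0), run1_end = integer(0),
      reinit_day = integer(0))
    for (nm in names(lands)) members[, (paste0("covered_", nm)) := integer(0)]
    return(list(episodes = empty_ep, members = members))
  }

  core <- .episode_core(post[, .(member_id, class, day, supply = as.integer(days_supply))],
                        gap_days = config$discontinuation_gap_days,
                        stockpile = config$stockpile)
  eps <- .episode_summary(core)
  ivs <- core[, .(start = min(start), end = max(end)),
              by = .(member_id, class, iv)]
  for (nm in names(lands)) {
    L <- lands[[nm]]
    cv <- ivs[, .(covered = sum(pmax(0L, pmin(end, L) - pmax(start, 0L) + 1L))),
              by = .(member_id, class)]
    eps[, (paste0("covered_", nm)) := cv[eps, on = c("member_id", "class"), x.covered]]
  }

  # first agent per member: earliest day, ties anabolic first then class order
  eps[, .cls_rank := match(class, op_med_classes())]
  data.table::setorder(eps, member_id, first_fill_day, .cls_rank)
  first_agent <- eps[, .SD[1], by = member_id]
  first_agent[, .cls_rank := NULL]
  first_agent[, supergroup := data.table::fifelse(class %in% anabolic_classes(),
                                                  "anabolic", "antiresorptive")]
  first_agent[, naive := !member_id %in% naive_not]

  # union coverage across classes per member (months on treatment)
  for (nm in names(lands)) {
    L <- lands[[nm]]
    u <- ivs[start <= L, {
      s <- pmax(start, 0L); e <- pmin(end, L)
      o <- order(s)
      s <- s[o]; e <- e[o]
      ce <- cummax(e)
      newiv <- c(TRUE, s[-1] > ce[-length(ce)] + 1L)
      grp <- cumsum(newiv)
      .(covered = sum(tapply(e, grp, max) - tapply(s, grp, min) + 1L))
    }, by = member_id]
    first_agent[, (paste0("union_covered_", nm)) :=
                  u[first_agent, on = "member_id", x.covered]]
    first_agent[is.na(get(paste0("union_covered_", nm))),
                (paste0("union_covered_", nm)) := 0L]
  }
  eps[, .cls_rank := NULL]
  list(episodes = eps[], members = first_agent[])
}

TREATMENT_STRATA <- c("overall", "pre_op_dx", "pre_op_med",
                      "pre_antiresorptive", "pre_anabolic",
                      "hip", "vertebral", "NHNV")

TTI_BANDS <- c("<=30", ">30-60", ">60-180", ">180-360", ">360-720")

.tti_band <- function(days) {
  ifelse(days <= 30, "<=30",
  ifelse(days <= 60, ">30-60",
  ifelse(days <= 180, ">60-180",
  ifelse(days <= 360, ">180-360", ">360-720"))))
}

#' Aggregate landmark treatment metrics by stratum
#'
#' For each landmark and stratum: the landmark denominator (members
#' continuously enrolled through the landmark), the share with any
#' post-index OP medication, per-class and per-supergroup utilization
#' (a member counts once per class ever used in the window),
#' discontinuation and re-initiation of the first agent, time to initiation
#' among treatment-naive initiators (mean, SD, bands), and mean months on
#' treatment (gap-excluded).
#'
#' @param episodes Output of [build_episodes()].
#' @param cohort Cohort table (with `follow_up_days`).
#' @param baseline Output of [build_baseline()].
#' @param config An [analysis_config()].
#' @param strata Strata names (default: overall, four pre-index subgroups,
#'   three index fracture types).
#' @return Long data.table: `landmark`, `stratum`, `measure`, `kind`,
#'   `numerator`, `denominator`, `value`, `sd`.
#' @export
aggregate_treatment <- function(episodes, cohort, baseline,
                                config = analysis_config(),
                                strata = TREATMENT_STRATA) {
  co <- landmark_denominators(cohort, config)
  bl <- data.table::as.data.table(baseline)
  mem <- episodes$members
  eps <- episodes$episodes
  g <- config$discontinuation_gap_days + 1L
  rows <- list()
  for (nm in names(config$landmark_days)) {
    L <- config$landmark_days[[nm]]
    denom_ids <- co[get(paste0("in_denom_", nm)) == TRUE, member_id]
    for (s in strata) {
      ids <- intersect(.stratum_members(s, co, bl), denom_ids)
      n <- length(ids)
      msub <- mem[member_id %in% ids]
      esub <- eps[member_id %in% ids]
      add <- function(measure, num, kind = "pct", value = pct_of(num, n),
                      sd = NA_real_, den = n) {
        rows[[length(rows) + 1]] <<- data.table::data.table(
          landmark = nm, stratum = s, measure = measure, kind = kind,
          numerator = num, denominator = den, value = value, sd = sd)
      }
      treated <- msub[first_fill_day <= L]
      add("any_op_med", nrow(treated))
      add("anabolic", length(unique(esub[class %in% anabolic_classes() &
                                           first_fill_day <= L, member_id])))
      add("antiresorptive", length(unique(esub[class %in% antiresorptive_classes() &
                                                 first_fill_day <= L, member_id])))
      for (cl in op_med_classes()) {
        add(paste0("class_", cl),
            length(unique(esub[class == cl & first_fill_day <= L, member_id])))
      }
      disc <- treated[!is.na(run1_end) & run1_end + g <= L]
      add("discontinued", nrow(disc))
      add("reinitiated", nrow(disc[!is.na(reinit_day) & reinit_day <= L]))

      tti <- msub[naive == TRUE & first_fill_day <= L, first_fill_day]
      add("time_to_initiation", length(tti), kind = "mean",
          value = if (length(tti)) mean(tti) else NA_real_,
          sd = if (length(tti) > 1) stats::sd(tti) else NA_real_,
          den = length(tti))
      for (b in TTI_BANDS) {
        add(paste0("tti_band_", b), sum(.tti_band(tti) == b),
            value = pct_of(sum(.tti_band(tti) == b), length(tti)),
            den = length(tti))
      }
      mot <- msub[[paste0("union_covered_", nm)]] / config$days_per_month
      mot <- c(mot, rep(0, n - nrow(msub)))  # untreated members: 0 months
      add("months_on_treatment", n, kind = "mean",
          value = if (n) mean(mot) else NA_real_,
          sd = if (n > 1) stats::sd(mot) else NA_real_)
    }
  }
  data.table::rbindlist(rows)
}
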