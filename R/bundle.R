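# Claims bundle: the pipeline's sole input. Four tables keyed by member_id:
# members, enrollment spans, medical claims, pharmacy claims. Dates are
# calendar dates at day resolution; all intervals are closed on both ends.

BUNDLE_SCHEMAS <- list(
  members = c("member_id", "sex", "birth_year", "region", "payer", "plan_type"),
  enrollment = c("member_id", "start_date", "end_date", "medical", "pharmacy"),
  medical_claims = c("member_id", "service_date", "setting", "dx_codes",
                     "proc_codes", "admission_date", "discharge_date"),
  pharmacy_claims = c("member_id", "fill_date", "drug_code", "days_supply")
)

CLAIM_SETTINGS <- c("inpatient", "outpatient", "snf", "home_health", "other")

#' Assemble and validate a claims bundle
#'
#' @param members data.frame: `member_id`, `sex` (F/M/U), `birth_year`,
#'   `region`, `payer`, `plan_type`.
#' @param enrollment data.frame of closed enrollment spans: `member_id`,
#'   `start_date`, `end_date`, logical `medical`, `pharmacy`.
#' @param medical_claims data.frame: `member_id`, `service_date`, `setting`
#'   (inpatient/outpatient/snf/home_health/other), `dx_codes` and
#'   `proc_codes` (pipe-delimited within a cell), optional
#'   `admission_date`/`discharge_date` for inpatient claims.
#' @param pharmacy_claims data.frame: `member_id`, `fill_date`, `drug_code`,
#'   `days_supply` (>= 1).
#' @return A `claims_bundle`: a list of the four tables as data.tables.
#' @export
claims_bundle <- function(members, enrollment, medical_claims, pharmacy_claims) {
  b <- list(members = data.table::as.data.table(members),
            enrollment = data.table::as.data.table(enrollment),
            medical_claims = data.table::as.data.table(medical_claims),
            pharmacy_claims = data.table::as.data.table(pharmacy_claims))
  for (tbl in names(BUNDLE_SCHEMAS)) {
    missing <- setdiff(BUNDLE_SCHEMAS[[tbl]], names(b[[tbl]]))
    if (length(missing))
      stop_input("table '", tbl, "' is missing column(s): ",
                 paste(missing, collapse = ", "))
  }
  for (col in c("dx_codes", "proc_codes"))
    b$medical_claims[[col]][is.na(b$medical_claims[[col]])] <- ""
  validate_bundle(b)
  class(b) <- "claims_bundle"
  b
}

#' Validate bundle invariants
#'
#' Checks referential integrity (every claim/span member exists in
#' `members`), unique member ids, span ordering, and positive days supply.
#' Called by [claims_bundle()]; exported for use on externally built lists.
#'
#' @param b A bundle-shaped list.
#' @return Invisibly `b`; stops on violation.
#' @export
validate_bundle <- function(b) {
  ids <- b$members$member_id
  if (anyDuplicated(ids)) stop_input("member_id not unique in members table")
  for (tbl in c("enrollment", "medical_claims", "pharmacy_claims")) {
    orphan <- setdiff(unique(b[[tbl]]$member_id), ids)
    if (length(orphan))
      stop_input("table '", tbl, "' references unknown member(s): ",
                 paste(utils::head(orphan, 5), collapse = ", "))
  }
  if (nrow(b$enrollment) && any(b$enrollment$start_date > b$enrollment$end_date))
    stop_input("enrollment spans with start_date > end_date")
  if (nrow(b$pharmacy_claims) && any(b$pharmacy_claims$days_supply < 1))
    stop_input("pharmacy claims with days_supply < 1")
  mc <- b$medical_claims
  if (nrow(mc)) {
    bad <- !is.na(mc$admission_date) & !is.na(mc$discharge_date) &
      mc$admission_date > mc$discharge_date
    if (any(bad)) stop_input("inpatient claims with admission_date > discharge_date")
    if (any(!mc$setting %in% CLAIM_SETTINGS))
      stop_input("unknown claim setting(s): ",
                 paste(setdiff(unique(mc$setting), CLAIM_SETTINGS), collapse = ", "))
  }
  invisible(b)
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("<claims_bundle>\n")
  cat(sprintf("  %d members | %d enrollment spans | %d medical | %d pharmacy claims\n",
              nrow(x$members), nrow(x$enrollment),
              nrow(x$medical_claims), nrow(x$pharmacy_claims)))
  invisible(x)
}

#' Read a claims bundle from delimited text files
#'
#' Expects four CSV files (RFC-4180, ISO-8601 dates; dx/proc code lists
#' pipe-delimited within a cell). Rows violating type invariants (for
#' example `days_supply = 0` or an unparseable date) are rejected and
#' reported with their line numbers in the validation log attached as
#' `attr(bundle, "validation")`; a missing required column is an error.
#'
#' @param dir Directory containing `members.csv`, `enrollment.csv`,
#'   `medical_claims.csv`, `pharmacy_claims.csv`.
#' @param paths Optional named list/vector overriding individual file paths
#'   (names among the four table names).
#' @return A `claims_bundle` with a `validation` attribute (data.table:
#'   `table`, `line`, `reason`; line numbers count the header as line 1).
#' @export
#' @examples
#' dir <- system.file("extdata", "tiny_bundle", package = "fracturepathways")
#' b <- read_bundle(dir)
#' b
read_bundle <- function(dir = NULL, paths = NULL) {
  files <- stats::setNames(
    file.path(dir %||% ".", paste0(names(BUNDLE_SCHEMAS), ".csv")),
    names(BUNDLE_SCHEMAS))
  if (!is.null(paths)) files[names(paths)] <- unlist(paths)
  for (f in files) if (!file.exists(f)) stop_input("file not found: ", f)

  rejects <- list()

  tabs <- lapply(names(files), function(tbl) {
    dt <- data.table::fread(files[[tbl]], colClasses = "character",
                            na.strings = c("NA", ""))
    missing <- setdiff(BUNDLE_SCHEMAS[[tbl]], names(dt))
    if (length(missing))
      stop_input("file '", files[[tbl]], "' is missing column(s): ",
                 paste(missing, collapse = ", "))
    dt[, .line := .I + 1L]  # header is line 1
    dt
  })
  names(tabs) <- names(files)

  drop_rows <- function(tbl, dt, bad, reason) {
    bad <- unique(bad[!is.na(bad)])
    if (length(bad)) {
      rejects[[length(rejects) + 1]] <<- data.table::data.table(
        table = tbl, line = dt$.line[bad], reason = reason)
      dt <- dt[-bad]
    }
    dt
  }

  m <- tabs$members
  .parse_date_col2 <- function(dt, col, tbl) {
    raw <- as.character(dt[[col]])
    parsed <- as.Date(raw, format = "%Y-%m-%d")
    bad <- which(!is.na(raw) & is.na(parsed))
    data.table::set(dt, j = col, value = parsed)
    list(dt = dt, bad = bad)
  }
  m[, birth_year := suppressWarnings(as.integer(birth_year))]
  m <- drop_rows("members", m, which(is.na(m$birth_year)), "missing/invalid birth_year")

  e <- tabs$enrollment
  for (col in c("start_date", "end_date")) {
    r <- .parse_date_col2(e, col, "enrollment")
    e <- drop_rows("enrollment", r$dt, r$bad, paste("unparseable", col))
  }
  e <- drop_rows("enrollment", e, which(is.na(e$start_date) | is.na(e$end_date)),
                 "missing span date")
  e <- drop_rows("enrollment", e, which(e$start_date > e$end_date),
                 "start_date after end_date")
  e[, medical := toupper(medical) %in% c("TRUE", "T", "1")]
  e[, pharmacy := toupper(pharmacy) %in% c("TRUE", "T", "1")]

  mc <- tabs$medical_claims
  for (col in c("service_date", "admission_date", "discharge_date")) {
    r <- .parse_date_col2(mc, col, "medical_claims")
    mc <- drop_rows("medical_claims", r$dt, r$bad, paste("unparseable", col))
  }
  mc <- drop_rows("medical_claims", mc, which(is.na(mc$service_date)),
                  "missing service_date")
  mc <- drop_rows("medical_claims", mc, which(!mc$setting %in% CLAIM_SETTINGS),
                  "unknown setting")
  mc <- drop_rows("medical_claims", mc,
                  which(!is.na(mc$admission_date) & !is.na(mc$discharge_date) &
                          mc$admission_date > mc$discharge_date),
                  "admission_date after discharge_date")
  for (col in c("dx_codes", "proc_codes")) mc[[col]][is.na(mc[[col]])] <- ""

  p <- tabs$pharmacy_claims
  r <- .parse_date_col2(p, "fill_date", "pharmacy_claims")
  p <- drop_rows("pharmacy_claims", r$dt, r$bad, "unparseable fill_date")
  p <- drop_rows("pharmacy_claims", p, which(is.na(p$fill_date)), "missing fill_date")
  p[, days_supply := suppressWarnings(as.integer(days_supply))]
  p <- drop_rows("pharmacy_claims", p, which(is.na(p$days_supply) | p$days_supply < 1),
                 "days_supply missing or < 1")

  known <- m$member_id
  e <- drop_rows("enrollment", e, which(!e$member_id %in% known), "unknown member_id")
  mc <- drop_rows("medical_claims", mc, which(!mc$member_id %in% known), "unknown member_id")
  p <- drop_rows("pharmacy_claims", p, which(!p$member_id %in% known), "unknown member_id")

  for (dt in list(m, e, mc, p)) dt[, .line := NULL]
  b <- claims_bundle(m, e, mc, p)
  attr(b, "validation") <- if (length(rejects)) {
    data.table::rbindlist(rejects)
  } else {
    data.table::data.table(table = character(0), line = integer(0),
                           reason = character(0))
  }
  b
}

#' Write a claims bundle to delimited text files
#'
#' Inverse of [read_bundle()]: writes the four CSV tables with ISO-8601
#' dates. A write/read round trip is lossless.
#'
#' @param bundle A `claims_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- stats::setNames(
    file.path(dir, paste0(names(BUNDLE_SCHEMAS), ".csv")), names(BUNDLE_SCHEMAS))
  for (tbl in names(BUNDLE_SCHEMAS)) {
    out <- data.table::copy(bundle[[tbl]])[, BUNDLE_SCHEMAS[[tbl]], with = FALSE]
    data.table::fwrite(out, paths[[tbl]], dateTimeAs = "ISO", na = "NA")
  }
  invisible(paths)
}

# --- enrollment interval algebra ------------------------------------------

# Bulk continuous-coverage check. `windows`: data.table(member_id, ws, we)
# (Dates). Returns logical per window row: TRUE iff spans carrying the
# required benefit(s) cover every day, tolerating interior/edge gaps of at
# most `allowed_gap_days`. Both-benefit coverage is the conjunction of the
# per-benefit checks, so a medical-only span plus a pharmacy-only span can
# jointly satisfy it.
enrollment_covered <- function(enrollment, windows, require_medical = TRUE,
                               require_pharmacy = TRUE, allowed_gap_days = 0L) {
  stopifnot(all(c("member_id", "ws", "we") %in% names(windows)))
  if (any(windows$ws > windows$we)) stop_input("empty enrollment window")
  res <- rep(TRUE, nrow(windows))
  for (benefit in c("medical", "pharmacy")[c(require_medical, require_pharmacy)]) {
    sp <- enrollment[enrollment[[benefit]] == TRUE,
                     .(member_id, s = as.integer(start_date), e = as.integer(end_date))]
    w <- data.table::data.table(member_id = windows$member_id,
                                ws = as.integer(windows$ws),
                                we = as.integer(windows$we),
                                .row = seq_len(nrow(windows)))
    j <- sp[w, on = .(member_id), allow.cartesian = TRUE, nomatch = NULL]
    j <- j[e >= ws & s <= we]
    if (!nrow(j)) {
      res <- res & FALSE
      next
    }
    j[, `:=`(s2 = pmax(s, ws), e2 = pmin(e, we))]
    data.table::setorder(j, .row, s2, e2)
    j[, ce := cummax(e2), by = .row]
    j[, gap := s2 - data.table::shift(ce, fill = NA_integer_) - 1L, by = .row]
    cov <- j[, .(
      ok = (s2[1] - ws[1] <= allowed_gap_days) &
        (we[1] - ce[.N] <= allowed_gap_days) &
        (.N == 1L || max(gap[-1]) <= allowed_gap_days)
    ), by = .row]
    ok <- rep(FALSE, nrow(windows))
    ok[cov$.row] <- cov$ok
    res <- res & ok
  }
  res
}

#' Continuous-enrollment check for one member
#'
#' `TRUE` iff the union of the member's spans carrying the required
#' benefit flags covers every calendar day of the closed window, tolerating
#' gaps of at most `allowed_gap_days` (default 0: a single uncovered day
#' fails).
#'
#' @param spans Enrollment spans of one member (data.frame with
#'   `start_date`, `end_date`, `medical`, `pharmacy`).
#' @param window_start,window_end Closed date window; an empty window
#'   (`window_start > window_end`) is an error.
#' @param require_medical,require_pharmacy Which benefits must be covered.
#' @param allowed_gap_days Maximum tolerated uncovered run, in days.
#' @return Logical scalar.
#' @export
#' @examples
#' sp <- data.frame(start_date = as.Date("2014-01-01"),
#'                  end_date = as.Date("2016-12-31"),
#'                  medical = TRUE, pharmacy = TRUE)
#' is_continuously_enrolled(sp, as.Date("2015-03-01"), as.Date("2015-12-31"))
is_continuously_enrolled <- function(spans, window_start, window_end,
                                     require_medical = TRUE,
                                     require_pharmacy = TRUE,
                                     allowed_gap_days = 0L) {
  window_start <- as_date_strict(window_start)
  window_end <- as_date_strict(window_end)
  if (window_start > window_end) stop_input("empty enrollment window")
  sp <- data.table::as.data.table(spans)
  sp[, member_id := "x"]
  enrollment_covered(
    sp, data.table::data.table(member_id = "x", ws = window_start, we = window_end),
    require_medical = require_medical, require_pharmacy = require_pharmacy,
    allowed_gap_days = as.integer(allowed_gap_days))
}

# Longest continuous both-benefit follow-up, in days, starting the day after
# `anchor`: the largest L >= 0 such that [anchor+1, anchor+L] is fully
# covered. `anchors`: data.table(member_id, anchor (Date)). Vectorized.
follow_up_days <- function(enrollment, anchors, allowed_gap_days = 0L) {
  run_end <- function(benefit) {
    sp <- enrollment[enrollment[[benefit]] == TRUE,
                     .(member_id, s = as.integer(start_date), e = as.integer(end_date))]
    a <- data.table::data.table(member_id = anchors$member_id,
                                d1 = as.integer(anchors$anchor) + 1L,
                                .row = seq_len(nrow(anchors)))
    j <- sp[a, on = .(member_id), allow.cartesian = TRUE, nomatch = NULL]
    j <- j[e >= d1]
    out <- rep(NA_integer_, nrow(anchors))
    if (!nrow(j)) return(out)
    data.table::setorder(j, .row, s, e)
    ends <- j[, {
      ce <- cummax(e)
      gap_ok <- c(TRUE, s[-1] - ce[-.N] - 1L <= allowed_gap_days)
      # walk merged runs; keep the run containing d1
      run_id <- cumsum(!gap_ok)
      first_run <- run_id[which(s <= d1[1])]
      if (!length(first_run)) {
        NA_integer_
      } else {
        r <- max(first_run)  # latest run starting on/before d1
        if (max(ce[run_id == r]) >= d1[1]) max(ce[run_id == r]) else NA_integer_
      }
    }, by = .row]
    out[ends$.row] <- ends$V1
    out
  }
  e_med <- run_end("medical")
  e_rx <- run_end("pharmacy")
  end_both <- pmin(e_med, e_rx)
  fu <- end_both - as.integer(anchors$anchor)
  fu[is.na(fu) | fu < 0] <- 0L
  as.integer(fu)
}

#' Age in whole years at a date
#'
#' Claims data carry birth year only, so age uses year arithmetic
#' (`year(date) - birth_year`), matching payer-data convention and the
#' usual age banding of baseline tables.
#'
#' @param member A data.frame/list with `birth_year` (vectorized).
#' @param date Date(s).
#' @return Integer years.
#' @export
age_at <- function(member, date) {
  date_year(as_date_strict(date)) - as.integer(member$birth_year)
}
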