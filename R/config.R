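#' Analysis configuration
#'
#' Bundles every date window and threshold the pipeline uses: the overall
#' study period, the index period (nested so that a full 1-year look-back and
#' a minimum 6-month follow-up fit inside the study period), the pre-index
#' look-back length, the 6/12/24-month landmark horizons, the permissible
#' refill gap that defines discontinuation, the subsequent-fracture same-site
#' gap, the readmission window, and the minimum age at index.
#'
#' All intervals in this package are closed calendar-day intervals;
#' durations are day counts (`end - start`).
#'
#' @param study_start,study_end Overall study period (defaults 2014-01-01 to
#'   2019-12-31). Claims outside it are ignored.
#' @param index_start,index_end Index period (defaults 2015-01-01 to
#'   2019-06-30) within which the first qualified fracture becomes the index.
#' @param pre_index_days Look-back length in days (365).
#' @param landmark_days Named integer vector of post-index horizons
#'   (183/365/730 days for 6/12/24 months).
#' @param discontinuation_gap_days Refill gap strictly above which a
#'   medication class is discontinued (60).
#' @param subsequent_gap_days Same-site gap strictly above which a repeat
#'   fracture at a previously fractured site counts as a new fracture (90).
#' @param readmission_window_days All-cause readmission window after the
#'   index-stay discharge (30).
#' @param min_age Minimum age (in years, year-arithmetic) at index (50).
#' @param days_per_month Divisor converting covered days to months (30.4375).
#' @param allowed_gap_days Enrollment gap tolerated by the continuous
#'   enrollment check (0).
#' @param pairing_window_days Maximum days between an outpatient fracture
#'   diagnosis claim and its same-site treatment (or vertebral E&M) procedure
#'   claim (7).
#' @param post_index_min_days Continuous enrollment required after index,
#'   starting the day after index (183).
#' @param index_hosp_window_days Latest admission day (relative to index) for
#'   a stay to count as the index hospitalization (7).
#' @param cancer_lookback_days Look-back for the cancer exclusion (365);
#'   bone-disease exclusions always use all pre-index study-period data.
#' @param min_claims Claims required to set a baseline comorbidity flag (1).
#' @param stockpile If `TRUE`, an overlapping refill is shifted to start the
#'   day after the previous supply ends instead of merging end-to-end.
#' @param require_sex Sex retained by the cohort filter (`"F"`).
#' @return An object of class `analysis_config` (a validated named list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$landmark_days
analysis_config <- function(study_start = as.Date("2014-01-01"),
                            study_end = as.Date("2019-12-31"),
                            index_start = as.Date("2015-01-01"),
                            index_end = as.Date("2019-06-30"),
                            pre_index_days = 365L,
                            landmark_days = c("6mo" = 183L, "12mo" = 365L, "24mo" = 730L),
                            discontinuation_gap_days = 60L,
                            subsequent_gap_days = 90L,
                            readmission_window_days = 30L,
                            min_age = 50L,
                            days_per_month = 30.4375,
                            allowed_gap_days = 0L,
                            pairing_window_days = 7L,
                            post_index_min_days = 183L,
                            index_hosp_window_days = 7L,
                            cancer_lookback_days = 365L,
                            min_claims = 1L,
                            stockpile = FALSE,
                            require_sex = "F") {
  cfg <- list(
    study_start = as_date_strict(study_start), study_end = as_date_strict(study_end),
    index_start = as_date_strict(index_start), index_end = as_date_strict(index_end),
    pre_index_days = as.integer(pre_index_days),
    landmark_days = vapply(landmark_days, as.integer, integer(1)),
    discontinuation_gap_days = as.integer(discontinuation_gap_days),
    subsequent_gap_days = as.integer(subsequent_gap_days),
    readmission_window_days = as.integer(readmission_window_days),
    min_age = as.integer(min_age),
    days_per_month = as.numeric(days_per_month),
    allowed_gap_days = as.integer(allowed_gap_days),
    pairing_window_days = as.integer(pairing_window_days),
    post_index_min_days = as.integer(post_index_min_days),
    index_hosp_window_days = as.integer(index_hosp_window_days),
    cancer_lookback_days = as.integer(cancer_lookback_days),
    min_claims = as.integer(min_claims),
    stockpile = isTRUE(stockpile),
    require_sex = as.character(require_sex)
  )
  class(cfg) <- "analysis_config"
  validate_analysis_config(cfg)
  cfg
}

validate_analysis_config <- function(cfg) {
  with(cfg, {
    if (is.na(study_start) || is.na(study_end) || study_start > study_end)
      stop_input("study period is empty or unparseable")
    if (index_start < study_start || index_end > study_end)
      stop_input("index period must be nested in the study period")
    lens <- c(pre_index_days, landmark_days, discontinuation_gap_days,
              subsequent_gap_days, readmission_window_days,
              post_index_min_days, pairing_window_days)
    if (any(lens <= 0)) stop_input("all window lengths must be positive")
    if (allowed_gap_days < 0) stop_input("allowed_gap_days must be >= 0")
    if (days_per_month <= 0) stop_input("days_per_month must be positive")
  })
  invisible(cfg)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Keys absent from the file keep their [analysis_config()] defaults.
#'
#' @param path Path to a YAML (or JSON, which YAML parses) config file.
#' @return An `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_input("unknown analysis_config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(raw$landmark_days)) raw$landmark_days <- unlist(raw$landmark_days)
  do.call(analysis_config, raw)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  study period : %s .. %s\n", x$study_start, x$study_end))
  cat(sprintf("  index period : %s .. %s\n", x$index_start, x$index_end))
  cat(sprintf("  pre-index %d d | post-index min %d d | landmarks %s d\n",
              x$pre_index_days, x$post_index_min_days,
              paste(x$landmark_days, collapse = "/")))
  cat(sprintf("  refill gap > %d d | same-site gap > %d d | readmission %d d\n",
              x$discontinuation_gap_days, x$subsequent_gap_days,
              x$readmission_window_days))
  invisible(x)
}
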