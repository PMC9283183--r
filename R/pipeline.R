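# Four-stage pipeline driver and aggregate-table emitters.
#
# Tables are plain CSV; every percentage cell is accompanied by its
# numerator and denominator, percentages are additionally rendered at one
# decimal (half away from zero), and empty strata yield NA cells, never 0%.

.fmt_pct <- function(value) {
  ifelse(is.na(value), NA_character_, sprintf("%.1f", round_half_up(value, 1)))
}

# Table 1-style demographic aggregate, split by post-index OP-medication
# status at 6 months (overall / with / without).
.table1 <- function(cohort, baseline, mgmt) {
  co <- data.table::as.data.table(cohort)
  bl <- data.table::as.data.table(baseline)
  with_ids <- mgmt[op_tx_6mo == TRUE, member_id]
  split_ids <- list(overall = co$member_id, with_op_med = with_ids,
                    without_op_med = setdiff(co$member_id, with_ids))
  rows <- list()
  add <- function(stratum, measure, num, den) {
    rows[[length(rows) + 1]] <<- data.table::data.table(
      stratum = stratum, measure = measure, numerator = num,
      denominator = den, value = pct_of(num, den))
  }
  for (s in names(split_ids)) {
    sub <- bl[member_id %in% split_ids[[s]]]
    n <- nrow(sub)
    for (b in AGE_BANDS) add(s, paste0("age_", b), sum(sub$age_band == b), n)
    for (r in unique(bl$region)) add(s, paste0("region_", r), sum(sub$region == r), n)
    for (p in unique(bl$payer)) add(s, paste0("payer_", p), sum(sub$payer == p), n)
    for (p in unique(bl$plan_type)) add(s, paste0("plan_", p), sum(sub$plan_type == p), n)
    rows[[length(rows) + 1]] <- data.table::data.table(
      stratum = s, measure = "age_mean", numerator = n, denominator = n,
      value = if (n) mean(co[member_id %in% split_ids[[s]], age_at_index]) else NA_real_)
  }
  data.table::rbindlist(rows)
}

# Table 2-style clinical-baseline aggregate with the same column split.
.table2 <- function(cohort, baseline, mgmt) {
  co <- data.table::as.data.table(cohort)
  bl <- data.table::as.data.table(baseline)
  with_ids <- mgmt[op_tx_6mo == TRUE, member_id]
  split_ids <- list(overall = co$member_id, with_op_med = with_ids,
                    without_op_med = setdiff(co$member_id, with_ids))
  flag_cols <- c("op_dx", "op_dx_or_tx", "dxa", "prior_ortho_surgery",
                 "op_med_use", "anabolic_use", "antiresorptive_use",
                 "smoking", "falls_history", "dme_use", "corticosteroid_6mo",
                 grep("^com_", names(bl), value = TRUE),
                 grep("^rx_", names(bl), value = TRUE))
  rows <- list()
  for (s in names(split_ids)) {
    sub <- bl[member_id %in% split_ids[[s]]]
    n <- nrow(sub)
    for (f in flag_cols) {
      num <- sum(sub[[f]])
      rows[[length(rows) + 1]] <- data.table::data.table(
        stratum = s, measure = f, kind = "pct", numerator = num,
        denominator = n, value = pct_of(num, n), sd = NA_real_)
    }
    rows[[length(rows) + 1]] <- data.table::data.table(
      stratum = s, measure = "cci", kind = "mean", numerator = n,
      denominator = n, value = if (n) mean(sub$cci) else NA_real_,
      sd = if (n > 1) stats::sd(sub$cci) else NA_real_)
    for (what in c("dxa", "surgery")) {
      col <- paste0(what, "_days_before_index")
      v <- sub[[col]][!is.na(sub[[col]])]
      rows[[length(rows) + 1]] <- data.table::data.table(
        stratum = s, measure = paste0(what, "_days_to_index"), kind = "mean",
        numerator = length(v), denominator = length(v),
        value = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_)
      bands <- interval_band(v)
      for (b in BASELINE_BANDS) {
        rows[[length(rows) + 1]] <- data.table::data.table(
          stratum = s, measure = paste0(what, "_band_", b), kind = "pct",
          numerator = sum(bands == b), denominator = length(v),
          value = pct_of(sum(bands == b), length(v)), sd = NA_real_)
      }
    }
  }
  data.table::rbindlist(rows)
}

#' Run the full post-fracture analysis pipeline
#'
#' Executes cohort construction, baseline profiling, six-month management
#' summaries, treatment-episode construction, subsequent-fracture
#' detection, and all aggregate tables.
#'
#' @param bundle A `claims_bundle`.
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return A list: `cohort`, `attrition`, `eligibility`, `events`,
#'   `baseline`, `management`, `episodes` (list from [build_episodes()]),
#'   `subsequent`, and the aggregates `table1` ... `table5` (`table4` =
#'   landmark treatment metrics, `table5` = landmark subsequent-fracture
#'   occurrence), plus `counts` per stage.
#' @export
run_pipeline <- function(bundle, registry = load_registry(),
                         config = analysis_config()) {
  cb <- build_cohort(bundle, registry, config)
  cohort <- cb$cohort
  baseline <- build_baseline(cohort, bundle, registry, config)
  mgmt <- summarize_management(cohort, bundle, registry, config)
  episodes <- build_episodes(cohort, bundle, registry, config)
  subsequent <- identify_subsequent(cb$events, cohort, config)
  subsequent <- subsequent[subsequent$member_id %in% cohort$member_id]

  res <- list(
    cohort = cohort, attrition = cb$attrition, eligibility = cb$eligibility,
    events = cb$events, baseline = baseline, management = mgmt,
    episodes = episodes, subsequent = subsequent,
    table1 = .table1(cohort, baseline, mgmt),
    table2 = .table2(cohort, baseline, mgmt),
    table3 = aggregate_table3(mgmt, cohort, baseline),
    table4 = aggregate_treatment(episodes, cohort, baseline, config),
    table5 = aggregate_subsequent(subsequent, cohort, baseline, config))
  res$counts <- data.table::data.table(
    stage = c("members", "indexed", "cohort", "baseline", "management",
              "episodes", "subsequent_events"),
    n = c(nrow(bundle$members), nrow(cb$eligibility), nrow(cohort),
          nrow(baseline), nrow(mgmt), nrow(episodes$episodes),
          nrow(subsequent)))
  res
}

#' Write pipeline reports to CSV
#'
#' Emits `attrition.csv`, `table1.csv` ... `table5.csv`, the member-level
#' files (`cohort.csv`, `baseline.csv`, `management.csv`, `episodes.csv`,
#' `subsequent.csv`) and a JSON run manifest with input digests and
#' per-stage row counts. Re-running on identical inputs produces
#' byte-identical tables.
#'
#' @param results Output of [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @param extra Optional named list merged into the manifest (e.g. seed).
#' @return Invisibly, the manifest list.
#' @export
emit_reports <- function(results, out_dir, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- c("attrition", "table1", "table2", "table3", "table4", "table5")
  for (nm in need) {
    if (is.null(results[[nm]])) stop_input("missing stage output: ", nm)
  }
  write1 <- function(dt, file) {
    dt <- data.table::as.data.table(dt)
    if ("value" %in% names(dt)) {
      dt <- data.table::copy(dt)
      if ("kind" %in% names(dt)) {
        dt[, display := ifelse(kind == "pct", .fmt_pct(value),
                               ifelse(is.na(value), NA_character_,
                                      sprintf("%.1f", round_half_up(value, 1))))]
      } else {
        dt[, display := .fmt_pct(value)]
      }
    }
    data.table::fwrite(dt, file.path(out_dir, file), na = "NA")
  }
  write1(results$attrition, "attrition.csv")
  for (k in 1:5) write1(results[[paste0("table", k)]], sprintf("table%d.csv", k))
  data.table::fwrite(results$cohort, file.path(out_dir, "cohort.csv"), na = "NA")
  data.table::fwrite(results$baseline, file.path(out_dir, "baseline.csv"), na = "NA")
  data.table::fwrite(results$management, file.path(out_dir, "management.csv"), na = "NA")
  data.table::fwrite(results$episodes$episodes, file.path(out_dir, "episodes.csv"), na = "NA")
  data.table::fwrite(results$subsequent, file.path(out_dir, "subsequent.csv"), na = "NA")

  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("fracturepathways")),
    stage_counts = stats::setNames(as.list(results$counts$n),
                                   results$counts$stage),
    file_digests = as.list(tools::md5sum(sort(files)))), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Digest of a claims bundle
#'
#' MD5 over the canonical CSV serialization of the four tables; identical
#' bundles give identical digests (used for run provenance).
#'
#' @param bundle A `claims_bundle`.
#' @return Named character vector of four MD5 digests.
#' @export
bundle_digest <- function(bundle) {
  vapply(names(BUNDLE_SCHEMAS), function(tbl) {
    f <- tempfile(fileext = ".csv")
    on.exit(unlink(f), add = TRUE)
    data.table::fwrite(bundle[[tbl]], f, na = "NA")
    unname(tools::md5sum(f))
  }, "")
}
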