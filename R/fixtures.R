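# Hand-built boundary fixtures exercising every rule edge: the 60- vs
# 61-day refill gap, day-90 vs day-91 same-site repeat fracture, all 36
# same-day two-site hierarchy pairs, a 1-day enrollment hole, index-day
# trauma, the non-melanoma skin cancer carve-out, and window edges at
# day 183.

.fx_member <- function(id, birth_year = 1950L, sex = "F") {
  data.table::data.table(member_id = id, sex = sex,
                         birth_year = as.integer(birth_year),
                         region = "South", payer = "Commercial",
                         plan_type = "PPO")
}

.fx_enroll <- function(id, start, end) {
  data.table::data.table(member_id = id, start_date = as.Date(start),
                         end_date = as.Date(end), medical = TRUE,
                         pharmacy = TRUE)
}

#' Adversarial boundary fixtures
#'
#' Builds a named list of tiny, fully deterministic claims bundles, each
#' engineered to sit exactly on one rule boundary, together with the
#' expected pipeline outcome. Used by the boundary test suite; exported so
#' users can inspect how each rule behaves at its edge.
#'
#' @param registry A [load_registry()] object.
#' @param config An [analysis_config()].
#' @return Named list; each element has `bundle` and `expected`.
#' @export
make_adversarial_fixtures <- function(registry = load_registry(),
                                      config = analysis_config()) {
  idx <- as.Date("2016-06-01")
  e_start <- idx - 400L
  e_end <- idx + 750L
  hip_dx <- .code1(registry$fracture_dx, "hip")
  obp <- .code1(registry$drug_class, "oral_BP")

  base_member <- function(id) list(
    members = .fx_member(id),
    enrollment = .fx_enroll(id, e_start, e_end),
    medical = .mc_rows(id, idx, "inpatient", dx = hip_dx,
                       admission = idx, discharge = idx + 3L))

  fx <- list()

  # --- refill gap boundary: supply ends day 29; a refill on day 90 (gap of
  # exactly 60) CONTINUES the run, which then ends at day 119 with no
  # re-initiation; a refill on day 91 (gap 61) discontinues the run at day
  # 29 and counts as a re-initiation ---------------------------------------
  for (case in c("gap60", "gap61")) {
    b <- base_member("G1")
    next_day <- if (case == "gap60") 90L else 91L
    rx <- .rx_rows(rep("G1", 2), idx + c(0L, next_day), obp, 30L)
    fx[[case]] <- list(
      bundle = claims_bundle(b$members, b$enrollment, b$medical, rx),
      expected = list(
        run1_end = if (case == "gap61") 29L else 119L,
        reinitiated = case == "gap61",
        reinit_day = if (case == "gap61") 91L else NA_integer_))
  }

  # --- same-site repeat at day 90 (rejected) vs 91 (accepted) -------------
  for (case in c("samesite_d90", "samesite_d91")) {
    b <- base_member("S1")
    d <- if (case == "samesite_d90") 90L else 91L
    rep_claim <- .mc_rows("S1", idx + d, "inpatient", dx = hip_dx,
                          admission = idx + d, discharge = idx + d + 1L)
    fx[[case]] <- list(
      bundle = claims_bundle(b$members, b$enrollment,
                             data.table::rbindlist(list(b$medical, rep_claim)),
                             .empty_rx()),
      expected = list(n_subsequent = if (case == "samesite_d91") 1L else 0L,
                      qualifying_reason = if (case == "samesite_d91")
                        "same_site_gt90" else NA_character_))
  }

  # --- all 36 same-day two-site pairs: lower hierarchy rank wins ----------
  sites <- registry$hierarchy
  pairs <- utils::combn(sites, 2)
  ids <- sprintf("H%02d", seq_len(ncol(pairs)))
  mc <- data.table::rbindlist(lapply(seq_len(ncol(pairs)), function(k) {
    .mc_rows(ids[k], idx, "inpatient",
             dx = paste(.code1(registry$fracture_dx, pairs[1, k]),
                        .code1(registry$fracture_dx, pairs[2, k]), sep = "|"),
             admission = idx, discharge = idx + 2L)
  }))
  fx$hierarchy_allpairs <- list(
    bundle = claims_bundle(.fx_member(ids), .fx_enroll(ids, e_start, e_end), mc,
                           .empty_rx()),
    expected = list(winner = stats::setNames(pairs[1, ], ids),
                    loser = stats::setNames(pairs[2, ], ids)))

  # --- 1-day enrollment hole in the pre-index year ------------------------
  hole <- idx - 100L
  enr <- data.table::rbindlist(list(.fx_enroll("E1", e_start, hole - 1L),
                                    .fx_enroll("E1", hole + 1L, e_end)))
  b <- base_member("E1")
  fx$enroll_hole_1day <- list(
    bundle = claims_bundle(b$members, enr, b$medical, .empty_rx()),
    expected = list(eligible = FALSE, exclusion_reason = "pre_index_enrollment"))

  # --- trauma diagnosis on the index date ---------------------------------
  b <- base_member("T1")
  trauma <- .mc_rows("T1", idx, "outpatient", dx = registry$trauma_dx[1])
  fx$trauma_index_day <- list(
    bundle = claims_bundle(b$members, b$enrollment,
                           data.table::rbindlist(list(b$medical, trauma)),
                           .empty_rx()),
    expected = list(eligible = FALSE, exclusion_reason = "trauma_same_day"))

  # --- cancer exclusion vs non-melanoma skin cancer carve-out -------------
  nmsc_code <- registry$nonmelanoma_skin_cancer_dx[1]
  cancer_code <- setdiff(
    names(registry$exclusion_dx)[registry$exclusion_dx == "cancer"],
    registry$nonmelanoma_skin_cancer_dx)[1]
  for (case in c("nmsc_carveout", "cancer_excluded")) {
    b <- base_member("C1")
    dx_code <- if (case == "nmsc_carveout") nmsc_code else cancer_code
    pre <- .mc_rows("C1", idx - 120L, "outpatient", dx = dx_code)
    fx[[case]] <- list(
      bundle = claims_bundle(b$members, b$enrollment,
                             data.table::rbindlist(list(b$medical, pre)),
                             .empty_rx()),
      expected = list(eligible = case == "nmsc_carveout",
                      exclusion_reason = if (case == "nmsc_carveout") ""
                      else "cancer_dx"))
  }

  # --- day-183 window edge: DME on day 183 counts, day 184 does not -------
  for (case in c("dme_d183", "dme_d184")) {
    b <- base_member("W1")
    d <- if (case == "dme_d183") 183L else 184L
    dme <- .mc_rows("W1", idx + d, "outpatient", proc = .code1(registry$dme, "walker"))
    fx[[case]] <- list(
      bundle = claims_bundle(b$members, b$enrollment,
                             data.table::rbindlist(list(b$medical, dme)),
                             .empty_rx()),
      expected = list(dme_6mo = case == "dme_d183"))
  }

  # --- post-index enrollment edge: exactly 183 days suffices, 182 fails ---
  for (case in c("fu_183", "fu_182")) {
    b <- base_member("F1")
    end <- idx + (if (case == "fu_183") 183L else 182L)
    fx[[case]] <- list(
      bundle = claims_bundle(b$members, .fx_enroll("F1", e_start, end),
                             b$medical, .empty_rx()),
      expected = list(eligible = case == "fu_183",
                      exclusion_reason = if (case == "fu_183") ""
                      else "post_index_enrollment"))
  }

  fx
}
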