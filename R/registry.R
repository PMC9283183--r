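# Code registry: maps raw diagnosis/procedure/drug codes to the semantic
# tags every rule consumes. Fully data-driven; the shipped default uses a
# synthetic vocabulary (see inst/extdata/registry_default.yaml).

#' The nine anatomic fracture sites, in hierarchy order
#'
#' Same-day multi-site events are resolved by this order: hip, femur, pelvis,
#' vertebral, humerus, radius/ulna, tibia/fibula, ankle, clavicle.
#' @export
fracture_sites <- function() {
  c("hip", "femur", "pelvis", "vertebral", "humerus",
    "radius_ulna", "tibia_fibula", "ankle", "clavicle")
}

#' Osteoporosis drug-class groupings
#'
#' Anabolic agents are teriparatide, abaloparatide and romosozumab;
#' antiresorptive agents are oral and IV bisphosphonates, denosumab, SERMs
#' and calcitonin. Together they are the osteoporosis (OP) medication
#' classes; everything else is non-OP.
#' @name op_classes
#' @export
anabolic_classes <- function() c("teriparatide", "abaloparatide", "romosozumab")

#' @rdname op_classes
#' @export
antiresorptive_classes <- function() c("oral_BP", "IV_BP", "denosumab", "SERM", "calcitonin")

#' @rdname op_classes
#' @export
op_med_classes <- function() c(anabolic_classes(), antiresorptive_classes())

non_op_classes <- function() {
  c("corticosteroid", "narcotic", "antidepressant", "muscle_relaxant",
    "tranquilizer", "sedative", "benzodiazepine", "anti_parkinson",
    "antihypertensive", "thyroid_agent")
}

# named-map helper: list(site = c(codes)) -> c(code = site)
.invert_code_map <- function(lst, what) {
  if (is.null(lst) || !length(lst)) return(stats::setNames(character(0), character(0)))
  codes <- unlist(lst, use.names = FALSE)
  tags <- rep(names(lst), lengths(lst))
  if (anyDuplicated(codes))
    stop_input("duplicate codes in ", what, ": ",
               paste(unique(codes[duplicated(codes)]), collapse = ", "))
  stats::setNames(tags, codes)
}

#' Load a code registry
#'
#' Reads a YAML registry mapping raw codes to semantic tags: fracture
#' diagnosis and fracture-treatment procedure codes per anatomic site,
#' evaluation-and-management (E&M) procedures, trauma diagnoses,
#' osteoporosis diagnoses, DXA and orthopedic-surgery procedures, durable
#' medical equipment (by subtype), rehabilitation codes, exclusionary
#' diagnoses (Paget's/other/metabolic bone disease, cancer with a
#' non-melanoma skin cancer carve-out), Charlson comorbidity index
#' categories with weights, comorbidity groups, and drug classes.
#'
#' @param path Registry file; `NULL` loads the packaged synthetic default.
#' @return A validated object of class `code_registry`.
#' @export
#' @examples
#' reg <- load_registry()
#' site_rank("hip", reg)
load_registry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "registry_default.yaml",
                        package = "fracturepathways", mustWork = TRUE)
  raw <- yaml::read_yaml(path)

  hierarchy <- as.character(raw$hierarchy %||% character(0))
  missing_sites <- setdiff(fracture_sites(), hierarchy)
  if (length(missing_sites))
    stop_input("registry hierarchy is missing site(s): ",
               paste(missing_sites, collapse = ", "))
  if (length(hierarchy) != 9L || anyDuplicated(hierarchy))
    stop_input("registry hierarchy must list each of the 9 sites exactly once")

  for (fld in c("fracture_dx", "fracture_proc")) {
    bad <- setdiff(names(raw[[fld]]), fracture_sites())
    if (length(bad))
      stop_input("unknown site(s) in ", fld, ": ", paste(bad, collapse = ", "))
  }

  drug_class_map <- .invert_code_map(raw$drug_class, "drug_class")
  known_classes <- c(op_med_classes(), non_op_classes())
  bad_classes <- setdiff(unique(unname(drug_class_map)), known_classes)
  if (length(bad_classes))
    stop_input("unknown drug class(es) in registry: ",
               paste(bad_classes, collapse = ", "))

  bad_excl <- setdiff(names(raw$exclusion_dx),
                      c("paget", "other_bone_disease", "metabolic_bone_disease", "cancer"))
  if (length(bad_excl))
    stop_input("unknown exclusion_dx reason(s): ", paste(bad_excl, collapse = ", "))

  cci <- raw$cci %||% list()
  cci_map <- if (length(cci)) {
    data.table::rbindlist(lapply(cci, function(row) {
      data.table::data.table(code = as.character(unlist(row$codes)),
                             category = as.character(row$category),
                             weight = as.numeric(row$weight))
    }))
  } else {
    data.table::data.table(code = character(0), category = character(0),
                           weight = numeric(0))
  }
  if (anyDuplicated(cci_map$code))
    stop_input("duplicate codes in cci map")

  reg <- list(
    hierarchy = hierarchy,
    fracture_dx = .invert_code_map(raw$fracture_dx, "fracture_dx"),
    fracture_proc = .invert_code_map(raw$fracture_proc, "fracture_proc"),
    em_proc = as.character(raw$em_proc %||% character(0)),
    trauma_dx = as.character(raw$trauma_dx %||% character(0)),
    op_dx = as.character(raw$op_dx %||% character(0)),
    dxa_proc = as.character(raw$dxa_proc %||% character(0)),
    ortho_surgery_proc = as.character(raw$ortho_surgery_proc %||% character(0)),
    dme = .invert_code_map(raw$dme, "dme"),
    rehab = as.character(raw$rehab %||% character(0)),
    exclusion_dx = .invert_code_map(raw$exclusion_dx, "exclusion_dx"),
    nonmelanoma_skin_cancer_dx = as.character(raw$nonmelanoma_skin_cancer_dx %||% character(0)),
    cci_map = cci_map,
    comorbidity_dx = .invert_code_map(raw$comorbidity_dx, "comorbidity_dx"),
    drug_class = drug_class_map
  )
  bad_dme <- setdiff(unique(unname(reg$dme)), c("walker", "wheelchair", "other"))
  if (length(bad_dme))
    stop_input("unknown DME subtype(s): ", paste(bad_dme, collapse = ", "))
  class(reg) <- "code_registry"
  reg
}

#' @export
print.code_registry <- function(x, ...) {
  cat("<code_registry>\n")
  cat(sprintf("  hierarchy: %s\n", paste(x$hierarchy, collapse = " > ")))
  cat(sprintf("  %d fracture dx, %d fracture proc, %d drug codes (%d classes)\n",
              length(x$fracture_dx), length(x$fracture_proc),
              length(x$drug_class), length(unique(unname(x$drug_class)))))
  invisible(x)
}

#' Classify drug codes
#'
#' Maps raw drug codes to their class and supergroup. Codes absent from the
#' registry are non-osteoporosis (`non_op`) by definition.
#'
#' @param drug_code Character vector of raw drug codes.
#' @param registry A [load_registry()] object.
#' @return A data.frame with columns `drug_code`, `class`, `supergroup`
#'   (`anabolic`, `antiresorptive` or `non_op`).
#' @export
classify_drug <- function(drug_code, registry) {
  cls <- unname(registry$drug_class[as.character(drug_code)])
  cls[is.na(cls)] <- "non_op"
  supergroup <- ifelse(cls %in% anabolic_classes(), "anabolic",
                ifelse(cls %in% antiresorptive_classes(), "antiresorptive", "non_op"))
  data.frame(drug_code = as.character(drug_code), class = cls,
             supergroup = supergroup, stringsAsFactors = FALSE)
}

#' Site hierarchy rank
#'
#' Rank 0 is the highest-priority site (hip); rank 8 the lowest (clavicle).
#' Used to resolve same-day multi-site fracture events.
#'
#' @param site Character vector of site names.
#' @param registry A [load_registry()] object.
#' @return Integer ranks.
#' @export
site_rank <- function(site, registry) {
  r <- match(as.character(site), registry$hierarchy) - 1L
  if (anyNA(r))
    stop_input("unknown site(s): ",
               paste(unique(site[is.na(r)]), collapse = ", "))
  r
}

#' Fracture-type grouping: hip / vertebral / NHNV
#'
#' NHNV (non-hip non-vertebral) comprises ankle, clavicle, femur, humerus,
#' pelvis, radius/ulna and tibia/fibula.
#'
#' @param site Character vector of site names.
#' @return Character vector in `{hip, vertebral, NHNV}`.
#' @export
site_group <- function(site) {
  site <- as.character(site)
  bad <- setdiff(unique(site), fracture_sites())
  if (length(bad)) stop_input("unknown site(s): ", paste(bad, collapse = ", "))
  ifelse(site == "hip", "hip", ifelse(site == "vertebral", "vertebral", "NHNV"))
}
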