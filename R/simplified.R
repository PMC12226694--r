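# Simplified two-level reading framework built from the three descriptors
# that drive malignancy in the pediatric cohort: peritoneal disease, lesion
# composition (purely cystic vs solid component) and intralesional fat.

#' Classify one lesion with the simplified pediatric reading framework
#'
#' Binary verdict derived from the predictors that carry the malignancy
#' signal in pediatric adnexal masses, applied in order:
#'
#' 1. no mass: likely benign;
#' 2. peritoneal disease: likely malignant;
#' 3. purely cystic (no fat, no solid tissue): likely benign;
#' 4. intralesional fat: likely malignant only when the enhancing component
#'    is large (>= [LARGE_ENHANCING_THRESHOLD] mm), otherwise likely benign;
#' 5. any other lesion (non-fatty with solid tissue): likely malignant.
#'
#' Rule 5 makes any solid tissue suffice, so dark-dark solid lesions —
#' which the full engine downgrades to class 2 — are still flagged likely
#' malignant: a deliberate, sensitivity-first choice for a pattern absent
#' from the validation cohort.
#'
#' @param f A [lesion_features()] object satisfying [validate_features()].
#' @return `"likely_benign"` or `"likely_malignant"`.
#' @export
classify_simplified <- function(f) {
  if (is.data.frame(f)) f <- record_features(f)
  v <- validate_features(f)
  if (length(v)) stop("invalid lesion features: ", v[1], call. = FALSE)

  if (!f$mass_present) return("likely_benign")
  if (.is_true(f$peritoneal_disease)) return("likely_malignant")
  if (!.is_true(f$fat_present) && !.is_true(f$solid_tissue_present))
    return("likely_benign")                       # purely cystic
  if (.is_true(f$fat_present)) {
    if (f$enhancing_component_diameter >= LARGE_ENHANCING_THRESHOLD)
      return("likely_malignant")
    return("likely_benign")
  }
  "likely_malignant"                              # non-fatty solid lesion
}

# Vectorised simplified framework; assumes validated records.
.simplify_records_vec <- function(records) {
  n <- nrow(records)
  if (n == 0) return(character(0))
  tt <- function(x) !is.na(x) & x

  mass  <- tt(records$mass_present)
  perit <- tt(records$peritoneal_disease)
  fat   <- tt(records$fat_present)
  solid <- tt(records$solid_tissue)

  lab <- rep(NA_character_, n)
  lab[!mass] <- "likely_benign"
  b <- is.na(lab) & perit
  lab[b] <- "likely_malignant"
  b <- is.na(lab) & !fat & !solid
  lab[b] <- "likely_benign"
  b <- is.na(lab) & fat
  lab[b] <- ifelse(records$enhancing_component_mm[b] >=
                     LARGE_ENHANCING_THRESHOLD,
                   "likely_malignant", "likely_benign")
  lab[is.na(lab)] <- "likely_malignant"
  lab
}

#' Annotate a cohort with simplified labels and risk groups
#'
#' Appends `simplified_label` (likely_benign / likely_malignant) and, when
#' an `orads_class` column is present or computable, `risk_group`
#' (low/high via [dichotomize_orads()]).
#'
#' @param records Data frame in the record schema.
#' @return `records` with `simplified_label` and `risk_group` columns.
#' @export
simplify_cohort <- function(records) {
  .check_record_frame(records)
  .stop_on_invalid(records)
  if (is.null(records$orads_class))
    records <- classify_cohort(records)
  records$simplified_label <- .simplify_records_vec(records)
  records$risk_group <- dichotomize_orads(records$orads_class)
  records
}
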