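# O-RADS MRI decision tree over structured lesion descriptors.
#
# Branch order is fixed and mutually exclusive: (1) no mass, (2) peritoneal
# disease, (3) intralesional fat, (4) solid tissue, (5) cystic. An earlier
# branch short-circuits everything after it, so descriptors irrelevant to
# the branch taken never influence the class.

#' Diameter (mm) at and above which an enhancing component within a
#' fat-containing lesion counts as "large" and routes the lesion to
#' O-RADS 5. The comparison is inclusive (>= 80 mm, i.e. >= 8 cm).
#' @export
LARGE_ENHANCING_THRESHOLD <- 80

#' Classify one lesion with the O-RADS MRI rule engine
#'
#' Deterministic decision tree returning an ordinal class 1-5 of increasing
#' malignancy likelihood:
#'
#' 1. no ovarian mass: class 1;
#' 2. peritoneal/mesenteric/omental nodularity or irregular thickening:
#'    class 5;
#' 3. intralesional fat: class 5 when the enhancing component is large
#'    (>= [LARGE_ENHANCING_THRESHOLD] mm), otherwise class 2;
#' 4. solid tissue: class 2 when "dark-dark" (homogeneously T2-hypointense
#'    and homogeneously without diffusion restriction), otherwise class 4
#'    for hypo/iso-enhancement and class 5 for hyperenhancement relative to
#'    the myometrium;
#' 5. cystic lesion: multilocular is class 3; a unilocular cyst is class 2
#'    for simple or endometriotic fluid, and otherwise class 3 with wall
#'    enhancement, class 2 without.
#'
#' @param f A [lesion_features()] object satisfying [validate_features()].
#' @return Integer O-RADS class in 1..5.
#' @examples
#' classify_orads(lesion_features(mass_present = FALSE))           # 1
#' classify_orads(lesion_features(TRUE, fat_present = TRUE,
#'                                enhancing_component_diameter = 90)) # 5
#' @export
classify_orads <- function(f) {
  if (is.data.frame(f)) f <- record_features(f)
  v <- validate_features(f)
  if (length(v)) stop("invalid lesion features: ", v[1], call. = FALSE)

  if (!f$mass_present) return(1L)
  if (.is_true(f$peritoneal_disease)) return(5L)
  if (.is_true(f$fat_present)) {
    if (f$enhancing_component_diameter >= LARGE_ENHANCING_THRESHOLD)
      return(5L)
    return(2L)
  }
  if (.is_true(f$solid_tissue_present)) {
    if (.is_dark_dark(f)) return(2L)
    if (f$enhancement_grade == "hypo_or_iso") return(4L)
    return(5L)
  }
  # cystic branch
  if (f$locularity == "multilocular") return(3L)
  if (f$fluid_type %in% c("simple", "endometriotic")) return(2L)
  if (.is_true(f$wall_enhancement)) return(3L)
  2L
}

# Vectorised engine over a record table; same tree, column arithmetic.
# Assumes records already validated.
.classify_records_vec <- function(records) {
  n <- nrow(records)
  if (n == 0) return(integer(0))
  tt <- function(x) !is.na(x) & x     # NA-as-FALSE truth

  mass  <- tt(records$mass_present)
  perit <- tt(records$peritoneal_disease)
  fat   <- tt(records$fat_present)
  solid <- tt(records$solid_tissue)
  dark  <- tt(records$t2_dark) & tt(records$dwi_no_restriction)

  cls <- rep(NA_integer_, n)
  cls[!mass] <- 1L
  b <- is.na(cls) & perit
  cls[b] <- 5L
  b <- is.na(cls) & fat
  cls[b] <- ifelse(records$enhancing_component_mm[b] >=
                     LARGE_ENHANCING_THRESHOLD, 5L, 2L)
  b <- is.na(cls) & solid
  cls[b] <- ifelse(dark[b], 2L,
                   ifelse(records$enhancement_grade[b] == "hypo_or_iso",
                          4L, 5L))
  b <- is.na(cls)   # cystic remainder
  multi  <- records$locularity[b] == "multilocular"
  benign_fluid <- records$fluid_type[b] %in% c("simple", "endometriotic")
  wall <- tt(records$wall_enhancement)[b]
  cls[b] <- ifelse(multi, 3L, ifelse(benign_fluid, 2L,
                                     ifelse(wall, 3L, 2L)))
  cls
}

#' Classify a cohort and tally classes
#'
#' Applies [classify_orads()] record-wise and appends an `orads_class`
#' column. The per-class tally (classes 1-5) is attached as attribute
#' `"tally"` and also available via [orads_tally()]. Raises, naming the
#' offending record id, if any record fails [validate_features()].
#'
#' @param records Data frame in the record schema.
#' @return `records` with an integer `orads_class` column appended.
#' @examples
#' cohort <- canonical_cohort()
#' tab <- orads_tally(classify_cohort(cohort))
#' tab   # 7 68 23 2 9
#' @export
classify_cohort <- function(records) {
  .check_record_frame(records)
  .stop_on_invalid(records)
  records$orads_class <- .classify_records_vec(records)
  attr(records, "tally") <- .tally(records$orads_class)
  records
}

.tally <- function(cls) {
  out <- vapply(1:5, function(k) sum(cls == k), integer(1))
  names(out) <- paste0("class", 1:5)
  out
}

#' Per-class tally of a classified cohort
#'
#' @param records Data frame with an `orads_class` column (see
#'   [classify_cohort()]).
#' @return Named integer vector `class1`..`class5` summing to `nrow(records)`.
#' @export
orads_tally <- function(records) {
  if (is.null(records$orads_class))
    stop("records carry no orads_class column; run classify_cohort() first")
  .tally(records$orads_class)
}

#' Dichotomize an O-RADS class into low/high malignancy risk
#'
#' Classes 1-3 are grouped as low risk, classes 4-5 as high risk.
#'
#' @param class Integer vector of O-RADS classes in 1..5.
#' @return Character vector, `"low"` or `"high"`.
#' @export
dichotomize_orads <- function(class) {
  if (any(is.na(class)) || !all(class %in% 1:5))
    stop("O-RADS classes must lie in 1..5")
  ifelse(class >= 4, "high", "low")
}
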