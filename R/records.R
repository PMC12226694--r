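# Record schema shared by every module: one row per patient, columns in a
# fixed order so CSV round-trips are bit-stable.

.record_columns <- c(
  "id", "age_years", "laterality", "mass_present", "peritoneal_disease",
  "fat_present", "enhancing_component_mm", "solid_tissue", "t2_dark",
  "dwi_no_restriction", "enhancement_grade", "locularity", "fluid_type",
  "wall_enhancement", "max_diameter_mm", "malignant", "histology",
  "reader2_class"
)

.logical_columns <- c(
  "mass_present", "peritoneal_disease", "fat_present", "solid_tissue",
  "t2_dark", "dwi_no_restriction", "wall_enhancement", "malignant"
)
.numeric_columns <- c("age_years", "enhancing_component_mm",
                      "max_diameter_mm", "reader2_class")

.enum_levels <- list(
  laterality        = c("left", "right"),
  enhancement_grade = c("hypo_or_iso", "hyper"),
  locularity        = c("unilocular", "multilocular"),
  fluid_type        = c("simple", "endometriotic", "hemorrhagic",
                        "proteinaceous")
)

#' Empty patient-record table
#'
#' Returns a zero-row data frame with the full record schema: identifier,
#' demographics, structured MRI descriptors, reference-standard malignancy
#' and the optional second-reader class. All downstream functions
#' (classification, statistics, I/O) consume and produce this layout.
#'
#' @return A zero-row `data.frame` with the 18 schema columns.
#' @export
empty_records <- function() {
  df <- data.frame(
    id = character(0), age_years = numeric(0), laterality = character(0),
    mass_present = logical(0), peritoneal_disease = logical(0),
    fat_present = logical(0), enhancing_component_mm = numeric(0),
    solid_tissue = logical(0), t2_dark = logical(0),
    dwi_no_restriction = logical(0), enhancement_grade = character(0),
    locularity = character(0), fluid_type = character(0),
    wall_enhancement = logical(0), max_diameter_mm = numeric(0),
    malignant = logical(0), histology = character(0),
    reader2_class = numeric(0),
    stringsAsFactors = FALSE
  )
  df[, .record_columns]
}

#' Structured MRI descriptors of one adnexal lesion
#'
#' Builds the descriptor set the rule engine consumes. Fields mirror the
#' O-RADS MRI lexicon: mass presence, peritoneal/mesenteric/omental
#' nodularity or irregular thickening (with or without ascites),
#' intralesional macroscopic fat with the maximum diameter of its enhancing
#' component, solid tissue with its T2 signal (homogeneously at or below
#' iliopsoas = "dark"), diffusion behaviour and myometrium-relative
#' enhancement grade, and for cystic lesions locularity, fluid type and
#' wall (parietal) enhancement.
#'
#' Absent optional findings are encoded as `NA`. For a present mass, an
#' `NA` in `peritoneal_disease`, `fat_present` or `solid_tissue_present` is
#' read as "finding not present"; the conditionally required descriptors
#' (see [validate_features()]) must be explicit.
#'
#' @param mass_present Is an ovarian mass detected?
#' @param peritoneal_disease Peritoneal, mesenteric or omental nodularity
#'   and/or irregular thickening (ascites alone does not qualify).
#' @param fat_present Intralesional macroscopic lipid on T1-based imaging.
#' @param enhancing_component_diameter Maximum diameter (mm) of enhancing
#'   tissue within a fat-containing lesion; required when `fat_present`.
#' @param solid_tissue_present Solid tissue per the lexicon (papillary
#'   projection, mural nodule, irregular wall/septum, larger solid portion;
#'   smooth enhancing walls/septa do not count).
#' @param t2_homogeneous_hypointense Solid tissue uniformly at or below
#'   iliopsoas intensity on T2; required when `solid_tissue_present`.
#' @param dwi_homogeneous_no_restriction Solid tissue homogeneously without
#'   diffusion restriction; required when `solid_tissue_present`.
#' @param enhancement_grade `"hypo_or_iso"` or `"hyper"` relative to outer
#'   myometrium; required for solid tissue that is not dark-dark.
#' @param locularity `"unilocular"` or `"multilocular"`; required for cystic
#'   lesions (mass without fat and without solid tissue).
#' @param fluid_type `"simple"`, `"endometriotic"`, `"hemorrhagic"` or
#'   `"proteinaceous"`; required for cystic lesions.
#' @param wall_enhancement Parietal enhancement; required for cystic lesions
#'   with non-simple fluid.
#' @param max_diameter Largest lesion dimension (mm), optional.
#' @return An object of class `lesion_features`.
#' @seealso [validate_features()], [classify_orads()], [classify_simplified()]
#' @examples
#' # fat-containing lesion with a 20-mm enhancing Rokitansky nodule
#' f <- lesion_features(mass_present = TRUE, fat_present = TRUE,
#'                      enhancing_component_diameter = 20)
#' classify_orads(f)
#' @export
lesion_features <- function(mass_present = FALSE,
                            peritoneal_disease = NA,
                            fat_present = NA,
                            enhancing_component_diameter = NA_real_,
                            solid_tissue_present = NA,
                            t2_homogeneous_hypointense = NA,
                            dwi_homogeneous_no_restriction = NA,
                            enhancement_grade = NA_character_,
                            locularity = NA_character_,
                            fluid_type = NA_character_,
                            wall_enhancement = NA,
                            max_diameter = NA_real_) {
  f <- list(
    mass_present = as.logical(mass_present),
    peritoneal_disease = as.logical(peritoneal_disease),
    fat_present = as.logical(fat_present),
    enhancing_component_diameter = as.numeric(enhancing_component_diameter),
    solid_tissue_present = as.logical(solid_tissue_present),
    t2_homogeneous_hypointense = as.logical(t2_homogeneous_hypointense),
    dwi_homogeneous_no_restriction = as.logical(dwi_homogeneous_no_restriction),
    enhancement_grade = as.character(enhancement_grade),
    locularity = as.character(locularity),
    fluid_type = as.character(fluid_type),
    wall_enhancement = as.logical(wall_enhancement),
    max_diameter = as.numeric(max_diameter)
  )
  structure(f, class = "lesion_features")
}

#' @export
print.lesion_features <- function(x, ...) {
  cat("Lesion features:\n")
  present <- !vapply(x, function(v) is.na(v), logical(1))
  for (nm in names(x)[present]) {
    cat(sprintf("  %-32s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}

# NA-tolerant truth test: absent boolean findings read as FALSE
.is_true <- function(x) !is.na(x) && isTRUE(x)

# A lesion is "cystic" in the structural sense when there is a mass but
# neither fat nor solid tissue; locularity/fluid descriptors then apply.
.is_cystic <- function(f) {
  .is_true(f$mass_present) && !.is_true(f$fat_present) &&
    !.is_true(f$solid_tissue_present)
}

.is_dark_dark <- function(f) {
  .is_true(f$t2_homogeneous_hypointense) &&
    .is_true(f$dwi_homogeneous_no_restriction)
}

#' Check lesion descriptors against the schema invariants
#'
#' Returns a character vector of violation messages, one per broken rule,
#' each naming the offending field; an empty vector means the descriptor set
#' is internally consistent and can be classified. Never raises.
#'
#' Rules enforced: without a mass no lesion-level descriptor (including
#' peritoneal disease) may be present; fat requires the enhancing-component
#' diameter; solid tissue requires explicit T2 and DWI homogeneity calls and,
#' unless dark-dark, an enhancement grade; cystic lesions require locularity
#' and fluid type, and non-simple fluid requires the wall-enhancement call;
#' diameters are non-negative with `max_diameter` at least the enhancing
#' component; enum fields must hold their allowed values. Descriptors
#' irrelevant to the branch actually taken (for example locularity supplied
#' for a fatty lesion) are ignored, not rejected.
#'
#' @param f A [lesion_features()] object (a record row coerced via
#'   [record_features()] also works).
#' @return Character vector of violations; `character(0)` when valid.
#' @export
validate_features <- function(f) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  if (is.na(f$mass_present)) {
    add("mass_present: must be TRUE or FALSE, not missing")
    return(v)
  }

  if (!is.na(f$enhancement_grade) &&
      !f$enhancement_grade %in% .enum_levels$enhancement_grade)
    add("enhancement_grade: must be 'hypo_or_iso' or 'hyper'")
  if (!is.na(f$locularity) && !f$locularity %in% .enum_levels$locularity)
    add("locularity: must be 'unilocular' or 'multilocular'")
  if (!is.na(f$fluid_type) && !f$fluid_type %in% .enum_levels$fluid_type)
    add("fluid_type: must be one of simple/endometriotic/hemorrhagic/proteinaceous")

  if (!f$mass_present) {
    if (.is_true(f$peritoneal_disease))
      add("peritoneal_disease: recorded TRUE without a mass")
    lesion_level <- c("fat_present", "enhancing_component_diameter",
                      "solid_tissue_present", "t2_homogeneous_hypointense",
                      "dwi_homogeneous_no_restriction", "enhancement_grade",
                      "locularity", "fluid_type", "wall_enhancement",
                      "max_diameter")
    for (nm in lesion_level) {
      val <- f[[nm]]
      if (!is.na(val) && !identical(val, FALSE))
        add(sprintf("%s: present although mass_present is FALSE", nm))
    }
    return(v)
  }

  if (.is_true(f$fat_present)) {
    if (is.na(f$enhancing_component_diameter))
      add("enhancing_component_diameter: required when fat_present")
    else if (f$enhancing_component_diameter < 0)
      add("enhancing_component_diameter: must be >= 0")
  }

  if (.is_true(f$solid_tissue_present) && !.is_true(f$fat_present)) {
    if (is.na(f$t2_homogeneous_hypointense))
      add("t2_homogeneous_hypointense: required when solid_tissue_present")
    if (is.na(f$dwi_homogeneous_no_restriction))
      add("dwi_homogeneous_no_restriction: required when solid_tissue_present")
    if (!is.na(f$t2_homogeneous_hypointense) &&
        !is.na(f$dwi_homogeneous_no_restriction) &&
        !.is_dark_dark(f) && is.na(f$enhancement_grade))
      add("enhancement_grade: required for solid tissue that is not dark-dark")
  }

  if (.is_cystic(f)) {
    if (is.na(f$locularity))
      add("locularity: required for cystic lesions")
    if (is.na(f$fluid_type)) {
      add("fluid_type: required for cystic lesions")
    } else if (f$fluid_type != "simple" && is.na(f$wall_enhancement)) {
      add("wall_enhancement: required for cystic lesions with non-simple fluid")
    }
  }

  if (!is.na(f$max_diameter) && f$max_diameter < 0)
    add("max_diameter: must be >= 0")
  if (!is.na(f$max_diameter) && !is.na(f$enhancing_component_diameter) &&
      f$max_diameter < f$enhancing_component_diameter)
    add("max_diameter: smaller than enhancing_component_diameter")

  v
}

#' Extract lesion features from one record row
#'
#' Maps the flat record columns (`mass_present`, `enhancing_component_mm`,
#' `solid_tissue`, `t2_dark`, ...) onto a [lesion_features()] object.
#'
#' @param record A one-row data frame in the record schema.
#' @return A `lesion_features` object.
#' @export
record_features <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1)
  lesion_features(
    mass_present = record$mass_present,
    peritoneal_disease = record$peritoneal_disease,
    fat_present = record$fat_present,
    enhancing_component_diameter = record$enhancing_component_mm,
    solid_tissue_present = record$solid_tissue,
    t2_homogeneous_hypointense = record$t2_dark,
    dwi_homogeneous_no_restriction = record$dwi_no_restriction,
    enhancement_grade = record$enhancement_grade,
    locularity = record$locularity,
    fluid_type = record$fluid_type,
    wall_enhancement = record$wall_enhancement,
    max_diameter = record$max_diameter_mm
  )
}

#' Validate every record of a cohort table
#'
#' @param records A data frame in the record schema.
#' @return A named list (by record id) of violation vectors; empty list when
#'   all records are valid.
#' @export
validate_records <- function(records) {
  .check_record_frame(records)
  out <- list()
  for (i in seq_len(nrow(records))) {
    v <- validate_features(record_features(records[i, , drop = FALSE]))
    if (length(v)) out[[as.character(records$id[i])]] <- v
  }
  out
}

.check_record_frame <- function(records) {
  if (!is.data.frame(records))
    stop("records must be a data.frame in the record schema")
  missing <- setdiff(.record_columns, names(records))
  if (length(missing))
    stop("records is missing schema columns: ", paste(missing, collapse = ", "))
  invisible(records)
}

.stop_on_invalid <- function(records) {
  bad <- validate_records(records)
  if (length(bad)) {
    id <- names(bad)[1]
    stop(sprintf("invalid record '%s': %s", id, bad[[1]][1]), call. = FALSE)
  }
  invisible(records)
}
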