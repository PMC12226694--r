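# Cohort-level validation statistics: malignancy proportions with
# confidence intervals by class, risk group and simplified label, plus
# median/IQR descriptives.

#' Median and interquartile range
#'
#' Percentiles use linear interpolation between order statistics
#' (`quantile(type = 7)`); conventions differ across software, so the choice
#' is fixed and documented here.
#'
#' @param values Numeric vector with at least one finite value.
#' @return Named numeric vector `median`, `q1`, `q3`.
#' @export
summarize_continuous <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1) stop("at least one finite value is required")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# One summary row: n, events, CI. Shared by all partitions.
.summary_row <- function(label, n, malignant, method, level) {
  ci <- if (n >= 1) binom_ci(malignant, n, level, method) else NULL
  data.frame(group = label, n = n, malignant = malignant,
             proportion = if (n >= 1) malignant / n else NA_real_,
             lower = if (n >= 1) ci$lower else NA_real_,
             upper = if (n >= 1) ci$upper else NA_real_,
             method = method, stringsAsFactors = FALSE)
}

.partition_summary <- function(records, key, labels, method, level) {
  if (nrow(records) == 0) stop("empty cohort")
  if (any(is.na(records$malignant)))
    stop("malignant status must be known for every record")
  rows <- lapply(labels, function(lab) {
    sel <- records[[key]] == lab
    .summary_row(as.character(lab), sum(sel),
                 sum(records$malignant[sel]), method, level)
  })
  do.call(rbind, rows)
}

#' Malignancy proportions per O-RADS class
#'
#' One row per class 1-5: size, malignant count, proportion with its
#' confidence interval. Records lacking an `orads_class` annotation are
#' classified first.
#'
#' @param records Record table with known `malignant` status.
#' @param method CI method, `"wilson"` (default) or `"clopper_pearson"`.
#' @param level Confidence level, default 0.95.
#' @return Data frame with one row per class; `n` sums to the cohort size.
#' @export
malignancy_by_class <- function(records,
                                method = c("wilson", "clopper_pearson"),
                                level = 0.95) {
  method <- match.arg(method)
  .check_record_frame(records)
  if (is.null(records$orads_class)) records <- classify_cohort(records)
  out <- .partition_summary(records, "orads_class", 1:5, method, level)
  out$group <- paste0("orads_", out$group)
  out
}

#' Malignancy proportions by risk group and simplified label
#'
#' Rows for the low (classes 1-3) and high (classes 4-5) risk groups,
#' followed by likely-benign / likely-malignant rows of the simplified
#' framework. Missing annotations are computed on the fly.
#'
#' @inheritParams malignancy_by_class
#' @return Data frame with four rows: low, high, likely_benign,
#'   likely_malignant.
#' @export
risk_group_summary <- function(records,
                               method = c("wilson", "clopper_pearson"),
                               level = 0.95) {
  method <- match.arg(method)
  .check_record_frame(records)
  if (nrow(records) == 0) stop("empty cohort")
  if (is.null(records$risk_group) || is.null(records$simplified_label))
    records <- simplify_cohort(records)
  rbind(
    .partition_summary(records, "risk_group", c("low", "high"),
                       method, level),
    .partition_summary(records, "simplified_label",
                       c("likely_benign", "likely_malignant"),
                       method, level)
  )
}

#' Full validation report for a classified cohort
#'
#' Bundles the per-class table, risk-group and simplified-label tables,
#' descriptive summaries (age, lesion size, laterality), inter-reader
#' weighted kappa when a second-reader column is populated, and Firth
#' predictor screening when requested.
#'
#' @inheritParams malignancy_by_class
#' @param predictors Predictor set for [screen_predictors()], or `NULL` to
#'   skip the regression.
#' @return An `orads_validation` object (list of tables) with a print
#'   method.
#' @export
validation_report <- function(records,
                              method = c("wilson", "clopper_pearson"),
                              level = 0.95,
                              predictors = c("peritoneal_disease",
                                             "composition", "fat_present",
                                             "age_years", "max_diameter_mm",
                                             "locularity", "fluid_type")) {
  method <- match.arg(method)
  .check_record_frame(records)
  if (any(is.na(records$malignant)))
    stop("malignant status must be known for every record")
  records <- simplify_cohort(records)

  lesions <- records[records$mass_present, , drop = FALSE]
  kappa <- NULL
  if (any(!is.na(records$reader2_class))) {
    both <- !is.na(records$reader2_class)
    kappa <- weighted_kappa(records$orads_class[both],
                            records$reader2_class[both], categories = 1:5)
  }
  effects <- if (!is.null(predictors)) screen_predictors(records, predictors)

  structure(list(
    per_class = malignancy_by_class(records, method, level),
    groups = risk_group_summary(records, method, level),
    age = summarize_continuous(records$age_years),
    size = if (any(is.finite(lesions$max_diameter_mm)))
      summarize_continuous(lesions$max_diameter_mm),
    laterality = table(factor(lesions$laterality, c("left", "right"))),
    kappa = kappa,
    predictors = effects,
    n = nrow(records), level = level, method = method
  ), class = "orads_validation")
}

#' @export
print.orads_validation <- function(x, ...) {
  fmt <- function(df) {
    df$proportion <- sprintf("%d%%", .round_half_up(100 * df$proportion))
    df$ci <- sprintf("%d-%d%%", .round_half_up(100 * df$lower),
                     .round_half_up(100 * df$upper))
    df[, c("group", "n", "malignant", "proportion", "ci")]
  }
  cat(sprintf("O-RADS validation report (n = %d, %s %d%% CIs)\n\n",
              x$n, x$method, round(100 * x$level)))
  cat("Malignancy by O-RADS class:\n")
  print(fmt(x$per_class), row.names = FALSE)
  cat("\nRisk groups and simplified labels:\n")
  print(fmt(x$groups), row.names = FALSE)
  cat(sprintf("\nAge, years: median %g (IQR %g-%g)\n",
              x$age["median"], x$age["q1"], x$age["q3"]))
  if (!is.null(x$size))
    cat(sprintf("Lesion size, mm: median %g (IQR %g-%g)\n",
                x$size["median"], x$size["q1"], x$size["q3"]))
  if (!is.null(x$kappa)) {
    cat("\nInter-reader agreement: ")
    print(x$kappa)
  }
  if (!is.null(x$predictors)) {
    cat("\nPredictor screening (Firth penalized logistic regression):\n")
    tab <- x$predictors[, c("name", "estimate", "std_error", "p_value")]
    tab[-1] <- round(tab[-1], 4)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

# JSON form of the report, used by the validate CLI command.
.validation_as_list <- function(x) {
  out <- list(
    n = x$n, method = x$method, level = x$level,
    per_class = x$per_class, groups = x$groups,
    age = as.list(x$age)
  )
  if (!is.null(x$size)) out$size <- as.list(x$size)
  out$laterality <- as.list(x$laterality)
  if (!is.null(x$kappa))
    out$kappa <- list(kappa = x$kappa$kappa, weighting = x$kappa$weighting,
                      n = x$kappa$n)
  if (!is.null(x$predictors))
    out$predictors <- x$predictors
  out
}
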