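#' Variable-level quality-control filtering
#'
#' Drops variables in three passes, in this order: (1) variables named in
#' `name_excluded`; (2) variables with strictly more than
#' `missing_threshold` missing entries; (3) variables whose modal observed
#' value is shared by strictly more than `identical_threshold` subjects
#' ("little variance").  Missing cells never count toward the modal value.
#' The input is not modified.
#'
#' The defaults (200 missing / 800 identical) are the thresholds used for
#' cohort tables of roughly a thousand subjects; scale them to your sample.
#'
#' @param t A [subject_table].
#' @param missing_threshold Drop a variable when its missing count exceeds
#'   this.
#' @param identical_threshold Drop a variable when more subjects than this
#'   share one observed value.
#' @param name_excluded Character vector of variable names to drop outright;
#'   unknown names are an error.
#' @return A list with the filtered `table` and a `report` (class
#'   `qc_report`) listing every dropped variable with its reason.
#' @seealso [filter_subjects()], [qc_pipeline()]
#' @export
filter_variables <- function(t, missing_threshold = 200,
                             identical_threshold = 800,
                             name_excluded = character(0)) {
  stopifnot(inherits(t, "subject_table"))
  if (missing_threshold <= 0 || identical_threshold <= 0)
    stop("thresholds must be positive")
  unknown <- setdiff(name_excluded, t$var_names)
  if (length(unknown) > 0)
    stop("name_excluded contains unknown variable(s): ",
         paste(unknown, collapse = ", "))

  keep <- setdiff(t$var_names, name_excluded)
  v <- t$values[, keep, drop = FALSE]

  n_missing <- colSums(is.na(v))
  drop_missing <- colnames(v)[n_missing > missing_threshold]
  keep <- setdiff(keep, drop_missing)
  v <- t$values[, keep, drop = FALSE]

  modal_count <- apply(v, 2, function(col) {
    col <- col[!is.na(col)]
    if (length(col) == 0) 0L else max(tabulate(match(col, unique(col))))
  })
  drop_lowvar <- colnames(v)[modal_count > identical_threshold]
  keep <- setdiff(keep, drop_lowvar)

  out <- subject_table(t$values[, keep, drop = FALSE])
  report <- structure(list(
    dropped_vars_by_name = as.character(name_excluded),
    dropped_vars_missing = as.character(drop_missing),
    dropped_vars_low_variance = as.character(drop_lowvar),
    dropped_subjects = character(0),
    n_vars_retained = length(keep),
    n_subjects_retained = nrow(out$values)), class = "qc_report")
  list(table = out, report = report)
}

#' Subject-level quality-control filtering
#'
#' Removes every subject with at least one missing value among the retained
#' variables; the order of the remaining subjects is preserved.
#'
#' @param t A [subject_table] (typically the output of
#'   [filter_variables()]).
#' @return A list with the filtered `table` and a `report` (class
#'   `qc_report`).
#' @export
filter_subjects <- function(t) {
  stopifnot(inherits(t, "subject_table"))
  bad <- rowSums(is.na(t$values)) > 0
  if (all(bad))
    stop("all ", nrow(t$values), " subjects have missing values; ",
         "nothing would remain")
  out <- subject_table(t$values[!bad, , drop = FALSE])
  report <- structure(list(
    dropped_vars_by_name = character(0),
    dropped_vars_missing = character(0),
    dropped_vars_low_variance = character(0),
    dropped_subjects = t$subject_ids[bad],
    n_vars_retained = ncol(out$values),
    n_subjects_retained = nrow(out$values)), class = "qc_report")
  list(table = out, report = report)
}

#' Full quality-control pipeline
#'
#' [filter_variables()] followed by [filter_subjects()], with the two
#' reports merged.
#'
#' @inheritParams filter_variables
#' @return A list with the filtered `table` and a merged `report`.
#' @export
qc_pipeline <- function(t, missing_threshold = 200, identical_threshold = 800,
                        name_excluded = character(0)) {
  fv <- filter_variables(t, missing_threshold, identical_threshold,
                         name_excluded)
  fs <- filter_subjects(fv$table)
  report <- fv$report
  report$dropped_subjects <- fs$report$dropped_subjects
  report$n_subjects_retained <- fs$report$n_subjects_retained
  list(table = fs$table, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  cat("  dropped by name:        ", length(x$dropped_vars_by_name), "\n")
  cat("  dropped (missing):      ", length(x$dropped_vars_missing), "\n")
  cat("  dropped (low variance): ", length(x$dropped_vars_low_variance), "\n")
  cat("  dropped subjects:       ", length(x$dropped_subjects), "\n")
  cat("  retained:               ", x$n_subjects_retained, "subjects x",
      x$n_vars_retained, "variables\n")
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' Z-score standardization of a subject table
#'
#' Centers every column to mean zero and scales it to unit sample variance
#' (denominator n - 1).  Standardization is applied once to the raw
#' variables before PCA and again to the PC scores before CCA ("double
#' standardization").
#'
#' @param t A [subject_table] or numeric matrix without missing values.
#' @return A [subject_table] of the same shape.  The column means and
#'   standard deviations used are attached as attributes `center` and
#'   `scale` for projecting new subjects.
#' @export
zscore <- function(t) {
  v <- as_values(t)
  if (anyNA(v))
    stop("zscore requires a complete table; run the QC filters first")
  mu <- colMeans(v)
  sdev <- apply(v, 2, stats::sd)
  zero <- sdev < .Machine$double.eps
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(v)[zero], collapse = ", "))
  z <- sweep(sweep(v, 2, mu, "-"), 2, sdev, "/")
  out <- subject_table(z)
  attr(out, "center") <- mu
  attr(out, "scale") <- sdev
  out
}
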