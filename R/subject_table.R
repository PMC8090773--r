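#' Subject-by-variable table
#'
#' The basic data container of the package: a numeric matrix of subjects
#' (rows) by variables (columns), with `NA` marking missing cells.  Both the
#' imaging-measure set and the subject-measure set of a CCA are held in this
#' form.
#'
#' @param values Numeric matrix (subjects x variables); `NA` = missing.
#' @param var_names Character vector of unique variable names; defaults to
#'   the column names of `values`.
#' @param subject_ids Character vector of unique subject identifiers;
#'   defaults to the row names of `values`, or `"s0001"`-style ids.
#'
#' @return An object of class `subject_table` with elements `values`
#'   (the matrix, dimnames set), `var_names` and `subject_ids`.
#' @seealso [missing_mask()], [read_subject_table()], [write_subject_table()]
#' @export
subject_table <- function(values, var_names = colnames(values),
                          subject_ids = rownames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(var_names))
    var_names <- sprintf("v%03d", seq_len(ncol(values)))
  if (is.null(subject_ids))
    subject_ids <- sprintf("s%04d", seq_len(nrow(values)))
  var_names <- as.character(var_names)
  subject_ids <- as.character(subject_ids)
  if (length(var_names) != ncol(values))
    stop("var_names length (", length(var_names),
         ") does not match number of columns (", ncol(values), ")")
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length (", length(subject_ids),
         ") does not match number of rows (", nrow(values), ")")
  if (anyDuplicated(var_names))
    stop("duplicated variable names: ",
         paste(unique(var_names[duplicated(var_names)]), collapse = ", "))
  if (anyDuplicated(subject_ids))
    stop("duplicated subject ids: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "))
  dimnames(values) <- list(subject_ids, var_names)
  structure(list(values = values, var_names = var_names,
                 subject_ids = subject_ids),
            class = "subject_table")
}

#' Missing-value mask of a subject table
#'
#' @param t A [subject_table].
#' @return Logical matrix, `TRUE` where a cell is missing.
#' @export
missing_mask <- function(t) {
  stopifnot(inherits(t, "subject_table"))
  is.na(t$values)
}

#' @export
print.subject_table <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat("subject_table: ", nrow(x$values), " subjects x ",
      ncol(x$values), " variables", sep = "")
  if (n_miss > 0) cat(" (", n_miss, " missing cells)", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
dim.subject_table <- function(x) dim(x$values)

#' Subset a subject table
#'
#' @param x A [subject_table].
#' @param i Subject (row) index.
#' @param j Variable (column) index.
#' @param ... Unused.
#' @return A [subject_table] restricted to the selected subjects/variables.
#' @export
`[.subject_table` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  subject_table(v)
}

#' Read a subject table from CSV
#'
#' Expects the package's CSV dialect: comma-separated, UTF-8, header row of
#' variable names, first column `subject_id`, empty cells for missing values.
#'
#' @param path Path to a CSV file.
#' @return A [subject_table].
#' @export
read_subject_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "",
                        colClasses = c(subject_id = "character"))
  if (names(df)[1] != "subject_id")
    stop("first column of ", path, " must be 'subject_id', found '",
         names(df)[1], "'")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  subject_table(m, var_names = names(df)[-1], subject_ids = ids)
}

#' Write a subject table to CSV
#'
#' Missing cells are written as empty fields so the file round-trips through
#' [read_subject_table()].
#'
#' @param t A [subject_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(t, path) {
  stopifnot(inherits(t, "subject_table"))
  df <- data.frame(subject_id = t$subject_ids, t$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# Internal: coerce subject_table or matrix to a plain numeric matrix.
as_values <- function(x) {
  if (inherits(x, "subject_table")) x$values else as.matrix(x)
}

# Internal: deterministic seed mixing on the Lehmer group mod 2^31-1, so that
# derived seeds stay valid 32-bit integers and per-unit streams (pairs, cells,
# permutations) are reproducible independently of execution order.
mix_seed <- function(a, b) {
  m <- 2147483647
  s <- (abs(as.numeric(a)) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + (abs(as.numeric(b)) %% m) * 16807) %% m
  as.integer(s %% (m - 1) + 1)
}

# Internal: run expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
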