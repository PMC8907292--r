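#' Expression matrix container
#'
#' An `expr_matrix` is a dense numeric matrix of non-negative expression
#' levels with features (e.g. mature miRNAs) in rows and samples in columns.
#' Values flagged as not detected are stored as `NA`. Row and column names
#' are mandatory and must be unique; they are the feature and sample
#' identifiers used throughout the package.
#'
#' @param values numeric matrix, features x samples.
#' @param feature_ids,sample_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @return An `expr_matrix` object (a classed numeric matrix).
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(paste0("miR-", 1:3), c("s1", "s2"))))
#' dim(m)
#' @export
expr_matrix <- function(values, feature_ids = NULL, sample_ids = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x samples).")
  }
  if (!is.null(feature_ids)) rownames(values) <- feature_ids
  if (!is.null(sample_ids)) colnames(values) <- sample_ids
  validate_expr_matrix(values)
  structure(values, class = c("expr_matrix", "matrix", "array"))
}

validate_expr_matrix <- function(values) {
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    abort("expression matrix needs feature (row) and sample (column) names.")
  }
  if (anyDuplicated(fid)) {
    abort(paste0("duplicated feature id(s): ",
                 paste(unique(fid[duplicated(fid)]), collapse = ", ")))
  }
  if (anyDuplicated(sid)) {
    abort(paste0("duplicated sample id(s): ",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  }
  ok <- is.na(values) | (is.finite(values) & values >= 0)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "expression values must be finite and >= 0 (or NA); offending cell [%s, %s]",
      fid[bad[1]], sid[bad[2]]))
  }
  invisible(values)
}

#' @exportS3Method base::print
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, %d missing value(s)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(head(unclass(x)[, seq_len(min(ncol(x), 5L)), drop = FALSE], 5L))
  invisible(x)
}

#' Tidy an expression matrix into long format
#'
#' @param x an [expr_matrix()].
#' @param ... unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `value`.
#' @export
tidy.expr_matrix <- function(x, ...) {
  tibble(
    feature_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}

#' Read a delimited expression table
#'
#' Reads a TSV/CSV file with one header row and one id column into an
#' [expr_matrix()]. By default rows are features and columns are samples;
#' set `orientation = "samples"` for a transposed (sample-rows) file.
#' Cells that are empty or `NA` are flagged missing (not detected).
#'
#' @param path file path; delimiter is inferred from the extension
#'   (`.csv` = comma, otherwise tab) unless `delim` is given.
#' @param orientation `"features"` (default) if rows are features,
#'   `"samples"` if rows are samples.
#' @param delim optional field delimiter.
#' @return An [expr_matrix()].
#' @export
read_expression <- function(path, orientation = c("features", "samples"),
                            delim = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2L) abort("expression table needs an id column plus data.")
  ids <- as.character(df[[1L]])
  num <- df[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    col <- num[[j]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & col != "NA" & col != "" & is.na(parsed))
      if (length(bad)) {
        abort(sprintf("malformed numeric cell at row %d, column '%s': '%s'",
                      bad[1L], names(num)[j], col[bad[1L]]))
      }
      num[[j]] <- parsed
    }
  }
  values <- as.matrix(num)
  rownames(values) <- ids
  if (orientation == "samples") values <- t(values)
  expr_matrix(values)
}

#' Write an expression matrix to a delimited file
#'
#' Inverse of [read_expression()]: feature rows, sample columns, first
#' column `feature_id`. Missing values are written as `NA`.
#'
#' @param x an [expr_matrix()].
#' @param path output path; `.csv` selects comma, otherwise tab.
#' @param delim optional field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, delim = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- tibble::as_tibble(unclass(x), rownames = "feature_id")
  readr::write_delim(df, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read a survival or follow-up cohort table
#'
#' Expects a delimited file with columns sample id, time and optionally a
#' follow-up flag (1/TRUE = right-censored follow-up time, 0/FALSE =
#' observed survival time). Times are converted to years at ingest.
#'
#' @param path file path.
#' @param time_unit `"years"` or `"months"`; the unit of the time column.
#' @param delim optional field delimiter (inferred from extension otherwise).
#' @return A tibble with columns `sample_id`, `time_years`, `is_followup`.
#' @export
read_cohort <- function(path, time_unit = c("years", "months"), delim = NULL) {
  time_unit <- match.arg(time_unit)
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  if (ncol(df) < 2L) abort("cohort table needs sample id and time columns.")
  out <- tibble(
    sample_id = as.character(df[[1L]]),
    time_years = as.numeric(df[[2L]]),
    is_followup = if (ncol(df) >= 3L) as.logical(df[[3L]]) else FALSE
  )
  if (time_unit == "months") out$time_years <- months_to_years(out$time_years)
  validate_survival_cohort(out)
  out
}

validate_survival_cohort <- function(cohort) {
  stopifnot(all(c("sample_id", "time_years") %in% names(cohort)))
  if (anyDuplicated(cohort$sample_id)) abort("duplicated sample id in cohort.")
  if (any(!is.finite(cohort$time_years)) || any(cohort$time_years <= 0)) {
    abort("cohort times must be finite and > 0.")
  }
  invisible(cohort)
}

#' Read a tumor/normal label table
#'
#' @param path delimited file with sample id and label columns.
#' @param delim optional field delimiter.
#' @return A tibble with columns `sample_id`, `label` (factor, two levels).
#' @export
read_labels <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                          progress = FALSE, show_col_types = FALSE)
  out <- tibble(sample_id = as.character(df[[1L]]),
                label = factor(as.character(df[[2L]])))
  if (anyDuplicated(out$sample_id)) abort("duplicated sample id in labels.")
  if (nlevels(out$label) != 2L) abort("label table must have exactly two classes.")
  out
}

#' Filter features by presence across samples
#'
#' Keeps a feature iff it is present — non-missing and strictly positive —
#' in strictly more than `threshold` of the samples. With the default 0.7
#' this is the "detected in more than 70% of samples" convention used for
#' miRNA-seq candidate pools. Feature order and the sample set are
#' preserved.
#'
#' @param x an [expr_matrix()].
#' @param threshold presence fraction in `[0, 1)`; strict inequality.
#' @return A filtered [expr_matrix()].
#' @export
filter_present <- function(x, threshold = 0.7) {
  stopifnot(inherits(x, "expr_matrix"))
  if (nrow(x) == 0L || ncol(x) == 0L) abort("empty expression matrix.")
  if (!is.numeric(threshold) || threshold < 0 || threshold >= 1) {
    abort("`threshold` must lie in [0, 1).")
  }
  present <- !is.na(x) & x > 0
  keep <- rowSums(present) / ncol(x) > threshold
  if (!any(keep)) abort("presence filter removed every feature.")
  expr_matrix(unclass(x)[keep, , drop = FALSE])
}

#' Impute missing expression values
#'
#' Missing (not-detected) cells surviving the presence filter are set to a
#' constant before modelling; the default 0 matches the read-count reading
#' of missingness.
#'
#' @param x an [expr_matrix()].
#' @param value replacement for `NA` cells.
#' @return An [expr_matrix()] with no missing values.
#' @export
impute_missing <- function(x, value = 0) {
  stopifnot(inherits(x, "expr_matrix"))
  v <- unclass(x)
  v[is.na(v)] <- value
  expr_matrix(v)
}

#' Align an expression matrix with a cohort table
#'
#' Restricts both to the (sorted) intersection of sample ids so rows of the
#' cohort correspond to columns of the matrix. Applying `align_cohort`
#' twice is a no-op.
#'
#' @param x an [expr_matrix()].
#' @param cohort a tibble with a `sample_id` column (survival or label).
#' @return A list with elements `expression` and `cohort`.
#' @export
align_cohort <- function(x, cohort) {
  stopifnot(inherits(x, "expr_matrix"), "sample_id" %in% names(cohort))
  shared <- sort(intersect(colnames(x), cohort$sample_id))
  if (length(shared) == 0L) abort("no shared sample ids between matrix and cohort.")
  xx <- expr_matrix(unclass(x)[, shared, drop = FALSE])
  cc <- cohort[match(shared, cohort$sample_id), , drop = FALSE]
  list(expression = xx, cohort = cc)
}

#' Convert between months and years
#'
#' Exact scaling by 12; the package's internal time unit is years.
#'
#' @param t positive times.
#' @return Converted times.
#' @export
months_to_years <- function(t) {
  if (any(!is.finite(t)) || any(t <= 0)) abort("times must be finite and > 0.")
  t / 12
}

#' @rdname months_to_years
#' @export
years_to_months <- function(t) {
  if (any(!is.finite(t)) || any(t <= 0)) abort("times must be finite and > 0.")
  t * 12
}
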