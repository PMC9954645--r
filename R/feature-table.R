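#' Construct a feature table
#'
#' The basic data container: a numeric matrix of subjects x itemized scores,
#' with unique sample ids, unique feature names, and an optional integer label
#' vector coding diagnosis as 0 = NC, 1 = MCI, 2 = AD (class indices
#' `0..n_classes-1` in general).
#'
#' @param values Numeric matrix, one row per sample, one column per feature.
#' @param sample_ids Character vector of unique row ids (default "s1", "s2", ...).
#' @param feature_names Character vector of unique column names.
#' @param labels Optional integer vector of class indices in `0..n_classes-1`.
#' @param n_classes Number of classes the labels may take (default 3).
#' @return An object of class `feature_table` with elements `values`,
#'   `sample_ids`, `feature_names`, `labels`, `n_classes`.
#' @export
feature_table <- function(values, sample_ids = NULL, feature_names = NULL,
                          labels = NULL, n_classes = 3L) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  if (is.null(feature_names)) feature_names <- colnames(values)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(p))
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (length(sample_ids) != n) stop_field("sample_ids", "length must equal nrow(values)")
  if (anyDuplicated(sample_ids)) stop_field("sample_ids", "ids must be unique")
  if (length(feature_names) != p) stop_field("feature_names", "length must equal ncol(values)")
  if (anyDuplicated(feature_names)) stop_field("feature_names", "names must be unique")
  if (any(!is.finite(values)))
    stop_field("values", "non-finite entries present; impute or drop them before constructing the table")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  if (!is.null(labels)) {
    if (length(labels) != n) stop_field("labels", "length must equal nrow(values)")
    if (any(is.na(labels)) || any(labels != as.integer(labels)))
      stop_field("labels", "must be integers")
    labels <- as.integer(labels)
    if (any(labels < 0L | labels >= n_classes))
      stop_field("labels", sprintf("values must lie in 0..%d", n_classes - 1L))
  }
  dimnames(values) <- list(sample_ids, feature_names)
  structure(
    list(values = values, sample_ids = sample_ids,
         feature_names = feature_names, labels = labels,
         n_classes = n_classes),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d features; labels %s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "absent"
              else paste0("present (", paste(table(factor(x$labels, levels = 0:(x$n_classes - 1))),
                                             collapse = "/"), " per class 0..", x$n_classes - 1, ")")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Read a feature table from CSV
#'
#' Expects a header row; the first column is taken as the sample id when named
#' `sample_id`, otherwise ids are generated. All remaining columns except the
#' label column must be numeric.
#'
#' @param path Path to a CSV file.
#' @param label_column Name of the label column, or `NULL` for an unlabeled
#'   table. A named column absent from the file is treated as `NULL`.
#' @param impute How to handle missing cells: `"error"` (default) rejects the
#'   file naming the offending row and column; `"mean"` replaces missing values
#'   with the column mean.
#' @param n_classes Number of classes for label validation (default 3).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, label_column = "label",
                               impute = c("error", "mean"), n_classes = 3L) {
  impute <- match.arg(impute)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1L) stop("empty CSV: ", path, call. = FALSE)
  ids <- NULL
  if (names(df)[1L] == "sample_id") {
    ids <- as.character(df[[1L]])
    df <- df[, -1L, drop = FALSE]
  }
  labels <- NULL
  if (!is.null(label_column) && label_column %in% names(df)) {
    labels <- df[[label_column]]
    df <- df[, setdiff(names(df), label_column), drop = FALSE]
  }
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]]))
      stop(sprintf("non-numeric values in feature column '%s'", names(df)[j]), call. = FALSE)
  }
  m <- as.matrix(df)
  if (anyNA(m)) {
    if (impute == "error") {
      idx <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at row %d, column '%s' (imputation is off)",
                   idx[1L], colnames(m)[idx[2L]]), call. = FALSE)
    }
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- mean(m[!nas, j])
    }
  }
  feature_table(m, sample_ids = ids, labels = labels, n_classes = n_classes)
}

#' Write a feature table to CSV
#'
#' Writes a header row, a leading `sample_id` column, one column per feature,
#' and (when present) a trailing `label` column.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = table$sample_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$labels)) df$label <- table$labels
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Standardize features to zero mean and unit standard deviation
#'
#' Rescales every feature column by z-scoring with the population standard
#' deviation (divide by n). When `stats` is supplied (fitted on training
#' data), those statistics are reused so that test folds never contribute to
#' the scaling. Constant features are mapped to all-zero columns.
#'
#' Pearson correlations with any target are unchanged by this transform, so
#' standardization may be applied before or after feature ranking.
#'
#' @param table A [feature_table()].
#' @param stats Optional list with elements `center` and `scale` as returned by
#'   a previous call; when `NULL`, statistics are fitted on `table`.
#' @return A list with elements `table` (the standardized [feature_table()])
#'   and `stats` (the statistics used, reusable on held-out data).
#' @export
standardize_features <- function(table, stats = NULL) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$values
  if (is.null(stats)) {
    if (nrow(x) < 2L) stop("need at least 2 rows to fit standardization statistics", call. = FALSE)
    center <- colMeans(x)
    scale <- sqrt(colMeans(sweep(x, 2L, center)^2)) # population SD
    stats <- list(center = center, scale = scale)
  } else {
    if (!all(c("center", "scale") %in% names(stats)))
      stop_field("stats", "must contain `center` and `scale`")
    if (length(stats$center) != ncol(x))
      stop_field("stats", "statistics dimension does not match the table")
  }
  sc <- stats$scale
  sc[sc == 0] <- 1 # constant feature -> centered column is all zeros anyway
  z <- sweep(sweep(x, 2L, stats$center), 2L, sc, "/")
  z[, stats$scale == 0] <- 0
  out <- table
  out$values <- z
  dimnames(out$values) <- dimnames(x)
  list(table = out, stats = stats)
}

# Restrict a feature table to a subset of rows (internal).
subset_rows <- function(table, idx) {
  feature_table(table$values[idx, , drop = FALSE],
                sample_ids = table$sample_ids[idx],
                feature_names = table$feature_names,
                labels = if (is.null(table$labels)) NULL else table$labels[idx],
                n_classes = table$n_classes)
}

# Restrict to a subset/reordering of feature columns (internal).
subset_features <- function(table, feats) {
  v <- table$values[, feats, drop = FALSE]
  feature_table(v, sample_ids = table$sample_ids, feature_names = colnames(v),
                labels = table$labels, n_classes = table$n_classes)
}
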