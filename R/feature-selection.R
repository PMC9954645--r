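#' Pearson's correlation coefficient
#'
#' Plain Pearson correlation, `cov(x, y) / (sd(x) * sd(y))`, with the contract
#' checks this package relies on: equal lengths of at least 2, and a hard
#' error on constant input (where the coefficient is undefined).
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single number in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant: correlation undefined (sd = 0)", call. = FALSE)
  if (stats::sd(y) == 0) stop("y is constant: correlation undefined (sd = 0)", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}

#' Rank features by absolute correlation with the diagnosis and select the top k
#'
#' Computes the Pearson correlation of every feature with the integer-coded
#' diagnosis (0 = NC < 1 = MCI < 2 = AD, so the label is treated as a single
#' ordered variable), ranks features by absolute correlation in descending
#' order, and returns both the ranking and the table restricted to the top
#' `k` features (columns reordered to ranking order).
#'
#' Ties in absolute correlation are broken by feature name, ascending.
#' A constant feature gets correlation 0 with a warning (so degenerate draws
#' do not abort a pipeline) and therefore ranks last.
#'
#' Because the Pearson coefficient is invariant to shifts and positive
#' rescaling of either variable, the ranking is the same before and after
#' feature standardization.
#'
#' @param table A labeled [feature_table()].
#' @param k Number of features to keep (default 15).
#' @param rows Optional row indices to compute correlations on (e.g. only the
#'   labeled subset for a leakage-free pipeline). Default: all rows with the
#'   table's full label vector, which mirrors selecting features once with all
#'   diagnoses known.
#' @return A list with elements `ranking` (class `pcc_ranking`: data frame
#'   with columns `feature`, `pcc`, `abs_pcc`, ordered by `abs_pcc`
#'   descending, plus attribute `k_selected`) and `table` (the top-`k`
#'   [feature_table()]).
#' @export
rank_and_select <- function(table, k = 15L, rows = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("table has no labels; correlation target undefined", call. = FALSE)
  k <- check_count(k, "k")
  p <- ncol(table$values)
  if (k > p) stop_field("k", sprintf("exceeds the number of features (%d)", p))
  if (is.null(rows)) rows <- seq_len(nrow(table$values))
  y <- as.numeric(table$labels[rows])
  x <- table$values[rows, , drop = FALSE]

  pcc <- vapply(seq_len(p), function(j) {
    xj <- x[, j]
    if (stats::sd(xj) == 0) {
      warning(sprintf("feature '%s' is constant; assigned pcc = 0",
                      table$feature_names[j]), call. = FALSE)
      return(0)
    }
    stats::cor(xj, y)
  }, numeric(1))

  ord <- order(-abs(pcc), table$feature_names)
  ranking <- data.frame(feature = table$feature_names[ord],
                        pcc = pcc[ord], abs_pcc = abs(pcc[ord]),
                        stringsAsFactors = FALSE)
  attr(ranking, "k_selected") <- k
  class(ranking) <- c("pcc_ranking", "data.frame")
  list(ranking = ranking,
       table = subset_features(table, ord[seq_len(k)]))
}

#' @export
print.pcc_ranking <- function(x, ...) {
  k <- attr(x, "k_selected")
  cat(sprintf("PCC ranking of %d features (top %d selected)\n", nrow(x), k))
  print.data.frame(utils::head(as.data.frame(x), k), row.names = FALSE, digits = 4)
  invisible(x)
}
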