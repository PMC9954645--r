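#' Specification for a synthetic neuropsychological score table
#'
#' Describes a three-class Gaussian mixture that emulates the statistical
#' shape of itemized neuropsychological test scores: classes are ordered by
#' disease severity (0 = NC, 1 = MCI, 2 = AD), informative score means are
#' monotone across the ordering, informative features share a common positive
#' correlation (scores from the same instrument co-vary), and distractor
#' features carry no class signal.
#'
#' The default class sizes follow the 229/402/188 NC/MCI/AD cohort
#' proportions of the ADNI-1 baseline sample this generator emulates, scaled
#' to the requested total.
#'
#' @param n_per_class Integer vector of length 3: samples per class, in class
#'   order NC, MCI, AD. Default `c(229, 402, 188)`.
#' @param n_informative Number of class-associated features (default 8).
#' @param n_noise Number of distractor features (default 7).
#' @param effect_size Separation between adjacent class means, in within-class
#'   SD units (default 2.0). Class `c` has mean `c * effect_size` on every
#'   informative axis.
#' @param feature_correlation Common pairwise correlation among informative
#'   features, in `[0, 1)` (default 0.3).
#' @param ordinal_clip Optional numeric `c(lo, hi)`; when set, scores are
#'   rounded to integers and clipped into the range, mimicking bounded item
#'   scores.
#' @param seed RNG seed (default 1).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = c(229L, 402L, 188L),
                           n_informative = 8L, n_noise = 7L,
                           effect_size = 2.0, feature_correlation = 0.3,
                           ordinal_clip = NULL, seed = 1L) {
  if (length(n_per_class) != 3L || any(n_per_class < 1) ||
      any(n_per_class != as.integer(n_per_class)))
    stop_field("n_per_class", "must be 3 positive integers (NC, MCI, AD)")
  n_informative <- check_count(n_informative, "n_informative", min = 0L)
  n_noise <- check_count(n_noise, "n_noise", min = 0L)
  if (n_informative + n_noise < 1L)
    stop_field("n_informative", "n_informative + n_noise must be >= 1")
  effect_size <- check_number(effect_size, "effect_size", lo = 0)
  feature_correlation <- check_number(feature_correlation, "feature_correlation", lo = 0)
  if (feature_correlation >= 1) stop_field("feature_correlation", "must be < 1")
  if (!is.null(ordinal_clip)) {
    if (length(ordinal_clip) != 2L || !is.numeric(ordinal_clip) ||
        ordinal_clip[1L] >= ordinal_clip[2L])
      stop_field("ordinal_clip", "must be numeric c(lo, hi) with lo < hi")
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(n_per_class = as.integer(n_per_class), n_informative = n_informative,
         n_noise = n_noise, effect_size = effect_size,
         feature_correlation = feature_correlation,
         ordinal_clip = ordinal_clip, seed = seed),
    class = "synthetic_spec"
  )
}

#' Simulate a labeled score table
#'
#' Draws the mixture described by a [synthetic_spec()]. Informative feature
#' values for a class-`c` subject are `c * effect_size + e`, where the noise
#' vector `e` has unit variances and common pairwise correlation `rho`
#' (generated exactly by the one-factor construction
#' `sqrt(rho) * z0 + sqrt(1 - rho) * z_j` with independent standard normals).
#' Distractor features are independent standard normal regardless of class.
#'
#' Identical spec and seed give bit-identical tables.
#'
#' @param spec A [synthetic_spec()].
#' @return A labeled [feature_table()] with `sum(n_per_class)` rows and
#'   `n_informative + n_noise` columns; informative columns are named
#'   `"inf1"..`, distractors `"noise1"..`.
#' @export
simulate_scores <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- sum(spec$n_per_class)
  p_inf <- spec$n_informative
  p_noi <- spec$n_noise
  labels <- rep(0:2, times = spec$n_per_class)
  rho <- spec$feature_correlation

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  vals <- matrix(0, n, p_inf + p_noi)
  if (p_inf > 0L) {
    z0 <- rnorm(n)
    zj <- matrix(rnorm(n * p_inf), n, p_inf)
    e <- sqrt(rho) * z0 + sqrt(1 - rho) * zj
    vals[, seq_len(p_inf)] <- labels * spec$effect_size + e
  }
  if (p_noi > 0L)
    vals[, p_inf + seq_len(p_noi)] <- matrix(rnorm(n * p_noi), n, p_noi)
  if (!is.null(spec$ordinal_clip)) {
    vals <- round(vals)
    vals <- pmin(pmax(vals, spec$ordinal_clip[1L]), spec$ordinal_clip[2L])
  }
  colnames(vals) <- c(if (p_inf > 0L) paste0("inf", seq_len(p_inf)),
                      if (p_noi > 0L) paste0("noise", seq_len(p_noi)))
  feature_table(vals, labels = labels, n_classes = 3L)
}

# Save/restore the global RNG state so generator calls do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Split training rows into labeled and unlabeled sets
#'
#' Randomly selects `n_labeled` rows to keep their diagnosis; the rest form
#' the unlabeled pool. By default the draw is stratified by class so that
#' every class contributes at least one labeled example, which keeps training
#' well-posed at very small label budgets.
#'
#' @param table A labeled [feature_table()].
#' @param n_labeled Number of rows to label.
#' @param seed RNG seed for the draw.
#' @param stratified Stratify by class (default `TRUE`).
#' @return An object of class `label_split`: list with integer index vectors
#'   `labeled` and `unlabeled` (disjoint, covering all rows).
#' @export
make_label_split <- function(table, n_labeled, seed = 1L, stratified = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("table has no labels to split", call. = FALSE)
  n <- nrow(table$values)
  n_labeled <- check_count(n_labeled, "n_labeled", min = 1L)
  if (n_labeled > n) stop_field("n_labeled", "exceeds the number of rows")
  classes <- 0:(table$n_classes - 1L)
  counts <- tabulate(table$labels + 1L, nbins = table$n_classes)
  if (any(counts == 0L))
    stop(sprintf("class %d absent from the table", classes[which(counts == 0L)[1L]]), call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  if (stratified) {
    if (n_labeled < table$n_classes)
      stop_field("n_labeled", "stratified split needs at least one label per class")
    # proportional allocation, at least 1 per class, largest-remainder rounding
    target <- counts / n * n_labeled
    alloc <- pmax(1L, floor(target))
    while (sum(alloc) < n_labeled) {
      j <- which.max(target - alloc)
      alloc[j] <- alloc[j] + 1L
    }
    while (sum(alloc) > n_labeled) {
      cand <- which(alloc > 1L)
      j <- cand[which.min((target - alloc)[cand])]
      alloc[j] <- alloc[j] - 1L
    }
    labeled <- integer(0)
    for (ci in seq_along(classes)) {
      rows <- which(table$labels == classes[ci])
      labeled <- c(labeled, rows[sample.int(length(rows), alloc[ci])])
    }
    labeled <- sort(labeled)
  } else {
    labeled <- sort(sample.int(n, n_labeled))
  }
  structure(list(labeled = labeled, unlabeled = setdiff(seq_len(n), labeled)),
            class = "label_split")
}

#' @export
print.label_split <- function(x, ...) {
  cat(sprintf("label_split: D = %d labeled, %d unlabeled\n",
              length(x$labeled), length(x$unlabeled)))
  invisible(x)
}
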