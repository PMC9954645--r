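#' Classification metrics with one-vs-rest macro averaging
#'
#' Builds the confusion matrix (rows = true class, columns = predicted) and,
#' for every class, the one-vs-rest counts TP, TN, FP, FN, from which five
#' metrics are computed per class and macro-averaged:
#' \describe{
#'   \item{acc}{`(TP + TN) / (TP + TN + FP + FN)`}
#'   \item{sen}{`TP / (TP + FP)` under the default `"paper"` convention (the
#'     printed definition this package follows, conventionally called
#'     precision); `TP / (TP + FN)` under `"standard"`.}
#'   \item{spe}{`TN / (TN + FP)`}
#'   \item{rec}{`TP / (TP + FN)`}
#'   \item{f1}{`2 TP / (2 TP + FP + FN)`}
#' }
#' A metric whose denominator is zero is reported as 0 and the affected
#' class/metric pair is listed in `zero_denominator`, so macro averages stay
#' defined on tiny folds.
#'
#' @param y_true,y_pred Integer class vectors of equal length (values in
#'   `0..n_classes-1`).
#' @param n_classes Number of classes (default 3).
#' @param sensitivity_convention `"paper"` (default) or `"standard"`, see
#'   above.
#' @return An object of class `metrics_report`: list with `confusion`,
#'   `per_class` (data frame), `macro` (named numeric), `overall_accuracy`,
#'   and `zero_denominator` (character vector of flagged cells).
#' @export
compute_metrics <- function(y_true, y_pred, n_classes = 3L,
                            sensitivity_convention = c("paper", "standard")) {
  sensitivity_convention <- match.arg(sensitivity_convention)
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (length(y_true) < 1L) stop("empty input", call. = FALSE)
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  lv <- 0:(n_classes - 1L)
  if (any(!y_true %in% lv) || any(!y_pred %in% lv))
    stop("labels outside 0..n_classes-1", call. = FALSE)
  conf <- table(factor(y_true, levels = lv), factor(y_pred, levels = lv))
  conf <- matrix(as.integer(conf), n_classes, n_classes,
                 dimnames = list(true = lv, pred = lv))
  n <- sum(conf)

  flagged <- character(0)
  safe_div <- function(num, den, cls, what) {
    if (den == 0) {
      flagged <<- c(flagged, sprintf("class %d %s", cls, what))
      return(0)
    }
    num / den
  }
  per <- lapply(seq_len(n_classes), function(ci) {
    tp <- conf[ci, ci]
    fn <- sum(conf[ci, ]) - tp
    fp <- sum(conf[, ci]) - tp
    tn <- n - tp - fn - fp
    cls <- ci - 1L
    sen <- if (sensitivity_convention == "paper")
      safe_div(tp, tp + fp, cls, "sen") else safe_div(tp, tp + fn, cls, "sen")
    data.frame(class = cls, tp = tp, tn = tn, fp = fp, fn = fn,
               acc = (tp + tn) / n,
               sen = sen,
               spe = safe_div(tn, tn + fp, cls, "spe"),
               rec = safe_div(tp, tp + fn, cls, "rec"),
               f1 = safe_div(2 * tp, 2 * tp + fp + fn, cls, "f1"))
  })
  per <- do.call(rbind, per)
  macro <- colMeans(per[, c("acc", "sen", "spe", "rec", "f1")])
  structure(list(confusion = conf, per_class = per, macro = macro,
                 overall_accuracy = sum(diag(conf)) / n,
                 sensitivity_convention = sensitivity_convention,
                 zero_denominator = flagged),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report (n = %d): overall accuracy %.4f\n",
              sum(x$confusion), x$overall_accuracy))
  cat(sprintf("macro: ACC %.4f  SEN %.4f  SPE %.4f  REC %.4f  F1 %.4f\n",
              x$macro["acc"], x$macro["sen"], x$macro["spe"],
              x$macro["rec"], x$macro["f1"]))
  if (length(x$zero_denominator))
    cat("zero-denominator cells reported as 0:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  invisible(x)
}

#' Pseudo-label quality diagnostics
#'
#' For a prediction matrix on unlabeled data with known ground truth:
#' the passing rate is the fraction of samples whose maximum predicted
#' probability reaches the confidence threshold, and the impurity rate is the
#' fraction of those passing samples whose predicted class disagrees with the
#' true label. When no sample passes, the impurity rate is undefined and
#' reported as `NA`.
#'
#' @param q Probability matrix, one row per sample.
#' @param y_true Integer true labels.
#' @param tau Confidence threshold in `[0, 1]`.
#' @return An object of class `pseudo_label_diagnostics`: list with `tau`,
#'   `passing_rate`, `impurity_rate`, `n_passing`.
#' @export
pseudo_label_diagnostics <- function(q, y_true, tau) {
  q <- check_prob_matrix(q)
  if (nrow(q) != length(y_true)) stop("length mismatch", call. = FALSE)
  tau <- check_number(tau, "tau", lo = 0, hi = 1)
  maxp <- apply(q, 1L, max)
  pred <- argmax_rows(q) - 1L
  pass <- maxp >= tau
  n_pass <- sum(pass)
  structure(list(tau = tau,
                 passing_rate = mean(pass),
                 impurity_rate = if (n_pass == 0L) NA_real_
                                 else sum(pass & (pred != y_true)) / n_pass,
                 n_passing = n_pass),
            class = "pseudo_label_diagnostics")
}

# Stratified fold assignment: returns an integer vector of fold ids 1..k.
stratified_folds <- function(labels, k, n_classes) {
  fold <- integer(length(labels))
  for (c in 0:(n_classes - 1L)) {
    rows <- which(labels == c)
    if (length(rows) < k)
      stop(sprintf("class %d has %d members, fewer than k = %d folds",
                   c, length(rows), k), call. = FALSE)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  fold
}

#' Stratified k-fold cross-validated semi-supervised evaluation
#'
#' Splits the table into `k` stratified folds. For each fold: the remaining
#' folds form the training set; standardization statistics are fitted on the
#' training set only; `n_labeled` training rows keep their diagnosis (the
#' rest are the unlabeled pool); a dual model is trained and evaluated on the
#' held-out fold.
#'
#' @param table A labeled [feature_table()] (features already selected).
#' @param k Number of folds (default 5).
#' @param n_labeled Labeled budget inside each training set (default 60).
#' @param model_config An [encoder_config()].
#' @param config A [train_config()]; per-fold seeds are derived from
#'   `config$seed`.
#' @param standardize Fit-and-apply z-scoring per fold (default `TRUE`).
#' @param seed Seed for the fold assignment.
#' @return A list of class `cv_result` with `folds` (list of
#'   [compute_metrics()] reports), `fold_assignment`, `mean_accuracy`,
#'   `sd_accuracy`, and `macro_mean` (averaged macro metrics).
#' @export
kfold_cv <- function(table, k = 5L, n_labeled = 60L,
                     model_config = encoder_config(), config = train_config(),
                     standardize = TRUE, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  k <- check_count(k, "k", min = 2L)
  n <- nrow(table$values)
  if (n < k) stop_field("k", "more folds than rows")
  if (is.null(table$labels)) stop("table has no labels", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 0L))
  fold <- stratified_folds(table$labels, k, table$n_classes)

  reports <- vector("list", k)
  for (fi in seq_len(k)) {
    train_tab <- subset_rows(table, which(fold != fi))
    test_tab <- subset_rows(table, which(fold == fi))
    if (standardize) {
      st <- standardize_features(train_tab)
      train_tab <- st$table
      test_tab <- standardize_features(test_tab, stats = st$stats)$table
    }
    split <- make_label_split(train_tab, n_labeled,
                              seed = derive_seed(seed, fi))
    cfg_fold <- config
    cfg_fold$seed <- derive_seed(config$seed, 100L + fi)
    fit <- dssl_train(train_tab, split, model_config, cfg_fold)
    pred <- predict_labels(fit, test_tab)
    reports[[fi]] <- compute_metrics(test_tab$labels, pred$labels,
                                     n_classes = table$n_classes)
  }
  accs <- vapply(reports, function(r) r$overall_accuracy, numeric(1))
  macro <- Reduce(`+`, lapply(reports, function(r) r$macro)) / k
  structure(list(folds = reports, fold_assignment = fold,
                 accuracies = accs, mean_accuracy = mean(accs),
                 sd_accuracy = stats::sd(accs), macro_mean = macro),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds; accuracy %.4f +/- %.4f\n",
              length(x$folds), x$mean_accuracy, x$sd_accuracy))
  invisible(x)
}

#' Labeled-set stability experiment
#'
#' Fixes one train/test split, then redraws the labeled subset of the
#' training set `n_repeats` times, training and evaluating each division.
#' The spread of the resulting test accuracies measures how sensitive the
#' semi-supervised method is to which subjects happen to be labeled; larger
#' labeled budgets should shrink it.
#'
#' @param table A labeled [feature_table()].
#' @param n_labeled Labeled budget per division.
#' @param n_repeats Number of labeled-set redraws (default 100).
#' @param model_config An [encoder_config()].
#' @param config A [train_config()].
#' @param test_fraction Held-out fraction for the fixed test set (default 0.2).
#' @param standardize Fit z-scoring on the training set (default `TRUE`).
#' @param seed Seed for the fixed split and the redraw sequence.
#' @return A list of class `stability_result` with `accuracies` (length
#'   `n_repeats`, proportions), `variance_percent` and `sd_percent` (variance
#'   / SD of the accuracies expressed in percentage points; 0 when
#'   `n_repeats == 1`).
#' @export
stability_experiment <- function(table, n_labeled, n_repeats = 100L,
                                 model_config = encoder_config(),
                                 config = train_config(),
                                 test_fraction = 0.2, standardize = TRUE,
                                 seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  n_repeats <- check_count(n_repeats, "n_repeats")
  test_fraction <- check_number(test_fraction, "test_fraction", lo = 0, hi = 0.9)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, 0L))
  n <- nrow(table$values)
  test_idx <- sort(sample.int(n, round(n * test_fraction)))
  train_tab <- subset_rows(table, setdiff(seq_len(n), test_idx))
  test_tab <- subset_rows(table, test_idx)
  if (n_labeled >= nrow(train_tab$values))
    stop_field("n_labeled", "must be smaller than the training set")
  if (standardize) {
    st <- standardize_features(train_tab)
    train_tab <- st$table
    test_tab <- standardize_features(test_tab, stats = st$stats)$table
  }

  accs <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    split <- make_label_split(train_tab, n_labeled, seed = derive_seed(seed, r))
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, 1000L + r)
    fit <- dssl_train(train_tab, split, model_config, cfg_r)
    pred <- predict_labels(fit, test_tab)
    accs[r] <- mean(pred$labels == test_tab$labels)
  }
  pct <- 100 * accs
  structure(list(accuracies = accs, n_labeled = n_labeled,
                 variance_percent = if (n_repeats > 1L) stats::var(pct) else 0,
                 sd_percent = if (n_repeats > 1L) stats::sd(pct) else 0),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability_result: %d divisions at %d labels; mean accuracy %.4f; variance %.3f (percent^2)\n",
              length(x$accuracies), x$n_labeled, mean(x$accuracies),
              x$variance_percent))
  invisible(x)
}

#' Confidence-threshold sweep
#'
#' Evaluates pseudo-label quality over a grid of confidence thresholds using
#' a trained model's predictions on an unlabeled pool with known ground
#' truth (branch 1's probabilities by default, matching the diagnostics'
#' definition). Optionally retrains the model at each threshold to also
#' report held-out accuracy.
#'
#' @param fit A `dssl_fit` or `dual_model_state`.
#' @param table A labeled [feature_table()] playing the role of the unlabeled
#'   pool with known truth.
#' @param taus Numeric vector of thresholds in `[0, 1]`.
#' @param branch Which branch's probabilities feed the diagnostics:
#'   `"1"`, `"2"`, or `"mean"` (default `"1"`).
#' @param use_ema Use EMA parameters (default `TRUE`).
#' @param retrain Retrain the model at each threshold and also report
#'   held-out accuracy (default `FALSE`). Requires the remaining arguments.
#' @param train_table,split,test_table Training table, label split and
#'   held-out table for the retraining protocol.
#' @param model_config,config Model and training configuration for the
#'   retraining protocol; `config$loss$tau` is overridden per threshold.
#' @return A data frame with one row per threshold: `tau`, `passing_rate`,
#'   `impurity_rate`, `n_passing`, and — with `retrain` — `accuracy` on the
#'   held-out table (diagnostics then come from each retrained model's
#'   predictions on the unlabeled pool).
#' @export
threshold_sweep <- function(fit, table, taus, branch = c("1", "2", "mean"),
                            use_ema = TRUE, retrain = FALSE,
                            train_table = NULL, split = NULL,
                            test_table = NULL,
                            model_config = encoder_config(),
                            config = train_config()) {
  branch <- match.arg(branch)
  stopifnot(inherits(table, "feature_table"))
  if (is.null(table$labels)) stop("ground-truth labels required", call. = FALSE)
  if (any(taus < 0 | taus > 1)) stop_field("taus", "must lie in [0, 1]")
  pick_q <- function(out) switch(branch, "1" = out$q1, "2" = out$q2,
                                 mean = (out$q1 + out$q2) / 2)
  if (!retrain) {
    state <- if (inherits(fit, "dssl_fit")) fit$state else fit
    q <- pick_q(dual_forward(state, table$values, use_ema = use_ema))
    rows <- lapply(taus, function(tau) {
      d <- pseudo_label_diagnostics(q, table$labels, tau)
      data.frame(tau = tau, passing_rate = d$passing_rate,
                 impurity_rate = d$impurity_rate, n_passing = d$n_passing)
    })
    return(do.call(rbind, rows))
  }
  if (is.null(train_table) || is.null(split) || is.null(test_table))
    stop("retrain = TRUE requires train_table, split and test_table", call. = FALSE)
  rows <- lapply(taus, function(tau) {
    cfg <- config
    cfg$loss$tau <- tau
    f <- dssl_train(train_table, split, model_config, cfg)
    q <- pick_q(dual_forward(f$state, table$values, use_ema = use_ema))
    d <- pseudo_label_diagnostics(q, table$labels, tau)
    pred <- predict_labels(f, test_table, use_ema = use_ema)
    data.frame(tau = tau, passing_rate = d$passing_rate,
               impurity_rate = d$impurity_rate, n_passing = d$n_passing,
               accuracy = mean(pred$labels == test_table$labels))
  })
  do.call(rbind, rows)
}
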