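#' Assemble a full pipeline configuration
#'
#' One object wiring the whole pipeline: data source (exactly one of a
#' synthetic spec or a CSV path), feature selection, model and training
#' settings, and the evaluation protocol.
#'
#' @param synthetic A [synthetic_spec()], or `NULL` when reading from file.
#' @param input Path to a CSV feature table, or `NULL` when simulating.
#' @param select_k Number of features to keep by PCC ranking; `NULL` skips
#'   selection.
#' @param n_labeled Labeled budget for training (default 60).
#' @param protocol One of `"holdout"`, `"cv"`, `"stability"`, `"sweep"`.
#' @param model An [encoder_config()] (its `input_dim` is resolved from the
#'   data after selection).
#' @param train A [train_config()].
#' @param test_fraction Held-out fraction for the `"holdout"`, `"stability"`
#'   and `"sweep"` protocols (default 0.2).
#' @param cv_k Folds for the `"cv"` protocol (default 5).
#' @param n_repeats Redraws for the `"stability"` protocol (default 100).
#' @param taus Threshold grid for the `"sweep"` protocol.
#' @param out_dir Output directory for reports.
#' @param seed Master seed for the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = NULL, input = NULL, select_k = 15L,
                       n_labeled = 60L, protocol = c("holdout", "cv", "stability", "sweep"),
                       model = encoder_config(), train = train_config(),
                       test_fraction = 0.2, cv_k = 5L, n_repeats = 100L,
                       taus = c(0.25, 0.5, 0.75, 0.85, 0.9, 0.95, 0.97, 0.99),
                       out_dir = ".", seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(synthetic) == is.null(input))
    stop_field("synthetic/input", "exactly one data source must be given")
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "synthetic_spec"))
  if (!is.null(input) && !file.exists(input)) stop_field("input", "file not found")
  stopifnot(inherits(model, "encoder_config"), inherits(train, "train_config"))
  if (!is.null(select_k)) select_k <- check_count(select_k, "select_k")
  n_labeled <- check_count(n_labeled, "n_labeled")
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(synthetic = synthetic, input = input, select_k = select_k,
                 n_labeled = n_labeled, protocol = protocol, model = model,
                 train = train, test_fraction = test_fraction, cv_k = cv_k,
                 n_repeats = n_repeats, taus = taus, out_dir = out_dir,
                 seed = seed),
            class = "run_config")
}

resolved_config_list <- function(config) {
  list(synthetic = if (is.null(config$synthetic)) NULL else unclass(config$synthetic),
       input = config$input, select_k = config$select_k,
       n_labeled = config$n_labeled, protocol = config$protocol,
       model = unclass(config$model),
       train = c(unclass(config$train)[setdiff(names(config$train), "loss")],
                 list(loss = unclass(config$train$loss))),
       test_fraction = config$test_fraction, cv_k = config$cv_k,
       n_repeats = config$n_repeats, taus = config$taus, seed = config$seed)
}

#' Read a pipeline configuration from YAML
#'
#' The file may define any subset of the [run_config()] fields; nested
#' sections `synthetic`, `model`, `train` and `train$loss` are passed to the
#' corresponding constructors, so defaults fill everything left unset.
#'
#' @param path Path to a YAML file.
#' @param overrides Named list of top-level fields overriding file values
#'   (how CLI flags are applied).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  if (!is.null(overrides) && length(overrides))
    raw[names(overrides)] <- overrides
  args <- raw
  if (!is.null(raw$synthetic)) args$synthetic <- do.call(synthetic_spec, raw$synthetic)
  if (!is.null(raw$model)) args$model <- do.call(encoder_config, raw$model)
  if (!is.null(raw$train)) {
    targs <- raw$train
    if (!is.null(targs$loss)) targs$loss <- do.call(loss_config, targs$loss)
    args$train <- do.call(train_config, targs)
  }
  unknown <- setdiff(names(args), names(formals(run_config)))
  if (length(unknown))
    stop(sprintf("unknown configuration key '%s'", unknown[1L]), call. = FALSE)
  do.call(run_config, args)
}

#' Execute a configured pipeline
#'
#' Simulates or reads the data, optionally ranks and selects features,
#' standardizes them, and runs the configured evaluation protocol. All
#' reports are written under `config$out_dir`; `report.json` always embeds
#' the resolved configuration and seed so a run can be audited and repeated.
#'
#' Protocols: `"holdout"` trains once on a labeled/unlabeled division of the
#' training portion and reports held-out metrics plus pseudo-label
#' diagnostics; `"cv"` runs [kfold_cv()]; `"stability"` runs
#' [stability_experiment()] (also writing per-repeat accuracies as CSV);
#' `"sweep"` trains once and runs [threshold_sweep()].
#'
#' @param config A [run_config()].
#' @return The report list, invisibly; side effect: files in
#'   `config$out_dir`.
#' @export
dssl_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  table <- if (!is.null(config$synthetic)) simulate_scores(config$synthetic)
           else read_feature_table(config$input)
  report <- list(config = resolved_config_list(config), seed = config$seed)

  if (!is.null(config$select_k)) {
    sel <- rank_and_select(table, k = config$select_k)
    table <- sel$table
    report$feature_ranking <- sel$ranking
    utils::write.csv(as.data.frame(sel$ranking),
                     file.path(config$out_dir, "feature_ranking.csv"),
                     row.names = FALSE)
  }
  model_cfg <- config$model
  if (model_cfg$input_dim != ncol(table$values)) {
    args <- unclass(model_cfg)
    args$input_dim <- ncol(table$values)
    model_cfg <- do.call(encoder_config, args)
  }

  holdout_parts <- function() {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(derive_seed(config$seed, 7L))
    n <- nrow(table$values)
    test_idx <- sort(sample.int(n, round(n * config$test_fraction)))
    train_tab <- subset_rows(table, setdiff(seq_len(n), test_idx))
    test_tab <- subset_rows(table, test_idx)
    st <- standardize_features(train_tab)
    list(train = st$table,
         test = standardize_features(test_tab, stats = st$stats)$table)
  }

  if (config$protocol %in% c("holdout", "sweep")) {
    parts <- holdout_parts()
    split <- make_label_split(parts$train, config$n_labeled,
                              seed = derive_seed(config$seed, 8L))
    fit <- dssl_train(parts$train, split, model_cfg, config$train)
    save_checkpoint(fit$state, file.path(config$out_dir, "model.json"))
    utils::write.csv(fit$history, file.path(config$out_dir, "train_history.csv"),
                     row.names = FALSE)
    if (config$protocol == "holdout") {
      pred <- predict_labels(fit, parts$test)
      m <- compute_metrics(parts$test$labels, pred$labels,
                           n_classes = table$n_classes)
      unl <- subset_rows(parts$train, split$unlabeled)
      qu <- predict_labels(fit, unl)$probabilities
      diag <- pseudo_label_diagnostics(qu, unl$labels, config$train$loss$tau)
      report$metrics <- list(overall_accuracy = m$overall_accuracy,
                             macro = as.list(m$macro),
                             confusion = m$confusion,
                             per_class = m$per_class)
      report$pseudo_label_diagnostics <- unclass(diag)
    } else {
      sw <- threshold_sweep(fit, subset_rows(parts$train, split$unlabeled),
                            config$taus)
      report$threshold_sweep <- sw
      utils::write.csv(sw, file.path(config$out_dir, "threshold_sweep.csv"),
                       row.names = FALSE)
    }
  } else if (config$protocol == "cv") {
    cv <- kfold_cv(table, k = config$cv_k, n_labeled = config$n_labeled,
                   model_config = model_cfg, config = config$train,
                   seed = derive_seed(config$seed, 9L))
    report$cv <- list(accuracies = cv$accuracies,
                      mean_accuracy = cv$mean_accuracy,
                      sd_accuracy = cv$sd_accuracy,
                      macro_mean = as.list(cv$macro_mean))
  } else { # stability
    stab <- stability_experiment(table, n_labeled = config$n_labeled,
                                 n_repeats = config$n_repeats,
                                 model_config = model_cfg, config = config$train,
                                 test_fraction = config$test_fraction,
                                 seed = derive_seed(config$seed, 10L))
    report$stability <- list(n_labeled = stab$n_labeled,
                             mean_accuracy = mean(stab$accuracies),
                             variance_percent = stab$variance_percent,
                             sd_percent = stab$sd_percent)
    utils::write.csv(data.frame(repeat_id = seq_along(stab$accuracies),
                                accuracy = stab$accuracies),
                     file.path(config$out_dir, "stability_accuracies.csv"),
                     row.names = FALSE)
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", dataframe = "rows")
  invisible(report)
}
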