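test_that("metrics are all 1 under perfect prediction", {
  y <- rep(0:2, each = 4)
  m <- compute_metrics(y, y)
  expect_equal(m$overall_accuracy, 1)
  expect_equal(unname(m$macro), rep(1, 5))
  expect_equal(diag(m$confusion), rep(4L, 3), ignore_attr = TRUE)
})

test_that("metrics reproduce a hand-counted confusion matrix", {
  y_true <- c(0L, 0L, 1L, 1L, 2L, 2L)
  y_pred <- c(0L, 1L, 1L, 1L, 2L, 0L)
  m <- compute_metrics(y_true, y_pred)
  expect_equal(m$overall_accuracy, 4 / 6)
  c0 <- m$per_class[m$per_class$class == 0L, ]
  expect_equal(c0$tp, 1L); expect_equal(c0$fp, 1L)
  expect_equal(c0$fn, 1L); expect_equal(c0$tn, 3L)
  expect_equal(c0$sen, 0.5)
  expect_equal(c0$rec, 0.5)
  expect_equal(c0$spe, 0.75)
  expect_equal(c0$f1, 0.5)
})

test_that("metrics equal an independent one-vs-rest recount on random vectors", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    y_true <- sample(0:2, n, replace = TRUE)
    y_pred <- sample(0:2, n, replace = TRUE)
    m <- compute_metrics(y_true, y_pred)
    o <- oracle_metrics(y_true, y_pred, 3L)
    expect_equal(m$overall_accuracy, o$overall)
    expect_equal(unname(m$macro), unname(o$macro))
    expect_equal(as.matrix(m$per_class[, c("acc", "sen", "spe", "rec", "f1")]),
                 o$per_class, ignore_attr = TRUE)
  }
})

test_that("zero denominators report 0 with a flag; conventions switch", {
  # nothing predicted as class 2 -> its paper-SEN denominator is zero
  m <- compute_metrics(c(0L, 1L, 2L), c(0L, 1L, 1L))
  expect_equal(m$per_class$sen[3], 0)
  expect_true(any(grepl("class 2 sen", m$zero_denominator)))
  ms <- compute_metrics(c(0L, 1L, 2L), c(0L, 1L, 1L),
                        sensitivity_convention = "standard")
  expect_equal(ms$per_class$sen, ms$per_class$rec)
})

test_that("pseudo-label diagnostics match hand counts", {
  q <- rbind(c(0.95, 0.03, 0.02), # passes, wrong
             c(0.10, 0.80, 0.10), # below threshold
             c(0.99, 0.005, 0.005)) # passes, right
  y <- c(1L, 0L, 0L)
  d <- pseudo_label_diagnostics(q, y, tau = 0.9)
  expect_equal(d$passing_rate, 2 / 3)
  expect_equal(d$impurity_rate, 1 / 2)
  expect_equal(pseudo_label_diagnostics(q, y, tau = 0)$passing_rate, 1)
  none <- pseudo_label_diagnostics(q, y, tau = 0.999)
  expect_true(is.na(none$impurity_rate))
  allright <- pseudo_label_diagnostics(q, c(0L, 1L, 0L), tau = 0.9)
  expect_equal(allright$impurity_rate, 0)
})

test_that("diagnostics equal a brute-force recount on random matrices", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(3:30, 1)
    q <- random_simplex(n, 3)
    y <- sample(0:2, n, replace = TRUE)
    tau <- runif(1)
    d <- pseudo_label_diagnostics(q, y, tau)
    pass <- 0; bad <- 0
    for (i in seq_len(n)) {
      if (max(q[i, ]) >= tau) {
        pass <- pass + 1
        if (which.max(q[i, ]) - 1L != y[i]) bad <- bad + 1
      }
    }
    expect_equal(d$passing_rate, pass / n)
    expect_equal(d$impurity_rate, if (pass == 0) NA_real_ else bad / pass)
  }
})

test_that("passing rate is non-increasing in the threshold", {
  set.seed(23)
  q <- random_simplex(200, 3)
  y <- sample(0:2, 200, replace = TRUE)
  rates <- vapply(seq(0, 1, by = 0.01), function(tau)
    pseudo_label_diagnostics(q, y, tau)$passing_rate, numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("cross-validation folds partition the rows and are seed-stable", {
  tab <- simulate_scores(synthetic_spec(n_per_class = c(30L, 40L, 30L),
                                        n_informative = 4L, n_noise = 2L, seed = 2L))
  cv <- kfold_cv(tab, k = 5L, n_labeled = 15L, model_config = tiny_cfg(),
                 config = train_config(epochs = 2L, seed = 3L), seed = 9L)
  expect_length(cv$fold_assignment, 100L)
  expect_equal(sort(unique(cv$fold_assignment)), 1:5)
  # stratification: each fold holds ~1/5 of each class
  for (f in 1:5)
    expect_equal(sum(tab$labels[cv$fold_assignment == f] == 0L), 6L)
  expect_length(cv$folds, 5L)
  expect_equal(cv$mean_accuracy, mean(cv$accuracies))
  cv2 <- kfold_cv(tab, k = 5L, n_labeled = 15L, model_config = tiny_cfg(),
                  config = train_config(epochs = 2L, seed = 3L), seed = 9L)
  expect_identical(cv$fold_assignment, cv2$fold_assignment)
  expect_equal(cv$accuracies, cv2$accuracies)
  expect_error(kfold_cv(tab, k = 50L, n_labeled = 5L), "fewer than")
})

test_that("stability experiment degenerates to variance 0 for one repeat", {
  tab <- simulate_scores(synthetic_spec(n_per_class = c(30L, 40L, 30L),
                                        n_informative = 4L, n_noise = 2L, seed = 4L))
  s <- stability_experiment(tab, n_labeled = 12L, n_repeats = 1L,
                            model_config = tiny_cfg(),
                            config = train_config(epochs = 2L, seed = 1L), seed = 5L)
  expect_length(s$accuracies, 1L)
  expect_equal(s$variance_percent, 0)
})

test_that("threshold sweep returns one monotone record per threshold", {
  tab <- simulate_scores(synthetic_spec(n_per_class = c(30L, 40L, 30L),
                                        n_informative = 4L, n_noise = 2L, seed = 6L))
  std <- standardize_features(tab)$table
  split <- make_label_split(std, 15L, seed = 2L)
  fit <- dssl_train(std, split, tiny_cfg(), train_config(epochs = 3L, seed = 2L))
  taus <- c(0.25, 0.5, 0.75, 0.9, 0.99)
  sw <- threshold_sweep(fit, subset_rows_tt(std, split$unlabeled), taus)
  expect_equal(nrow(sw), length(taus))
  expect_equal(sw$tau, taus)
  expect_true(all(diff(sw$passing_rate) <= 0))
  expect_lte(sw$passing_rate[nrow(sw)], sw$passing_rate[1])
})

test_that("threshold sweep can retrain per threshold and report accuracy", {
  tab <- simulate_scores(synthetic_spec(n_per_class = c(30L, 40L, 30L),
                                        n_informative = 4L, n_noise = 2L, seed = 7L))
  std <- standardize_features(tab)$table
  test_tab <- subset_rows_tt(std, 81:100)
  train_tab <- subset_rows_tt(std, 1:80)
  split <- make_label_split(train_tab, 15L, seed = 3L)
  sw <- threshold_sweep(NULL, subset_rows_tt(train_tab, split$unlabeled),
                        taus = c(0.5, 0.9), retrain = TRUE,
                        train_table = train_tab, split = split,
                        test_table = test_tab, model_config = tiny_cfg(),
                        config = train_config(epochs = 2L, seed = 3L))
  expect_equal(nrow(sw), 2L)
  expect_true(all(sw$accuracy >= 0 & sw$accuracy <= 1))
  expect_error(threshold_sweep(NULL, train_tab, 0.5, retrain = TRUE),
               "requires")
})
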