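make_train_fixture <- function(seed = 1L, n_per_class = c(40L, 60L, 40L),
                               n_labeled = 21L) {
  tab <- simulate_scores(synthetic_spec(n_per_class = n_per_class,
                                        n_informative = 4L, n_noise = 2L,
                                        seed = seed))
  std <- standardize_features(tab)$table
  split <- make_label_split(std, n_labeled, seed = seed)
  list(tab = std, split = split)
}

test_that("ema_update matches its closed forms", {
  live <- list(W = matrix(0, 2, 2), b = c(0, 0))
  shadow <- list(W = matrix(1, 2, 2), b = c(1, 1))
  expect_identical(ema_update(shadow, live, decay = 1), shadow)
  expect_identical(ema_update(shadow, live, decay = 0), live)
  out <- ema_update(shadow, live, decay = 0.999)
  expect_equal(out$W[1, 1], 0.999, tolerance = 1e-15)
  bad <- list(W = matrix(1, 3, 2), b = c(1, 1))
  expect_error(ema_update(bad, live, 0.5), "shape mismatch")
  expect_error(ema_update(list(a = 1), list(b = 1), 0.5), "do not match")
})

test_that("zero epochs returns the initialized state untouched", {
  fx <- make_train_fixture()
  cfg <- tiny_cfg()
  fit <- dssl_train(fx$tab, fx$split, cfg, train_config(epochs = 0L, seed = 4L))
  ref <- init_dual_model(cfg, seed = dssl:::derive_seed(4L, 0L))
  expect_identical(fit$state$params1, ref$params1)
  expect_identical(fit$state$ema2, ref$ema2)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training is bit-reproducible given the seed", {
  fx <- make_train_fixture()
  cfg <- train_config(epochs = 3L, seed = 11L)
  f1 <- dssl_train(fx$tab, fx$split, tiny_cfg(), cfg)
  f2 <- dssl_train(fx$tab, fx$split, tiny_cfg(), cfg)
  expect_identical(f1$state$params1, f2$state$params1)
  expect_identical(f1$state$ema1, f2$state$ema1)
  expect_identical(f1$history, f2$history)
  f3 <- dssl_train(fx$tab, fx$split, tiny_cfg(),
                   train_config(epochs = 3L, seed = 12L))
  expect_false(identical(f1$state$params1, f3$state$params1))
})

test_that("with lambda = beta = 0 the unlabeled pool is ignored entirely", {
  fx <- make_train_fixture()
  sup <- train_config(epochs = 3L, seed = 2L,
                      loss = loss_config(lambda_u = 0, beta = 0))
  f1 <- dssl_train(fx$tab, fx$split, tiny_cfg(), sup)
  # perturb only the unlabeled rows: a supervised run must not notice
  vals <- fx$tab$values
  vals[fx$split$unlabeled, ] <- vals[fx$split$unlabeled, ] + 100
  tab2 <- feature_table(vals, sample_ids = fx$tab$sample_ids,
                        labels = fx$tab$labels)
  f2 <- dssl_train(tab2, fx$split, tiny_cfg(), sup)
  expect_identical(f1$state$params1, f2$state$params1)
  expect_identical(f1$state$params2, f2$state$params2)
  expect_equal(f1$history$lu1, rep(0, 3))
  expect_equal(f1$history$total, f1$history$lx1 + f1$history$lx2,
               tolerance = 1e-12)
})

test_that("EMA shadows converge to live parameters once updates stop", {
  fx <- make_train_fixture()
  cfg <- train_config(epochs = 2L, seed = 6L, ema_decay = 0.9, ema_ramp = FALSE)
  fit <- dssl_train(fx$tab, fx$split, tiny_cfg(), cfg)
  gap0 <- max(abs(fit$state$ema1$W1 - fit$state$params1$W1))
  sh <- fit$state$ema1
  for (i in 1:5) sh <- ema_update(sh, fit$state$params1, 0.9)
  gap5 <- max(abs(sh$W1 - fit$state$params1$W1))
  expect_equal(gap5 / gap0, 0.9^5, tolerance = 1e-6)
})

test_that("training fits an easily separable labeled set", {
  fx <- make_train_fixture(seed = 3L)
  cfg <- train_config(epochs = 250L, seed = 3L)
  fit <- dssl_train(fx$tab, fx$split, tiny_cfg(), cfg)
  lab <- subset_rows_tt(fx$tab, fx$split$labeled)
  pred <- predict_labels(fit, lab)
  expect_gte(mean(pred$labels == lab$labels), 0.95)
  expect_lt(fit$history$lx1[nrow(fit$history)], fit$history$lx1[1])
})

test_that("prediction averages branches and breaks ties toward the lowest class", {
  fx <- make_train_fixture()
  fit <- dssl_train(fx$tab, fx$split, tiny_cfg(), train_config(epochs = 2L, seed = 9L))
  st <- fit$state
  pred <- predict_labels(st, fx$tab)
  out <- dual_forward(st, fx$tab$values, use_ema = TRUE)
  expect_equal(pred$probabilities, (out$q1 + out$q2) / 2, tolerance = 1e-12)
  # swapping the branches leaves predictions unchanged
  sw <- st
  sw$params1 <- st$params2; sw$params2 <- st$params1
  sw$ema1 <- st$ema2; sw$ema2 <- st$ema1
  sw$config$pooling <- rev(st$config$pooling)
  expect_identical(predict_labels(sw, fx$tab)$labels, pred$labels)
  # exact tie goes to the lowest index (branch probs [1,0,0] vs [0,1,0])
  tie <- (matrix(c(1, 0, 0), 1, 3) + matrix(c(0, 1, 0), 1, 3)) / 2
  expect_equal(dssl:::argmax_rows(tie) - 1L, 0L)
})

test_that("the EMA-teacher variant trains and differs from the live teacher", {
  fx <- make_train_fixture()
  live <- dssl_train(fx$tab, fx$split, tiny_cfg(),
                     train_config(epochs = 3L, seed = 8L,
                                  loss = loss_config(tau = 0.2)))
  ema <- dssl_train(fx$tab, fx$split, tiny_cfg(),
                    train_config(epochs = 3L, seed = 8L, teacher = "ema",
                                 loss = loss_config(tau = 0.2)))
  expect_false(identical(live$state$params1, ema$state$params1))
  expect_true(all(is.finite(ema$history$total)))
})

test_that("training contract violations error", {
  fx <- make_train_fixture()
  one_class <- fx$split
  one_class$labeled <- which(fx$tab$labels == 0L)[1:5]
  expect_error(dssl_train(fx$tab, one_class, tiny_cfg(), train_config(epochs = 1L)),
               "single class")
  expect_error(dssl_train(fx$tab, fx$split, encoder_config(input_dim = 9L),
                          train_config(epochs = 1L)),
               "does not match")
})
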