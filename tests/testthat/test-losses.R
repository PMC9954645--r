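test_that("supervised loss matches closed forms", {
  u <- matrix(1 / 3, 4, 3)
  expect_equal(supervised_loss(u, c(0L, 1L, 2L, 0L)), log(3), tolerance = 1e-12)
  hot <- matrix(c(1 - 1e-7, 5e-8, 5e-8), 1, 3)
  expect_lt(supervised_loss(hot, 0L), 1e-6)
  q <- matrix(c(0.9, 0.05, 0.05), 1, 3)
  expect_equal(supervised_loss(q, 0L), -log(0.9), tolerance = 1e-12)
  expect_error(supervised_loss(matrix(numeric(0), 0, 3), integer(0)), "empty")
  expect_error(supervised_loss(matrix(c(0.5, 0.2, 0.1), 1, 3), 0L), "probability")
})

test_that("consistency loss applies the confidence mask and muD denominator", {
  t1 <- matrix(c(0.9, 0.05, 0.05), 1, 3)
  expect_equal(consistency_loss(t1, t1, tau = 0.5), -log(0.9), tolerance = 1e-12)
  # teacher below threshold contributes exactly zero
  t2 <- rbind(c(0.4, 0.35, 0.25), c(0.95, 0.03, 0.02))
  s2 <- rbind(c(0.2, 0.5, 0.3), c(0.7, 0.2, 0.1))
  expect_equal(consistency_loss(t2, s2, tau = 0.9), -log(0.7) / 2, tolerance = 1e-12)
  # tau = 0: plain mean cross-entropy toward the teacher argmaxes
  expect_equal(consistency_loss(t2, s2, tau = 0),
               mean(c(-log(0.2), -log(0.7))), tolerance = 1e-12)
})

test_that("consistency loss is non-increasing in the threshold", {
  set.seed(13)
  for (rep in 1:20) {
    tch <- random_simplex(12, 3)
    stu <- random_simplex(12, 3)
    vals <- vapply(seq(0, 1, by = 0.05), function(tau)
      consistency_loss(tch, stu, tau), numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("difference regularizer matches closed forms and is scale invariant", {
  f <- matrix(rnorm(12), 3, 4)
  expect_equal(difference_regularizer(f, f, epsilon = 1e-8), 1e8)
  expect_equal(difference_regularizer(matrix(c(1, 0), 1), matrix(c(0, 1), 1)),
               1 / sqrt(2), tolerance = 1e-7)
  expect_equal(difference_regularizer(matrix(c(2, 0), 1), matrix(c(0, 3), 1)),
               1 / sqrt(2), tolerance = 1e-7)
  set.seed(5)
  a <- matrix(rnorm(20), 4, 5); b <- matrix(rnorm(20), 4, 5)
  expect_equal(difference_regularizer(a * 3.7, b * 0.2),
               difference_regularizer(a, b), tolerance = 1e-9)
  expect_error(difference_regularizer(a, b[, 1:3]), "shapes differ")
})

test_that("the regularizer strictly decreases as embeddings move apart", {
  # rows at angle theta: distance grows with theta, RD must fall
  thetas <- seq(0.1, 3, by = 0.2)
  rd <- vapply(thetas, function(th)
    difference_regularizer(matrix(c(1, 0), 1),
                           matrix(c(cos(th), sin(th)), 1)), numeric(1))
  expect_true(all(diff(rd) < 0))
  # numeric derivative sign at a generic point
  h <- 1e-6
  d <- (difference_regularizer(matrix(c(1, 0), 1), matrix(c(cos(1 + h), sin(1 + h)), 1)) -
        difference_regularizer(matrix(c(1, 0), 1), matrix(c(cos(1 - h), sin(1 - h)), 1))) / (2 * h)
  expect_lt(d, 0)
})

test_that("total_loss combines terms per the objective and is branch-symmetric", {
  set.seed(77)
  mk <- function(n) structure(list(f1 = matrix(rnorm(n * 4), n, 4),
                                   f2 = matrix(rnorm(n * 4), n, 4),
                                   q1 = random_simplex(n, 3),
                                   q2 = random_simplex(n, 3)),
                              class = "batch_outputs")
  ol <- mk(3); ou <- mk(5); y <- c(0L, 2L, 1L)

  zero <- total_loss(ol, y, ou, loss_config(lambda_u = 0, beta = 0))
  expect_equal(zero$total, zero$lx1 + zero$lx2, tolerance = 1e-12)

  cfg <- loss_config(lambda_u = 0.8, beta = 1.7, tau = 0.4)
  lt <- total_loss(ol, y, ou, cfg)
  expect_equal(lt$total,
               lt$lx1 + lt$lx2 + 0.8 * (lt$lu1 + lt$lu2) + 1.7 * lt$rd,
               tolerance = 1e-12)

  swap <- function(o) structure(list(f1 = o$f2, f2 = o$f1, q1 = o$q2, q2 = o$q1),
                                class = "batch_outputs")
  ls <- total_loss(swap(ol), y, swap(ou), cfg)
  expect_equal(ls$total, lt$total, tolerance = 1e-12)
  expect_equal(ls$lx1, lt$lx2)
  expect_equal(ls$lu1, lt$lu2)
})

test_that("total_loss equals an independent loop-based recomputation", {
  set.seed(99)
  for (rep in 1:10) {
    nl <- sample(2:5, 1); nu <- sample(2:7, 1)
    ol <- structure(list(f1 = matrix(rnorm(nl * 4), nl, 4),
                         f2 = matrix(rnorm(nl * 4), nl, 4),
                         q1 = random_simplex(nl, 3), q2 = random_simplex(nl, 3)),
                    class = "batch_outputs")
    ou <- structure(list(f1 = matrix(rnorm(nu * 4), nu, 4),
                         f2 = matrix(rnorm(nu * 4), nu, 4),
                         q1 = random_simplex(nu, 3), q2 = random_simplex(nu, 3)),
                    class = "batch_outputs")
    y <- sample(0:2, nl, replace = TRUE)
    cfg <- loss_config(lambda_u = runif(1, 0, 2), beta = runif(1, 0, 3),
                       tau = runif(1))
    got <- total_loss(ol, y, ou, cfg)
    want <- oracle_total_loss(ol$q1, ol$q2, y, ou$q1, ou$q2,
                              ol$f1, ol$f2, ou$f1, ou$f2,
                              cfg$lambda_u, cfg$beta, cfg$tau, cfg$epsilon)
    expect_equal(got$total, want$total, tolerance = 1e-6)
    expect_equal(got$lu1, want$lu1, tolerance = 1e-9)
    expect_equal(got$rd, want$rd, tolerance = 1e-9)
  }
})
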