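# Shared fixtures: all test data is generated in code.

# small network so unit tests run in milliseconds
tiny_cfg <- function(input_dim = 6L) {
  encoder_config(conv_channels = 4L, embed_dim = 6L, head_hidden = 5L,
                 conv_kernel = 3L, input_dim = input_dim)
}

# random probability matrix with rows on the simplex (gamma normalization)
random_simplex <- function(n, K) {
  g <- matrix(rgamma(n * K, shape = 1), n, K)
  g / rowSums(g)
}

# simulate, select k features, hold out n_test rows, standardize on train
make_std_data <- function(seed, n_per_class = c(229L, 402L, 188L), k = 15L,
                          n_test = 160L, effect_size = 2.0) {
  tab <- simulate_scores(synthetic_spec(n_per_class = n_per_class,
                                        effect_size = effect_size, seed = seed))
  sel <- rank_and_select(tab, k = k)
  n <- nrow(sel$table$values)
  set.seed(seed + 7919L)
  test_idx <- sort(sample.int(n, n_test))
  tr <- subset_rows_tt(sel$table, setdiff(seq_len(n), test_idx))
  te <- subset_rows_tt(sel$table, test_idx)
  st <- standardize_features(tr)
  list(train = st$table, test = standardize_features(te, stats = st$stats)$table)
}

# row subsetting through the public constructor (kept out of package internals)
subset_rows_tt <- function(tab, idx) {
  feature_table(tab$values[idx, , drop = FALSE],
                sample_ids = tab$sample_ids[idx],
                labels = if (is.null(tab$labels)) NULL else tab$labels[idx],
                n_classes = tab$n_classes)
}

# independent from-scratch evaluation of the combined objective: plain loops,
# no shared code with the package's matrix implementation
oracle_total_loss <- function(q1l, q2l, y, q1u, q2u, f1l, f2l, f1u, f2u,
                              lambda, beta, tau, eps = 1e-8) {
  D <- nrow(q1l)
  lx1 <- 0; lx2 <- 0
  for (i in seq_len(D)) {
    lx1 <- lx1 - log(q1l[i, y[i] + 1])
    lx2 <- lx2 - log(q2l[i, y[i] + 1])
  }
  lx1 <- lx1 / D; lx2 <- lx2 / D
  mu <- nrow(q1u)
  lu1 <- 0; lu2 <- 0
  for (i in seq_len(mu)) {
    if (max(q2u[i, ]) >= tau) {
      ps <- which(q2u[i, ] == max(q2u[i, ]))[1]
      lu1 <- lu1 - log(q1u[i, ps])
    }
    if (max(q1u[i, ]) >= tau) {
      ps <- which(q1u[i, ] == max(q1u[i, ]))[1]
      lu2 <- lu2 - log(q2u[i, ps])
    }
  }
  lu1 <- lu1 / mu; lu2 <- lu2 / mu
  f1 <- rbind(f1l, f1u); f2 <- rbind(f2l, f2u)
  ss <- 0
  for (i in seq_len(nrow(f1))) {
    r1 <- sqrt(sum(f1[i, ]^2)); n1 <- if (r1 > 0) f1[i, ] / r1 else f1[i, ] * 0
    r2 <- sqrt(sum(f2[i, ]^2)); n2 <- if (r2 > 0) f2[i, ] / r2 else f2[i, ] * 0
    ss <- ss + sum((n1 - n2)^2)
  }
  rd <- 1 / (sqrt(ss) + eps)
  list(lx1 = lx1, lx2 = lx2, lu1 = lu1, lu2 = lu2, rd = rd,
       total = lx1 + lx2 + lambda * (lu1 + lu2) + beta * rd)
}

# independent one-vs-rest metric recount (direct set counting, no confusion
# matrix), mirroring the printed formula set with the paper's SEN convention
oracle_metrics <- function(y_true, y_pred, K) {
  out <- NULL
  n <- length(y_true)
  for (c in 0:(K - 1)) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    tn <- n - tp - fp - fn
    div <- function(a, b) if (b == 0) 0 else a / b
    out <- rbind(out, c(acc = (tp + tn) / n, sen = div(tp, tp + fp),
                        spe = div(tn, tn + fp), rec = div(tp, tp + fn),
                        f1 = div(2 * tp, 2 * tp + fp + fn)))
  }
  list(per_class = out, macro = colMeans(out),
       overall = mean(y_true == y_pred))
}
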