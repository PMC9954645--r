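#' Training configuration
#'
#' @param epochs Number of passes over the unlabeled pool (default 200).
#' @param labeled_batch Labeled mini-batch size (default 16). Sampled with
#'   replacement when the labeled set is smaller than the batch.
#' @param unlabeled_batch Unlabeled mini-batch size (default 64).
#' @param learning_rate Adam step size (default 1e-3). No learning-rate decay
#'   schedule is used; EMA parameter averaging takes that role.
#' @param ema_decay EMA decay in `[0, 1]` (default 0.999).
#' @param ema_ramp Warm up the EMA decay as `min(ema_decay, (1 + t) / (10 + t))`
#'   over steps `t` (default `TRUE`). Without the ramp the shadow parameters
#'   stay anchored to the random initialization for roughly `1/(1 - decay)`
#'   steps, which at small problem sizes can exceed the whole run.
#' @param teacher Where the consistency pseudo-labels come from: `"live"`
#'   (default) hardens the other branch's live-parameter predictions from the
#'   same forward pass; `"ema"` hardens its EMA-parameter predictions
#'   (mean-teacher style).
#' @param loss A [loss_config()].
#' @param seed Master seed; model initialization, labeled batch sampling and
#'   unlabeled batch order are derived from it as independent streams.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, labeled_batch = 16L,
                         unlabeled_batch = 64L, learning_rate = 1e-3,
                         ema_decay = 0.999, ema_ramp = TRUE,
                         teacher = c("live", "ema"),
                         loss = loss_config(), seed = 1L) {
  epochs <- check_count(epochs, "epochs", min = 0L)
  labeled_batch <- check_count(labeled_batch, "labeled_batch")
  unlabeled_batch <- check_count(unlabeled_batch, "unlabeled_batch")
  learning_rate <- check_number(learning_rate, "learning_rate", lo = 0)
  ema_decay <- check_number(ema_decay, "ema_decay", lo = 0, hi = 1)
  stopifnot(is.logical(ema_ramp), length(ema_ramp) == 1L)
  teacher <- match.arg(teacher)
  stopifnot(inherits(loss, "loss_config"))
  seed <- check_count(seed, "seed", min = 0L)
  structure(list(epochs = epochs, labeled_batch = labeled_batch,
                 unlabeled_batch = unlabeled_batch,
                 learning_rate = learning_rate, ema_decay = ema_decay,
                 ema_ramp = ema_ramp, teacher = teacher, loss = loss,
                 seed = seed),
            class = "train_config")
}

#' Exponential-moving-average parameter update
#'
#' Every shadow tensor is replaced by
#' `decay * shadow + (1 - decay) * live`. With decay 1 the shadow never
#' moves; with decay 0 it tracks the live parameters exactly.
#'
#' @param shadow,live Parameter lists of identical shapes.
#' @param decay EMA decay in `[0, 1]`.
#' @return The updated shadow list.
#' @export
ema_update <- function(shadow, live, decay) {
  decay <- check_number(decay, "decay", lo = 0, hi = 1)
  if (length(shadow) != length(live) || !identical(names(shadow), names(live)))
    stop("shadow and live parameter lists do not match", call. = FALSE)
  for (nm in names(shadow)) {
    if (!identical(dim2(shadow[[nm]]), dim2(live[[nm]])))
      stop(sprintf("shape mismatch in parameter '%s'", nm), call. = FALSE)
    shadow[[nm]] <- decay * shadow[[nm]] + (1 - decay) * live[[nm]]
  }
  shadow
}

dim2 <- function(x) if (is.matrix(x)) dim(x) else length(x)

# --- Adam optimizer over a branch's parameter list -------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros)
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# hot-loop EMA without the per-call shape validation of ema_update()
ema_fast <- function(shadow, live, decay) {
  for (nm in names(shadow))
    shadow[[nm]] <- decay * shadow[[nm]] + (1 - decay) * live[[nm]]
  shadow
}

# --- gradient of the combined objective ------------------------------------

onehot <- function(y, K) {
  m <- matrix(0, length(y), K)
  m[cbind(seq_along(y), y + 1L)] <- 1
  m
}

# Gradient of beta * RD wrt the two stacked embedding matrices.
# RD = 1/(s + eps), s = ||N(f1) - N(f2)||_F with row-normalized N.
rd_gradient <- function(f1, f2, epsilon, beta) {
  n1 <- normalize_rows(f1)
  n2 <- normalize_rows(f2)
  Dm <- n1 - n2
  s <- sqrt(sum(Dm^2))
  rd <- 1 / (s + epsilon)
  if (s < 1e-12 || beta == 0) {
    z <- f1 * 0
    return(list(rd = rd, df1 = z, df2 = z))
  }
  dN1 <- -beta * Dm / (s * (s + epsilon)^2) # d(beta*RD)/dN1; dN2 = -dN1
  back_norm <- function(dN, f, nf) {
    r <- sqrt(rowSums(f^2))
    keep <- r > 0
    r[!keep] <- 1
    proj <- rowSums(dN * nf)
    out <- (dN - nf * proj) / r
    out[!keep, ] <- 0
    out
  }
  list(rd = rd, df1 = back_norm(dN1, f1, n1), df2 = back_norm(-dN1, f2, n2))
}

# One training step on a labeled batch (Xl, y) and optional unlabeled batch
# Xu: evaluates all loss terms and returns gradients for both branches. The
# labeled and unlabeled rows go through one joint forward/backward pass per
# branch (the network has no cross-sample coupling, so stacking is exact).
dssl_step_grads <- function(state, Xl, y, Xu, lcfg, teacher = "live") {
  cfg <- state$config
  K <- cfg$n_classes
  p1 <- state$params1; p2 <- state$params2
  pool1 <- cfg$pooling[1L]; pool2 <- cfg$pooling[2L]

  nl <- nrow(Xl)
  semi <- !is.null(Xu)
  X <- if (semi) rbind(Xl, Xu) else Xl
  o1 <- forward_branch(p1, X, pool1, cfg, want_cache = TRUE)
  o2 <- forward_branch(p2, X, pool2, cfg, want_cache = TRUE)
  il <- seq_len(nl)

  Y <- onehot(y, K)
  dlog1 <- matrix(0, nrow(X), K)
  dlog2 <- matrix(0, nrow(X), K)
  dlog1[il, ] <- (o1$q[il, , drop = FALSE] - Y) / nl
  dlog2[il, ] <- (o2$q[il, , drop = FALSE] - Y) / nl
  lx1 <- -mean(log(o1$q[cbind(il, y + 1L)]))
  lx2 <- -mean(log(o2$q[cbind(il, y + 1L)]))

  if (semi) {
    nu <- nrow(Xu)
    iu <- nl + seq_len(nu)
    q1u <- o1$q[iu, , drop = FALSE]
    q2u <- o2$q[iu, , drop = FALSE]
    # branch 2 teaches branch 1 (lu1) and vice versa; teachers are detached.
    # Pseudo-labels and masks come from the live predictions above or, in
    # mean-teacher mode, from an extra EMA-parameter forward pass.
    if (teacher == "ema") {
      q1t <- forward_branch(state$ema1, Xu, pool1, cfg)$q
      q2t <- forward_branch(state$ema2, Xu, pool2, cfg)$q
    } else {
      q1t <- q1u
      q2t <- q2u
    }
    pse1 <- max.col(q1t, ties.method = "first"); pass1 <- row_max(q1t) >= lcfg$tau
    pse2 <- max.col(q2t, ties.method = "first"); pass2 <- row_max(q2t) >= lcfg$tau
    lu1 <- sum(-log(q1u[cbind(seq_len(nu), pse2)]) * pass2) / nu
    lu2 <- sum(-log(q2u[cbind(seq_len(nu), pse1)]) * pass1) / nu
    dlog1[iu, ] <- lcfg$lambda_u * ((q1u - onehot(pse2 - 1L, K)) * pass2) / nu
    dlog2[iu, ] <- lcfg$lambda_u * ((q2u - onehot(pse1 - 1L, K)) * pass1) / nu
  } else {
    lu1 <- 0; lu2 <- 0
  }

  rg <- rd_gradient(o1$f, o2$f, lcfg$epsilon, lcfg$beta)
  g1 <- backward_branch(p1, o1$cache, dlog1, rg$df1, pool1, cfg)
  g2 <- backward_branch(p2, o2$cache, dlog2, rg$df2, pool2, cfg)

  total <- lx1 + lx2 + lcfg$lambda_u * (lu1 + lu2) + lcfg$beta * rg$rd
  list(g1 = g1, g2 = g2,
       terms = c(lx1 = lx1, lx2 = lx2, lu1 = lu1, lu2 = lu2,
                 rd = rg$rd, total = total))
}

#' Train a dual semi-supervised model
#'
#' Runs the DSSL optimization loop: each step draws one labeled and one
#' unlabeled mini-batch, evaluates the combined objective (supervised
#' cross-entropy, mutual confidence-thresholded pseudo-label consistency,
#' difference regularizer), applies a single Adam update to the parameters of
#' both branches jointly, and then updates the EMA shadow parameters. An
#' epoch is one shuffled pass over the unlabeled pool.
#'
#' When `loss$lambda_u == 0` and `loss$beta == 0` the unlabeled pool is
#' ignored entirely and the loop reduces to plain supervised training of the
#' two branches (the step count is kept identical so runs are comparable).
#'
#' Fully reproducible: the master seed is split into independent streams for
#' model initialization, labeled batch sampling and unlabeled batch order, so
#' two calls with the same inputs return bit-identical parameters.
#'
#' @param table A [feature_table()] of already selected and standardized
#'   features, with labels at least on the labeled rows.
#' @param split A [make_label_split()] partition of the table's rows.
#' @param model_config An [encoder_config()]; its `input_dim` must match the
#'   table width.
#' @param config A [train_config()].
#' @return A list of class `dssl_fit` with elements `state` (the trained
#'   [init_dual_model()] state), `history` (data frame of per-epoch means of
#'   `lx1, lx2, lu1, lu2, rd, total`), and the resolved configs.
#' @export
dssl_train <- function(table, split, model_config = encoder_config(),
                       config = train_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(split, "label_split"),
            inherits(model_config, "encoder_config"), inherits(config, "train_config"))
  if (model_config$input_dim != ncol(table$values))
    stop(sprintf("model input_dim (%d) does not match the table (%d features)",
                 model_config$input_dim, ncol(table$values)), call. = FALSE)
  D <- length(split$labeled)
  if (D == 0L) stop("labeled set is empty", call. = FALSE)
  y <- table$labels[split$labeled]
  if (is.null(y) || anyNA(y)) stop("labeled rows must carry labels", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("labeled set contains a single class; training is ill-posed", call. = FALSE)

  Xlab <- table$values[split$labeled, , drop = FALSE]
  Xunl <- table$values[split$unlabeled, , drop = FALSE]
  nu <- nrow(Xunl)
  lcfg <- config$loss
  supervised_only <- lcfg$lambda_u == 0 && lcfg$beta == 0
  use_unlabeled <- nu > 0L && !supervised_only

  lb <- config$labeled_batch
  ub <- config$unlabeled_batch
  steps <- if (nu > 0L) ceiling(nu / ub) else ceiling(D / lb)

  state <- init_dual_model(model_config, seed = derive_seed(config$seed, 0L))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  # pre-draw all batch indices so the labeled stream is identical whether or
  # not the unlabeled pool is consumed
  set.seed(derive_seed(config$seed, 1L))
  lab_batches <- replicate(config$epochs * steps,
                           sample.int(D, min(lb, D), replace = D < lb),
                           simplify = FALSE)
  set.seed(derive_seed(config$seed, 2L))
  unl_orders <- replicate(config$epochs, sample.int(max(nu, 1L)), simplify = FALSE)

  opt1 <- adam_init(state$params1)
  opt2 <- adam_init(state$params2)
  t_step <- 0L
  hist <- matrix(NA_real_, config$epochs, 6L,
                 dimnames = list(NULL, c("lx1", "lx2", "lu1", "lu2", "rd", "total")))

  for (ep in seq_len(config$epochs)) {
    acc <- numeric(6L)
    ord <- unl_orders[[ep]]
    for (st in seq_len(steps)) {
      bi <- lab_batches[[(ep - 1L) * steps + st]]
      Xu <- NULL
      if (use_unlabeled) {
        lo <- (st - 1L) * ub + 1L
        hi <- min(st * ub, nu)
        Xu <- Xunl[ord[lo:hi], , drop = FALSE]
      }
      sg <- dssl_step_grads(state, Xlab[bi, , drop = FALSE], y[bi], Xu, lcfg,
                            teacher = config$teacher)
      if (!is.finite(sg$terms[["total"]]))
        stop(sprintf("non-finite loss at epoch %d step %d: %s", ep, st,
                     paste(sprintf("%s=%.3g", names(sg$terms), sg$terms), collapse = " ")),
             call. = FALSE)
      t_step <- t_step + 1L
      r1 <- adam_step(state$params1, sg$g1, opt1, config$learning_rate, t_step)
      r2 <- adam_step(state$params2, sg$g2, opt2, config$learning_rate, t_step)
      state$params1 <- r1$params; opt1 <- r1$state
      state$params2 <- r2$params; opt2 <- r2$state
      decay_t <- if (config$ema_ramp)
        min(config$ema_decay, (1 + t_step) / (10 + t_step)) else config$ema_decay
      state$ema1 <- ema_fast(state$ema1, state$params1, decay_t)
      state$ema2 <- ema_fast(state$ema2, state$params2, decay_t)
      acc <- acc + sg$terms
    }
    hist[ep, ] <- acc / steps
  }

  structure(list(state = state,
                 history = data.frame(epoch = seq_len(config$epochs), hist),
                 model_config = model_config, config = config),
            class = "dssl_fit")
}

#' @export
print.dssl_fit <- function(x, ...) {
  cat(sprintf("dssl_fit: %d epochs; final total loss %.4f\n",
              nrow(x$history),
              if (nrow(x$history)) x$history$total[nrow(x$history)] else NA))
  print(x$state)
  invisible(x)
}

#' Predict diagnostic classes
#'
#' Inference rule: forward both branches with their EMA parameters, average
#' the two softmax outputs elementwise, and take the argmax (ties broken
#' toward the lowest class index). Averaging is symmetric in the branches.
#'
#' @param fit A `dssl_fit` or `dual_model_state`.
#' @param table A [feature_table()] or numeric matrix with matching features.
#' @param use_ema Use EMA parameters (default `TRUE`).
#' @return A list with `labels` (integer vector, class indices) and
#'   `probabilities` (matrix of averaged class probabilities).
#' @export
predict_labels <- function(fit, table, use_ema = TRUE) {
  state <- if (inherits(fit, "dssl_fit")) fit$state else fit
  stopifnot(inherits(state, "dual_model_state"))
  X <- if (inherits(table, "feature_table")) table$values else as.matrix(table)
  out <- dual_forward(state, X, use_ema = use_ema)
  probs <- (out$q1 + out$q2) / 2
  list(labels = argmax_rows(probs) - 1L, probabilities = probs)
}
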