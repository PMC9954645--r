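#' Configuration of the dual-encoder model
#'
#' Each of the two branches is a small 1-D convolutional encoder followed by a
#' perceptron head. An input score vector passes through: a fully connected
#' expansion (kept at the input width), a one-dimensional convolution along
#' the feature axis, a pooling layer (window 2, stride 2), and a fully
#' connected projection to the embedding. The head is a one-hidden-layer
#' perceptron with softmax output over the diagnostic classes.
#'
#' The only architectural difference between the two branches in the default
#' configuration is the pooling operator: branch 1 uses max pooling, branch 2
#' average pooling. This model perturbation is what makes the two branches
#' produce genuinely different representations of the same subject.
#'
#' @param pooling Character vector of length 2 with the pooling operator of
#'   each branch, each `"max"` or `"avg"` (default `c("max", "avg")`).
#' @param conv_channels Number of convolution channels (default 16).
#' @param conv_kernel Odd convolution kernel width (default 3).
#' @param embed_dim Embedding dimension (default 32).
#' @param head_hidden Hidden width of the perceptron head (default 32).
#' @param n_classes Number of classes (default 3).
#' @param input_dim Number of input features (default 15).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(pooling = c("max", "avg"), conv_channels = 16L,
                           conv_kernel = 3L, embed_dim = 32L,
                           head_hidden = 32L, n_classes = 3L, input_dim = 15L) {
  if (length(pooling) != 2L || !all(pooling %in% c("max", "avg")))
    stop_field("pooling", 'must be two values from {"max", "avg"}')
  conv_channels <- check_count(conv_channels, "conv_channels")
  conv_kernel <- check_count(conv_kernel, "conv_kernel")
  if (conv_kernel %% 2L == 0L) stop_field("conv_kernel", "must be odd")
  embed_dim <- check_count(embed_dim, "embed_dim")
  head_hidden <- check_count(head_hidden, "head_hidden")
  n_classes <- check_count(n_classes, "n_classes", min = 2L)
  input_dim <- check_count(input_dim, "input_dim", min = 2L)
  if (conv_kernel > input_dim) stop_field("conv_kernel", "must not exceed input_dim")
  structure(
    list(pooling = pooling, conv_channels = conv_channels,
         conv_kernel = conv_kernel, embed_dim = embed_dim,
         head_hidden = head_hidden, n_classes = n_classes,
         input_dim = input_dim),
    class = "encoder_config"
  )
}

# He-initialized weight matrix (gain 2 / fan_in, suited to ReLU units).
init_weight <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

# One branch's parameters: encoder (W1/b1 expansion, Wc/bc convolution,
# W2/b2 projection) and head (Wh1/bh1, Wh2/bh2). He initialization for every
# weight matrix, zero biases — the standard scheme for ReLU networks. The two
# branches draw independently, so their heads start genuinely different;
# that diversity is what makes the mutual pseudo-labels informative.
init_branch <- function(cfg) {
  d <- cfg$input_dim; k <- cfg$conv_kernel; C <- cfg$conv_channels
  P <- d %/% 2L; E <- cfg$embed_dim; H <- cfg$head_hidden; K <- cfg$n_classes
  list(W1 = init_weight(d, d, d), b1 = numeric(d),
       Wc = init_weight(k, C, k), bc = numeric(C),
       W2 = init_weight(P * C, E, P * C), b2 = numeric(E),
       Wh1 = init_weight(E, H, E), bh1 = numeric(H),
       Wh2 = init_weight(H, K, H), bh2 = numeric(K))
}

#' Initialize a dual model
#'
#' Draws independent parameters for the two branches and sets the EMA shadow
#' copies equal to the live parameters. Deterministic given the seed.
#'
#' @param config An [encoder_config()].
#' @param seed RNG seed.
#' @return An object of class `dual_model_state`: list with `config`,
#'   `params1`, `params2` (live parameters) and `ema1`, `ema2` (shadow
#'   parameters of identical shapes).
#' @export
init_dual_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "encoder_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  p1 <- init_branch(config)
  p2 <- init_branch(config)
  structure(list(config = config, params1 = p1, params2 = p2,
                 ema1 = p1, ema2 = p2),
            class = "dual_model_state")
}

#' @export
print.dual_model_state <- function(x, ...) {
  n_par <- sum(vapply(c(x$params1, x$params2), length, integer(1)))
  cat(sprintf("dual_model_state: %d features -> %d-dim embeddings -> %d classes; pooling %s + %s; %d parameters\n",
              x$config$input_dim, x$config$embed_dim, x$config$n_classes,
              x$config$pooling[1], x$config$pooling[2], n_par))
  invisible(x)
}

# Forward pass through one branch. Returns f (embeddings), q (class
# probabilities) and, when want_cache, the intermediates needed by backprop.
forward_branch <- function(params, X, pooling, cfg, want_cache = FALSE) {
  n <- nrow(X)
  d <- cfg$input_dim; k <- cfg$conv_kernel; C <- cfg$conv_channels
  h <- (k - 1L) %/% 2L; P <- d %/% 2L

  Z1 <- X %*% params$W1 + rep(params$b1, each = n)
  A1 <- relu(Z1)

  # im2col for the length-d, zero-padded, stride-1 "same" convolution
  A1pad <- matrix(0, n, d + 2L * h)
  A1pad[, (h + 1L):(h + d)] <- A1
  M <- matrix(0, n * d, k)
  for (j in seq_len(k)) M[, j] <- A1pad[, j:(j + d - 1L)]
  Z2 <- M %*% params$Wc + rep(params$bc, each = n * d)
  A2 <- relu(Z2)

  dim(A2) <- c(n, d, C)
  odd <- seq.int(1L, 2L * P - 1L, by = 2L)
  a_odd <- A2[, odd, , drop = FALSE]
  a_even <- A2[, odd + 1L, , drop = FALSE]
  if (pooling == "max") {
    pool <- pmax(a_odd, a_even)
    mask_odd <- a_odd >= a_even # ties credited to the first element
  } else {
    pool <- (a_odd + a_even) / 2
    mask_odd <- NULL
  }
  dim(pool) <- c(n, P * C)
  Fl <- pool

  f <- Fl %*% params$W2 + rep(params$b2, each = n)
  Zh1 <- f %*% params$Wh1 + rep(params$bh1, each = n)
  Ah1 <- relu(Zh1)
  logits <- Ah1 %*% params$Wh2 + rep(params$bh2, each = n)
  q <- softmax_rows(logits)

  out <- list(f = f, q = q)
  if (want_cache)
    out$cache <- list(X = X, Z1 = Z1, M = M, Z2 = Z2, mask_odd = mask_odd,
                      Fl = Fl, f = f, Zh1 = Zh1, Ah1 = Ah1, n = n)
  out
}

# Backward pass through one branch. dlogits is the gradient of the loss wrt
# the pre-softmax logits; df the gradient arriving directly at the embedding
# (from the difference regularizer). Returns a gradient list shaped like the
# parameter list.
backward_branch <- function(params, cache, dlogits, df, pooling, cfg) {
  n <- cache$n
  d <- cfg$input_dim; k <- cfg$conv_kernel; C <- cfg$conv_channels
  h <- (k - 1L) %/% 2L; P <- d %/% 2L

  gWh2 <- crossprod(cache$Ah1, dlogits)
  gbh2 <- colSums(dlogits)
  dAh1 <- tcrossprod(dlogits, params$Wh2)
  dZh1 <- dAh1 * (cache$Zh1 > 0)
  gWh1 <- crossprod(cache$f, dZh1)
  gbh1 <- colSums(dZh1)

  df_tot <- tcrossprod(dZh1, params$Wh1)
  if (!is.null(df)) df_tot <- df_tot + df

  gW2 <- crossprod(cache$Fl, df_tot)
  gb2 <- colSums(df_tot)
  dFl <- tcrossprod(df_tot, params$W2)

  dpool <- dFl
  dim(dpool) <- c(n, P, C)
  dA2 <- array(0, c(n, d, C))
  odd <- seq.int(1L, 2L * P - 1L, by = 2L)
  if (pooling == "max") {
    dA2[, odd, ] <- dpool * cache$mask_odd
    dA2[, odd + 1L, ] <- dpool * !cache$mask_odd
  } else {
    dA2[, odd, ] <- dpool / 2
    dA2[, odd + 1L, ] <- dpool / 2
  }
  dim(dA2) <- c(n * d, C)
  dZ2 <- dA2 * (cache$Z2 > 0)

  gWc <- crossprod(cache$M, dZ2)
  gbc <- colSums(dZ2)
  dM <- tcrossprod(dZ2, params$Wc)

  dA1pad <- matrix(0, n, d + 2L * h)
  for (j in seq_len(k)) {
    dMj <- dM[, j]
    dim(dMj) <- c(n, d)
    dA1pad[, j:(j + d - 1L)] <- dA1pad[, j:(j + d - 1L)] + dMj
  }
  dZ1 <- dA1pad[, (h + 1L):(h + d), drop = FALSE] * (cache$Z1 > 0)

  gW1 <- crossprod(cache$X, dZ1)
  gb1 <- colSums(dZ1)

  list(W1 = gW1, b1 = gb1, Wc = gWc, bc = gbc, W2 = gW2, b2 = gb2,
       Wh1 = gWh1, bh1 = gbh1, Wh2 = gWh2, bh2 = gbh2)
}

#' Forward pass through both branches
#'
#' Inference-mode forward: no dropout, no batch coupling — the output of each
#' row depends only on that row. Returns embeddings and class probabilities
#' of both branches.
#'
#' @param state A [init_dual_model()] state.
#' @param batch Numeric matrix with `input_dim` columns.
#' @param use_ema Use the EMA shadow parameters instead of the live ones.
#' @return An object of class `batch_outputs`: list with embedding matrices
#'   `f1`, `f2` (`batch x embed_dim`) and probability matrices `q1`, `q2`
#'   (`batch x n_classes`, rows on the simplex).
#' @export
dual_forward <- function(state, batch, use_ema = FALSE) {
  stopifnot(inherits(state, "dual_model_state"))
  batch <- as.matrix(batch)
  if (ncol(batch) != state$config$input_dim)
    stop(sprintf("batch has %d columns but the model expects %d",
                 ncol(batch), state$config$input_dim), call. = FALSE)
  p1 <- if (use_ema) state$ema1 else state$params1
  p2 <- if (use_ema) state$ema2 else state$params2
  o1 <- forward_branch(p1, batch, state$config$pooling[1L], state$config)
  o2 <- forward_branch(p2, batch, state$config$pooling[2L], state$config)
  structure(list(f1 = o1$f, f2 = o2$f, q1 = o1$q, q2 = o2$q),
            class = "batch_outputs")
}

#' Save / load a model checkpoint
#'
#' Checkpoints are plain JSON holding the configuration and the live and EMA
#' parameters at full printed double precision, so a reloaded model
#' reproduces the saved model's predictions to within rounding of the last
#' significant digit.
#'
#' @param state A `dual_model_state`.
#' @param path File path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `dual_model_state`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "dual_model_state"))
  ser_branch <- function(p) lapply(p, function(m) {
    if (is.matrix(m)) list(dim = dim(m), data = as.vector(m))
    else list(dim = length(m), data = as.vector(m))
  })
  obj <- list(config = unclass(state$config),
              params1 = ser_branch(state$params1), params2 = ser_branch(state$params2),
              ema1 = ser_branch(state$ema1), ema2 = ser_branch(state$ema2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(encoder_config, obj$config)
  de_branch <- function(p) lapply(p, function(e) {
    if (length(e$dim) == 2L) matrix(e$data, e$dim[1L], e$dim[2L]) else as.numeric(e$data)
  })
  structure(list(config = cfg,
                 params1 = de_branch(obj$params1), params2 = de_branch(obj$params2),
                 ema1 = de_branch(obj$ema1), ema2 = de_branch(obj$ema2)),
            class = "dual_model_state")
}
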