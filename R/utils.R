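# Internal helpers: validation and seed-stream derivation.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    stop_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_number <- function(x, field, lo = -Inf, hi = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi)
    stop_field(field, sprintf("must be a single number in [%s, %s]", lo, hi))
  as.numeric(x)
}

#' Derive an independent child seed from a master seed
#'
#' Splits one master seed into named sub-streams (model init, label split,
#' batch order, ...) so that experiments can vary one source of randomness at
#' a time. Uses a multiplicative congruential step on the 31-bit integer ring,
#' so derived seeds stay valid R seeds.
#'
#' @param seed Master seed (single integer).
#' @param stream Small non-negative integer identifying the sub-stream.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(as.double(seed)) %% (m - 1)) + 1
  for (i in seq_len(stream + 1L)) {
    s <- (s * 48271) %% m
  }
  as.integer(max(1, s %% (m - 1)))
}

# Maximum of each row (column-major recycling keeps this allocation-light).
row_max <- function(q) q[cbind(seq_len(nrow(q)), max.col(q, ties.method = "first"))]

# Row-wise softmax, numerically stable.
softmax_rows <- function(z) {
  e <- exp(z - row_max(z))
  e / rowSums(e)
}

relu <- function(x) x * (x > 0)

# argmax per row, ties broken toward the lowest index
argmax_rows <- function(q) max.col(q, ties.method = "first")
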