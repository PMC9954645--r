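#' Loss configuration
#'
#' Coefficients of the combined training objective
#' `total = lx1 + lx2 + lambda * (lu1 + lu2) + beta * RD`:
#' supervised cross-entropy on both branches, mutual pseudo-label consistency
#' on the unlabeled pool weighted by `lambda`, and the difference regularizer
#' weighted by `beta`.
#'
#' @param lambda_u Consistency weight `lambda >= 0` (default 1: supervised and
#'   consistency losses treated as equally important).
#' @param beta Difference-regularizer weight `beta >= 0` (default 2).
#' @param tau Confidence threshold in `[0, 1]` (default 0.9): an unlabeled
#'   sample contributes to the consistency loss only when the teacher
#'   branch's maximum predicted probability reaches `tau`.
#' @param epsilon Small positive guard added to the regularizer denominator
#'   (default 1e-8), which is otherwise singular when the two normalized
#'   embeddings coincide.
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(lambda_u = 1, beta = 2, tau = 0.9, epsilon = 1e-8) {
  lambda_u <- check_number(lambda_u, "lambda_u", lo = 0)
  beta <- check_number(beta, "beta", lo = 0)
  tau <- check_number(tau, "tau", lo = 0, hi = 1)
  epsilon <- check_number(epsilon, "epsilon")
  if (epsilon <= 0) stop_field("epsilon", "must be > 0")
  structure(list(lambda_u = lambda_u, beta = beta, tau = tau, epsilon = epsilon),
            class = "loss_config")
}

check_prob_matrix <- function(q, name = "q") {
  q <- as.matrix(q)
  if (any(q < 0) || any(abs(rowSums(q) - 1) > 1e-6))
    stop(sprintf("`%s` rows must be probability vectors", name), call. = FALSE)
  q
}

#' Supervised cross-entropy loss
#'
#' Mean negative log-probability of the true class:
#' `-(1/D) * sum_i log q[i, y_i]`.
#'
#' @param q Probability matrix, one row per labeled sample.
#' @param y Integer class labels in `0..n_classes-1`.
#' @return A single non-negative number.
#' @export
supervised_loss <- function(q, y) {
  q <- check_prob_matrix(q)
  if (nrow(q) == 0L) stop("empty batch", call. = FALSE)
  if (length(y) != nrow(q)) stop("length(y) must equal nrow(q)", call. = FALSE)
  if (any(y < 0L | y >= ncol(q))) stop("labels outside 0..n_classes-1", call. = FALSE)
  -mean(log(q[cbind(seq_len(nrow(q)), y + 1L)]))
}

#' Confidence-thresholded pseudo-label consistency loss
#'
#' Each teacher row is turned into a hard pseudo-label (argmax, ties broken
#' toward the lowest class index). A row contributes the cross-entropy
#' `-log q_student[pseudo]` when the teacher's maximum probability reaches
#' `tau`, and 0 otherwise. The sum is divided by the total number of rows —
#' masked-out rows still count in the denominator — so the loss is the
#' per-unlabeled-sample average.
#'
#' @param q_teacher,q_student Probability matrices of identical shape.
#' @param tau Confidence threshold in `[0, 1]`.
#' @return A single non-negative number, non-increasing in `tau`.
#' @export
consistency_loss <- function(q_teacher, q_student, tau) {
  q_teacher <- check_prob_matrix(q_teacher, "q_teacher")
  q_student <- check_prob_matrix(q_student, "q_student")
  if (!all(dim(q_teacher) == dim(q_student)))
    stop("teacher and student shapes differ", call. = FALSE)
  if (nrow(q_teacher) == 0L) stop("empty batch", call. = FALSE)
  tau <- check_number(tau, "tau", lo = 0, hi = 1)
  maxp <- apply(q_teacher, 1L, max)
  pseudo <- argmax_rows(q_teacher)
  pass <- maxp >= tau
  contrib <- -log(q_student[cbind(seq_len(nrow(q_student)), pseudo)]) * pass
  sum(contrib) / nrow(q_teacher)
}

# Row-wise L2 normalization; all-zero rows are left as zeros.
normalize_rows <- function(f) {
  r <- sqrt(rowSums(f^2))
  r[r == 0] <- 1
  f / r
}

#' Difference regularizer
#'
#' The reciprocal Frobenius distance between the two branches' row-normalized
#' embeddings, `RD = 1 / (||Norm(f1) - Norm(f2)||_F + epsilon)`. Minimizing
#' `RD` pushes the two representations of the same batch apart; row
#' normalization makes the term invariant to per-sample rescaling of either
#' embedding.
#'
#' @param f1,f2 Embedding matrices of identical shape, at least one row.
#' @param epsilon Positive guard for the coinciding-embedding singularity.
#' @return A single positive number; `1/epsilon` when `f1` and `f2` normalize
#'   identically.
#' @export
difference_regularizer <- function(f1, f2, epsilon = 1e-8) {
  f1 <- as.matrix(f1); f2 <- as.matrix(f2)
  if (!all(dim(f1) == dim(f2))) stop("f1 and f2 shapes differ", call. = FALSE)
  if (nrow(f1) == 0L) stop("empty batch", call. = FALSE)
  s <- sqrt(sum((normalize_rows(f1) - normalize_rows(f2))^2))
  1 / (s + epsilon)
}

#' Combined training objective
#'
#' Evaluates all loss terms on one labeled and one unlabeled batch:
#' supervised cross-entropy of each branch on the labeled batch (`lx1`,
#' `lx2`), the two mutual consistency losses on the unlabeled batch — branch
#' 2's prediction serves as the pseudo-label for branch 1 (`lu1`) and vice
#' versa (`lu2`) — and the difference regularizer `rd` computed over the
#' row-concatenation of both batches' embeddings. The total is
#' `lx1 + lx2 + lambda * (lu1 + lu2) + beta * rd`.
#'
#' The combination is symmetric under swapping the two branches.
#'
#' @param outputs_labeled [dual_forward()] outputs on the labeled batch.
#' @param y Integer labels of the labeled batch.
#' @param outputs_unlabeled [dual_forward()] outputs on the unlabeled batch,
#'   or `NULL` for a supervised-only evaluation (then `lu1 = lu2 = 0` and
#'   `rd` uses the labeled embeddings alone).
#' @param cfg A [loss_config()].
#' @return An object of class `loss_terms`: list with `lx1`, `lx2`, `lu1`,
#'   `lu2`, `rd`, `total` and the coefficients used.
#' @export
total_loss <- function(outputs_labeled, y, outputs_unlabeled, cfg) {
  stopifnot(inherits(cfg, "loss_config"))
  lx1 <- supervised_loss(outputs_labeled$q1, y)
  lx2 <- supervised_loss(outputs_labeled$q2, y)
  if (!is.null(outputs_unlabeled)) {
    lu1 <- consistency_loss(outputs_unlabeled$q2, outputs_unlabeled$q1, cfg$tau)
    lu2 <- consistency_loss(outputs_unlabeled$q1, outputs_unlabeled$q2, cfg$tau)
    f1 <- rbind(outputs_labeled$f1, outputs_unlabeled$f1)
    f2 <- rbind(outputs_labeled$f2, outputs_unlabeled$f2)
  } else {
    lu1 <- 0; lu2 <- 0
    f1 <- outputs_labeled$f1
    f2 <- outputs_labeled$f2
  }
  rd <- difference_regularizer(f1, f2, cfg$epsilon)
  structure(list(lx1 = lx1, lx2 = lx2, lu1 = lu1, lu2 = lu2, rd = rd,
                 total = lx1 + lx2 + cfg$lambda_u * (lu1 + lu2) + cfg$beta * rd,
                 lambda_u = cfg$lambda_u, beta = cfg$beta, tau = cfg$tau),
            class = "loss_terms")
}

#' @export
print.loss_terms <- function(x, ...) {
  cat(sprintf("loss_terms: lx1 %.4f lx2 %.4f lu1 %.4f lu2 %.4f rd %.4f | total %.4f (lambda %.3g, beta %.3g, tau %.3g)\n",
              x$lx1, x$lx2, x$lu1, x$lu2, x$rd, x$total, x$lambda_u, x$beta, x$tau))
  invisible(x)
}
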