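#' Numerically stabilized softmax
#'
#' Maps per-class scores to conditional class probabilities
#' `p_k = exp(f_k) / sum_m exp(f_m)`, subtracting the row maximum before
#' exponentiation.
#'
#' @param logits numeric vector, or matrix with one row per trial.
#' @return Probabilities of the same shape; rows sum to 1.
#' @export
softmax <- function(logits) {
  if (is.null(dim(logits))) logits <- matrix(logits, nrow = 1L)
  if (any(is.na(logits))) stop_field("logits", "contains NaN")
  z <- exp(logits - apply(logits, 1L, max))
  p <- z / rowSums(z)
  if (nrow(p) == 1L && is.null(dim(p))) p <- as.numeric(p)
  p
}

## one-hot encode labels against a fixed class set
one_hot <- function(y, classes) {
  y <- factor(y, levels = classes)
  m <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

check_probs <- function(probs, y) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop_field("probs", "rows must sum to 1")
  if (length(y) != nrow(probs))
    stop_field("y", "length must match the number of trials")
  probs
}

#' Negative log-likelihood loss
#'
#' Mean over the batch of `-log p(true class)`. Zero probabilities at the
#' true class are clamped at 1e-12 with a warning.
#'
#' @param probs trials x classes probability matrix (or a vector for one
#'   trial).
#' @param y true labels: integer class indices or factor/character matched
#'   against `colnames(probs)`.
#' @return Scalar loss.
#' @export
nll_loss <- function(probs, y) {
  probs <- check_probs(probs, y)
  yi <- if (is.numeric(y)) as.integer(y) else
    match(as.character(y), colnames(probs))
  p <- probs[cbind(seq_len(nrow(probs)), yi)]
  if (any(p <= 0)) {
    warning("zero probability at a true class; clamping at 1e-12")
    p <- pmax(p, 1e-12)
  }
  mean(-log(p))
}

#' Summed per-class binary cross-entropy loss
#'
#' Mean over trials of `-sum_j [y_j log p_j + (1 - y_j) log(1 - p_j)]`,
#' where the sum runs over all classes and `y` is the one-hot truth. Like
#' [nll_loss()], probabilities are clamped away from 0 and 1 at 1e-12.
#'
#' @inheritParams nll_loss
#' @return Scalar loss; zero exactly when predictions are one-hot truths.
#' @export
ce_loss <- function(probs, y) {
  probs <- check_probs(probs, y)
  yi <- if (is.numeric(y)) as.integer(y) else
    match(as.character(y), colnames(probs))
  Y <- matrix(0, nrow(probs), ncol(probs))
  Y[cbind(seq_len(nrow(probs)), yi)] <- 1
  if (any(probs[Y == 1] <= 0) || any(probs[Y == 0] >= 1))
    warning("degenerate probability; clamping at 1e-12")
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  ## exact one-hot rows must give exactly zero loss
  term <- ifelse(Y == 1, ifelse(probs >= 1, 0, -log(p)),
                 ifelse(probs <= 0, 0, -log(1 - p)))
  mean(rowSums(term))
}
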