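#' Decoder specification
#'
#' Pairs a decoder family with one hyperparameter combination. Families:
#' `shallow_cnn`, `deep_cnn`, `eegnet` (trained on raw `channels x samples`
#' trials), `svm`, `rdf` (trained on relative wavelet energy vectors),
#' `rlda` (trained on FBCSP features) and `majority` (a constant
#' majority-class baseline, useful for chance calibration).
#'
#' @param family decoder family name.
#' @param hp named list, one value per hyperparameter of the family's grid.
#' @param n_classes number of classes (>= 2).
#' @param input_shape `c(channels, samples)` for CNN families, feature
#'   length otherwise (informational).
#' @return A `decoder_spec`.
#' @export
decoder_spec <- function(family, hp = list(), n_classes = 2L,
                         input_shape = NULL) {
  families <- c("shallow_cnn", "deep_cnn", "eegnet", "svm", "rdf", "rlda",
                "majority")
  if (!family %in% families)
    stop_field("family", paste("must be one of:", paste(families, collapse = ", ")))
  n_classes <- assert_count(n_classes, "n_classes", min = 2L)
  known <- names(default_grid(family)$dimensions)
  extra <- setdiff(names(hp), known)
  if (length(extra))
    stop_field("hp", sprintf("unknown hyperparameter(s) %s for family %s (valid: %s)",
                             paste(extra, collapse = ", "), family,
                             paste(known, collapse = ", ")))
  structure(list(family = family, hp = hp, n_classes = n_classes,
                 input_shape = input_shape),
            class = "decoder_spec")
}

is_cnn_family <- function(family) family %in% c("shallow_cnn", "deep_cnn", "eegnet")

#' Build an untrained CNN from a decoder specification
#'
#' @param spec a [decoder_spec()] with a CNN family; `spec$hp$activation`
#'   selects the principal nonlinearity (`elu`, `square`, `relu`,
#'   `leaky_relu`).
#' @param arch named list of architecture overrides (filter counts, kernel
#'   and pool sizes).
#' @return List of network layers; `attr(, "n_parameters")` gives the
#'   trainable parameter count.
#' @export
build_cnn <- function(spec, arch = list()) {
  stopifnot(inherits(spec, "decoder_spec"))
  if (!is_cnn_family(spec$family))
    stop_field("family", "not a CNN family")
  shape <- spec$input_shape %||% c(6L, 512L)
  net <- build_cnn_net(spec$family, spec$n_classes, shape,
                       spec$hp$activation %||% "elu", arch)
  attr(net, "n_parameters") <- nn_count_params(net)
  net
}

## regularized LDA: pooled covariance shrunk toward scaled identity with
## the Ledoit-Wolf analytic intensity; posteriors via softmax of the
## linear discriminant scores.
rlda_fit <- function(X, y) {
  y <- as.factor(y)
  classes <- levels(y)
  p <- ncol(X)
  mus <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                  numeric(p)))
  Xc <- X - mus[as.integer(y), , drop = FALSE]
  n <- nrow(X)
  S <- crossprod(Xc) / n
  nu <- mean(diag(S))
  ## Ledoit-Wolf shrinkage toward nu * I
  d2 <- sum((S - nu * diag(p))^2)
  b2 <- 0
  for (i in seq_len(n)) {
    xi <- Xc[i, ]
    b2 <- b2 + sum((tcrossprod(xi) - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  gamma <- if (d2 > 0) b2 / d2 else 1
  Sigma <- (1 - gamma) * S + gamma * nu * diag(p)
  Sinv <- solve(Sigma)
  priors <- as.numeric(table(y)) / n
  list(mus = mus, Sinv = Sinv, log_priors = log(priors), classes = classes,
       gamma = gamma)
}

rlda_predict_probs <- function(model, X) {
  sc <- vapply(seq_along(model$classes), function(k) {
    mu <- model$mus[k, ]
    as.numeric(X %*% (model$Sinv %*% mu)) -
      0.5 * as.numeric(t(mu) %*% model$Sinv %*% mu) + model$log_priors[k]
  }, numeric(nrow(X)))
  if (is.null(dim(sc))) sc <- matrix(sc, nrow = 1L)
  P <- softmax(sc)
  colnames(P) <- model$classes
  P
}

#' Fit a decoder
#'
#' CNN families receive raw trials (`trials x channels x samples`); `svm`
#' and `rdf` receive feature matrices (RWE vectors in the standard
#' pipeline); `rlda` receives FBCSP features. Training is deterministic for
#' a fixed seed. A CNN whose loss diverges is returned flagged (it predicts
#' uniform probabilities) rather than raising, so exhaustive grid searches
#' complete.
#'
#' @param spec a [decoder_spec()].
#' @param X raw trial array or feature matrix, per family.
#' @param y training labels.
#' @param seed RNG seed.
#' @param arch optional CNN architecture overrides.
#' @return A `trained_decoder`.
#' @export
fit_decoder <- function(spec, X, y, seed = 1L, arch = list()) {
  stopifnot(inherits(spec, "decoder_spec"))
  y <- as.factor(y)
  hp <- spec$hp
  fit <- switch(spec$family,
    svm = {
      set.seed(seed)
      kern <- hp$kernel %||% "linear"
      kern <- switch(kern, rbf = "radial", poly = "polynomial", kern)
      e1071::svm(x = X, y = y, kernel = kern,
                 cost = hp$C %||% 1, gamma = hp$g %||% (1 / ncol(X)),
                 probability = TRUE, scale = TRUE)
    },
    rdf = {
      set.seed(seed)
      randomForest::randomForest(
        x = X, y = y, ntree = hp$trees %||% 100,
        mtry = min(hp$nof %||% max(1, floor(sqrt(ncol(X)))), ncol(X)),
        nodesize = hp$msl %||% 1)
    },
    rlda = rlda_fit(X, y),
    majority = list(classes = levels(y),
                    major = names(which.max(table(y)))),
    cnn_fit(spec$family, X, y, hp, seed = seed, arch = arch))
  structure(list(spec = spec, fit = fit, classes = levels(y), seed = seed),
            class = "trained_decoder")
}

#' Per-trial class probabilities and labels from a trained decoder
#'
#' @param object a `trained_decoder`.
#' @param X trials or features, matching the family's training input.
#' @param ... unused.
#' @return A `prediction_batch`: list with `probs` (rows sum to 1) and
#'   `labels_hat` (row-wise argmax).
#' @export
predict.trained_decoder <- function(object, X, ...) {
  fam <- object$spec$family
  P <- switch(fam,
    svm = {
      pr <- predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, object$classes, drop = FALSE]
    },
    rdf = predict(object$fit, X, type = "prob")[, object$classes,
                                                drop = FALSE],
    rlda = rlda_predict_probs(object$fit, X),
    majority = {
      ## constant soft vote: half the mass on the majority class
      n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
      k <- length(object$classes)
      P <- matrix(1 / (2 * k), n, k, dimnames = list(NULL, object$classes))
      P[, object$fit$major] <- P[, object$fit$major] + 0.5
      P / rowSums(P)
    },
    cnn_predict_probs(object$fit, X))
  P <- as.matrix(P)
  prediction_batch(P)
}

#' Construct a prediction batch
#'
#' @param probs trials x classes probability matrix with class column names.
#' @return `prediction_batch` with validated rows and argmax labels.
#' @export
prediction_batch <- function(probs) {
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop_field("probs", "rows must sum to 1")
  if (any(probs < -1e-12 | probs > 1 + 1e-12))
    stop_field("probs", "entries must lie in [0, 1]")
  labels_hat <- colnames(probs)[max.col(probs, ties.method = "first")]
  structure(list(probs = probs, labels_hat = labels_hat),
            class = "prediction_batch")
}

#' Classification accuracy of a prediction batch
#' @param pred a `prediction_batch`.
#' @param y true labels.
#' @return Fraction of correctly labelled trials.
#' @export
accuracy <- function(pred, y) mean(pred$labels_hat == as.character(y))

#' Trainable parameter count of a fitted CNN decoder
#' @param model a `trained_decoder` with a CNN family.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "trained_decoder"))
  model$fit$n_parameters %||%
    stop_field("model", "parameter counts are defined for CNN families")
}
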