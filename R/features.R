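#' Canonical six-band edges for the filter bank
#'
#' delta (2-4), theta (4-8), mu (8-12), lower beta (12-18), upper beta
#' (18-28) and gamma (28-40 Hz).
#' @return Data frame with columns `band`, `lo`, `hi`.
#' @export
default_band_edges <- function() {
  data.frame(band = c("delta", "theta", "mu", "lower_beta", "upper_beta",
                      "gamma"),
             lo = c(2, 4, 8, 12, 18, 28),
             hi = c(4, 8, 12, 18, 28, 40))
}

#' Build a band-pass filter bank
#'
#' One Hamming-windowed FIR band-pass per edge pair, same design family as
#' [bandpass_fir()] with the order scaled per band (`3 * fs / lo`, at least
#' 64 taps so narrow high bands keep useful roll-off).
#'
#' @param edges data frame with columns `lo`, `hi` (Hz), optionally `band`;
#'   defaults to [default_band_edges()].
#' @param fs sampling rate the filters are designed for.
#' @return A `filterbank` object (list of taps plus `band_edges`).
#' @export
build_filterbank <- function(edges = default_band_edges(), fs = 128) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L)
    stop_field("edges", "must contain at least one band")
  edges <- as.data.frame(edges)
  if (any(edges$lo >= edges$hi))
    stop_field("edges", "every band requires lo < hi")
  if (any(edges$hi >= fs / 2))
    stop_field("edges", "band edge at or above the Nyquist frequency")
  filters <- lapply(seq_len(nrow(edges)), function(i)
    fir_design(edges$lo[i], edges$hi[i], fs,
               order = max(64, round(3 * fs / edges$lo[i]))))
  names(filters) <- edges$band %||% paste0("band", seq_len(nrow(edges)))
  structure(list(filters = filters, band_edges = edges, fs = fs),
            class = "filterbank")
}

#' Apply a filter bank to a trial set
#'
#' @param trials a [trial_set()] at the filter bank's sampling rate.
#' @param fb a `filterbank`.
#' @return List of filtered `trial_set`s, one per band. Filtering is
#'   per-trial and label-free, so it may be computed once before
#'   cross-validation without information leakage.
#' @export
apply_filterbank <- function(trials, fb) {
  stopifnot(inherits(trials, "trial_set"), inherits(fb, "filterbank"))
  if (abs(trials$fs - fb$fs) > 1e-9)
    stop_field("trials", "sampling rate does not match the filter bank")
  lapply(fb$filters, function(h)
    with_data(trials, filter_trialset_data(trials$data, h)))
}

## per-trial trace-normalized spatial covariances: (nc, nc, trials)
trial_covs <- function(dat) {
  d <- dim(dat)
  out <- array(0, c(d[2], d[2], d[1]))
  for (i in seq_len(d[1])) {
    x <- matrix(dat[i, , ], nrow = d[2])
    x <- x - rowMeans(x)
    cv <- x %*% t(x)
    out[, , i] <- cv / sum(diag(cv))
  }
  out
}

## trial-wise spatial covariance, trace-normalized, averaged over trials;
## `covs` (from trial_covs) short-circuits the recomputation
mean_normalized_cov <- function(dat, idx, covs = NULL) {
  if (!is.null(covs))
    return(rowMeans(covs[, , idx, drop = FALSE], dims = 2L))
  nc <- dim(dat)[2]
  S <- matrix(0, nc, nc)
  for (i in idx) {
    x <- matrix(dat[i, , ], nrow = nc)
    x <- x - rowMeans(x)
    cv <- x %*% t(x)
    S <- S + cv / sum(diag(cv))
  }
  S / length(idx)
}

## two-class CSP: generalized eigendecomposition of (S1, S1 + S2) via
## whitening; rows of W are spatial filters ordered by decreasing eigenvalue
csp_two_class <- function(S1, S2, ridge = 1e-8) {
  Sc <- S1 + S2
  solve_csp <- function(Sc) {
    ev <- eigen(Sc, symmetric = TRUE)
    if (min(ev$values) < 1e-10 * max(ev$values)) return(NULL)
    P <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
    ew <- eigen(P %*% S1 %*% t(P), symmetric = TRUE)
    list(W = t(ew$vectors) %*% P, lambda = ew$values)
  }
  res <- solve_csp(Sc)
  if (is.null(res)) {
    warning("singular composite covariance; applying ridge regularization")
    res <- solve_csp(Sc + ridge * mean(diag(Sc)) * diag(nrow(Sc)))
    if (is.null(res)) stop("covariance still singular after regularization",
                           call. = FALSE)
  }
  res
}

#' Fit common spatial patterns for one frequency band
#'
#' Two classes: spatial filters from the generalized eigendecomposition of
#' the class covariances, retaining the `nsf` filters from each end of the
#' eigenvalue spectrum (2 * nsf filters). More than two classes: one-vs-rest
#' decompositions are computed per class, their filters pooled and the
#' 2 * nsf filters with the most extreme eigenvalues (largest |lambda - 0.5|)
#' retained. Filters whiten the composite covariance of the data they were
#' fit on.
#'
#' @param dat `trials x channels x samples` array (one band).
#' @param labels per-trial class labels.
#' @param nsf number of spatial-filter pairs to retain.
#' @param covs optional precomputed per-trial normalized covariances
#'   (`channels x channels x trials`), reused across folds for speed.
#' @return A `csp_band` object: `filters` (2 * nsf x channels), `lambda`,
#'   and the composite covariance used for the whitening check.
#' @export
fit_csp <- function(dat, labels, nsf = 2L, covs = NULL) {
  labels <- as.factor(labels)
  nsf <- assert_count(nsf, "nsf")
  cls <- levels(labels)
  if (length(cls) < 2L) stop_field("labels", "need at least two classes")
  if (any(tabulate(labels) < 2L))
    stop_field("labels", "need at least two trials per class")
  nc <- dim(dat)[2]
  if (2L * nsf > nc)
    stop_field("nsf", "2 * nsf exceeds the channel count")
  if (length(cls) == 2L) {
    S1 <- mean_normalized_cov(dat, which(labels == cls[1]), covs)
    S2 <- mean_normalized_cov(dat, which(labels == cls[2]), covs)
    r <- csp_two_class(S1, S2)
    pick <- c(seq_len(nsf), nc - seq_len(nsf) + 1L)
    W <- r$W[pick, , drop = FALSE]
    lam <- r$lambda[pick]
    Sc <- S1 + S2
  } else {
    Ws <- NULL; lam <- NULL
    for (cl in cls) {
      S1 <- mean_normalized_cov(dat, which(labels == cl), covs)
      S2 <- mean_normalized_cov(dat, which(labels != cl), covs)
      r <- csp_two_class(S1, S2)
      pick <- c(seq_len(nsf), nc - seq_len(nsf) + 1L)
      Ws <- rbind(Ws, r$W[pick, , drop = FALSE])
      lam <- c(lam, r$lambda[pick])
    }
    keep <- order(abs(lam - 0.5), decreasing = TRUE)[seq_len(2L * nsf)]
    W <- Ws[keep, , drop = FALSE]
    lam <- lam[keep]
    Sc <- NULL
  }
  structure(list(filters = W, lambda = lam, nsf = nsf, composite_cov = Sc),
            class = "csp_band")
}

## log-variance of CSP projections: trials x (2 nsf)
csp_logvar <- function(dat, csp) {
  nc <- dim(dat)[2]
  t(apply(dat, 1L, function(x) {
    x <- matrix(x, nrow = nc)
    x <- x - rowMeans(x)
    p <- csp$filters %*% x
    log(rowMeans(p^2) + 1e-12)
  }))
}

## equal-frequency quantization into q bins (bin edges from the data given)
quantize_ef <- function(x, q, breaks = NULL) {
  if (is.null(breaks)) {
    breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = q + 1),
                                     names = FALSE, type = 7))
    breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  }
  findInterval(x, breaks[-c(1, length(breaks))]) + 1L
}

#' Plug-in mutual information between a quantized feature and labels
#'
#' The feature is quantized into `q` equal-frequency bins and the MI of the
#' joint bin/label histogram is returned in bits.
#'
#' @param x numeric feature values.
#' @param labels class labels.
#' @param q quantization level (number of bins, the MIQL hyperparameter).
#' @return MI in bits (non-negative).
#' @export
mutual_information <- function(x, labels, q) {
  labels <- as.factor(labels)
  b <- quantize_ef(x, q)
  joint <- table(b, labels) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py))
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
  max(mi, 0)
}

#' Fit the FBCSP feature extractor on training data
#'
#' Filter bank -> per-band CSP -> log-variance candidate features
#' (`bands * 2 * nsf` of them) -> mutual-information ranking after
#' equal-frequency quantization into `miql` bins -> retain the `nof`
#' top-ranked features (ties broken by candidate index).
#'
#' @param band_data list of `trials x channels x samples` arrays, one per
#'   band (training trials only).
#' @param labels training labels.
#' @param nsf CSP filter pairs per band.
#' @param miql mutual-information quantization level.
#' @param nof number of features retained per trial.
#' @param band_covs optional list of per-band precomputed trial covariances.
#' @return An `fbcsp_model` with the per-band CSP filters, the selection
#'   (`mi_scores`, `selected`, `miql`) and feature provenance.
#' @export
fbcsp_fit <- function(band_data, labels, nsf = 2L, miql = 6L, nof = 8L,
                      band_covs = NULL) {
  nof <- assert_count(nof, "nof")
  miql <- assert_count(miql, "miql", min = 2L)
  csps <- if (is.null(band_covs))
    lapply(band_data, fit_csp, labels = labels, nsf = nsf)
  else Map(function(b, cv) fit_csp(b, labels, nsf, covs = cv),
           band_data, band_covs)
  feats <- do.call(cbind, Map(csp_logvar, band_data, csps))
  n_cand <- ncol(feats)
  if (nof > n_cand)
    stop_field("nof", sprintf("exceeds the %d candidate features", n_cand))
  mi <- vapply(seq_len(n_cand), function(j)
    mutual_information(feats[, j], labels, miql), 0)
  selected <- order(-mi, seq_len(n_cand))[seq_len(nof)]
  prov <- data.frame(
    band = rep(names(band_data) %||% seq_along(band_data),
               each = 2L * nsf),
    filter = rep(seq_len(2L * nsf), length(band_data)))
  structure(list(csps = csps, mi_scores = mi, selected = selected,
                 miql = miql, nof = nof, nsf = nsf, provenance = prov),
            class = "fbcsp_model")
}

#' Extract selected FBCSP features with a fitted model
#'
#' @param model an `fbcsp_model` from [fbcsp_fit()].
#' @param band_data list of per-band trial arrays (any trials).
#' @return Feature matrix `trials x nof`.
#' @export
fbcsp_transform <- function(model, band_data) {
  stopifnot(inherits(model, "fbcsp_model"))
  feats <- do.call(cbind, Map(csp_logvar, band_data, model$csps))
  feats[, model$selected, drop = FALSE]
}
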