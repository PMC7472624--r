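#' Windowed-sinc FIR band-pass design
#'
#' Hamming-windowed FIR design via [signal::fir1()]. The default order is
#' `3 * fs / lo` (rounded to even), giving a transition band proportional to
#' the low cut-off.
#'
#' @param lo,hi band edges in Hz (`0 < lo < hi < fs/2`).
#' @param fs sampling rate in Hz.
#' @param order filter order (number of taps minus one).
#' @return Numeric vector of filter taps.
#' @export
fir_design <- function(lo, hi, fs, order = NULL) {
  if (!(lo > 0 && hi > lo)) stop_field("lo/hi", "requires 0 < lo < hi")
  if (hi >= fs / 2) stop_field("hi", "must be below the Nyquist frequency")
  if (is.null(order)) order <- round(3 * fs / lo)
  order <- max(8L, 2L * (as.integer(order) %/% 2L))
  as.numeric(signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass"))
}

## causal FIR filtering via FFT convolution (keeps the first n outputs);
## pads to a power of two so the FFT never hits a slow prime length
fir_apply <- function(x, h) {
  n <- length(x)
  L <- stats::nextn(n + length(h) - 1L, 2)
  Y <- stats::fft(c(x, rep(0, L - n))) * stats::fft(c(h, rep(0, L - length(h))))
  Re(stats::fft(Y, inverse = TRUE))[seq_len(n)] / L
}

## zero-phase forward-backward FIR with reflective edge padding
zero_phase_filter <- function(x, h) {
  n <- length(x)
  pad <- min(n - 1L, 3L * length(h))
  xe <- c(2 * x[1] - x[pad + 1L + 1L - seq_len(pad)],
          x,
          2 * x[n] - x[n - seq_len(pad)])
  y <- fir_apply(xe, h)
  y <- rev(fir_apply(rev(y), h))
  y[pad + seq_len(n)]
}

## batched zero-phase filtering: signals in columns, one FFT plan for all
zero_phase_filter_mat <- function(X, h) {
  n <- nrow(X); m <- ncol(X)
  pad <- min(n - 1L, 3L * length(h))
  top <- 2 * matrix(X[1L, ], pad, m, byrow = TRUE) -
    X[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(X[n, ], pad, m, byrow = TRUE) -
    X[(n - 1L):(n - pad), , drop = FALSE]
  Xe <- rbind(top, X, bot)
  ne <- n + 2L * pad
  L <- stats::nextn(ne + length(h) - 1L)
  H <- stats::fft(c(h, rep(0, L - length(h))))
  run <- function(M) {
    Y <- Re(stats::mvfft(stats::mvfft(rbind(M, matrix(0, L - ne, m))) * H,
                         inverse = TRUE)) / L
    Y[seq_len(ne), , drop = FALSE]
  }
  Y <- run(Xe)
  Y <- run(Y[ne:1L, , drop = FALSE])[ne:1L, , drop = FALSE]
  Y[pad + seq_len(n), , drop = FALSE]
}

## zero-phase filter every channel of every trial (batched over trials)
filter_trialset_data <- function(dat, h) {
  d <- dim(dat)
  X <- matrix(aperm(dat, c(3, 1, 2)), nrow = d[3])  # samples x (trial*ch)
  Y <- zero_phase_filter_mat(X, h)
  aperm(array(Y, c(d[3], d[1], d[2])), c(2, 3, 1))
}

## apply a per-channel 1-d function over every trial of a trial_set
apply_trialwise <- function(ts, fun, out_samples = n_samples(ts)) {
  d <- dim(ts$data)
  out <- array(0, c(d[1], d[2], out_samples))
  for (i in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      out[i, ch, ] <- fun(ts$data[i, ch, ])
  out
}

#' Zero-phase FIR band-pass filtering of a trial set
#'
#' Filters every channel of every trial forward and backward with a
#' Hamming-windowed FIR band-pass, preserving shape and phase.
#'
#' @param trials a [trial_set()].
#' @param lo,hi band edges in Hz.
#' @param order optional FIR order; defaults to `3 * fs / lo`.
#' @return A filtered `trial_set` of identical shape.
#' @export
bandpass_fir <- function(trials, lo = 2, hi = 40, order = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  h <- fir_design(lo, hi, trials$fs, order)
  with_data(trials, filter_trialset_data(trials$data, h))
}

#' Downsample a trial set with anti-alias filtering
#'
#' Low-pass filters (zero-phase FIR, cut-off `0.45 * target_fs`, i.e. 90% of
#' the target Nyquist) and decimates by the integer factor `fs / target_fs`.
#'
#' @param trials a [trial_set()].
#' @param target_fs target sampling rate in Hz; must divide `fs`.
#' @return A `trial_set` with `trial_dur * target_fs` samples per channel.
#' @examples
#' ts <- generate_dataset(protocol_words(n_subjects = 1, trials_per_class = 1),
#'                        signal_model_spec(snr = 0))[[1]]
#' dim(downsample(ts, 128))  # 6 x 6 x 512
#' @export
downsample <- function(trials, target_fs) {
  stopifnot(inherits(trials, "trial_set"))
  assert_scalar_num(target_fs, "target_fs", lower = 0, strict = TRUE)
  if (target_fs > trials$fs) stop_field("target_fs", "exceeds the input rate")
  if (target_fs == trials$fs) return(trials)
  fac <- trials$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9)
    stop_field("target_fs", "must divide fs (integer decimation only)")
  fac <- as.integer(round(fac))
  cutoff <- 0.45 * target_fs
  h <- signal::fir1(max(24L, 12L * fac), cutoff / (trials$fs / 2), type = "low")
  keep <- seq(1L, n_samples(trials), by = fac)
  dat <- filter_trialset_data(trials$data, h)[, , keep, drop = FALSE]
  with_data(trials, dat, fs = target_fs)
}

#' Independent component decomposition of a trial set
#'
#' Fits FastICA (symmetric decorrelation, log-cosh contrast) on the
#' trial-concatenated, internally decimated recording and returns the
#' spatial unmixing matrix, source time courses and component topographies
#' (columns of the mixing matrix). Deterministic for a fixed seed.
#'
#' @param trials a [trial_set()].
#' @param n_components number of components (<= channel count).
#' @param decim integer decimation factor applied internally before the fit
#'   (the unmixing is spatial, so it transfers to the full-rate data).
#' @param seed RNG seed for the orthogonal initialization.
#' @param max_iter,tol FastICA iteration controls.
#' @return A `component_set` with fields `unmixing` (components x channels,
#'   acts on centered data), `sources`, `topographies` and `center`.
#' @export
fit_ica <- function(trials, n_components = n_channels(trials), decim = 3L,
                    seed = 1L, max_iter = 400L, tol = 1e-7) {
  stopifnot(inherits(trials, "trial_set"))
  nc <- n_channels(trials)
  n_components <- assert_count(n_components, "n_components")
  if (n_components > nc) stop_field("n_components", "exceeds channel count")
  ## concatenate trials -> channels x samples, then decimate for speed
  X <- matrix(aperm(trials$data, c(2, 3, 1)), nrow = nc)
  if (decim > 1L) {
    h <- signal::fir1(48L, 0.9 / decim, type = "low")
    X <- t(apply(X, 1L, zero_phase_filter, h = h))
    X <- X[, seq(1L, ncol(X), by = decim), drop = FALSE]
  }
  ctr <- rowMeans(X)
  Xc <- X - ctr
  cv <- Xc %*% t(Xc) / ncol(Xc)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[n_components] < 1e-10 * ev$values[1])
    stop("rank-deficient data: covariance eigenvalue ",
         n_components, " is numerically zero", call. = FALSE)
  K <- diag(1 / sqrt(ev$values[1:n_components]), n_components) %*%
    t(ev$vectors[, 1:n_components, drop = FALSE])
  Z <- K %*% Xc
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(n_components^2), n_components)))
  sym_decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), n_components) %*% t(s$vectors) %*% W
  }
  W <- sym_decorrelate(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    gp <- rowMeans(1 - G^2)
    W1 <- sym_decorrelate(G %*% t(Z) / ncol(Z) - diag(gp, n_components) %*% W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  ## fix sign convention: largest-magnitude topography weight positive
  unmix <- W %*% K
  A <- if (n_components == nc) solve(unmix) else
    t(unmix) %*% solve(unmix %*% t(unmix))
  sgn <- apply(A, 2L, function(a) sign(a[which.max(abs(a))]))
  A <- sweep(A, 2L, sgn, `*`)
  unmix <- sweep(unmix, 1L, sgn, `*`)
  structure(list(unmixing = unmix, sources = unmix %*% Xc,
                 topographies = A, center = ctr,
                 channel_names = trials$channel_names),
            class = "component_set")
}

#' Screen independent components against an artefact topography template
#'
#' Computes the Pearson correlation of every component topography with the
#' supplied template and flags components whose absolute correlation meets
#' the threshold (absolute value is used because ICA component signs are
#' arbitrary).
#'
#' @param components a `component_set` from [fit_ica()].
#' @param template numeric topography, one value per channel.
#' @param threshold flagging threshold in `(0, 1]` (default 0.8).
#' @param override optional integer vector of component indices to accept
#'   (remove) regardless of the screen; the non-interactive replacement for
#'   visual inspection.
#' @return An `artifact_screen_result` with fields `correlations`, `flagged`
#'   and `threshold`.
#' @export
screen_blink_components <- function(components, template, threshold = 0.8,
                                    override = NULL) {
  stopifnot(inherits(components, "component_set"))
  if (length(template) != nrow(components$topographies))
    stop_field("template", "length must equal the channel count")
  if (stats::sd(template) == 0)
    stop_field("template", "has zero variance")
  if (!(threshold > 0 && threshold <= 1))
    stop_field("threshold", "must lie in (0, 1]")
  r <- apply(components$topographies, 2L, stats::cor, y = as.numeric(template))
  flagged <- which(abs(r) >= threshold)
  if (!is.null(override)) flagged <- sort(unique(as.integer(override)))
  structure(list(correlations = r, flagged = flagged, threshold = threshold),
            class = "artifact_screen_result")
}

#' Remove flagged independent components from a trial set
#'
#' Applies the spatial unmixing to each trial, zeroes the flagged source
#' rows and remixes, leaving non-flagged activity untouched.
#'
#' @param trials a [trial_set()] at any sampling rate.
#' @param components `component_set` fitted on (a decimated version of) the
#'   same recording.
#' @param flagged integer component indices to remove.
#' @return A cleaned `trial_set`.
#' @export
remove_artifact_components <- function(trials, components, flagged) {
  stopifnot(inherits(trials, "trial_set"),
            inherits(components, "component_set"))
  if (length(flagged) == 0L) return(trials)
  A <- components$topographies
  W <- components$unmixing
  keep <- setdiff(seq_len(nrow(W)), flagged)
  P <- A[, keep, drop = FALSE] %*% W[keep, , drop = FALSE]  # projection
  d <- dim(trials$data)
  out <- trials$data
  for (i in seq_len(d[1])) {
    x <- matrix(trials$data[i, , ], nrow = d[2])
    mu <- rowMeans(x)
    out[i, , ] <- P %*% (x - mu) + mu
  }
  with_data(trials, out)
}

#' One-call blink screening and removal
#'
#' Convenience wrapper: fit ICA, screen against a blink topography template
#' at the given threshold and remove flagged components.
#'
#' @inheritParams fit_ica
#' @inheritParams screen_blink_components
#' @return List with `trials` (cleaned), `screen` and `components`.
#' @export
remove_blinks <- function(trials, template = blink_topography(trials$channel_names),
                          threshold = 0.8, seed = 1L) {
  comp <- fit_ica(trials, seed = seed)
  scr <- screen_blink_components(comp, template, threshold)
  list(trials = remove_artifact_components(trials, comp, scr$flagged),
       screen = scr, components = comp)
}
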