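## Daubechies scaling filters (orthonormal, sum = sqrt(2)).
## "db4" is the fourth-order (8-tap) Daubechies wavelet.
daubechies_filter <- function(wavelet = "db4") {
  lo <- switch(wavelet,
    db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
            -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    db2 = c(0.48296291314469025, 0.8365163037378079, 0.22414386804185735,
            -0.12940952255092145),
    stop_field("wavelet", sprintf("unknown wavelet '%s'", wavelet)))
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)  # quadrature mirror filter
  list(lo = lo, hi = hi, len = L)
}

## one analysis step with symmetric (half-point) boundary extension;
## analysis filters are the time-reversed scaling/wavelet filters, and the
## decimation phase keeps coefficients at even shifts of the extended
## convolution (matching the usual DWT convention)
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- filt$len
  xe <- c(x[(L - 1L):1L], x, x[n:(n - L + 2L)])
  idx <- seq(L + 1L, by = 2L, length.out = (n + L - 1L) %/% 2L)
  conv_lo <- stats::convolve(xe, filt$lo, type = "open")
  conv_hi <- stats::convolve(xe, filt$hi, type = "open")
  list(approx = conv_lo[idx], detail = conv_hi[idx])
}

#' Multi-level discrete wavelet decomposition of a signal
#'
#' Cascade DWT with symmetric boundary extension. Level `j` details cover
#' the nominal band `fs/2^(j+1)` to `fs/2^j`.
#'
#' @param x numeric signal.
#' @param levels decomposition depth.
#' @param wavelet wavelet name (`"db4"` default).
#' @return List with `details` (list D1..Dlevels) and `approx` (A_levels).
#' @export
wavedec <- function(x, levels = 5L, wavelet = "db4") {
  levels <- assert_count(levels, "levels")
  if (length(x) < 2^levels)
    stop_field("x", sprintf("too short for %d levels (need >= %d samples)",
                            levels, 2^levels))
  filt <- daubechies_filter(wavelet)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(a, filt)
    details[[j]] <- st$detail
    a <- st$approx
  }
  names(details) <- paste0("D", seq_len(levels))
  list(details = details, approx = a)
}

#' Relative wavelet energy features
#'
#' Decomposes each channel of each trial to `levels` levels with the given
#' wavelet and computes the relative energy of detail levels D2..D5 and the
#' approximation A5 (D1, nominally 32-64 Hz at a 128 Hz sampling rate, is
#' computed but discarded). Energies are sums of squared coefficients and
#' are normalized per channel so the five retained values sum to one,
#' yielding `5 * channels` features per trial (30 for the 6-channel
#' montage). Nominal bands at 128 Hz: D2 16-32 Hz, D3 8-16 Hz, D4 4-8 Hz,
#' D5 2-4 Hz, A5 < 2 Hz.
#'
#' @param trials a [trial_set()] (expected at 128 Hz).
#' @param wavelet wavelet name.
#' @param levels decomposition depth (5).
#' @return Numeric matrix `trials x (5 * channels)` with named columns
#'   (`<channel>.<level>`), attribute `level_bands` giving nominal Hz ranges.
#' @export
rwe_extract <- function(trials, wavelet = "db4", levels = 5L) {
  stopifnot(inherits(trials, "trial_set"))
  if (n_samples(trials) < 2^levels)
    stop_field("trials", "trials too short for the decomposition depth")
  keep <- c("D2", "D3", "D4", "D5", "A5")
  nch <- n_channels(trials)
  out <- matrix(0, n_trials(trials), 5L * nch)
  colnames(out) <- as.vector(vapply(trials$channel_names,
                                    function(ch) paste(ch, keep, sep = "."),
                                    character(5)))
  for (i in seq_len(n_trials(trials))) {
    for (ch in seq_len(nch)) {
      dec <- wavedec(trials$data[i, ch, ], levels, wavelet)
      e <- c(vapply(dec$details[2:5], function(d) sum(d^2), 0),
             sum(dec$approx^2))
      out[i, (ch - 1L) * 5L + 1:5] <- e / sum(e)
    }
  }
  fs <- trials$fs
  attr(out, "level_bands") <- data.frame(
    level = keep,
    lo = c(fs / 8, fs / 16, fs / 32, fs / 64, 0),
    hi = c(fs / 4, fs / 8, fs / 16, fs / 32, fs / 64))
  out
}
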