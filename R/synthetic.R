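#' Acquisition protocol specification
#'
#' Describes the structure of an imagined-speech EEG recording protocol:
#' cohort size, montage, sampling rate, trial length and class structure.
#' The defaults of [protocol_words()] and [protocol_vowels()] mirror a
#' 15-subject, 6-channel (F3, F4, C3, C4, P3, P4), 1024 Hz acquisition with
#' 4 s trials and 40 imagined trials per class.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param channels ordered channel-name vector.
#' @param fs sampling rate in Hz.
#' @param trial_dur trial duration in seconds.
#' @param classes ordered vector of unique class labels.
#' @param trials_per_class imagined trials recorded per class (>= 1).
#' @param task task tag attached to generated trial sets.
#' @return A `protocol_spec` object.
#' @export
protocol_spec <- function(n_subjects, channels, fs, trial_dur, classes,
                          trials_per_class, task = "words") {
  n_subjects <- assert_count(n_subjects, "n_subjects")
  if (length(channels) < 1L) stop_field("channels", "must be non-empty")
  assert_scalar_num(fs, "fs", lower = 0, strict = TRUE)
  assert_scalar_num(trial_dur, "trial_dur", lower = 0, strict = TRUE)
  if (length(classes) < 1L || anyDuplicated(classes))
    stop_field("classes", "must be non-empty with unique labels")
  trials_per_class <- assert_count(trials_per_class, "trials_per_class")
  structure(list(n_subjects = n_subjects, channels = as.character(channels),
                 fs = fs, trial_dur = trial_dur, classes = as.character(classes),
                 trials_per_class = trials_per_class, task = task),
            class = "protocol_spec")
}

#' @rdname protocol_spec
#' @export
protocol_words <- function(n_subjects = 15, fs = 1024, trials_per_class = 40) {
  protocol_spec(n_subjects,
                channels = c("F3", "F4", "C3", "C4", "P3", "P4"),
                fs = fs, trial_dur = 4,
                classes = c("arriba", "abajo", "derecha", "izquierda",
                            "adelante", "atras"),
                trials_per_class = trials_per_class, task = "words")
}

#' @rdname protocol_spec
#' @export
protocol_vowels <- function(n_subjects = 15, fs = 1024, trials_per_class = 40) {
  protocol_spec(n_subjects,
                channels = c("F3", "F4", "C3", "C4", "P3", "P4"),
                fs = fs, trial_dur = 4,
                classes = c("a", "e", "i", "o", "u"),
                trials_per_class = trials_per_class, task = "vowels")
}

#' Signal model for the synthetic EEG generator
#'
#' Parameterizes the statistical structure of generated data: a `1/f^a`
#' Gaussian background band-limited to 2-40 Hz, class-dependent narrow-band
#' oscillatory power on selected channels, multiplicative between-subject
#' variability and Poisson eye-blink contamination.
#'
#' `snr` is the ratio of class-signal variance to background variance on the
#' affected channels; `snr = 0` makes labels statistically independent of the
#' signal. `band_effects` is a data frame with columns `class`, `lo`, `hi`,
#' `channels` (comma-separated names or `"all"`) and `gain`; when `NULL`, a
#' default assignment of one canonical EEG band per class is used.
#'
#' @param background_exponent spectral slope `a` of the `1/f^a` background.
#' @param band_effects class/band/channel gain table, or `NULL` for defaults.
#' @param snr class signal-to-background variance ratio (>= 0).
#' @param blink_rate expected blink count per trial (>= 0).
#' @param subject_gain_sd sd (log scale) of the per-subject gain.
#' @param seed RNG seed; a fixed seed makes generation bit-reproducible.
#' @return A `signal_model_spec` object.
#' @export
signal_model_spec <- function(background_exponent = 1, band_effects = NULL,
                              snr = 1, blink_rate = 0, subject_gain_sd = 0.2,
                              seed = 1L) {
  assert_scalar_num(background_exponent, "background_exponent", lower = 0)
  assert_scalar_num(snr, "snr", lower = 0)
  assert_scalar_num(blink_rate, "blink_rate", lower = 0)
  assert_scalar_num(subject_gain_sd, "subject_gain_sd", lower = 0)
  seed <- assert_count(seed, "seed", min = 0L)
  if (!is.null(band_effects)) {
    need <- c("class", "lo", "hi", "channels", "gain")
    if (!is.data.frame(band_effects) || !all(need %in% names(band_effects)))
      stop_field("band_effects", paste("must be a data frame with columns",
                                       paste(need, collapse = ", ")))
    if (any(band_effects$lo < 2) || any(band_effects$hi > 40))
      stop_field("band_effects", "bands must lie inside 2-40 Hz")
    if (any(band_effects$lo >= band_effects$hi))
      stop_field("band_effects", "requires lo < hi")
  }
  structure(list(background_exponent = background_exponent,
                 band_effects = band_effects, snr = snr,
                 blink_rate = blink_rate, subject_gain_sd = subject_gain_sd,
                 seed = seed),
            class = "signal_model_spec")
}

#' Default class-to-band assignment for synthetic effects
#'
#' Assigns each class one canonical EEG band (cycling through theta, mu,
#' lower beta, upper beta, delta, gamma) on a class-specific pair of
#' channels, so that classes are separable through band-power features.
#'
#' @param classes class labels.
#' @param channels channel names.
#' @return Data frame usable as `band_effects` in [signal_model_spec()].
#' @export
default_band_effects <- function(classes,
                                 channels = c("F3", "F4", "C3", "C4", "P3", "P4")) {
  bands <- list(c(4, 8), c(8, 12), c(12, 18), c(18, 28), c(2, 4), c(28, 40))
  nch <- length(channels)
  rows <- lapply(seq_along(classes), function(i) {
    b <- bands[[(i - 1L) %% length(bands) + 1L]]
    ch <- channels[c((i - 1L) %% nch + 1L, i %% nch + 1L)]
    data.frame(class = classes[i], lo = b[1], hi = b[2],
               channels = paste(ch, collapse = ","), gain = 1)
  })
  do.call(rbind, rows)
}

## 1/f^a Gaussian noise, synthesized in the frequency domain then band-limited
## with the same windowed-sinc FIR family the preprocessing module uses.
## Returns an n_channels x n_samples matrix with ~unit variance per channel.
generate_background <- function(n_channels, n_samples, fs, exponent,
                                lo = 2, hi = 40) {
  nf <- n_samples %/% 2L
  f <- seq_len(nf) * fs / n_samples
  amp <- f^(-exponent / 2)
  x <- matrix(0, n_channels, n_samples)
  for (ch in seq_len(n_channels)) {
    ph <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = ph)
    full <- c(0, spec, Conj(rev(spec[-nf])))
    if (n_samples %% 2L == 0L) full[nf + 1L] <- complex(real = amp[nf], imaginary = 0)
    x[ch, ] <- Re(stats::fft(full, inverse = TRUE)) / n_samples
  }
  h <- fir_design(lo, hi, fs)
  x <- t(apply(x, 1L, zero_phase_filter, h = h))
  x / apply(x, 1L, stats::sd)
}

## narrow-band Gaussian noise in [lo, hi], unit variance
narrowband_noise <- function(n_samples, fs, lo, hi) {
  h <- fir_design(lo, hi, fs)
  y <- zero_phase_filter(stats::rnorm(n_samples), h)
  y / stats::sd(y)
}

#' Generate a seeded multi-subject synthetic imagined-speech EEG dataset
#'
#' Produces one [trial_set()] per subject with balanced classes. Each trial
#' is `1/f` band-limited background noise; when `snr > 0` the trial's class
#' adds narrow-band oscillatory power on that class's channels/band (scaled
#' so signal variance = `snr * gain^2` times the background variance).
#' Subjects differ by a log-normal global gain and log-normal jitter on
#' their effect sizes. Blinks are added when `model$blink_rate > 0`.
#'
#' @param protocol a [protocol_spec()].
#' @param model a [signal_model_spec()].
#' @return List of `trial_set`, one per subject.
#' @examples
#' ds <- generate_dataset(protocol_words(n_subjects = 1, fs = 128),
#'                        signal_model_spec(snr = 0, seed = 7))
#' dim(ds[[1]])
#' @export
generate_dataset <- function(protocol, model) {
  stopifnot(inherits(protocol, "protocol_spec"),
            inherits(model, "signal_model_spec"))
  eff <- model$band_effects
  if (is.null(eff) && model$snr > 0)
    eff <- default_band_effects(protocol$classes, protocol$channels)
  if (!is.null(eff)) {
    bad <- setdiff(eff$class, protocol$classes)
    if (length(bad)) stop_field("band_effects",
      paste("unknown class:", paste(bad, collapse = ", ")))
  }
  n_samp <- round(protocol$fs * protocol$trial_dur)
  n_tr <- protocol$trials_per_class * length(protocol$classes)
  lapply(seq_len(protocol$n_subjects), function(s) {
    set.seed(child_seed(model$seed, 101L, s))
    gain <- exp(stats::rnorm(1, 0, model$subject_gain_sd))
    jitter <- exp(stats::rnorm(length(protocol$classes), 0,
                               model$subject_gain_sd / 2))
    labels <- sample(rep(protocol$classes, protocol$trials_per_class))
    dat <- array(0, c(n_tr, length(protocol$channels), n_samp))
    for (i in seq_len(n_tr)) {
      bg <- generate_background(length(protocol$channels), n_samp,
                                protocol$fs, model$background_exponent)
      tr <- bg
      if (model$snr > 0 && !is.null(eff)) {
        cls_idx <- match(labels[i], protocol$classes)
        rows <- eff[eff$class == labels[i], , drop = FALSE]
        for (r in seq_len(nrow(rows))) {
          chs <- if (identical(rows$channels[r], "all")) protocol$channels else
            trimws(strsplit(rows$channels[r], ",")[[1]])
          ci <- match(chs, protocol$channels)
          if (anyNA(ci)) stop_field("band_effects", "unknown channel name")
          amp <- sqrt(model$snr) * rows$gain[r] * jitter[cls_idx]
          for (cc in ci)
            tr[cc, ] <- tr[cc, ] +
              amp * narrowband_noise(n_samp, protocol$fs, rows$lo[r], rows$hi[r])
        }
      }
      dat[i, , ] <- gain * tr
    }
    ts <- trial_set(dat, labels, subject_id = sprintf("S%02d", s),
                    fs = protocol$fs, channel_names = protocol$channels,
                    task = protocol$task)
    if (model$blink_rate > 0)
      ts <- inject_blinks(ts, model$blink_rate,
                          seed = child_seed(model$seed, 202L, s))
    ts
  })
}

#' Biphasic eye-blink template waveform
#'
#' A 300 ms biphasic waveform (positive lobe followed by a smaller negative
#' rebound) used both to contaminate synthetic data and as the matched
#' template for ICA component screening.
#'
#' @param fs sampling rate in Hz.
#' @param dur duration in seconds.
#' @return Numeric vector of `round(fs * dur)` samples with unit peak.
#' @export
blink_template <- function(fs, dur = 0.3) {
  n <- round(fs * dur)
  t <- seq(0, 1, length.out = n)
  w <- exp(-((t - 0.35) / 0.16)^2) - 0.45 * exp(-((t - 0.78) / 0.2)^2)
  w / max(abs(w))
}

#' Per-channel blink weighting for the standard 6-channel montage
#'
#' Frontal channels carry full blink amplitude, central channels an
#' attenuated copy and parietal channels a small residual, mimicking the
#' scalp fall-off of ocular artefacts.
#'
#' @param channel_names channel names; weights default to 0.15 for channels
#'   not recognized as frontal (`F*`) or central (`C*`).
#' @return Named numeric vector of weights in `[0, 1]`.
#' @export
blink_topography <- function(channel_names) {
  w <- ifelse(grepl("^F", channel_names), 1,
              ifelse(grepl("^C", channel_names), 0.4, 0.15))
  names(w) <- channel_names
  w
}

#' Inject Poisson-distributed eye blinks into a trial set
#'
#' Adds `Poisson(rate)` blink events per trial at uniform random onsets. The
#' blink amplitude is 5 times the per-trial background standard deviation on
#' frontal channels, scaled across the montage by [blink_topography()]. The
#' input is not modified.
#'
#' @param trials a [trial_set()].
#' @param rate expected blinks per trial (>= 0).
#' @param template blink waveform; must be shorter than the trial.
#' @param seed RNG seed.
#' @return A new `trial_set` with blinks added.
#' @export
inject_blinks <- function(trials, rate,
                          template = blink_template(trials$fs),
                          seed = 1L) {
  stopifnot(inherits(trials, "trial_set"))
  assert_scalar_num(rate, "rate", lower = 0)
  nt <- n_samples(trials)
  if (length(template) >= nt)
    stop_field("template", "must be shorter than the trial")
  if (rate == 0) return(trials)
  set.seed(seed)
  w <- blink_topography(trials$channel_names)
  dat <- trials$data
  L <- length(template)
  total <- 0L
  for (i in seq_len(n_trials(trials))) {
    k <- stats::rpois(1, rate)
    if (k == 0) next
    total <- total + k
    amp <- 5 * stats::sd(dat[i, , ])
    for (j in seq_len(k)) {
      onset <- sample.int(nt - L, 1)
      seg <- onset:(onset + L - 1L)
      for (ch in seq_along(w))
        dat[i, ch, seg] <- dat[i, ch, seg] + amp * w[ch] * template
    }
  }
  out <- with_data(trials, dat)
  attr(out, "n_blinks") <- total
  out
}
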