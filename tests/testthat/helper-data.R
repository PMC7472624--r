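## shared fixture builders (all generated in code, no stored data)

std_channels <- c("F3", "F4", "C3", "C4", "P3", "P4")

## small 128 Hz protocol, defaults to two classes
toy_protocol <- function(n_subjects = 1, classes = c("A", "B"),
                         trials_per_class = 10, fs = 128) {
  protocol_spec(n_subjects, std_channels, fs = fs, trial_dur = 4,
                classes = classes, trials_per_class = trials_per_class,
                task = "toy")
}

toy_trialset <- function(snr = 0, seed = 1, classes = c("A", "B"),
                         trials_per_class = 10, blink_rate = 0, fs = 128) {
  generate_dataset(toy_protocol(classes = classes,
                                trials_per_class = trials_per_class, fs = fs),
                   signal_model_spec(snr = snr, seed = seed,
                                     blink_rate = blink_rate))[[1]]
}

## deterministic single-trial set from an explicit channels x samples matrix
matrix_trialset <- function(M, fs = 128, label = "A") {
  arr <- array(0, c(1, nrow(M), ncol(M)))
  arr[1, , ] <- M
  trial_set(arr, label, "S01", fs, paste0("ch", seq_len(nrow(M))))
}

## sine-wave trial set: one trial per requested frequency
sine_trialset <- function(freqs, fs = 128, dur = 4, n_channels = 1) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  arr <- array(0, c(length(freqs), n_channels, length(t)))
  for (i in seq_along(freqs))
    for (ch in seq_len(n_channels))
      arr[i, ch, ] <- sin(2 * pi * freqs[i] * t)
  trial_set(arr, rep("A", length(freqs)), "S01", fs,
            paste0("ch", seq_len(n_channels)))
}

small_rlda_grid <- function() hp_grid("rlda", list(nsf = c(2, 3), miql = 6,
                                                   nof = 8))
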