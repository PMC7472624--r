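#' Labelled EEG trials for one subject and task
#'
#' A `trial_set` holds a `trials x channels x samples` numeric array together
#' with per-trial class labels, the subject identifier, the sampling rate and
#' the channel montage. It is the unit of data every other module consumes.
#'
#' @param data numeric array, `trials x channels x samples` (arbitrary
#'   microvolt-scale units).
#' @param labels factor or character vector of per-trial class labels.
#' @param subject_id subject identifier (character or integer).
#' @param fs sampling rate in Hz.
#' @param channel_names character vector naming the channel dimension.
#' @param task task tag, `"words"` or `"vowels"` (free-form allowed).
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, labels, subject_id, fs, channel_names,
                      task = "words") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_field("data", "must be a 3-d array (trials x channels x samples)")
  if (any(!is.finite(data)))
    stop_field("data", "contains NaN/Inf values")
  labels <- as.factor(labels)
  if (length(labels) != dim(data)[1L])
    stop_field("labels", "length must equal the number of trials")
  assert_scalar_num(fs, "fs", lower = 0, strict = TRUE)
  if (length(channel_names) != dim(data)[2L])
    stop_field("channel_names", "length must equal the channel dimension")
  structure(
    list(data = data, labels = labels,
         subject_id = as.character(subject_id), fs = fs,
         channel_names = as.character(channel_names), task = task),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> subject %s, task %s: %d trials x %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$task, d[1], d[2], d[3], x$fs))
  cat("  classes:", paste(sprintf("%s (%d)", levels(x$labels),
                                  tabulate(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.trial_set <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1L]
n_channels <- function(x) dim(x$data)[2L]
n_samples <- function(x) dim(x$data)[3L]

#' Subset a trial set by trial index
#' @param ts a `trial_set`.
#' @param idx integer or logical trial index.
#' @return A `trial_set` with the selected trials.
#' @export
subset_trials <- function(ts, idx) {
  trial_set(ts$data[idx, , , drop = FALSE], droplevels(ts$labels[idx]),
            ts$subject_id, ts$fs, ts$channel_names, ts$task)
}

## replace the data array, keeping metadata (shape-preserving ops)
with_data <- function(ts, data, fs = ts$fs) {
  trial_set(data, ts$labels, ts$subject_id, fs, ts$channel_names, ts$task)
}
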