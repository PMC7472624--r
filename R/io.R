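#' Save a multi-subject dataset to a single-file container
#'
#' Serializes the list of trial sets (one group per subject: data array,
#' labels, channel and rate metadata) to a single RDS file, and writes a
#' CSV label manifest (`<path>.manifest.csv`) with one row per trial.
#'
#' @param dataset list of [trial_set()]s.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(all(vapply(dataset, inherits, TRUE, "trial_set")))
  saveRDS(dataset, path)
  manifest <- do.call(rbind, lapply(dataset, function(ts)
    data.frame(subject = ts$subject_id, task = ts$task,
               trial = seq_len(n_trials(ts)), label = as.character(ts$labels),
               fs = ts$fs, n_channels = n_channels(ts),
               n_samples = n_samples(ts))))
  utils::write.csv(manifest, paste0(path, ".manifest.csv"), row.names = FALSE)
  invisible(path)
}

#' Load a dataset container written by [save_dataset()]
#' @param path container file path.
#' @return List of `trial_set`s.
#' @export
load_dataset <- function(path) {
  dataset <- readRDS(path)
  stopifnot(all(vapply(dataset, inherits, TRUE, "trial_set")))
  dataset
}

#' Flatten nested-CV results to a tidy fold-level table
#'
#' One row per (subject, outer fold): family, mode, selected
#' hyperparameters, fold accuracy, macro precision.
#'
#' @param results list of `cv_result`s.
#' @param mode selection mode tag to attach (`"intra"` or `"inter"`).
#' @return A data frame suitable for CSV export.
#' @export
results_to_table <- function(results, mode = "intra") {
  do.call(rbind, lapply(results, function(r) {
    data.frame(subject = r$subject_id, task = r$task, family = r$family,
               mode = mode, fold = seq_along(r$outer_accs), split = "test",
               theta = format_theta(r$theta_star),
               accuracy = r$outer_accs,
               macro_precision = r$precision$macro)
  }))
}
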