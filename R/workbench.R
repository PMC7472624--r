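#' Experiment configuration
#'
#' Bundles the protocol, signal model, preprocessing choices,
#' decoder families, grids, fold count, selection modes and seed into one
#' validated object. `scale` shrinks the study design to desk size
#' (subject count, trials per class, grid subset, CNN epoch cap).
#'
#' @param protocol a [protocol_spec()] or `"words"`/`"vowels"`.
#' @param model a [signal_model_spec()].
#' @param families decoder families to run.
#' @param grids named list of [hp_grid()]s; defaults per family.
#' @param k fold count.
#' @param modes subset of `c("intra", "inter")`.
#' @param seed master seed.
#' @param preprocess list: `bandpass = c(lo, hi)`, `target_fs`,
#'   `blink_threshold`, `remove_blinks` (logical).
#' @param scale list: `grid_subset` (first n combinations; NULL = all),
#'   `epochs_cap` (cap CNN epochs; NULL = none).
#' @param out_dir output directory for [run_experiment()].
#' @return An `experiment_config`.
#' @export
experiment_config <- function(protocol = "words",
                              model = signal_model_spec(),
                              families = "rlda",
                              grids = NULL, k = 4L,
                              modes = "intra", seed = 1L,
                              preprocess = list(bandpass = c(2, 40),
                                                target_fs = 128,
                                                blink_threshold = 0.8,
                                                remove_blinks = FALSE),
                              scale = list(grid_subset = NULL,
                                           epochs_cap = NULL),
                              out_dir = tempfile("bcidecode_run_")) {
  if (is.character(protocol))
    protocol <- switch(protocol, words = protocol_words(),
                       vowels = protocol_vowels(),
                       stop_field("protocol", "unknown protocol name"))
  cfg <- structure(list(protocol = protocol, model = model,
                        families = families, grids = grids, k = k,
                        modes = modes, seed = seed, preprocess = preprocess,
                        scale = scale, out_dir = out_dir),
                   class = "experiment_config")
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "),
                         call. = FALSE)
  cfg
}

#' Validate an experiment configuration
#'
#' Returns every violation (with a path into the config) instead of
#' stopping at the first.
#'
#' @param cfg an `experiment_config` (or plain list with the same fields).
#' @return Character vector of problems; empty when valid.
#' @export
validate_config <- function(cfg) {
  errs <- character()
  push <- function(m) errs <<- c(errs, m)
  if (!inherits(cfg$protocol, "protocol_spec"))
    push("protocol: not a protocol_spec")
  if (!inherits(cfg$model, "signal_model_spec"))
    push("model: not a signal_model_spec")
  known <- c("shallow_cnn", "deep_cnn", "eegnet", "svm", "rdf", "rlda",
             "majority")
  bad <- setdiff(cfg$families, known)
  if (length(bad)) push(paste0("families: unknown family ",
                               paste(bad, collapse = ", ")))
  if (!is.numeric(cfg$k) || length(cfg$k) != 1L || cfg$k < 2L)
    push("k: must be an integer >= 2")
  if (inherits(cfg$protocol, "protocol_spec") && is.numeric(cfg$k) &&
      length(cfg$k) == 1L && cfg$protocol$trials_per_class < cfg$k)
    push("protocol.trials_per_class: fewer trials per class than folds")
  if (!all(cfg$modes %in% c("intra", "inter")))
    push("modes: must be a subset of intra, inter")
  if (is.null(cfg$seed)) push("seed: must be explicit")
  pp <- cfg$preprocess
  if (!is.null(pp$bandpass) &&
      !(length(pp$bandpass) == 2L && pp$bandpass[1] < pp$bandpass[2]))
    push("preprocess.bandpass: requires lo < hi")
  if (!is.null(pp$target_fs) && inherits(cfg$protocol, "protocol_spec") &&
      pp$target_fs > cfg$protocol$fs)
    push("preprocess.target_fs: exceeds the protocol sampling rate")
  for (fam in intersect(cfg$families, names(cfg$grids %||% list()))) {
    g <- cfg$grids[[fam]]
    if (!inherits(g, "hp_grid")) { push(paste0("grids.", fam, ": not an hp_grid")); next }
    ref <- default_grid(fam)$dimensions
    for (d in intersect(names(g$dimensions), names(ref))) {
      out_of <- setdiff(g$dimensions[[d]], ref[[d]])
      if (length(out_of))
        push(sprintf("grids.%s.%s: value %s not in the declared dimension",
                     fam, d, paste(out_of, collapse = ", ")))
    }
  }
  errs
}

#' Read an experiment configuration from a YAML file
#'
#' See the packaged examples under `system.file("configs",
#' package = "bcidecode")`: `paper_words.yaml` / `paper_vowels.yaml` encode
#' the full study design, `desk.yaml` a desk-scale run.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  proto <- if (is.character(y$protocol)) y$protocol else
    protocol_spec(y$protocol$n_subjects, y$protocol$channels, y$protocol$fs,
                  y$protocol$trial_dur, y$protocol$classes,
                  y$protocol$trials_per_class, y$protocol$task %||% "words")
  model <- do.call(signal_model_spec, y$model %||% list())
  grids <- NULL
  if (!is.null(y$grids))
    grids <- lapply(stats::setNames(names(y$grids), names(y$grids)),
                    function(f) hp_grid(f, y$grids[[f]]))
  experiment_config(protocol = proto, model = model,
                    families = y$families %||% "rlda",
                    grids = grids, k = y$k %||% 4L,
                    modes = y$modes %||% "intra", seed = y$seed %||% 1L,
                    preprocess = utils::modifyList(
                      list(bandpass = c(2, 40), target_fs = 128,
                           blink_threshold = 0.8, remove_blinks = FALSE),
                      y$preprocess %||% list()),
                    scale = y$scale %||% list(),
                    out_dir = y$out_dir %||% tempfile("bcidecode_run_"))
}

#' Run a full experiment from a configuration
#'
#' Generates the dataset, preprocesses it (band-pass, optional ICA blink
#' removal, downsampling), runs nested CV for every family x mode, and
#' writes a deterministic directory: the dataset container, fold-level and
#' summary CSV tables, a statistics report and a manifest with content
#' hashes of every output file.
#'
#' @param cfg an [experiment_config()].
#' @return The output directory path, invisibly; results are also returned
#'   in the `results` attribute.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- generate_dataset(cfg$protocol, cfg$model)
  save_dataset(dataset, file.path(cfg$out_dir, "dataset.rds"))
  pp <- cfg$preprocess
  dataset <- lapply(dataset, function(ts) {
    if (!is.null(pp$bandpass))
      ts <- bandpass_fir(ts, pp$bandpass[1], pp$bandpass[2])
    if (isTRUE(pp$remove_blinks))
      ts <- remove_blinks(ts, threshold = pp$blink_threshold %||% 0.8,
                          seed = cfg$seed)$trials
    if (!is.null(pp$target_fs) && pp$target_fs < ts$fs)
      ts <- downsample(ts, pp$target_fs)
    ts
  })
  save_dataset(dataset, file.path(cfg$out_dir, "preprocessed.rds"))
  all_results <- list()
  fold_tables <- list()
  for (fam in cfg$families) {
    grid <- cfg$grids[[fam]] %||% default_grid(fam)
    if (!is.null(cfg$scale$grid_subset)) {
      combos <- enumerate_grid(grid)
      keep <- seq_len(min(cfg$scale$grid_subset, length(combos)))
      dims <- lapply(seq_along(grid$dimensions), function(j)
        unique(vapply(combos[keep], function(th) th[[j]], grid$dimensions[[j]][1])))
      names(dims) <- names(grid$dimensions)
      grid <- hp_grid(fam, dims)
    }
    if (!is.null(cfg$scale$epochs_cap) && is_cnn_family(fam))
      grid$dimensions$epochs <-
        pmin(grid$dimensions$epochs, cfg$scale$epochs_cap)
    for (mode in cfg$modes) {
      res <- if (mode == "intra")
        run_intra_subject(dataset, fam, grid, cfg$k, cfg$seed)
      else run_inter_subject(dataset, fam, grid, cfg$k, cfg$seed)
      res <- lapply(res, function(r) { r$mode <- mode; r })
      all_results <- c(all_results, res)
      fold_tables[[paste(fam, mode, sep = "_")]] <-
        results_to_table(res, mode)
    }
  }
  folds <- do.call(rbind, fold_tables)
  utils::write.csv(folds, file.path(cfg$out_dir, "cv_folds.csv"),
                   row.names = FALSE)
  tabs <- assemble_tables(all_results)
  utils::write.csv(tabs$accuracy, file.path(cfg$out_dir, "accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$hp_frequency,
                   file.path(cfg$out_dir, "hp_frequency.csv"),
                   row.names = FALSE)
  report_stats(all_results, file.path(cfg$out_dir, "stats_report.txt"))
  files <- setdiff(list.files(cfg$out_dir), "manifest.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(cfg$out_dir, files))),
    seed = cfg$seed)
  utils::write.csv(manifest, file.path(cfg$out_dir, "manifest.csv"),
                   row.names = FALSE)
  out <- cfg$out_dir
  attr(out, "results") <- all_results
  invisible(out)
}

## run-report: per family x mode ANOVA across families where possible
report_stats <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(subject = r$subject_id, family = r$family,
               mode = r$mode %||% "intra", y = r$mean_test_acc)))
  writeLines("# nested-CV statistical report", con)
  fams <- unique(tab$family)
  if (length(fams) >= 2L && length(unique(tab$mode)) >= 2L) {
    an <- twoway_anova(tab, c("family", "mode"))
    writeLines("\n## two-way ANOVA: family x mode", con)
    writeLines(utils::capture.output(print(an)), con)
    tk <- tryCatch(tukey_hsd(split(tab$y, tab$family)), error = function(e) NULL)
    if (!is.null(tk)) {
      writeLines("\n## Tukey HSD across families", con)
      writeLines(utils::capture.output(print(tk)), con)
    }
  } else {
    writeLines("\n(single family/mode: no between-method ANOVA)", con)
  }
  writeLines("\n## per-run accuracies", con)
  writeLines(utils::capture.output(print(tab, row.names = FALSE)), con)
  invisible(path)
}
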