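#' Stratified nested fold plan
#'
#' Partitions trials into `k` outer folds stratified by class (per-fold
#' class counts equal within 1), and for each outer fold partitions the
#' remaining trials into `k` inner folds, again stratified. Inner
#' assignments are re-seeded deterministically from the outer fold index
#' and the master seed.
#'
#' @param labels per-trial class labels (or a [trial_set()]).
#' @param k fold count (>= 2); every class needs at least `k` trials.
#' @param seed RNG seed.
#' @return A `fold_plan`: `k`, `outer_assignments` (per-trial fold index),
#'   `inner_assignments` (list per outer fold; `NA` for held-out trials),
#'   `seed`.
#' @export
make_folds <- function(labels, k = 4L, seed = 1L) {
  if (inherits(labels, "trial_set")) labels <- labels$labels
  labels <- as.factor(labels)
  k <- assert_count(k, "k", min = 2L)
  cnt <- tabulate(labels)
  if (any(cnt < k))
    stop_field("labels", sprintf("class '%s' has fewer than k = %d trials",
                                 levels(labels)[which.min(cnt)], k))
  outer <- stratified_assign(labels, k, child_seed(seed, 1L))
  inner <- lapply(seq_len(k), function(i) {
    a <- rep(NA_integer_, length(labels))
    idx <- which(outer != i)
    a[idx] <- stratified_assign(droplevels(labels[idx]), k,
                                child_seed(seed, 2L, i))
    a
  })
  structure(list(k = k, outer_assignments = outer,
                 inner_assignments = inner, seed = seed),
            class = "fold_plan")
}

## round-robin fold assignment within each class, shuffled, with a rotating
## starting fold so remainder trials spread evenly across folds
stratified_assign <- function(labels, k, seed) {
  set.seed(seed)
  a <- integer(length(labels))
  offset <- 0L
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    a[idx] <- (seq_along(idx) - 1L + offset) %% k + 1L
    offset <- (offset + length(idx)) %% k
  }
  a
}

## ---- decoding pipelines ------------------------------------------------

#' Prepare a trial set for decoding with a given family
#'
#' Computes the per-trial, label-free representation each family consumes:
#' RWE vectors for `svm`/`rdf`, the filter-bank decomposition for `rlda`
#' (supervised CSP/MI fitting happens later, inside the training folds) and
#' raw trials for the CNNs. Doing this once, before cross-validation, is
#' leak-free because none of it uses labels.
#'
#' @param trials a [trial_set()] (128 Hz for the standard pipelines).
#' @param family decoder family.
#' @param fb filter bank for `rlda` (defaults to the canonical six bands).
#' @return A `decoding_data` list.
#' @export
prepare_decoding_data <- function(trials, family,
                                  fb = build_filterbank(fs = trials$fs)) {
  stopifnot(inherits(trials, "trial_set"))
  out <- list(family = family, labels = trials$labels,
              subject_id = trials$subject_id, task = trials$task)
  if (family %in% c("svm", "rdf")) {
    out$X <- rwe_extract(trials)
  } else if (family == "rlda") {
    out$bands <- lapply(apply_filterbank(trials, fb), function(ts) ts$data)
    out$band_covs <- lapply(out$bands, trial_covs)
  } else {
    out$X <- trials$data
  }
  structure(out, class = "decoding_data")
}

## fit on train_idx, return accuracy on test_idx (0 on failure/divergence)
fit_and_score <- function(prep, theta, train_idx, test_idx, seed,
                          return_pred = FALSE) {
  fam <- prep$family
  y_tr <- droplevels(prep$labels[train_idx])
  y_te <- prep$labels[test_idx]
  res <- tryCatch({
    if (fam == "rlda") {
      tr_bands <- lapply(prep$bands, function(b) b[train_idx, , , drop = FALSE])
      te_bands <- lapply(prep$bands, function(b) b[test_idx, , , drop = FALSE])
      tr_covs <- if (!is.null(prep$band_covs))
        lapply(prep$band_covs, function(cv) cv[, , train_idx, drop = FALSE])
      fm <- fbcsp_fit(tr_bands, y_tr, nsf = theta$nsf %||% 2L,
                      miql = theta$miql %||% 6L, nof = theta$nof %||% 8L,
                      band_covs = tr_covs)
      model <- fit_decoder(decoder_spec("rlda", theta,
                                        n_classes = nlevels(y_tr)),
                           fbcsp_transform(fm, tr_bands), y_tr, seed = seed)
      pred <- predict(model, fbcsp_transform(fm, te_bands))
    } else {
      Xtr <- if (is.matrix(prep$X)) prep$X[train_idx, , drop = FALSE]
             else prep$X[train_idx, , , drop = FALSE]
      Xte <- if (is.matrix(prep$X)) prep$X[test_idx, , drop = FALSE]
             else prep$X[test_idx, , , drop = FALSE]
      model <- fit_decoder(decoder_spec(fam, theta, n_classes = nlevels(y_tr)),
                           Xtr, y_tr, seed = seed)
      pred <- predict(model, Xte)
    }
    list(acc = accuracy(pred, y_te), pred = pred)
  }, error = function(e) list(acc = 0, pred = NULL))
  if (return_pred) res else res$acc
}

#' Exhaustive inner-fold hyperparameter evaluation
#'
#' For every outer fold, re-partitions the concatenated training folds into
#' `k` inner folds and records one validation accuracy per (combination,
#' outer fold, inner fold). Failed or diverged fits score 0, keeping the
#' grid search total. Feature fitting (CSP, MI selection) is confined to
#' the inner training folds.
#'
#' @param prep a `decoding_data` from [prepare_decoding_data()].
#' @param plan a [make_folds()] plan.
#' @param combos list of hyperparameter combinations
#'   (from [enumerate_grid()]).
#' @param seed master seed; per-fit seeds derive from it.
#' @return List with `inner_table` (array `combos x outer x inner`) and
#'   `mean_acc` (per-combination mean over all inner folds of all outer
#'   folds).
#' @export
inner_search <- function(prep, plan, combos, seed = plan$seed) {
  k <- plan$k
  tab <- array(NA_real_, c(length(combos), k, k),
               dimnames = list(vapply(combos, format_theta, ""),
                               paste0("outer", seq_len(k)),
                               paste0("inner", seq_len(k))))
  for (i in seq_len(k)) {
    ia <- plan$inner_assignments[[i]]
    for (j in seq_len(k)) {
      tr <- which(!is.na(ia) & ia != j)
      va <- which(!is.na(ia) & ia == j)
      ## per-cell seed shared by all combinations, so duplicated
      ## combinations score identically and runs are reproducible
      cell_seed <- child_seed(seed, 3L, i, j)
      for (t in seq_along(combos)) {
        tab[t, i, j] <- fit_and_score(prep, combos[[t]], tr, va,
                                      seed = cell_seed)
      }
    }
  }
  list(inner_table = tab, mean_acc = apply(tab, 1L, mean))
}

#' Select the optimal hyperparameter combination
#'
#' Argmax of the mean validation accuracy; exact ties resolve to the
#' earliest combination in enumeration order.
#'
#' @param mean_acc numeric vector of per-combination mean accuracies.
#' @return Index of the selected combination.
#' @export
select_theta_star <- function(mean_acc) {
  if (length(mean_acc) == 0L) stop_field("mean_acc", "is empty")
  which.max(mean_acc)
}

## evaluate a single combination on every outer fold
outer_evaluate <- function(prep, plan, theta, seed) {
  k <- plan$k
  accs <- numeric(k)
  preds <- character(length(prep$labels))
  for (i in seq_len(k)) {
    te <- which(plan$outer_assignments == i)
    tr <- which(plan$outer_assignments != i)
    r <- fit_and_score(prep, theta, tr, te,
                       seed = child_seed(seed, 4L, i), return_pred = TRUE)
    accs[i] <- r$acc
    preds[te] <- if (!is.null(r$pred)) r$pred$labels_hat else NA_character_
  }
  list(outer_accs = accs, predictions = preds)
}

#' Nested cross-validation for one subject
#'
#' Runs the full nested procedure: stratified outer/inner partitions,
#' exhaustive inner-fold grid evaluation, argmax selection of the
#' hyperparameter combination on the mean inner-fold validation accuracy
#' aggregated across all outer folds, then final training and testing of
#' that single combination on each outer fold.
#'
#' @param trials a [trial_set()] (or a prepared `decoding_data`).
#' @param family decoder family.
#' @param grid an [hp_grid()]; defaults to the family's study grid.
#' @param k fold count (4 in the study design).
#' @param seed master seed.
#' @return A `cv_result`: `inner_table`, `mean_acc`, `theta_star` (+ index),
#'   `outer_accs`, `mean_test_acc`, `precision` (per class and macro),
#'   `subject_id`, `task`, `family`.
#' @export
run_ncv <- function(trials, family, grid = default_grid(family), k = 4L,
                    seed = 1L) {
  prep <- if (inherits(trials, "decoding_data")) trials
          else prepare_decoding_data(trials, family)
  combos <- enumerate_grid(grid)
  plan <- make_folds(prep$labels, k, seed)
  srch <- inner_search(prep, plan, combos, seed)
  ti <- select_theta_star(srch$mean_acc)
  fin <- outer_evaluate(prep, plan, combos[[ti]], seed)
  prec <- precision_scores(fin$predictions, prep$labels)
  structure(list(inner_table = srch$inner_table, mean_acc = srch$mean_acc,
                 theta_star = combos[[ti]], theta_star_index = ti,
                 outer_accs = fin$outer_accs,
                 mean_test_acc = mean(fin$outer_accs),
                 precision = prec, predictions = fin$predictions,
                 subject_id = prep$subject_id, task = prep$task,
                 family = family, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s subject %s (%s): mean test acc %.2f%%\n",
              x$family, x$subject_id, x$task, 100 * x$mean_test_acc))
  cat("  theta*:", format_theta(x$theta_star), "\n")
  invisible(x)
}

#' Intra-subject nested CV over a cohort
#'
#' Selects a hyperparameter combination independently for every subject
#' from that subject's own inner folds, then tests it on the subject's
#' outer folds.
#'
#' @param dataset list of [trial_set()]s, one per subject.
#' @param family decoder family.
#' @param grid an [hp_grid()].
#' @param k fold count.
#' @param seed master seed; per-subject seeds derive from it.
#' @return List of `cv_result` (one per subject) with a `cohort` attribute
#'   holding mean/sd/max test accuracy.
#' @export
run_intra_subject <- function(dataset, family, grid = default_grid(family),
                              k = 4L, seed = 1L) {
  res <- lapply(seq_along(dataset), function(s)
    run_ncv(dataset[[s]], family, grid, k, seed = child_seed(seed, 7L, s)))
  attr(res, "cohort") <- cohort_summary(res)
  res
}

#' Inter-subject nested CV: one shared hyperparameter combination
#'
#' Computes every subject's inner-fold table, selects the single
#' combination maximizing the mean validation accuracy pooled across all
#' subjects' inner folds, then trains and tests per subject with that
#' shared combination.
#'
#' @inheritParams run_intra_subject
#' @return List of `cv_result` sharing one `theta_star`, with a `cohort`
#'   attribute.
#' @export
run_inter_subject <- function(dataset, family, grid = default_grid(family),
                              k = 4L, seed = 1L) {
  combos <- enumerate_grid(grid)
  preps <- lapply(dataset, prepare_decoding_data, family = family)
  plans <- lapply(seq_along(dataset), function(s)
    make_folds(preps[[s]]$labels, k, child_seed(seed, 7L, s)))
  searches <- lapply(seq_along(dataset), function(s)
    inner_search(preps[[s]], plans[[s]], combos, child_seed(seed, 7L, s)))
  pooled <- rowMeans(do.call(cbind, lapply(searches, `[[`, "mean_acc")))
  ti <- select_theta_star(pooled)
  res <- lapply(seq_along(dataset), function(s) {
    fin <- outer_evaluate(preps[[s]], plans[[s]], combos[[ti]],
                          child_seed(seed, 7L, s))
    structure(list(inner_table = searches[[s]]$inner_table,
                   mean_acc = searches[[s]]$mean_acc,
                   pooled_mean_acc = pooled,
                   theta_star = combos[[ti]], theta_star_index = ti,
                   outer_accs = fin$outer_accs,
                   mean_test_acc = mean(fin$outer_accs),
                   precision = precision_scores(fin$predictions,
                                                preps[[s]]$labels),
                   predictions = fin$predictions,
                   subject_id = preps[[s]]$subject_id,
                   task = preps[[s]]$task,
                   family = family, k = k, seed = seed),
              class = "cv_result")
  })
  attr(res, "cohort") <- cohort_summary(res)
  res
}

cohort_summary <- function(results) {
  acc <- vapply(results, `[[`, 0, "mean_test_acc")
  data.frame(mean = mean(acc), sd = if (length(acc) > 1) stats::sd(acc) else 0,
             max = max(acc))
}
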