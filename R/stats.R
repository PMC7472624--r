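#' One-factor repeated-measures ANOVA on a subject x level accuracy table
#'
#' Within-subject ANOVA with the subject-by-level interaction as the error
#' term (the standard univariate RM decomposition). Accuracies enter
#' untransformed by default; `arcsine = TRUE` applies the arcsine-square-
#' root variance-stabilizing transform first.
#'
#' @param table numeric matrix or data frame, rows = subjects, columns =
#'   factor levels; complete and balanced.
#' @param arcsine apply `asin(sqrt(x))` (expects values in `[0, 1]`).
#' @return An `anova_result` data frame: `effect`, `F`, `df1`, `df2`, `p`.
#' @export
rm_anova <- function(table, arcsine = FALSE) {
  table <- as.matrix(table)
  if (any(!is.finite(table))) stop_field("table", "has missing cells")
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop_field("table", "needs >= 2 subjects and >= 2 levels")
  if (arcsine) table <- asin(sqrt(pmin(pmax(table, 0), 1)))
  n <- nrow(table); a <- ncol(table)
  df <- data.frame(y = as.vector(table),
                   subject = factor(rep(seq_len(n), a)),
                   level = factor(rep(seq_len(a), each = n)))
  fit <- stats::aov(y ~ level + Error(subject / level), data = df)
  st <- summary(fit)[["Error: subject:level"]][[1]]
  ss_eff <- st["level", "Sum Sq"]; ss_err <- st["Residuals", "Sum Sq"]
  df1 <- st["level", "Df"]; df2 <- st["Residuals", "Df"]
  if (ss_eff <= .Machine$double.eps * max(1, ss_err)) {
    Fv <- 0; p <- 1
  } else if (ss_err <= .Machine$double.eps * ss_eff) {
    Fv <- Inf; p <- 0
  } else {
    Fv <- (ss_eff / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  structure(data.frame(effect = "level", F = Fv, df1 = df1, df2 = df2, p = p),
            class = c("anova_result", "data.frame"))
}

#' Two-way ANOVA with interaction on replicated accuracies
#'
#' Fixed-effects crossed design (e.g. hyperparameter level x CNN type) with
#' main effects and the interaction.
#'
#' @param data data frame with numeric `y` and two factor columns.
#' @param factors length-2 character vector naming the factor columns.
#' @param response name of the response column.
#' @return An `anova_result` data frame with one row per effect
#'   (two mains + interaction).
#' @export
twoway_anova <- function(data, factors, response = "y") {
  stopifnot(is.data.frame(data), length(factors) == 2L)
  f1 <- factors[1]; f2 <- factors[2]
  data[[f1]] <- as.factor(data[[f1]]); data[[f2]] <- as.factor(data[[f2]])
  cell <- table(data[[f1]], data[[f2]])
  if (any(cell == 0)) stop_field("data", "empty design cells")
  if (all(cell == 1))
    stop_field("data", "interaction requires replicated cells")
  form <- stats::as.formula(paste(response, "~", f1, "*", f2))
  fit <- stats::aov(form, data = data)
  st <- summary(fit)[[1]]
  rn <- trimws(rownames(st))
  keep <- rn != "Residuals"
  out <- data.frame(effect = rn[keep],
                    F = st[keep, "F value"],
                    df1 = st[keep, "Df"],
                    df2 = st["Residuals" == rn, "Df"],
                    p = st[keep, "Pr(>F)"])
  out$F[is.na(out$F)] <- 0
  out$p[is.na(out$p)] <- 1
  structure(out, class = c("anova_result", "data.frame"))
}

#' Tukey HSD post-hoc comparisons
#'
#' Studentized-range adjusted pairwise p-values over group means.
#'
#' @param groups named list of replicate numeric vectors (>= 2 each), or a
#'   data frame with columns `y` and `group`.
#' @param alpha significance threshold for the `significant` flags.
#' @return A `posthoc_result` data frame: `pair`, `diff`, `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups))
    groups <- split(groups$y, groups$group)
  if (length(groups) < 2L) stop_field("groups", "need at least two groups")
  if (any(vapply(groups, length, 0L) < 2L))
    stop_field("groups", "every group needs >= 2 replicates")
  df <- data.frame(y = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, 0L))))
  if (stats::var(df$y) == 0) {
    pairs <- utils::combn(names(groups), 2L)
    out <- data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                      diff = 0, p_adj = 1, significant = FALSE)
    return(structure(out, class = c("posthoc_result", "data.frame")))
  }
  tk <- stats::TukeyHSD(stats::aov(y ~ group, data = df))$group
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    p_adj = tk[, "p adj"],
                    significant = tk[, "p adj"] < alpha,
                    row.names = NULL)
  structure(out, class = c("posthoc_result", "data.frame"))
}

#' Per-class and macro precision
#'
#' Precision = true positives / (true positives + false positives) per
#' class. A class never predicted has undefined precision; it is reported
#' as `NA` and excluded from the macro mean.
#'
#' @param pred predicted labels, or a `prediction_batch`.
#' @param y true labels.
#' @return List with `per_class` (named, `NA` where undefined) and `macro`.
#' @export
precision_scores <- function(pred, y) {
  if (inherits(pred, "prediction_batch")) pred <- pred$labels_hat
  y <- as.character(y); pred <- as.character(pred)
  classes <- sort(unique(y))
  per <- vapply(classes, function(cl) {
    pp <- sum(pred == cl, na.rm = TRUE)
    if (pp == 0) return(NA_real_)
    sum(pred == cl & y == cl, na.rm = TRUE) / pp
  }, 0)
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' Summary tables over a collection of nested-CV results
#'
#' Builds the per-task mean/sd/max accuracy table per family x selection
#' mode, the selected-hyperparameter table, and selection frequency counts
#' per hyperparameter value. A pure function of the result set: output is
#' invariant to the order of `results`.
#'
#' @param results list of `cv_result` objects; each may carry a `mode`
#'   field/attribute (`"intra"`/`"inter"`), defaulting to `"intra"`.
#' @return List of data frames `accuracy`, `selected_hps`, `hp_frequency`.
#' @export
assemble_tables <- function(results) {
  if (length(results) == 0L) stop_field("results", "is empty")
  rows <- lapply(results, function(r) {
    data.frame(subject = r$subject_id, task = r$task, family = r$family,
               mode = r$mode %||% attr(r, "mode") %||% "intra",
               accuracy = r$mean_test_acc,
               theta = format_theta(r$theta_star))
  })
  long <- do.call(rbind, rows)
  long <- long[order(long$task, long$family, long$mode, long$subject), ]
  acc <- do.call(rbind, lapply(
    split(long, list(long$task, long$family, long$mode), drop = TRUE),
    function(g) data.frame(task = g$task[1], family = g$family[1],
                           mode = g$mode[1],
                           mean = mean(g$accuracy),
                           sd = if (nrow(g) > 1) stats::sd(g$accuracy) else 0,
                           max = max(g$accuracy))))
  rownames(acc) <- NULL
  acc <- acc[order(acc$task, acc$family, acc$mode), ]
  hp_rows <- do.call(rbind, lapply(results, function(r) {
    th <- r$theta_star
    data.frame(subject = r$subject_id, task = r$task, family = r$family,
               mode = r$mode %||% attr(r, "mode") %||% "intra",
               hp = names(th),
               value = vapply(th, function(v) format(v, trim = TRUE), ""))
  }))
  freq <- stats::aggregate(list(count = rep(1L, nrow(hp_rows))),
                           by = hp_rows[c("family", "hp", "value")], FUN = sum)
  freq <- freq[order(freq$family, freq$hp, freq$value), ]
  rownames(freq) <- NULL
  list(accuracy = acc, selected_hps = long, hp_frequency = freq)
}
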