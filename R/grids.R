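#' Hyperparameter grid
#'
#' A named list of allowed values per dimension, tied to the decoder family
#' it parameterizes. The full grid is the Cartesian product of dimensions.
#'
#' @param family decoder family the grid parameterizes.
#' @param dimensions named list of non-empty value vectors.
#' @return An `hp_grid`.
#' @export
hp_grid <- function(family, dimensions) {
  if (length(dimensions) == 0L || is.null(names(dimensions)) ||
      any(!nzchar(names(dimensions))))
    stop_field("dimensions", "must be a named list")
  if (any(vapply(dimensions, length, 0L) == 0L))
    stop_field("dimensions", "every dimension must be non-empty")
  structure(list(family = family, dimensions = dimensions), class = "hp_grid")
}

#' Study-default hyperparameter grids
#'
#' The CNN grid (shared by all three architectures) crosses 4 activations,
#' 4 learning rates, 4 epoch counts and 2 loss functions (128
#' combinations). `svm`: 4 kernels x 4 C x 4 g. `rdf`: features per split
#' 4-7, trees \{50, 100, 200, 500\}, minimum samples per leaf 1-4. `rlda`
#' (FBCSP): spatial-filter pairs 2-5, MI quantization level \{6, 8, 10,
#' 12\} (an alternate level set \{2, 4, 6, 8\} is selectable via
#' `miql_grid`), features per trial \{8, 10, 12, 14\}.
#'
#' @param family decoder family.
#' @param miql_grid MIQL values for the `rlda` grid.
#' @return An [hp_grid()].
#' @export
default_grid <- function(family, miql_grid = c(6, 8, 10, 12)) {
  if (is_cnn_family(family))
    return(hp_grid(family, list(
      activation = c("elu", "square", "relu", "leaky_relu"),
      lr = c(0.001, 0.01, 0.1, 1.0),
      epochs = c(20L, 40L, 60L, 80L),
      loss = c("nll", "ce"))))
  switch(family,
    svm = hp_grid("svm", list(
      kernel = c("linear", "radial", "polynomial", "sigmoid"),
      C = c(0.1, 1, 10, 100),
      g = c(0.01, 0.1, 1, 10))),
    rdf = hp_grid("rdf", list(
      nof = 4:7,
      trees = c(50L, 100L, 200L, 500L),
      msl = 1:4)),
    rlda = hp_grid("rlda", list(
      nsf = 2:5,
      miql = miql_grid,
      nof = c(8L, 10L, 12L, 14L))),
    majority = hp_grid("majority", list(dummy = 1)),
    stop_field("family", paste("no default grid for", family)))
}

#' Enumerate every combination of a hyperparameter grid
#'
#' Lexicographic over dimensions as declared: the first dimension varies
#' slowest.
#'
#' @param grid an [hp_grid()].
#' @return List of named hyperparameter lists, of length equal to the
#'   product of dimension sizes.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "hp_grid"))
  dims <- grid$dimensions
  sizes <- vapply(dims, length, 0L)
  n <- prod(sizes)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- i - 1L
    combo <- vector("list", length(dims))
    names(combo) <- names(dims)
    for (j in rev(seq_along(dims))) {
      combo[[j]] <- dims[[j]][idx %% sizes[j] + 1L]
      idx <- idx %/% sizes[j]
    }
    out[[i]] <- combo
  }
  out
}

## compact single-line label for a combination (used in result tables)
format_theta <- function(theta) {
  paste(vapply(names(theta), function(nm)
    paste0(nm, "=", format(theta[[nm]], trim = TRUE)), ""), collapse = ",")
}
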