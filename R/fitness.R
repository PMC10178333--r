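#' Threshold a continuous position into a feature mask
#'
#' Strict threshold at 0.5: feature `j` is selected iff `x[j] > 0.5`
#' (a position of exactly 0.5 deselects).
#'
#' @param x Finite numeric vector.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize <- function(x) {
  if (any(!is.finite(x))) stop("position must be finite", call. = FALSE)
  as.integer(x > 0.5)
}

#' k-nearest-neighbour prediction
#'
#' Euclidean distance, majority vote among the `k` nearest training rows.
#' A tied vote is broken by the label of the nearest neighbour belonging to
#' one of the tied classes; tied distances are broken by training-row order,
#' so predictions are fully deterministic.
#'
#' @param train_x Numeric training matrix (rows = samples).
#' @param train_y Factor of training labels.
#' @param test_x Numeric matrix of query rows.
#' @param k Number of neighbours (at most `nrow(train_x)`).
#' @return Factor of predicted labels with the levels of `train_y`.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 5) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  train_y <- as.factor(train_y)
  n_tr <- nrow(train_x)
  if (k > n_tr) stop("`k` exceeds the number of training samples", call. = FALSE)
  # squared Euclidean distances, train rows x test rows
  cross <- train_x %*% t(test_x)
  d2 <- matrix(rowSums(train_x^2), n_tr, nrow(test_x)) - 2 * cross +
    matrix(rowSums(test_x^2), n_tr, nrow(test_x), byrow = TRUE)
  lev <- levels(train_y)
  y_int <- as.integer(train_y)
  out <- integer(nrow(test_x))
  for (j in seq_len(nrow(test_x))) {
    nn <- y_int[order(d2[, j])[seq_len(k)]]
    counts <- tabulate(nn, nbins = length(lev))
    winners <- which(counts == max(counts))
    out[j] <- if (length(winners) == 1L) winners else nn[nn %in% winners][1L]
  }
  factor(lev[out], levels = lev)
}

#' Classification error of a feature subset
#'
#' Fits the KNN wrapper classifier on the training rows restricted to the
#' selected columns and returns the misclassification fraction on the
#' validation rows. Features are used unstandardized.
#'
#' @param train_x,train_y Training matrix and labels.
#' @param val_x,val_y Validation matrix and labels.
#' @param mask 0/1 vector over columns (at least one selected).
#' @param k Number of neighbours.
#' @return Misclassification fraction `gamma` in \[0, 1\].
#' @export
subset_error <- function(train_x, train_y, val_x, val_y, mask, k = 5) {
  idx <- which(mask == 1L)
  if (length(idx) == 0L) {
    stop("mask selects no features; the fitness sentinel handles this case",
         call. = FALSE)
  }
  pred <- knn_predict(train_x[, idx, drop = FALSE], train_y,
                      val_x[, idx, drop = FALSE], k)
  mean(pred != val_y)
}

#' Wrapper fitness of a masked subset
#'
#' `Fit = lambda * gamma + (1 - lambda) * |mask| / dim`: a convex balance of
#' classification error against the fraction of features retained. Smaller
#' is better. An empty mask receives the sentinel fitness 1 (the maximum
#' attainable value) with `gamma = NA`.
#'
#' @param gamma Classification error in \[0, 1\] (ignored for empty masks).
#' @param mask 0/1 vector.
#' @param lambda Balance parameter in \[0, 1\]; default 0.99 favours error.
#' @param dim Total number of features; defaults to `length(mask)`.
#' @return List of class `fitness_record` with `fitness`, `gamma`, `ratio`,
#'   `lambda`.
#' @export
mask_fitness <- function(gamma, mask, lambda = 0.99, dim = length(mask)) {
  stopifnot(lambda >= 0, lambda <= 1)
  size <- sum(mask == 1L)
  if (size == 0L) {
    return(structure(list(fitness = 1, gamma = NA_real_, ratio = 0,
                          lambda = lambda), class = "fitness_record"))
  }
  stopifnot(gamma >= 0, gamma <= 1)
  structure(list(fitness = lambda * gamma + (1 - lambda) * size / dim,
                 gamma = gamma, ratio = size / dim, lambda = lambda),
            class = "fitness_record")
}

#' Build the memoized wrapper-fitness evaluator for a training set
#'
#' Splits the training partition once into a seeded, stratified internal
#' fit/validation pair (default 80/20) and returns a closure mapping a
#' binary mask to its [mask_fitness()] record. Because the split is fixed
#' for the lifetime of the evaluator, fitness is a deterministic function of
#' the mask, and records are cached by mask.
#'
#' @param train_x Training feature matrix.
#' @param train_y Training labels.
#' @param lambda Balance parameter of [mask_fitness()].
#' @param k KNN neighbours.
#' @param split_fraction Fraction of training rows in the internal fit part.
#' @param seed Seed of the internal split.
#' @return Function `mask -> fitness_record`.
#' @export
make_fitness_evaluator <- function(train_x, train_y, lambda = 0.99, k = 5,
                                   split_fraction = 0.8, seed = 1) {
  train_x <- as.matrix(train_x)
  train_y <- as.factor(train_y)
  if (nlevels(droplevels(train_y)) < 2L) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  parts <- stratified_indices(train_y, split_fraction, make_rng(seed))
  fx <- train_x[parts$first, , drop = FALSE]
  fy <- droplevels(train_y[parts$first])
  vx <- train_x[parts$second, , drop = FALSE]
  vy <- factor(train_y[parts$second], levels = levels(fy))
  if (k > nrow(fx)) {
    stop("`k` exceeds the internal fit partition size", call. = FALSE)
  }
  dim <- ncol(train_x)
  cache <- new.env(parent = emptyenv())
  function(mask) {
    mask <- as.integer(mask)
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    rec <- if (sum(mask) == 0L) {
      mask_fitness(NA, mask, lambda, dim)
    } else {
      mask_fitness(subset_error(fx, fy, vx, vy, mask, k), mask, lambda, dim)
    }
    cache[[key]] <- rec
    rec
  }
}
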