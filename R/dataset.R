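#' Construct a feature dataset
#'
#' The tabular container consumed by the optimizers: a numeric sample-by-
#' feature matrix with one categorical label per row, optionally tagged with
#' a train/test membership.
#'
#' @param features Numeric matrix (or data frame of numeric columns), rows
#'   are samples.
#' @param labels Per-row class labels (coerced to factor).
#' @param split Optional per-row `"train"`/`"test"` tags.
#' @param feature_names Optional column names; defaults to existing names or
#'   `f1..fD`.
#' @return An object of class `feature_dataset` with fields `features`,
#'   `labels`, `split`.
#' @export
feature_dataset <- function(features, labels, split = NULL,
                            feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (any(!is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite feature value at row %d, column %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  labels <- droplevels(as.factor(labels))
  if (length(labels) != nrow(features)) {
    stop("labels and feature rows differ in length", call. = FALSE)
  }
  if (!is.null(split)) {
    split <- factor(split, levels = c("train", "test"))
    if (anyNA(split) || length(split) != nrow(features)) {
      stop("`split` must tag every row as \"train\" or \"test\"",
           call. = FALSE)
    }
  }
  if (is.null(feature_names)) feature_names <- colnames(features)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(features)))
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels, split = split),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("feature_dataset: %d samples x %d features, %d classes (%s)\n",
              nrow(x$features), ncol(x$features), nlevels(x$labels),
              paste(levels(x$labels), collapse = ", ")))
  if (!is.null(x$split)) {
    cat(sprintf("  split: %d train / %d test\n",
                sum(x$split == "train"), sum(x$split == "test")))
  }
  inf <- attr(x, "informative")
  if (!is.null(inf)) {
    cat(sprintf("  planted informative features: %s\n",
                paste(inf, collapse = " ")))
  }
  invisible(x)
}

# rows of the training (resp. test) partition; datasets without a split tag
# are treated as all-training
dataset_train <- function(dataset) {
  if (is.null(dataset$split)) return(dataset)
  i <- dataset$split == "train"
  feature_dataset(dataset$features[i, , drop = FALSE],
                  droplevels(dataset$labels[i]))
}

dataset_test <- function(dataset) {
  if (is.null(dataset$split) || !any(dataset$split == "test")) return(NULL)
  i <- dataset$split == "test"
  feature_dataset(dataset$features[i, , drop = FALSE],
                  factor(dataset$labels[i], levels = levels(dataset$labels)))
}

# seeded stratified partition of a label vector into two index sets
stratified_indices <- function(labels, fraction, rng) {
  labels <- as.factor(labels)
  first <- integer()
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) {
      stop("class \"", cl, "\" has fewer than 2 samples", call. = FALSE)
    }
    m <- round(fraction * length(idx))
    m <- max(1L, min(length(idx) - 1L, m))
    ord <- idx[order(rng_uniform(rng, length(idx)))]
    first <- c(first, ord[seq_len(m)])
  }
  first <- sort(first)
  list(first = first, second = setdiff(seq_along(labels), first))
}

#' Stratified split of a dataset
#'
#' Seeded partition into two parts preserving class proportions within
#' rounding; the parts are disjoint and exhaustive. Supports both the
#' internal fitness-validation split and making held-out test sets.
#'
#' @param dataset A [feature_dataset()].
#' @param fraction Fraction of each class in the first part (default 0.8).
#' @param seed Integer seed.
#' @return List with elements `train` and `validation`, both
#'   `feature_dataset`s.
#' @export
stratified_split <- function(dataset, fraction = 0.8, seed = 1) {
  parts <- stratified_indices(dataset$labels, fraction, make_rng(seed))
  keep_attr <- attr(dataset, "informative")
  mk <- function(i) {
    d <- feature_dataset(dataset$features[i, , drop = FALSE],
                         droplevels(dataset$labels[i]))
    attr(d, "informative") <- keep_attr
    d
  }
  list(train = mk(parts$first), validation = mk(parts$second))
}

#' Generate a class-structured synthetic embedding dataset
#'
#' Emulates the output of a deep feature extractor: per-sample embedding
#' vectors in which a planted subset of columns carries class signal. Class
#' `k`'s informative columns are normal with mean `(k - 1) * effect_size`;
#' all remaining columns are shared noise, `N(0, noise_sd)`. Rows are
#' shuffled within each partition and the ground-truth informative column
#' indices are recorded in the `"informative"` attribute for use as a
#' recovery oracle.
#'
#' @param n_per_class Named integer vector of training samples per class
#'   (names become class labels).
#' @param dim Total number of features (default 64).
#' @param n_informative Number of class-separating columns (default 10).
#' @param effect_size Centroid separation between adjacent classes on
#'   informative columns (default 1.5).
#' @param noise_sd Standard deviation of every column (default 1).
#' @param n_test_per_class Optional test counts per class (same order); when
#'   supplied the dataset carries a train/test split tag.
#' @param seed Integer seed.
#' @return A [feature_dataset()]; informative indices in
#'   `attr(, "informative")`.
#' @export
make_embedding_dataset <- function(n_per_class, dim = 64, n_informative = 10,
                                   effect_size = 1.5, noise_sd = 1,
                                   n_test_per_class = NULL, seed = 1) {
  stopifnot(n_informative <= dim, n_informative >= 0, effect_size >= 0,
            noise_sd > 0, length(n_per_class) >= 2)
  if (is.null(names(n_per_class))) {
    names(n_per_class) <- paste0("class", seq_along(n_per_class))
  }
  rng <- make_rng(seed)
  informative <- sort(order(rng_uniform(rng, dim))[seq_len(n_informative)])
  gen_block <- function(counts) {
    xs <- list()
    ys <- character()
    for (k in seq_along(counts)) {
      nk <- counts[k]
      if (nk == 0L) next
      x <- matrix(rng_normal(rng, nk * dim) * noise_sd, nrow = nk,
                  byrow = TRUE)
      if (n_informative > 0) {
        x[, informative] <- x[, informative] + (k - 1) * effect_size
      }
      xs[[length(xs) + 1L]] <- x
      ys <- c(ys, rep(names(counts)[k], nk))
    }
    x <- do.call(rbind, xs)
    ord <- order(rng_uniform(rng, nrow(x)))
    list(x = x[ord, , drop = FALSE], y = ys[ord])
  }
  tr <- gen_block(n_per_class)
  if (!is.null(n_test_per_class)) {
    names(n_test_per_class) <- names(n_per_class)
    te <- gen_block(n_test_per_class)
    d <- feature_dataset(rbind(tr$x, te$x),
                         factor(c(tr$y, te$y), levels = names(n_per_class)),
                         split = rep(c("train", "test"),
                                     c(nrow(tr$x), nrow(te$x))))
  } else {
    d <- feature_dataset(tr$x, factor(tr$y, levels = names(n_per_class)))
  }
  attr(d, "informative") <- informative
  d
}

#' Synthetic two-class imbalanced embedding preset
#'
#' 128-dimensional embeddings for an imbalanced benign/malignant problem:
#' 727 benign and 173 malignant training samples, 304 and 75 test samples
#' (1031 benign of 1279 total, about 80% benign) — the class geometry of a
#' typical dermoscopy challenge split.
#'
#' @param seed Integer seed.
#' @param ... Passed to [make_embedding_dataset()] to override the synthetic
#'   geometry (`n_informative`, `effect_size`, `noise_sd`).
#' @return A [feature_dataset()] with a train/test split.
#' @export
make_isic_like <- function(seed = 1, ...) {
  defaults <- list(n_per_class = c(benign = 727, malignant = 173),
                   n_test_per_class = c(benign = 304, malignant = 75),
                   dim = 128, n_informative = 10, effect_size = 1,
                   noise_sd = 1, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(make_embedding_dataset, args)
}

#' Synthetic three-class embedding preset
#'
#' 128-dimensional embeddings for a three-class nevus/melanoma problem:
#' training counts 68/68/34 (common nevus, atypical nevus, melanoma) and
#' test counts 12/12/6, i.e. 200 samples with 40 melanomas overall.
#'
#' @inheritParams make_isic_like
#' @return A [feature_dataset()] with a train/test split.
#' @export
make_ph2_like <- function(seed = 1, ...) {
  defaults <- list(n_per_class = c(common_nevus = 68, atypical_nevus = 68,
                                   melanoma = 34),
                   n_test_per_class = c(common_nevus = 12, atypical_nevus = 12,
                                        melanoma = 6),
                   dim = 128, n_informative = 10, effect_size = 1,
                   noise_sd = 1, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(make_embedding_dataset, args)
}
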