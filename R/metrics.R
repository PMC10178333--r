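#' Confusion counts
#'
#' Cross-tabulates true against predicted labels and derives one-vs-rest
#' counts (tp, fp, fn, tn) per class. For a binary problem the row of the
#' positive class gives the usual TP/FP/FN/TN decomposition.
#'
#' @param y_true,y_pred Equal-length label vectors; levels are taken from
#'   their union.
#' @return List of class `confusion_counts` with the full `table` and a
#'   per-class data frame `by_class` (`class`, `support`, `tp`, `fp`, `fn`,
#'   `tn`).
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  lev <- union(levels(as.factor(y_true)), levels(as.factor(y_pred)))
  yt <- factor(y_true, levels = lev)
  yp <- factor(y_pred, levels = lev)
  tab <- table(truth = yt, predicted = yp)
  n <- length(yt)
  by_class <- do.call(rbind, lapply(lev, function(cl) {
    tp <- tab[cl, cl]
    fp <- sum(tab[, cl]) - tp
    fn <- sum(tab[cl, ]) - tp
    data.frame(class = cl, support = sum(tab[cl, ]),
               tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, by_class = by_class, n = n),
            class = "confusion_counts")
}

.safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning("zero denominator in ", what, "; returning 0", call. = FALSE)
    return(0)
  }
  num / den
}

#' Classification metrics
#'
#' Accuracy, precision, recall and F1 from a prediction. Multiclass (and, by
#' default, binary) scores are one-vs-rest values combined by
#' support-weighted averaging, under which recall equals accuracy exactly.
#' `average = "binary"` instead reports the positive class alone;
#' `average = "macro"` averages classes unweighted.
#'
#' @param y_true,y_pred Label vectors.
#' @param average `"weighted"` (default), `"macro"` or `"binary"`.
#' @param positive Positive class for `average = "binary"`; defaults to the
#'   second level.
#' @return List of class `metrics_report` with `accuracy`, `precision`,
#'   `recall`, `f1`, the per-class table and the confusion counts.
#' @export
classification_metrics <- function(y_true, y_pred,
                                   average = c("weighted", "macro", "binary"),
                                   positive = NULL) {
  average <- match.arg(average)
  cc <- confusion_counts(y_true, y_pred)
  bc <- cc$by_class
  prec <- mapply(function(tp, fp) .safe_ratio(tp, tp + fp, "precision"),
                 bc$tp, bc$fp)
  rec <- mapply(function(tp, fn) .safe_ratio(tp, tp + fn, "recall"),
                bc$tp, bc$fn)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  per_class <- data.frame(class = bc$class, support = bc$support,
                          precision = prec, recall = rec, f1 = f1,
                          stringsAsFactors = FALSE)
  acc <- sum(diag(cc$table)) / cc$n
  if (average == "binary") {
    if (is.null(positive)) positive <- bc$class[min(2L, nrow(bc))]
    if (!positive %in% bc$class) stop("unknown positive class", call. = FALSE)
    i <- match(positive, bc$class)
    w <- c(precision = prec[i], recall = rec[i], f1 = f1[i])
  } else {
    wts <- if (average == "weighted") bc$support / cc$n else
      rep(1 / nrow(bc), nrow(bc))
    w <- c(precision = sum(wts * prec), recall = sum(wts * rec),
           f1 = sum(wts * f1))
  }
  structure(list(accuracy = acc, precision = unname(w["precision"]),
                 recall = unname(w["recall"]), f1 = unname(w["f1"]),
                 average = average, per_class = per_class, confusion = cc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  F1 %.2f%% (%s)\n",
              100 * x$accuracy, 100 * x$precision, 100 * x$recall,
              100 * x$f1, x$average))
  invisible(x)
}

#' Performance improvement rate
#'
#' Percentage improvement of an accuracy `ac` over a comparator `ac_prime`.
#' Two conventions are provided: `"table"` computes
#' `100 * (ac - ac_prime) / ac` (the convention under which published
#' comparison tables for this method reproduce), and `"ratio"` computes the
#' textbook relative improvement `100 * (ac - ac_prime) / ac_prime`. The two
#' agree to first order for small improvements and always share a sign.
#'
#' Inputs may be on the percent or the fraction scale, as long as both share
#' it; the result is always in percent.
#'
#' @param ac Accuracy of the method of interest.
#' @param ac_prime Accuracy of the comparator.
#' @param convention `"table"` (default) or `"ratio"`.
#' @return Improvement rate in percent.
#' @export
pir <- function(ac, ac_prime, convention = c("table", "ratio")) {
  convention <- match.arg(convention)
  if (any(ac <= 0) || any(ac_prime <= 0)) {
    stop("accuracies must be positive", call. = FALSE)
  }
  den <- if (convention == "table") ac else ac_prime
  100 * (ac - ac_prime) / den
}

#' Friedman mean ranks
#'
#' Nonparametric comparison of methods across cases: within each case (a
#' column) methods are ranked ascending by score — the best (highest) score
#' receives the highest rank, ties share the average rank — and each
#' method's ranks are averaged across cases.
#'
#' @param scores Numeric matrix, methods in rows (named), cases in columns.
#' @return Named numeric vector of mean ranks.
#' @export
friedman_mean_rank <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2L) stop("need at least two methods", call. = FALSE)
  ranks <- apply(scores, 2L, rank)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, ncol = 1L)
  out <- rowMeans(ranks)
  names(out) <- rownames(scores)
  out
}
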