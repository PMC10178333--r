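# small in-code fixtures shared across test files

# tiny two-class dataset: 2 informative of `dim` features
tiny_dataset <- function(n_per_class = 30, dim = 6, effect = 2, seed = 42,
                         n_informative = 2) {
  make_embedding_dataset(c(a = n_per_class, b = n_per_class), dim = dim,
                         n_informative = n_informative, effect_size = effect,
                         seed = seed)
}

# a hand-built population_state for operator-level tests
manual_population <- function(pos, fit, hunger = rep(0, nrow(pos)),
                              best_fit = min(fit),
                              best_pos = pos[which.min(fit), ]) {
  structure(list(
    pos = pos,
    vel = matrix(0, nrow(pos), ncol(pos)),
    hunger = hunger,
    fit = fit,
    pbest_pos = pos,
    pbest_fit = fit,
    best_pos = best_pos,
    best_fit = best_fit,
    worst_fit = max(fit),
    hunger_sum = sum(hunger)
  ), class = "population_state")
}

# independent naive KNN: double loop, majority vote, nearest-label ties —
# written as directly as possible, used only as an oracle
naive_knn <- function(train_x, train_y, test_x, k) {
  train_y <- as.factor(train_y)
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- numeric(nrow(train_x))
    for (j in seq_len(nrow(train_x))) {
      d[j] <- sqrt(sum((train_x[j, ] - test_x[i, ])^2))
    }
    nn <- as.character(train_y[order(d)[1:k]])
    tab <- table(nn)
    best <- names(tab)[tab == max(tab)]
    out[i] <- if (length(best) == 1L) best else nn[nn %in% best][1L]
  }
  factor(out, levels = levels(train_y))
}
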