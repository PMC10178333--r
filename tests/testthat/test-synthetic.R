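test_that("embedding generation is reproducible and class-structured", {
  d1 <- make_embedding_dataset(c(a = 20, b = 20), dim = 16,
                               n_informative = 4, effect_size = 3, seed = 5)
  d2 <- make_embedding_dataset(c(a = 20, b = 20), dim = 16,
                               n_informative = 4, effect_size = 3, seed = 5)
  expect_identical(d1$features, d2$features)
  expect_identical(d1$labels, d2$labels)
  inf <- attr(d1, "informative")
  expect_length(inf, 4)
  # per-column two-sample t statistics single out exactly the planted set
  tstat <- apply(d1$features, 2, function(col) {
    abs(t.test(col[d1$labels == "a"], col[d1$labels == "b"])$statistic)
  })
  expect_setequal(order(tstat, decreasing = TRUE)[1:4], inf)
  expect_true(all(tstat[inf] > 5))
  expect_true(all(tstat[-inf] < 5))
})

test_that("zero effect size yields chance-level structure", {
  d <- make_embedding_dataset(c(a = 150, b = 150), dim = 8,
                              n_informative = 3, effect_size = 0, seed = 9)
  g <- subset_error(d$features[1:200, ], d$labels[1:200],
                    d$features[201:300, ], d$labels[201:300], rep(1, 8), 5)
  expect_gt(g, 0.3)  # near the 50% chance level for balanced classes
  # while a large effect on one feature is essentially separable
  d2 <- make_embedding_dataset(c(a = 150, b = 150), dim = 8,
                               n_informative = 1, effect_size = 5, seed = 9)
  m <- integer(8); m[attr(d2, "informative")] <- 1L
  g2 <- subset_error(d2$features[1:200, ], d2$labels[1:200],
                     d2$features[201:300, ], d2$labels[201:300], m, 5)
  expect_lt(g2, 0.05)
})

test_that("the two-class imbalanced preset reproduces its split geometry", {
  d <- make_isic_like(seed = 3)
  expect_equal(sum(d$split == "train"), 900)
  expect_equal(sum(d$split == "test"), 379)
  expect_equal(ncol(d$features), 128)
  expect_equal(sum(d$labels == "benign"), 1031)
  expect_equal(nrow(d$features), 1279)
  expect_equal(as.vector(table(d$labels[d$split == "train"])), c(727, 173))
  expect_equal(as.vector(table(d$labels[d$split == "test"])), c(304, 75))
})

test_that("the three-class preset reproduces its split geometry", {
  d <- make_ph2_like(seed = 3)
  expect_equal(sum(d$split == "train"), 170)
  expect_equal(sum(d$split == "test"), 30)
  expect_equal(sum(d$labels == "melanoma"), 40)
  expect_equal(nrow(d$features), 200)
  expect_equal(ncol(d$features), 128)
  expect_equal(as.vector(table(d$labels[d$split == "train"])),
               c(68, 68, 34))
  expect_equal(as.vector(table(d$labels[d$split == "test"])), c(12, 12, 6))
})

test_that("stratified splits preserve proportions, partition the rows", {
  d <- make_embedding_dataset(c(a = 50, b = 50), dim = 4,
                              n_informative = 1, seed = 2)
  parts <- stratified_split(d, 0.8, seed = 4)
  expect_equal(as.vector(table(parts$train$labels)), c(40, 40))
  expect_equal(as.vector(table(parts$validation$labels)), c(10, 10))
  expect_equal(nrow(parts$train$features) + nrow(parts$validation$features),
               100)
  # disjoint and exhaustive: every original row appears exactly once
  allrows <- rbind(parts$train$features, parts$validation$features)
  expect_equal(dim(allrows), dim(d$features))
  key <- function(m) sort(apply(m, 1, function(r) paste(r, collapse = ",")))
  expect_equal(key(allrows), key(d$features))
  # reproducible
  parts2 <- stratified_split(d, 0.8, seed = 4)
  expect_identical(parts$train$features, parts2$train$features)
  # single-sample classes are rejected
  bad <- feature_dataset(matrix(rnorm(6), 3, 2), c("a", "a", "b"))
  expect_error(stratified_split(bad, 0.5, 1), "fewer than 2")
})
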