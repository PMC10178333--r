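test_that("opposite points mirror across the box centre", {
  s <- search_space(1)
  expect_equal(opposite_point(0.3, s), 0.7)
  # involution and fixed point at the centre, over random boxes
  rng <- make_rng(6)
  for (i in 1:20) {
    lo <- rng_uniform(rng, 3)
    hi <- lo + rng_uniform(rng, 3)
    sp <- search_space(3, lo, hi)
    x <- lo + (hi - lo) * rng_uniform(rng, 3)
    xo <- opposite_point(x, sp)
    expect_true(all(xo >= lo - 1e-12 & xo <= hi + 1e-12))
    expect_equal(opposite_point(xo, sp), x)
  }
  mid <- search_space(2, c(0, 1), c(2, 3))
  expect_equal(opposite_point(c(1, 2), mid), c(1, 2))
})

test_that("dynamic-opposite points follow the weighted jump formula", {
  s <- search_space(1)
  p <- dol_params(dol_weight = 1)
  # r8 = r9 = 1 collapses onto the opposite point
  expect_equal(dynamic_opposite_point(0.3, s, p,
                                      make_fixed_rng(uniform = c(1, 1))),
               0.7)
  # r8 = 0 is a null jump
  expect_equal(dynamic_opposite_point(0.3, s, p,
                                      make_fixed_rng(uniform = c(0, 0.4))),
               0.3)
  # r8 = 1, r9 = 0: x + (0 - x) = 0
  expect_equal(dynamic_opposite_point(0.4, s, p,
                                      make_fixed_rng(uniform = c(1, 0))),
               0)
  # zero-width box: the opposite equals x, candidates differ only through
  # the r9 contraction: x' = x + w * r8 * (r9 * x - x)
  zw <- search_space(1, 0.4, 0.4)
  got <- dynamic_opposite_point(0.4, zw, p,
                                make_fixed_rng(uniform = c(1, 0.5)))
  expect_equal(got, 0.4 + 1 * 1 * (0.5 * 0.4 - 0.4))
  # results are clamped to the static box even for large weights
  pw <- dol_params(dol_weight = 8)
  rng <- make_rng(2)
  for (i in 1:20) {
    x <- rng_uniform(rng, 4)
    y <- dynamic_opposite_point(x, search_space(4), pw, rng)
    expect_true(all(y >= 0 & y <= 1))
  }
})

test_that("elite selection keeps the N best of the union, incumbents on ties", {
  pop <- manual_population(rbind(0.1, 0.9), fit = c(0.3, 0.5))
  sel <- dol_select(pop, rbind(0.2, 0.7), c(0.2, 0.9), c(1L, 2L))
  expect_equal(sort(sel$fit), c(0.2, 0.3))
  expect_equal(sel$best_fit, 0.2)
  # all candidates worse: population unchanged
  sel2 <- dol_select(pop, rbind(0.2, 0.7), c(0.8, 0.9), c(1L, 2L))
  expect_equal(sort(sel2$fit), c(0.3, 0.5))
  # a candidate tying an incumbent loses to it
  sel3 <- dol_select(pop, rbind(0.25), 0.5, 1L)
  expect_equal(sel3$pos[2, ], 0.9)
  # selection can only improve the best fitness
  rng <- make_rng(8)
  for (i in 1:10) {
    p <- manual_population(matrix(rng_uniform(rng, 6), 3, 2),
                           fit = rng_uniform(rng, 3))
    before <- p$best_fit
    cand <- matrix(rng_uniform(rng, 4), 2, 2)
    after <- dol_select(p, cand, rng_uniform(rng, 2), c(1L, 3L))$best_fit
    expect_lte(after, before)
  }
})

test_that("the jumping step gates on its threshold and never loses the best", {
  sphere <- function(x) sum((x - 0.25)^2)
  rng <- make_rng(3)
  pop <- init_population(search_space(4), 6, rng)
  pop$fit <- apply(pop$pos, 1, sphere)
  pop <- dolhgs:::refresh_best(pop)
  # threshold 0: no candidates, population unchanged
  off <- dol_jump(pop, dol_params(jump_threshold = 0), rng, sphere)
  expect_equal(off$pos, pop$pos)
  # threshold 1: every agent forms a candidate; best cannot worsen
  evals <- 0
  counting <- function(x) { evals <<- evals + 1; sphere(x) }
  on <- dol_jump(pop, dol_params(jump_threshold = 1), rng, counting)
  expect_equal(evals, 6)
  expect_lte(on$best_fit, pop$best_fit)
})

test_that("dynamic-opposite enhancement of an initial population never hurts", {
  sphere <- function(x) sum((x - 0.8)^2)
  for (seed in 1:5) {
    rng <- make_rng(seed)
    pop <- init_population(search_space(5), 8, rng)
    pop$fit <- apply(pop$pos, 1, sphere)
    pop <- dolhgs:::refresh_best(pop)
    raw_best <- pop$best_fit
    p <- dol_params()
    cand <- t(apply(pop$pos, 1, function(x)
      dynamic_opposite_point(x, search_space(5), p, rng)))
    sel <- dol_select(pop, cand, apply(cand, 1, sphere), 1:8)
    expect_lte(sel$best_fit, raw_best)
  }
})
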