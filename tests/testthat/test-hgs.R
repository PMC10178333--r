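test_that("shrink factor decays linearly and bounds the escape value", {
  expect_equal(shrink_factor(10, 10, make_rng(1)), list(s = 0, R = 0))
  init <- shrink_factor(0, 10, make_rng(1))
  expect_equal(init$s, 2)
  expect_true(abs(init$R) <= 2)
  mid <- shrink_factor(5, 10, make_fixed_rng(uniform = 0.5))
  expect_equal(mid$s, 1)
  expect_equal(mid$R, 0)  # 2 * 0.5 * 1 - 1
  rng <- make_rng(2)
  for (t in 0:10) {
    sf <- shrink_factor(t, 10, rng)
    expect_true(abs(sf$R) <= sf$s + 1e-12)
  }
  expect_error(shrink_factor(0, 0, make_rng(1)), ">= 1")
})

test_that("variation control is sech of the fitness gap", {
  expect_equal(variation_control(0.3, 0.3), 1)
  expect_equal(variation_control(1.3, 0.3), 2 / (exp(1) + exp(-1)))
  expect_equal(variation_control(1.3, 0.3), 0.6480543, tolerance = 1e-6)
  # even in its arguments, bounded in (0, 1], vanishing for large gaps
  rng <- make_rng(4)
  for (i in 1:20) {
    g <- rng_normal(rng, 2)
    e <- variation_control(g[1], g[2])
    expect_equal(e, variation_control(g[2], g[1]))
    expect_true(e > 0 && e <= 1)
  }
  expect_lt(variation_control(50, 0), 1e-20)
  expect_error(variation_control(Inf, 0), "finite")
})

test_that("hunger accrues by the floored temporary hunger and resets at the best", {
  space <- search_space(1)
  params <- hgs_params()
  # best agent resets to zero even with prior hunger
  pop <- manual_population(rbind(0.1, 0.9), fit = c(0.3, 0.5),
                           hunger = c(5, 7))
  pop$best_fit <- 0.3
  up <- update_hunger(pop, space, params, make_rng(1))
  expect_equal(up$hunger[1], 0)
  # worst agent with r6 = 1: TH = 2 < LH = 100, so Hn = 100 * (1 + r)
  up2 <- update_hunger(pop, space, params, make_fixed_rng(uniform = c(1, 1)))
  expect_equal(up2$hunger[2], 7 + 200)
  expect_equal(up2$hunger_sum, sum(up2$hunger))
  # a population sharing one fitness all ties for best: all hungers zero
  flat <- manual_population(rbind(0.1, 0.5, 0.9), fit = rep(0.4, 3),
                            hunger = c(1, 2, 3))
  flat$best_fit <- 0.4
  expect_equal(update_hunger(flat, space, params, make_rng(1))$hunger,
               rep(0, 3))
  # non-negativity under random draws
  rng <- make_rng(9)
  p <- manual_population(matrix(rng_uniform(rng, 8), 4, 2),
                         fit = c(0.2, 0.4, 0.4, 0.9), hunger = rep(0, 4))
  p$best_fit <- 0.2
  for (i in 1:5) {
    p <- update_hunger(p, search_space(2), params, rng)
    expect_true(all(p$hunger >= 0))
    expect_equal(p$hunger[1], 0)
  }
})

test_that("hunger weights follow their two-branch definitions", {
  params <- hgs_params()
  pop <- manual_population(rbind(0.1, 0.9), fit = c(0.2, 0.5),
                           hunger = c(5, 5))
  pop$hunger_sum <- 10
  # r3 above the threshold: W1 = 1
  w <- hunger_weights(1, pop, 2, params, make_fixed_rng(uniform = c(0.9, 0.3)))
  expect_equal(w[1], 1)
  # r3 below: W1 = H * N / SH * r4 = 5 * 2 / 10 * 0.5
  w2 <- hunger_weights(1, pop, 2, params,
                       make_fixed_rng(uniform = c(0.01, 0.5, 0.3)))
  expect_equal(w2[1], 0.5, tolerance = 1e-8)
  expect_equal(w2[2], 2 * (1 - exp(-5)) * 0.3)
  # H_i equal to SH makes W2 vanish
  solo <- manual_population(rbind(0.1, 0.9), fit = c(0.2, 0.5),
                            hunger = c(10, 0))
  solo$hunger_sum <- 10
  w3 <- hunger_weights(1, solo, 2, params,
                       make_fixed_rng(uniform = c(0.9, 0.7)))
  expect_equal(w3[2], 0)
})

test_that("the position update dispatches between its three branches", {
  space <- search_space(1)
  params <- hgs_params()
  pop <- manual_population(rbind(0.3, 0.8), fit = c(0.5, 0.2))
  pop$best_pos <- 0.5
  st <- list(weight1 = 1, weight2 = 1, escape_R = 1, variation_E = 0.5)
  # branch 1 with a zero perturbation returns x unchanged
  x1 <- hgs_move(0.3, pop, st, params,
                 make_fixed_rng(uniform = 0.01, normal = 0), space)
  expect_equal(x1, 0.3)
  # branch 2 with R = 0, W1 = 1 collapses onto the best position
  st2 <- list(weight1 = 1, weight2 = 1, escape_R = 0, variation_E = 0.5)
  x2 <- hgs_move(0.3, pop, st2, params,
                 make_fixed_rng(uniform = c(0.5, 0.1)), space)
  expect_equal(x2, 0.5)
  # branch 3: x' = W1 * Xb + R * W2 * |Xb - x| = 0.5 + 0.2 = 0.7
  x3 <- hgs_move(0.3, pop, st, params,
                 make_fixed_rng(uniform = c(0.5, 0.9)), space)
  expect_equal(x3, 0.7)
  # moves are always clamped to the unit box
  stBig <- list(weight1 = 3, weight2 = 2, escape_R = 1.5, variation_E = 0.5)
  xb <- hgs_move(0.3, pop, stBig, params,
                 make_fixed_rng(uniform = c(0.5, 0.9)), space)
  expect_true(xb >= 0 && xb <= 1)
})

test_that("at the final iteration attraction moves land exactly on W1 * best", {
  # s = 0 forces R = 0, so branches 2-3 lose their escape term
  space <- search_space(2)
  params <- hgs_params()
  pop <- manual_population(rbind(c(0.3, 0.6), c(0.8, 0.1)), fit = c(0.2, 0.5))
  sf <- shrink_factor(100, 100, make_rng(1))
  st <- list(weight1 = 1, weight2 = 1.3, escape_R = sf$R, variation_E = 0.5)
  x <- hgs_move(c(0.8, 0.1), pop, st, params,
                make_fixed_rng(uniform = c(0.5, 0.1)), space)
  expect_equal(x, pop$best_pos)
})
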