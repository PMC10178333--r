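#' Hunger Games Search parameters
#'
#' @param l_threshold Branch threshold `l` of the position update: with
#'   probability `l` an agent makes a self-scaled random move instead of a
#'   hunger-weighted move around the best solution. The original algorithm's
#'   value 0.08 is the default.
#' @param hunger_floor Lower bound `LH` on the hunger increment: a temporary
#'   hunger below this floor is replaced by `LH * (1 + r)`. Default 100, as
#'   in the original algorithm.
#' @param epsilon Small guard added to the `SH` and `Fit_w - Fit_b`
#'   denominators. Default `1e-9`.
#' @param perturbation Distribution of the first-branch perturbation in
#'   `x * (1 + z)`: `"normal"` (standard normal, the original convention,
#'   default) or `"uniform"` (on \[0, 1\]).
#' @param abs_diff Use `|X_b - x|` in the attraction/repulsion branches
#'   (original convention, default `TRUE`); `FALSE` keeps the signed
#'   difference.
#' @return An object of class `hgs_params`.
#' @export
hgs_params <- function(l_threshold = 0.08, hunger_floor = 100,
                       epsilon = 1e-9,
                       perturbation = c("normal", "uniform"),
                       abs_diff = TRUE) {
  perturbation <- match.arg(perturbation)
  stopifnot(l_threshold > 0, l_threshold < 1,
            hunger_floor > 0, epsilon > 0)
  structure(list(l_threshold = l_threshold, hunger_floor = hunger_floor,
                 epsilon = epsilon, perturbation = perturbation,
                 abs_diff = abs_diff),
            class = "hgs_params")
}

#' Shrink factor and escape range
#'
#' `s = 2 * (1 - t / T)` decreases linearly from 2 to 0 over the run; the
#' escape value `R` is uniform on `[-s, s]` (`R = 2 * rand * s - s`). As `s`
#' shrinks, attraction/repulsion moves contract toward the best solution.
#'
#' @param t Current iteration (0 to `T`).
#' @param T Total iterations (>= 1).
#' @param rng Random stream.
#' @return List with elements `s` and `R`.
#' @export
shrink_factor <- function(t, T, rng) {
  if (length(T) != 1L || is.na(T) || T < 1) {
    stop("total iterations `T` must be >= 1", call. = FALSE)
  }
  if (t < 0 || t > T) stop("iteration `t` must lie in [0, T]", call. = FALSE)
  s <- 2 * (1 - t / T)
  R <- 2 * rng_uniform(rng) * s - s
  list(s = s, R = R)
}

#' Variation control
#'
#' `E = sech(|Fit_i - Fit_b|)`, in (0, 1]: near 1 when an agent's fitness is
#' close to the best, decaying to 0 as the gap grows. Gates the choice
#' between the attraction and repulsion branches of the position update.
#'
#' @param fit_i Agent fitness.
#' @param fit_b Best fitness.
#' @return Scalar in (0, 1].
#' @export
variation_control <- function(fit_i, fit_b) {
  if (!is.finite(fit_i) || !is.finite(fit_b)) {
    stop("fitness values must be finite", call. = FALSE)
  }
  1 / cosh(fit_i - fit_b)
}

#' Update hunger levels
#'
#' Agents matching the best-ever fitness have their hunger reset to 0.
#' Every other agent accrues
#' `TH = 2 * (Fit_i - Fit_b) / (Fit_w - Fit_b + eps) * r6 * (UB - LB)`,
#' floored at `LH`: when `TH < LH` the increment is `LH * (1 + r)` with a
#' fresh uniform `r`. The hunger sum `SH` is recomputed afterwards.
#'
#' Draw order: agents are visited in index order; a non-best agent draws
#' `r6` first and, only if the floor applies, `r`.
#'
#' @param pop A `population_state` with evaluated fitness.
#' @param space The static [search_space()] (its scalar width enters `TH`).
#' @param params An [hgs_params()].
#' @param rng Random stream.
#' @return The population with updated `hunger` and `hunger_sum`.
#' @export
update_hunger <- function(pop, space, params, rng) {
  width <- mean(space$upper - space$lower)
  fb <- pop$best_fit
  fw <- pop$worst_fit
  n <- nrow(pop$pos)
  for (i in seq_len(n)) {
    if (pop$fit[i] == fb) {
      pop$hunger[i] <- 0
    } else {
      r6 <- rng_uniform(rng)
      th <- 2 * (pop$fit[i] - fb) / (fw - fb + params$epsilon) * r6 * width
      hn <- if (th < params$hunger_floor) {
        params$hunger_floor * (1 + rng_uniform(rng))
      } else {
        th
      }
      pop$hunger[i] <- pop$hunger[i] + hn
    }
  }
  pop$hunger_sum <- sum(pop$hunger)
  pop
}

#' Hunger weights of one agent
#'
#' `W1 = H_i * N / (SH + eps) * r4` with probability `l` (else 1), and
#' `W2 = 2 * (1 - exp(-|H_i - SH|)) * r5`. The weights modulate attraction
#' toward the best solution in [hgs_move()].
#'
#' @param i Agent index.
#' @param pop A `population_state` with current `hunger` and `hunger_sum`.
#' @param n Population size `N`.
#' @param params An [hgs_params()].
#' @param rng Random stream (draws `r3`, then `r4` only when `r3 < l`, then `r5`).
#' @return Numeric vector `c(W1, W2)`.
#' @export
hunger_weights <- function(i, pop, n, params, rng) {
  r3 <- rng_uniform(rng)
  w1 <- if (r3 < params$l_threshold) {
    pop$hunger[i] * n / (pop$hunger_sum + params$epsilon) * rng_uniform(rng)
  } else {
    1
  }
  w2 <- 2 * (1 - exp(-abs(pop$hunger[i] - pop$hunger_sum))) * rng_uniform(rng)
  c(w1, w2)
}

#' Hunger Games Search position update
#'
#' Three branches: with probability `l` the agent rescales itself,
#' `x' = x * (1 + z)`; otherwise it moves around the best solution,
#' attracted (`W1 * X_b - R * W2 * |X_b - x|`) when a fresh uniform `r2`
#' falls below the variation control `E`, repelled
#' (`W1 * X_b + R * W2 * |X_b - x|`) otherwise. The result is clamped to the
#' static space.
#'
#' @param x Current position.
#' @param pop A `population_state` supplying the best position.
#' @param state List with the per-agent iteration quantities `weight1`,
#'   `weight2`, `escape_R`, `variation_E`.
#' @param params An [hgs_params()].
#' @param rng Random stream (draws `r1`, then either the perturbation or `r2`).
#' @param space Static [search_space()] used for clamping.
#' @return The updated, clamped position.
#' @export
hgs_move <- function(x, pop, state, params, rng, space) {
  r1 <- rng_uniform(rng)
  if (r1 < params$l_threshold) {
    z <- if (params$perturbation == "normal") rng_normal(rng) else rng_uniform(rng)
    xn <- x * (1 + z)
  } else {
    r2 <- rng_uniform(rng)
    d <- pop$best_pos - x
    if (params$abs_diff) d <- abs(d)
    xn <- if (r2 < state$variation_E) {
      state$weight1 * pop$best_pos - state$escape_R * state$weight2 * d
    } else {
      state$weight1 * pop$best_pos + state$escape_R * state$weight2 * d
    }
  }
  clamp_position(xn, space)
}
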