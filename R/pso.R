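#' Particle Swarm Optimization parameters
#'
#' @param c1,c2 Cognitive and social acceleration coefficients; the
#'   canonical 2.0 is the default for both.
#' @param w_max,w_min Inertia weight at the start and end of the run; the
#'   inertia decays linearly between them (defaults 0.9 and 0.2).
#' @param v_max Velocity clamp magnitude (default 6).
#' @return An object of class `pso_params`.
#' @export
pso_params <- function(c1 = 2, c2 = 2, w_max = 0.9, w_min = 0.2, v_max = 6) {
  stopifnot(c1 >= 0, c2 >= 0, w_min <= w_max, v_max > 0)
  structure(list(c1 = c1, c2 = c2, w_max = w_max, w_min = w_min,
                 v_max = v_max),
            class = "pso_params")
}

#' Inertia weight at an iteration
#'
#' Linear decay `w = w_max - (w_max - w_min) * t / T`.
#'
#' @param t Current iteration (0 to `T`).
#' @param T Total iterations.
#' @param params A [pso_params()].
#' @return Scalar inertia weight.
#' @export
inertia_at <- function(t, T, params) {
  if (t < 0 || t > T) stop("iteration `t` must lie in [0, T]", call. = FALSE)
  params$w_max - (params$w_max - params$w_min) * t / T
}

#' Particle velocity update
#'
#' Per dimension `j`:
#' `v' = w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`, with `r1`, `r2`
#' drawn fresh per dimension (interleaved: `r1[1], r2[1], r1[2], ...`),
#' then clamped to `[-v_max, v_max]`.
#'
#' @param x Current position.
#' @param v Current velocity.
#' @param pbest Personal-best position.
#' @param gbest Global-best position.
#' @param w Inertia weight for this iteration (see [inertia_at()]).
#' @param params A [pso_params()].
#' @param rng Random stream.
#' @return The clamped new velocity.
#' @export
pso_velocity <- function(x, v, pbest, gbest, w, params, rng) {
  d <- length(x)
  u <- rng_uniform(rng, 2L * d)
  r1 <- u[seq(1L, 2L * d, by = 2L)]
  r2 <- u[seq(2L, 2L * d, by = 2L)]
  vn <- w * v + params$c1 * r1 * (pbest - x) + params$c2 * r2 * (gbest - x)
  pmin(params$v_max, pmax(-params$v_max, vn))
}

#' Particle position update
#'
#' `x' = x + v'`, clamped to the static space.
#'
#' @param x Current position.
#' @param v_new Updated velocity.
#' @param space Static [search_space()].
#' @return The updated, clamped position.
#' @export
pso_move <- function(x, v_new, space) {
  clamp_position(x + v_new, space)
}

#' Update an agent's personal best
#'
#' Replaces the stored personal best only on strict improvement; ties keep
#' the incumbent.
#'
#' @param pop A `population_state`.
#' @param i Agent index whose fitness was just refreshed.
#' @return The population, with agent `i`'s personal best possibly replaced.
#' @export
update_personal_best <- function(pop, i) {
  if (pop$fit[i] < pop$pbest_fit[i]) {
    pop$pbest_fit[i] <- pop$fit[i]
    pop$pbest_pos[i, ] <- pop$pos[i, ]
  }
  pop
}
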