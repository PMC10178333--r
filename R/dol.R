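#' Dynamic-opposite learning parameters
#'
#' @param dol_weight Positive weighting factor `w` of the dynamic-opposite
#'   point (distinct from the PSO inertia weight). Default 8, the value
#'   commonly used in the dynamic-opposite-learning literature.
#' @param jump_threshold Probability cut for the per-iteration jumping step:
#'   an agent jumps when its fresh uniform `PrDO` is strictly below this
#'   value. Default 0.5; a draw of exactly the threshold does not jump.
#' @param apply_at_init Apply dynamic opposition to the whole initial
#'   population (unconditionally, no probability gate). Default `TRUE`.
#' @return An object of class `dol_params`.
#' @export
dol_params <- function(dol_weight = 8, jump_threshold = 0.5,
                       apply_at_init = TRUE) {
  stopifnot(dol_weight > 0, jump_threshold >= 0, jump_threshold <= 1)
  structure(list(dol_weight = dol_weight, jump_threshold = jump_threshold,
                 apply_at_init = apply_at_init),
            class = "dol_params")
}

#' Opposite point
#'
#' Mirror image across the box centre: `x_o[j] = upper[j] + lower[j] - x[j]`.
#' An involution that maps the box onto itself.
#'
#' @param x Position vector.
#' @param space A [search_space()] (static or dynamically contracted).
#' @return The opposite position.
#' @export
opposite_point <- function(x, space) {
  space$upper + space$lower - x
}

#' Dynamic-opposite point
#'
#' Randomized, weighted generalization of the opposite point: per dimension,
#' with fresh uniforms `r8`, `r9` (interleaved draws),
#' `x_do[j] = x[j] + w * r8 * (r9 * x_o[j] - x[j])`,
#' where `x_o` is the opposite point in `space`. Because the jump can leave
#' the box, the result is clamped to the static space.
#'
#' @param x Position vector.
#' @param space Box against which the opposite point is formed; may be the
#'   contracted box from [dynamic_bounds()].
#' @param params A [dol_params()].
#' @param rng Random stream.
#' @param static Static [search_space()] used for clamping; defaults to the
#'   unit box of matching dimension.
#' @return The clamped dynamic-opposite position.
#' @export
dynamic_opposite_point <- function(x, space, params, rng,
                                   static = search_space(length(x))) {
  d <- length(x)
  xo <- opposite_point(x, space)
  u <- rng_uniform(rng, 2L * d)
  r8 <- u[seq(1L, 2L * d, by = 2L)]
  r9 <- u[seq(2L, 2L * d, by = 2L)]
  clamp_position(x + params$dol_weight * r8 * (r9 * xo - x), static)
}

#' Greedy elite selection over a population and its candidates
#'
#' Keeps the `N` lowest-fitness agents from the union of the current
#' population and a set of evaluated candidates. Ties favour incumbents. A
#' surviving candidate inherits the hunger, velocity and personal-best
#' memory of its source agent (its personal best is then updated against the
#' candidate fitness). Best/worst/hunger-sum bookkeeping is refreshed.
#'
#' @param pop A `population_state`.
#' @param cand_pos Matrix of candidate positions (rows are candidates).
#' @param cand_fit Numeric vector of candidate fitness values.
#' @param cand_src Integer vector: source agent index of each candidate.
#' @return The selected `population_state`.
#' @export
dol_select <- function(pop, cand_pos, cand_fit, cand_src) {
  n <- nrow(pop$pos)
  m <- if (is.null(cand_pos)) 0L else nrow(cand_pos)
  if (m == 0L) return(refresh_best(pop))
  all_fit <- c(pop$fit, cand_fit)
  # stable sort with incumbents listed first => ties keep the incumbent
  keep <- order(all_fit)[seq_len(n)]
  new <- pop
  for (slot in seq_len(n)) {
    idx <- keep[slot]
    if (idx <= n) {
      new$pos[slot, ] <- pop$pos[idx, ]
      new$vel[slot, ] <- pop$vel[idx, ]
      new$hunger[slot] <- pop$hunger[idx]
      new$fit[slot] <- pop$fit[idx]
      new$pbest_pos[slot, ] <- pop$pbest_pos[idx, ]
      new$pbest_fit[slot] <- pop$pbest_fit[idx]
    } else {
      j <- idx - n
      src <- cand_src[j]
      new$pos[slot, ] <- cand_pos[j, ]
      new$vel[slot, ] <- pop$vel[src, ]
      new$hunger[slot] <- pop$hunger[src]
      new$fit[slot] <- cand_fit[j]
      if (cand_fit[j] < pop$pbest_fit[src]) {
        new$pbest_pos[slot, ] <- cand_pos[j, ]
        new$pbest_fit[slot] <- cand_fit[j]
      } else {
        new$pbest_pos[slot, ] <- pop$pbest_pos[src, ]
        new$pbest_fit[slot] <- pop$pbest_fit[src]
      }
    }
  }
  refresh_best(new)
}

#' Dynamic-opposite jumping step
#'
#' Recomputes the contracted box spanned by the current population, then for
#' each agent draws `PrDO`; agents with `PrDO < jump_threshold` form a
#' dynamic-opposite candidate against that box. Candidates are evaluated and
#' the best `N` of the union survive via [dol_select()].
#'
#' @param pop A freshly moved and evaluated `population_state`.
#' @param params A [dol_params()].
#' @param rng Random stream (per agent: `PrDO`, then `2 * dim` uniforms for
#'   jumpers).
#' @param evaluate Function `position -> fitness`.
#' @param static Static [search_space()] for clamping candidates.
#' @return The selected `population_state`.
#' @export
dol_jump <- function(pop, params, rng, evaluate,
                     static = search_space(ncol(pop$pos))) {
  box <- dynamic_bounds(pop)
  n <- nrow(pop$pos)
  cand_pos <- NULL
  cand_fit <- numeric()
  cand_src <- integer()
  for (i in seq_len(n)) {
    pr <- rng_uniform(rng)
    if (pr < params$jump_threshold) {
      x <- dynamic_opposite_point(pop$pos[i, ], box, params, rng, static)
      cand_pos <- rbind(cand_pos, x)
      cand_fit <- c(cand_fit, evaluate(x))
      cand_src <- c(cand_src, i)
    }
  }
  dol_select(pop, cand_pos, cand_fit, cand_src)
}
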