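#' Define a box-constrained search space
#'
#' For feature selection the static space is the unit box: one dimension per
#' feature, bounded by 0 and 1. A contracted box spanned by the current
#' population (see [dynamic_bounds()]) is used only to construct opposite
#' points; positions are always clamped to the static box.
#'
#' @param dim Number of decision variables (= number of features).
#' @param lower,upper Per-dimension bounds; scalars are recycled.
#' @return An object of class `search_space` with fields `dim`, `lower`, `upper`.
#' @export
search_space <- function(dim, lower = 0, upper = 1) {
  dim <- as.integer(dim)
  if (length(dim) != 1L || is.na(dim) || dim < 1L) {
    stop("`dim` must be a single positive integer", call. = FALSE)
  }
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower > upper)) {
    stop("every lower bound must be <= the matching upper bound", call. = FALSE)
  }
  structure(list(dim = dim, lower = lower, upper = upper),
            class = "search_space")
}

#' Clamp a position to a search space
#'
#' Componentwise projection onto the box: values below a lower bound are set
#' to it, values above an upper bound likewise. Idempotent.
#'
#' @param x Numeric vector of length `space$dim`.
#' @param space A [search_space()].
#' @return The clamped vector.
#' @export
clamp_position <- function(x, space) {
  if (length(x) != space$dim) {
    stop("position length ", length(x), " does not match space dim ",
         space$dim, call. = FALSE)
  }
  pmin(space$upper, pmax(space$lower, x))
}

#' Initialize a population of search agents
#'
#' Each agent's position is drawn uniformly inside the box,
#' `x[j] = rand * (upper[j] - lower[j]) + lower[j]`, agent by agent.
#' Velocities and hunger levels start at zero; fitness is unset until the
#' first evaluation. Personal bests are seeded from the initial positions.
#'
#' @param space A [search_space()].
#' @param n Number of agents (at least 2).
#' @param rng A stream from [make_rng()].
#' @return An object of class `population_state`: a list with the position
#'   matrix `pos` (`n` x `dim`), velocity matrix `vel`, vectors `hunger` and
#'   `fit`, personal-best fields, the elitist best (`best_pos`, `best_fit`),
#'   current `worst_fit` and `hunger_sum`.
#' @export
init_population <- function(space, n, rng) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) {
    stop("population size `n` must be an integer >= 2", call. = FALSE)
  }
  u <- matrix(rng_uniform(rng, n * space$dim), nrow = n, byrow = TRUE)
  width <- space$upper - space$lower
  pos <- sweep(sweep(u, 2L, width, `*`), 2L, space$lower, `+`)
  structure(list(
    pos = pos,
    vel = matrix(0, nrow = n, ncol = space$dim),
    hunger = rep(0, n),
    fit = rep(NA_real_, n),
    pbest_pos = pos,
    pbest_fit = rep(Inf, n),
    best_pos = rep(NA_real_, space$dim),
    best_fit = Inf,
    worst_fit = -Inf,
    hunger_sum = 0
  ), class = "population_state")
}

#' Bounding box spanned by the current population
#'
#' Per-dimension minimum and maximum over agent positions. This contracted
#' box replaces the static bounds when constructing dynamic-opposite points;
#' it is never used to clamp positions.
#'
#' @param pop A `population_state`.
#' @return A [search_space()] with `lower[j] = min_i pos[i, j]` and
#'   `upper[j] = max_i pos[i, j]`.
#' @export
dynamic_bounds <- function(pop) {
  if (is.null(pop$pos) || nrow(pop$pos) == 0L) {
    stop("population is empty", call. = FALSE)
  }
  search_space(ncol(pop$pos),
               lower = apply(pop$pos, 2L, min),
               upper = apply(pop$pos, 2L, max))
}

# evaluate every agent with `evaluate(position) -> fitness`, refresh the
# elitist best, the current worst and personal bests (strict improvement:
# ties keep the incumbent)
evaluate_population <- function(pop, evaluate) {
  n <- nrow(pop$pos)
  for (i in seq_len(n)) {
    pop$fit[i] <- evaluate(pop$pos[i, ])
  }
  pop$pbest_fit <- pop$fit
  pop$pbest_pos <- pop$pos
  pop <- refresh_best(pop)
  pop
}

refresh_best <- function(pop) {
  i <- which.min(pop$fit)
  if (length(i) && pop$fit[i] < pop$best_fit) {
    pop$best_fit <- pop$fit[i]
    pop$best_pos <- pop$pos[i, ]
  }
  pop$worst_fit <- max(pop$fit)
  pop$hunger_sum <- sum(pop$hunger)
  pop
}
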