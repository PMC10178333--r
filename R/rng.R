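#' Create a deterministic random-number stream
#'
#' All randomness in this package flows through an explicit stream object so
#' that a run is a pure function of its seed: two runs with identical
#' configuration and seed produce identical results, independent of the state
#' of R's global random-number generator. The stream keeps a private copy of
#' the Mersenne-Twister state; drawing from it never disturbs (and is never
#' disturbed by) `set.seed()` or random draws elsewhere in the session.
#'
#' A single stream per run feeds every operator in a fixed, documented call
#' order (see the methods vignette); there are no per-operator sub-streams.
#'
#' @param seed Single non-negative integer.
#' @return An object of class `rng_stream`.
#' @examples
#' r <- make_rng(7)
#' rng_uniform(r, 3)
#' @export
make_rng <- function(seed) {
  if (length(seed) != 1L || is.na(seed) || !is.numeric(seed) ||
      seed < 0 || seed != floor(seed)) {
    stop("`seed` must be a single non-negative integer", call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  old <- .get_global_rng_state()
  on.exit(.set_global_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = .GlobalEnv)
  env$seed <- as.integer(seed)
  class(env) <- "rng_stream"
  env
}

#' Create a scripted random-number stream
#'
#' Plays back a fixed sequence of "uniform" and "normal" draws. Intended for
#' tests and worked examples where an operator must be evaluated at chosen
#' values of its random inputs (e.g. forcing a branch of the position update).
#' Draws beyond the supplied sequences raise an error.
#'
#' @param uniform Numeric vector of values returned, in order, by uniform draws.
#' @param normal Numeric vector of values returned, in order, by normal draws.
#' @return An object of class `rng_fixed`.
#' @export
make_fixed_rng <- function(uniform = numeric(), normal = numeric()) {
  env <- new.env(parent = emptyenv())
  env$uniform <- as.numeric(uniform)
  env$normal <- as.numeric(normal)
  env$iu <- 0L
  env$in_ <- 0L
  class(env) <- "rng_fixed"
  env
}

.get_global_rng_state <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else {
    NULL
  }
}

.set_global_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  } else {
    assign(".Random.seed", state, envir = .GlobalEnv)
  }
}

.rng_draw <- function(rng, fn, n) {
  old <- .get_global_rng_state()
  on.exit(.set_global_rng_state(old), add = TRUE)
  assign(".Random.seed", rng$state, envir = .GlobalEnv)
  x <- fn(n)
  rng$state <- get(".Random.seed", envir = .GlobalEnv)
  x
}

#' Draw uniform variates from a stream
#'
#' @param rng A stream from [make_rng()] or [make_fixed_rng()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` with values in \[0, 1).
#' @export
rng_uniform <- function(rng, n = 1L) {
  if (inherits(rng, "rng_fixed")) {
    if (rng$iu + n > length(rng$uniform)) {
      stop("fixed rng exhausted its uniform draws", call. = FALSE)
    }
    out <- rng$uniform[(rng$iu + 1L):(rng$iu + n)]
    rng$iu <- rng$iu + as.integer(n)
    return(out)
  }
  if (!inherits(rng, "rng_stream")) stop("not an rng stream", call. = FALSE)
  .rng_draw(rng, stats::runif, n)
}

#' Draw standard-normal variates from a stream
#'
#' @inheritParams rng_uniform
#' @return Numeric vector of length `n`.
#' @export
rng_normal <- function(rng, n = 1L) {
  if (inherits(rng, "rng_fixed")) {
    if (rng$in_ + n > length(rng$normal)) {
      stop("fixed rng exhausted its normal draws", call. = FALSE)
    }
    out <- rng$normal[(rng$in_ + 1L):(rng$in_ + n)]
    rng$in_ <- rng$in_ + as.integer(n)
    return(out)
  }
  if (!inherits(rng, "rng_stream")) stop("not an rng stream", call. = FALSE)
  .rng_draw(rng, stats::rnorm, n)
}

# derive an auxiliary seed (e.g. the fitness-protocol split) from the run
# seed; stays below 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + as.numeric(k) * 1000003) %% 2147483629)
}
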