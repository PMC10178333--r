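#' Configure an optimizer run
#'
#' @param n_agents Population size `N` (default 50).
#' @param n_iterations Iteration budget `T` (default 1000; 0 returns the
#'   initial population's best).
#' @param seed Integer seed; fixes the entire run.
#' @param mode `"dolhgs"` (hybrid, default), `"hgs"` or `"pso"`.
#' @param lambda_weight Error/size balance of the wrapper fitness
#'   (default 0.99).
#' @param knn_k Neighbours of the wrapper classifier (default 5).
#' @param hgs,pso,dol Operator parameter records ([hgs_params()],
#'   [pso_params()], [dol_params()]); `dol = NULL` disables dynamic-opposite
#'   learning in `"dolhgs"` mode.
#' @param split_fraction Internal fit/validation fraction of the fitness
#'   protocol (default 0.8).
#' @param force_hgs_prob Optional constant substituted for the per-agent
#'   competition draw `Pr_i` (no draw is consumed). `1` forces the HGS
#'   operator everywhere, `0` the PSO operator; mainly for degeneration
#'   checks.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_agents = 50, n_iterations = 1000, seed = 1,
                       mode = c("dolhgs", "hgs", "pso"),
                       lambda_weight = 0.99, knn_k = 5,
                       hgs = hgs_params(), pso = pso_params(),
                       dol = dol_params(), split_fraction = 0.8,
                       force_hgs_prob = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_agents >= 2, n_iterations >= 0,
            lambda_weight >= 0, lambda_weight <= 1, knn_k >= 1)
  structure(list(n_agents = as.integer(n_agents),
                 n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed), mode = mode,
                 lambda_weight = lambda_weight, knn_k = as.integer(knn_k),
                 hgs = hgs, pso = pso, dol = dol,
                 split_fraction = split_fraction,
                 force_hgs_prob = force_hgs_prob),
            class = "run_config")
}

# one engine drives all three modes; the standalone algorithms are the
# degenerate gate settings, so degeneration equivalence holds by
# construction. Draw order per iteration (see the methods vignette):
# hunger update, per-agent weights, then per agent the gate draw, the
# operator's own draws, and finally the jumping step.
run_search_engine <- function(dataset, config) {
  train <- dataset_train(dataset)
  test <- dataset_test(dataset)
  if (nlevels(train$labels) < 2L) {
    stop("dataset must contain at least two classes", call. = FALSE)
  }
  dim <- ncol(train$features)
  if (dim < 1L) stop("dataset has no features", call. = FALSE)
  space <- search_space(dim)
  evaluator <- make_fitness_evaluator(train$features, train$labels,
                                      config$lambda_weight, config$knn_k,
                                      config$split_fraction,
                                      derive_seed(config$seed, 1))
  evaluate <- function(x) evaluator(binarize(x))$fitness
  rng <- make_rng(config$seed)
  n <- config$n_agents
  T <- config$n_iterations
  gate <- switch(config$mode, hgs = 1, pso = 0,
                 dolhgs = config$force_hgs_prob)  # NULL => draw Pr_i
  use_dol <- config$mode == "dolhgs" && !is.null(config$dol)
  hgs_machinery_on <- is.null(gate) || gate > 0.5

  pop <- init_population(space, n, rng)
  pop <- evaluate_population(pop, evaluate)
  if (use_dol && config$dol$apply_at_init) {
    cand_pos <- matrix(NA_real_, n, dim)
    cand_fit <- numeric(n)
    for (i in seq_len(n)) {
      cand_pos[i, ] <- dynamic_opposite_point(pop$pos[i, ], space,
                                              config$dol, rng, space)
      cand_fit[i] <- evaluate(cand_pos[i, ])
    }
    pop <- dol_select(pop, cand_pos, cand_fit, seq_len(n))
  }

  tr_it <- integer(T + 1L)
  tr_best <- tr_mean <- numeric(T + 1L)
  tr_size <- integer(T + 1L)
  record <- function(t) {
    tr_it[t + 1L] <<- t
    tr_best[t + 1L] <<- pop$best_fit
    tr_mean[t + 1L] <<- mean(pop$fit)
    tr_size[t + 1L] <<- sum(binarize(pop$best_pos))
  }
  record(0L)

  for (t in seq_len(T)) {
    if (hgs_machinery_on) {
      pop <- update_hunger(pop, space, config$hgs, rng)
      W <- t(vapply(seq_len(n),
                    function(i) hunger_weights(i, pop, n, config$hgs, rng),
                    numeric(2)))
    }
    w_inertia <- inertia_at(t, T, config$pso)
    for (i in seq_len(n)) {
      pri <- if (is.null(gate)) rng_uniform(rng) else gate
      if (pri > 0.5) {
        sf <- shrink_factor(t, T, rng)
        st <- list(weight1 = W[i, 1L], weight2 = W[i, 2L],
                   escape_R = sf$R,
                   variation_E = variation_control(pop$fit[i], pop$best_fit))
        pop$pos[i, ] <- hgs_move(pop$pos[i, ], pop, st, config$hgs, rng, space)
      } else {
        vn <- pso_velocity(pop$pos[i, ], pop$vel[i, ], pop$pbest_pos[i, ],
                           pop$best_pos, w_inertia, config$pso, rng)
        pop$vel[i, ] <- vn
        pop$pos[i, ] <- pso_move(pop$pos[i, ], vn, space)
      }
      pop$fit[i] <- evaluate(pop$pos[i, ])
      pop <- update_personal_best(pop, i)
      if (pop$fit[i] < pop$best_fit) {
        pop$best_fit <- pop$fit[i]
        pop$best_pos <- pop$pos[i, ]
      }
    }
    pop$worst_fit <- max(pop$fit)
    pop$hunger_sum <- sum(pop$hunger)
    if (use_dol) {
      pop <- dol_jump(pop, config$dol, rng, evaluate, space)
    }
    record(t)
  }

  trace <- data.frame(iteration = tr_it, best_fitness = tr_best,
                      mean_fitness = tr_mean, subset_size = tr_size)
  build_report(pop$best_pos, evaluator, train, test, config, trace)
}

build_report <- function(best_pos, evaluator, train, test, config, trace) {
  mask <- binarize(best_pos)
  if (sum(mask) == 0L) {
    stop("search converged to an empty feature subset", call. = FALSE)
  }
  rec <- evaluator(mask)
  selected <- which(mask == 1L)
  test_metrics <- NULL
  if (!is.null(test)) {
    pred <- knn_predict(train$features[, selected, drop = FALSE],
                        train$labels,
                        test$features[, selected, drop = FALSE],
                        config$knn_k)
    test_metrics <- classification_metrics(test$labels, pred, "weighted")
  }
  structure(list(selected_indices = selected,
                 selected_names = colnames(train$features)[selected],
                 best_fitness = rec$fitness, gamma = rec$gamma,
                 ratio = rec$ratio, lambda = rec$lambda,
                 test_metrics = test_metrics, config = config,
                 trace = trace),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("%s run (N = %d, T = %d, seed = %d)\n", x$config$mode,
              x$config$n_agents, x$config$n_iterations, x$config$seed))
  cat(sprintf("  selected %d of %d features; fitness %.6f (error %.4f, ratio %.4f, lambda %.2f)\n",
              length(x$selected_indices),
              round(length(x$selected_indices) / x$ratio),
              x$best_fitness, x$gamma, x$ratio, x$lambda))
  if (!is.null(x$test_metrics)) {
    cat("  held-out: ")
    print(x$test_metrics)
  }
  invisible(x)
}

#' Run the hybrid dynamic-opposite Hunger Games Search selector
#'
#' The full pipeline: uniform initialization, dynamic-opposite enhancement
#' of the initial population, then `T` iterations in which each agent is
#' moved by either the Hunger Games Search operator or the Particle Swarm
#' operator — chosen by a fresh per-agent probability draw (`Pr_i > 0.5`
#' selects HGS) — followed by a probabilistic dynamic-opposite jumping step
#' against the population's contracted bounding box and greedy elite
#' selection. The best-ever solution is archived outside the population and
#' can never be lost. Held-out metrics come from refitting the KNN wrapper
#' on the full training partition restricted to the selected subset.
#'
#' @param dataset A [feature_dataset()]; rows tagged `"test"` are held out.
#' @param config A [run_config()]; its `mode` is forced to `"dolhgs"`.
#' @return A `selection_report`: selected feature indices, the fitness
#'   decomposition of the best subset, held-out metrics (when a test split
#'   exists), the configuration echo and the per-iteration convergence
#'   trace.
#' @export
run_dolhgs <- function(dataset, config = run_config()) {
  config$mode <- "dolhgs"
  run_search_engine(dataset, config)
}

#' Run standalone Hunger Games Search
#'
#' Pure HGS baseline: hunger dynamics, hunger weights and the three-branch
#' position update, with no PSO competition and no dynamic-opposite
#' learning.
#'
#' @inheritParams run_dolhgs
#' @return A `selection_report`.
#' @export
run_hgs <- function(dataset, config = run_config()) {
  config$mode <- "hgs"
  run_search_engine(dataset, config)
}

#' Run standalone Particle Swarm Optimization
#'
#' Pure PSO baseline: linearly decaying inertia, per-dimension velocity
#' updates clamped at `v_max`, personal and global bests.
#'
#' @inheritParams run_dolhgs
#' @return A `selection_report`.
#' @export
run_pso <- function(dataset, config = run_config()) {
  config$mode <- "pso"
  run_search_engine(dataset, config)
}

#' Random-subset baseline
#'
#' Evaluates `n_agents * n_iterations` uniformly random masks (each drawn by
#' binarizing a uniform position) under the same fitness protocol and keeps
#' the best. Serves as the equal-budget floor any guided search must beat.
#'
#' @inheritParams run_dolhgs
#' @return A `selection_report` (trace has one row per block of `n_agents`
#'   evaluations).
#' @export
run_random_baseline <- function(dataset, config = run_config()) {
  train <- dataset_train(dataset)
  test <- dataset_test(dataset)
  dim <- ncol(train$features)
  evaluator <- make_fitness_evaluator(train$features, train$labels,
                                      config$lambda_weight, config$knn_k,
                                      config$split_fraction,
                                      derive_seed(config$seed, 1))
  rng <- make_rng(config$seed)
  n <- config$n_agents
  T <- max(1L, config$n_iterations)
  best_fit <- Inf
  best_pos <- NULL
  tr <- vector("list", T + 1L)
  tr[[1L]] <- data.frame(iteration = 0L, best_fitness = NA_real_,
                         mean_fitness = NA_real_, subset_size = NA_integer_)
  for (t in seq_len(T)) {
    block <- numeric(n)
    for (i in seq_len(n)) {
      x <- rng_uniform(rng, dim)
      f <- evaluator(binarize(x))$fitness
      block[i] <- f
      if (f < best_fit) {
        best_fit <- f
        best_pos <- x
      }
    }
    tr[[t + 1L]] <- data.frame(iteration = t, best_fitness = best_fit,
                               mean_fitness = mean(block),
                               subset_size = sum(binarize(best_pos)))
  }
  trace <- do.call(rbind, tr)
  trace$best_fitness[1L] <- trace$best_fitness[2L]
  trace$mean_fitness[1L] <- trace$mean_fitness[2L]
  trace$subset_size[1L] <- trace$subset_size[2L]
  config$mode <- "dolhgs"  # echo only; report labels itself below
  rep <- build_report(best_pos, evaluator, train, test, config, trace)
  rep$config$mode <- "random"
  rep
}

#' Exhaustive feature-subset search
#'
#' Enumerates every non-empty mask over up to 20 features under the same
#' seeded fitness protocol as the optimizers and returns the global minimum.
#' The independent oracle against which small-dimension optimizer runs are
#' validated.
#'
#' @param dataset A [feature_dataset()] (training rows are used).
#' @param config A [run_config()]; only the fitness-protocol fields
#'   (`lambda_weight`, `knn_k`, `split_fraction`, `seed`) matter.
#' @return List with `best_fitness`, `best_mask`, `n_masks`.
#' @export
exhaustive_subset_search <- function(dataset, config = run_config()) {
  train <- dataset_train(dataset)
  dim <- ncol(train$features)
  if (dim > 20L) stop("exhaustive search supports at most 20 features",
                      call. = FALSE)
  evaluator <- make_fitness_evaluator(train$features, train$labels,
                                      config$lambda_weight, config$knn_k,
                                      config$split_fraction,
                                      derive_seed(config$seed, 1))
  best_fit <- Inf
  best_mask <- NULL
  n_masks <- 2L^dim - 1L
  for (code in seq_len(n_masks)) {
    mask <- as.integer(bitwAnd(bitwShiftR(code, 0:(dim - 1L)), 1L))
    f <- evaluator(mask)$fitness
    if (f < best_fit) {
      best_fit <- f
      best_mask <- mask
    }
  }
  list(best_fitness = best_fit, best_mask = best_mask, n_masks = n_masks)
}
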