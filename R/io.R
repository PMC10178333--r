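#' Read a feature table from CSV/TSV
#'
#' Expects a header row, one categorical label column and numeric feature
#' columns. The separator follows the file extension (`.tsv`/`.tab` read as
#' tab-separated, anything else as comma-separated) unless given. Missing
#' or non-numeric feature cells are rejected with the offending row and
#' column named.
#'
#' @param path File path.
#' @param label_column Name of the label column (default `"label"`).
#' @param split_column Optional name of a `"train"`/`"test"` column.
#' @param sep Field separator; default inferred from the extension.
#' @return A [feature_dataset()].
#' @export
read_feature_table <- function(path, label_column = "label",
                               split_column = NULL, sep = NULL) {
  if (!file.exists(path)) stop_data("no such file: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) stop_data("cannot parse ", path, ": ",
                                  conditionMessage(e)))
  if (nrow(df) == 0L) stop_data("empty table: ", path)
  if (!label_column %in% names(df)) {
    stop_data("label column \"", label_column, "\" not found in ", path)
  }
  labels <- df[[label_column]]
  split <- NULL
  drop <- label_column
  if (!is.null(split_column)) {
    if (!split_column %in% names(df)) {
      stop_data("split column \"", split_column, "\" not found in ", path)
    }
    split <- df[[split_column]]
    drop <- c(drop, split_column)
  }
  feats <- df[, setdiff(names(df), drop), drop = FALSE]
  for (cn in names(feats)) {
    col <- feats[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
      if (is.na(bad)) bad <- 1L
      stop_data("non-numeric feature value in column \"", cn, "\", row ",
                bad)
    }
    if (anyNA(col)) {
      stop_data("missing feature value in column \"", cn, "\", row ",
                which(is.na(col))[1L])
    }
  }
  feature_dataset(as.matrix(feats), labels, split = split)
}

#' Write a feature table to CSV/TSV
#'
#' Inverse of [read_feature_table()]: features, a `label` column and, when
#' the dataset carries one, a `split` column.
#'
#' @param dataset A [feature_dataset()].
#' @param path Output path (`.tsv`/`.tab` writes tab-separated).
#' @export
write_feature_table <- function(dataset, path) {
  df <- as.data.frame(dataset$features)
  df$label <- as.character(dataset$labels)
  if (!is.null(dataset$split)) df$split <- as.character(dataset$split)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

serialize_params <- function(p) {
  if (is.null(p)) return(NULL)
  unclass(p)
}

#' Write a selection report as JSON
#'
#' Full-precision JSON: selected indices, the fitness decomposition,
#' held-out metrics with their confusion table, and a manifest (tool
#' version, resolved configuration, seed) from which the run can be
#' reproduced. The convergence trace is written separately by
#' [write_trace()].
#'
#' @param report A `selection_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  tm <- report$test_metrics
  cfg <- report$config
  x <- list(
    tool = "dolhgs",
    version = as.character(utils::packageVersion("dolhgs")),
    config = list(
      n_agents = cfg$n_agents, n_iterations = cfg$n_iterations,
      seed = cfg$seed, mode = cfg$mode,
      lambda_weight = cfg$lambda_weight, knn_k = cfg$knn_k,
      split_fraction = cfg$split_fraction,
      hgs = serialize_params(cfg$hgs), pso = serialize_params(cfg$pso),
      dol = serialize_params(cfg$dol)
    ),
    selected_indices = report$selected_indices,
    selected_names = report$selected_names,
    best_fitness = report$best_fitness,
    gamma = report$gamma, ratio = report$ratio, lambda = report$lambda,
    test_metrics = if (is.null(tm)) NULL else list(
      accuracy = tm$accuracy, precision = tm$precision,
      recall = tm$recall, f1 = tm$f1, average = tm$average,
      confusion = list(labels = rownames(tm$confusion$table),
                       counts = unclass(unname(tm$confusion$table)))
    )
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON selection report
#'
#' @param path Path written by [write_report()].
#' @return Nested list mirroring the JSON.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write a convergence trace as CSV
#'
#' One row per iteration (plus the post-initialization state): iteration,
#' best fitness, mean fitness, selected-subset size of the best agent.
#'
#' @param trace Trace data frame from a `selection_report`.
#' @param path Output path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

stop_usage <- function(...) {
  stop(structure(class = c("dolhgs_usage_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

stop_data <- function(...) {
  stop(structure(class = c("dolhgs_data_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

log_line <- function(level, ...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " [", level, "] ", ...)
}

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop_usage("unexpected argument: ", a)
    key <- substring(a, 3L)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

flag <- function(flags, name, default = NULL) {
  if (!is.null(flags[[name]])) flags[[name]] else default
}

flag_num <- function(flags, name, default = NULL) {
  v <- flag(flags, name, default)
  if (is.null(v)) return(NULL)
  v <- suppressWarnings(as.numeric(v))
  if (is.na(v)) stop_usage("flag --", name, " needs a numeric value")
  v
}

config_from_flags <- function(flags) {
  base <- list()
  if (!is.null(flags$config)) {
    base <- yaml::read_yaml(flags$config)
  }
  pick <- function(cli_name, yaml_name, default, numeric = TRUE) {
    v <- if (numeric) flag_num(flags, cli_name) else flag(flags, cli_name)
    if (!is.null(v)) return(v)
    if (!is.null(base[[yaml_name]])) return(base[[yaml_name]])
    default
  }
  run_config(
    n_agents = pick("agents", "n_agents", 50),
    n_iterations = pick("iters", "n_iterations", 1000),
    seed = pick("seed", "seed", 1),
    mode = pick("mode", "mode", "dolhgs", numeric = FALSE),
    lambda_weight = pick("lambda", "lambda_weight", 0.99),
    knn_k = pick("k", "knn_k", 5)
  )
}

cli_select <- function(flags) {
  if (is.null(flags$input) || is.null(flags$out)) {
    stop_usage("select needs --input and --out")
  }
  dataset <- read_feature_table(flags$input,
                                label_column = flag(flags, "label", "label"),
                                split_column = flag(flags, "split-col"))
  config <- config_from_flags(flags)
  quiet <- isTRUE(flag(flags, "quiet", FALSE))
  if (!quiet) {
    log_line("INFO", "running ", config$mode, " on ", flags$input,
             " (N=", config$n_agents, ", T=", config$n_iterations,
             ", seed=", config$seed, ")")
  }
  runner <- switch(config$mode, dolhgs = run_dolhgs, hgs = run_hgs,
                   pso = run_pso, random = run_random_baseline,
                   stop_usage("unknown mode: ", config$mode))
  report <- runner(dataset, config)
  write_report(report, flags$out)
  if (!is.null(flags$trace)) write_trace(report$trace, flags$trace)
  if (!quiet) {
    log_line("INFO", "selected ", length(report$selected_indices),
             " features; best fitness ",
             formatC(report$best_fitness, digits = 6, format = "f"))
    if (!is.null(report$test_metrics)) {
      log_line("INFO", sprintf("held-out accuracy %.2f%%",
                               100 * report$test_metrics$accuracy))
    }
  }
  0L
}

cli_synth <- function(flags) {
  preset <- flag(flags, "preset")
  if (is.null(preset) || is.null(flags$out)) {
    stop_usage("synth needs --preset and --out")
  }
  seed <- flag_num(flags, "seed", 1)
  dataset <- switch(preset,
                    "isic-like" = make_isic_like(seed),
                    "ph2-like" = make_ph2_like(seed),
                    stop_usage("unknown preset: ", preset))
  write_feature_table(dataset, flags$out)
  if (!is.null(flags[["truth-out"]])) {
    jsonlite::write_json(list(informative = attr(dataset, "informative")),
                         flags[["truth-out"]], auto_unbox = TRUE)
  }
  log_line("INFO", "wrote ", nrow(dataset$features), " rows to ", flags$out)
  0L
}

cli_compare <- function(flags) {
  if (is.null(flags$input)) stop_usage("compare needs --input")
  dataset <- read_feature_table(flags$input,
                                label_column = flag(flags, "label", "label"),
                                split_column = flag(flags, "split-col",
                                                    "split"))
  if (is.null(dataset$split) || !any(dataset$split == "test")) {
    stop_data("compare needs a train/test split column")
  }
  methods <- strsplit(flag(flags, "methods", "dolhgs,hgs,pso,random"),
                      ",")[[1]]
  config <- config_from_flags(flags)
  scores <- matrix(NA_real_, length(methods), 4L,
                   dimnames = list(methods, c("AC", "R", "P", "F1")))
  for (m in methods) {
    runner <- switch(m, dolhgs = run_dolhgs, hgs = run_hgs, pso = run_pso,
                     random = run_random_baseline,
                     stop_usage("unknown method: ", m))
    rep <- runner(dataset, config)
    tm <- rep$test_metrics
    scores[m, ] <- c(tm$accuracy, tm$recall, tm$precision, tm$f1)
  }
  cat(sprintf("%-10s %8s %8s %8s %8s\n", "method", "AC", "R", "P", "F1"))
  for (m in methods) {
    cat(sprintf("%-10s %8.2f %8.2f %8.2f %8.2f\n", m,
                100 * scores[m, "AC"], 100 * scores[m, "R"],
                100 * scores[m, "P"], 100 * scores[m, "F1"]))
  }
  mr <- friedman_mean_rank(scores)
  cat("mean rank:", paste(sprintf("%s=%.2f", names(mr), mr), collapse = " "),
      "\n")
  0L
}

cli_pir <- function(flags) {
  ac <- flag_num(flags, "ac")
  ref <- flag_num(flags, "ref")
  if (is.null(ac) || is.null(ref)) stop_usage("pir needs --ac and --ref")
  conv <- flag(flags, "convention", "table")
  cat(sprintf("%.2f\n", pir(ac, ref, conv)))
  0L
}

#' Command-line entry point
#'
#' Subcommands: `select` (run an optimizer on a feature table), `synth`
#' (emit a synthetic embedding dataset), `compare` (run several optimizers
#' and print a metrics table with Friedman mean ranks), `pir` (improvement
#' rates). Returns the process exit status: 0 on success, 2 on usage
#' errors, 3 on data/format errors. The installed script
#' `system.file("cli", "dolhgs.R", package = "dolhgs")` wraps this function
#' for shell use.
#'
#' @param args Character vector of command-line arguments (without the
#'   program name).
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dolhgs <select|synth|compare|pir> [--flags]",
    "  select  --input d.csv --out report.json [--label label]",
    "          [--split-col split] [--mode dolhgs|hgs|pso|random]",
    "          [--agents N] [--iters T] [--seed S] [--lambda L] [--k K]",
    "          [--trace trace.csv] [--config run.yaml] [--quiet]",
    "  synth   --preset isic-like|ph2-like --out d.csv [--seed S]",
    "          [--truth-out truth.json]",
    "  compare --input d.csv [--methods dolhgs,hgs,pso,random] [...]",
    "  pir     --ac 88.19 --ref 85.50 [--convention table|ratio]",
    sep = "\n")
  status <- tryCatch({
    if (length(args) == 0L) stop_usage("no subcommand given\n", usage)
    cmd <- args[1L]
    flags <- parse_flags(args[-1L])
    switch(cmd,
           select = cli_select(flags),
           synth = cli_synth(flags),
           compare = cli_compare(flags),
           pir = cli_pir(flags),
           stop_usage("unknown subcommand: ", cmd, "\n", usage))
  },
  dolhgs_usage_error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  },
  dolhgs_data_error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    3L
  })
  invisible(status)
}
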