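#' Benchmark harness
#'
#' A [run_config()] fully specifies a benchmark run (task, model, dataset,
#' hyperparameters, seeds); [run_benchmark()] executes it through the
#' fit-predict-score contract, averaging the task's metrics over seeds;
#' [to_command_line()] serializes any config to a single reproducible
#' command line and [parse_command_line()] inverts it exactly.
#'
#' @name bench
NULL

the_models <- new.env(parent = emptyenv())

#' Register a model with the benchmark harness
#'
#' @param name model name used in configs and on the command line.
#' @param task one of `"clustering"`, `"annotation"`, `"imputation"`,
#'   `"deconvolution"`.
#' @param pipeline the model's default preprocessing [sc_pipeline].
#' @param runner function `(data, hyper, seed)` returning a named list of
#'   metric values (first one primary).
#' @return `name`, invisibly.
#' @export
register_model <- function(name, task, pipeline, runner) {
  stopifnot(is.function(runner))
  task <- match.arg(task, c("clustering", "annotation", "imputation",
                            "deconvolution"))
  the_models[[name]] <- list(name = name, task = task, pipeline = pipeline,
                             runner = runner)
  invisible(name)
}

#' List registered model names
#' @return character vector.
#' @export
list_models <- function() sort(ls(the_models))

#' @keywords internal
model_info <- function(name) {
  if (!exists(name, envir = the_models, inherits = FALSE))
    stop("unknown model '", name, "'; available: ",
         paste(list_models(), collapse = ", "))
  get(name, envir = the_models, inherits = FALSE)
}

#' Primary metric per task and its preferred direction
#' @param task task name.
#' @return list with `metric` and `higher_better`.
#' @export
task_primary_metric <- function(task) {
  switch(task,
         clustering = list(metric = "ari", higher_better = TRUE),
         annotation = list(metric = "accuracy", higher_better = TRUE),
         imputation = list(metric = "mse", higher_better = FALSE),
         deconvolution = list(metric = "mse", higher_better = FALSE),
         stop("unknown task '", task, "'"))
}

#' Benchmark run configuration
#'
#' @param task task name.
#' @param model registered model name (task-compatible).
#' @param dataset registered dataset name.
#' @param hyperparameters flat named list of scalar overrides passed to the
#'   model; stored sorted by name (canonical form).
#' @param seeds integer vector of run seeds.  The default protocol uses the
#'   fixed list 0..19 so every model sees the same twenty seeds.
#' @param device `"cpu"` or `"accelerator"` (pass-through flag; all
#'   correctness contracts are CPU-defined).
#' @return object of class `run_config`.
#' @export
run_config <- function(task, model, dataset, hyperparameters = list(),
                       seeds = 0:19, device = "cpu") {
  task <- match.arg(task, c("clustering", "annotation", "imputation",
                            "deconvolution"))
  device <- match.arg(device, c("cpu", "accelerator"))
  info <- model_info(model)
  if (!identical(info$task, task))
    stop("model '", model, "' is registered for task '", info$task,
         "', not '", task, "'")
  if (length(hyperparameters)) {
    if (is.null(names(hyperparameters)) || any(names(hyperparameters) == ""))
      stop("hyperparameters must be named")
    hyperparameters <- hyperparameters[order(names(hyperparameters))]
    ## canonical scalar types so serialization round trips are identical
    hyperparameters <- lapply(hyperparameters, function(v)
      if (is.numeric(v)) as.numeric(v) else v)
  }
  structure(list(task = task, model = model, dataset = dataset,
                 hyperparameters = hyperparameters,
                 seeds = as.integer(seeds), device = device),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(to_command_line(x), "\n")
  invisible(x)
}

## exact numeric round trip through text
#' @keywords internal
num_to_str <- function(x) {
  if (is.logical(x)) return(if (x) "TRUE" else "FALSE")
  if (!is.numeric(x)) return(as.character(x))
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  if (as.numeric(s) == x) s else sprintf("%.17g", x)
}

#' @keywords internal
str_to_value <- function(s) {
  if (s %in% c("TRUE", "FALSE")) return(as.logical(s))
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n) && grepl("^[-+0-9.eE]+$", s)) n else s
}

#' Serialize a run config to one command line
#'
#' Canonical form: the `scbench run` invocation with flags in sorted order
#' (`--dataset`, `--device`, `--model`, one `--param k=v` per hyperparameter
#' sorted by name, one `--seed` per seed in order, `--task`).
#' `parse_command_line(to_command_line(cfg))` equals `cfg` exactly.
#'
#' @param cfg a [run_config()].
#' @return a single string.
#' @export
to_command_line <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  parts <- c("scbench run",
             paste("--dataset", cfg$dataset),
             paste("--device", cfg$device),
             paste("--model", cfg$model))
  for (nm in names(cfg$hyperparameters))
    parts <- c(parts, paste0("--param ", nm, "=",
                             num_to_str(cfg$hyperparameters[[nm]])))
  for (s in cfg$seeds) parts <- c(parts, paste("--seed", s))
  parts <- c(parts, paste("--task", cfg$task))
  paste(parts, collapse = " ")
}

#' @rdname to_command_line
#' @param argv a command line string or a character vector of tokens
#'   (leading `scbench`/`run` tokens are permitted and ignored).
#' @export
parse_command_line <- function(argv) {
  if (length(argv) == 1 && grepl(" ", argv))
    argv <- strsplit(trimws(argv), "\\s+")[[1]]
  if (length(argv) && argv[1] == "scbench") argv <- argv[-1]
  if (length(argv) && argv[1] == "run") argv <- argv[-1]
  fields <- list(task = NULL, model = NULL, dataset = NULL, device = "cpu")
  hyper <- list()
  seeds <- integer(0)
  i <- 1L
  while (i <= length(argv)) {
    flag <- argv[i]
    if (!startsWith(flag, "--"))
      stop("expected a --flag, got '", flag, "'")
    if (i + 1L > length(argv)) stop("flag ", flag, " is missing a value")
    val <- argv[i + 1L]
    key <- substring(flag, 3)
    switch(key,
           task = , model = , dataset = , device = {
             fields[[key]] <- val
           },
           seed = {
             s <- suppressWarnings(as.integer(val))
             if (is.na(s)) stop("malformed value for --seed: '", val, "'")
             seeds <- c(seeds, s)
           },
           param = {
             kv <- strsplit(val, "=", fixed = TRUE)[[1]]
             if (length(kv) < 2) stop("malformed --param '", val,
                                      "'; expected key=value")
             hyper[[kv[1]]] <- str_to_value(paste(kv[-1], collapse = "="))
           },
           stop("unknown flag --", key))
    i <- i + 2L
  }
  if (is.null(fields$task) || is.null(fields$model) ||
      is.null(fields$dataset))
    stop("command line must set --task, --model and --dataset")
  if (!length(seeds)) seeds <- 0:19
  run_config(task = fields$task, model = fields$model,
             dataset = fields$dataset, hyperparameters = hyper,
             seeds = seeds, device = fields$device)
}

#' Execute a benchmark run
#'
#' For each seed the dataset is loaded by name, preprocessed with the
#' model's default pipeline (clustering/annotation tasks), the model is fit,
#' predictions are made and scored with the task's metrics.  Per-seed
#' failures are recorded and the summary is computed over the successes with
#' a warning.
#'
#' @param cfg a [run_config()].
#' @param verbose print per-seed progress.
#' @return object of class `benchmark_result`: `config`, `per_seed` (seed ->
#'   [metric_report]), `summary` (data.frame metric/mean/sd), `command_line`,
#'   `tool_version`.
#' @export
run_benchmark <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  info <- model_info(cfg$model)       # errors before any training
  data <- get_dataset(cfg$dataset)
  per_seed <- list()
  failures <- character(0)
  for (s in cfg$seeds) {
    res <- tryCatch(info$runner(data, cfg$hyperparameters, s),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, paste0("seed ", s, ": ",
                                     conditionMessage(res)))
      next
    }
    n_items <- if (inherits(data, "sc_mixture")) nrow(data$spots)
    else n_cells(data)
    ## append (never index by name): repeated seeds keep separate entries
    per_seed <- c(per_seed, stats::setNames(
      list(metric_report(cfg$task, res, n_items)), as.character(s)))
    if (verbose)
      message("seed ", s, ": ",
              paste(names(res), signif(unlist(res), 4), sep = "=",
                    collapse = ", "))
  }
  if (length(failures))
    warning("failed seeds (summary over successes): ",
            paste(failures, collapse = "; "))
  if (!length(per_seed)) stop("every seed failed")
  metrics <- names(per_seed[[1]]$values)
  summary <- do.call(rbind, lapply(metrics, function(m) {
    vals <- vapply(per_seed, function(r) r$values[[m]], numeric(1))
    data.frame(metric = m, mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0)
  }))
  structure(list(config = cfg, per_seed = per_seed, summary = summary,
                 command_line = to_command_line(cfg),
                 tool_version = as.character(
                   utils::packageVersion("scbench"))),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("benchmark_result:", x$command_line, "\n")
  cat("  seeds:", length(x$per_seed), "\n")
  for (r in seq_len(nrow(x$summary)))
    cat(sprintf("  %s: mean %.4f, sd %.4f\n", x$summary$metric[r],
                x$summary$mean[r], x$summary$sd[r]))
  invisible(x)
}

#' Grid search over hyperparameter candidates
#'
#' Evaluates every point of the Cartesian product of `space` (a named list
#' of candidate vectors) with the base config's seeds; the best config
#' maximizes the mean primary metric (minimizes it for MSE tasks), ties
#' broken by grid enumeration order.
#'
#' @param space named list mapping hyperparameter names to finite candidate
#'   vectors.
#' @param base a [run_config()] providing task/model/dataset/seeds.
#' @return list with `best` (a [run_config()]) and `table` (data.frame of
#'   one row per grid point, sorted best-first, with the serialized params
#'   and the summary mean/sd of the primary metric).
#' @export
grid_search <- function(space, base) {
  stopifnot(inherits(base, "run_config"))
  if (!length(space) || is.null(names(space)))
    stop("search space must be a non-empty named list")
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  pm <- task_primary_metric(base$task)
  rows <- vector("list", nrow(grid))
  cfgs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hp <- utils::modifyList(base$hyperparameters,
                            as.list(grid[i, , drop = FALSE]))
    cfg_i <- run_config(base$task, base$model, base$dataset, hp,
                        seeds = base$seeds, device = base$device)
    res <- run_benchmark(cfg_i)
    srow <- res$summary[res$summary$metric == pm$metric, ]
    rows[[i]] <- data.frame(grid_index = i,
                            params = paste(names(grid),
                                           unlist(grid[i, , drop = FALSE]),
                                           sep = "=", collapse = ","),
                            metric = pm$metric,
                            mean = srow$mean, sd = srow$sd)
    cfgs[[i]] <- cfg_i
  }
  table <- do.call(rbind, rows)
  ord <- order(if (pm$higher_better) -table$mean else table$mean,
               table$grid_index)
  table <- table[ord, ]
  rownames(table) <- NULL
  list(best = cfgs[[table$grid_index[1]]], table = table)
}

#' Write benchmark results to disk
#'
#' Produces `detail.csv` (one row per config and seed and metric),
#' `summary.csv` and a `configs.json` sidecar holding the full configs and
#' command lines.
#'
#' @param results list of `benchmark_result`s.
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "benchmark_result")) results <- list(results)
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE,
                                       showWarnings = FALSE)
  if (!ok) stop("cannot create output directory: ", path)
  detail <- do.call(rbind, lapply(results, function(r) {
    do.call(rbind, lapply(names(r$per_seed), function(s) {
      vals <- r$per_seed[[s]]$values
      data.frame(task = r$config$task, model = r$config$model,
                 dataset = r$config$dataset, seed = as.integer(s),
                 metric = names(vals), value = unlist(vals),
                 row.names = NULL)
    }))
  }))
  summary <- do.call(rbind, lapply(results, function(r)
    cbind(data.frame(task = r$config$task, model = r$config$model,
                     dataset = r$config$dataset), r$summary)))
  utils::write.csv(detail, file.path(path, "detail.csv"), row.names = FALSE)
  utils::write.csv(summary, file.path(path, "summary.csv"),
                   row.names = FALSE)
  sidecar <- lapply(results, function(r)
    list(command_line = r$command_line, tool_version = r$tool_version,
         config = list(task = r$config$task, model = r$config$model,
                       dataset = r$config$dataset,
                       hyperparameters = r$config$hyperparameters,
                       seeds = r$config$seeds, device = r$config$device)))
  jsonlite::write_json(sidecar, file.path(path, "configs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reconstruct run configs from a results sidecar
#' @param path directory written by [write_results()].
#' @return list of [run_config()]s.
#' @export
read_result_configs <- function(path) {
  sidecar <- jsonlite::read_json(file.path(path, "configs.json"),
                                 simplifyVector = FALSE)
  lapply(sidecar, function(e) {
    cf <- e$config
    run_config(cf$task, cf$model, cf$dataset,
               hyperparameters = lapply(cf$hyperparameters, identity),
               seeds = unlist(cf$seeds), device = cf$device)
  })
}
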