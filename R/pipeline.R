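# End-to-end workflow: generate -> split -> fit -> evaluate -> surface ->
# scatter -> summarize, with every artifact written to disk and every
# seed recorded, so a run is fully reconstructible from its log.

#' Full pipeline configuration
#'
#' Bundles the generator, split, model and surface settings of one
#' analysis run. Defaults follow the study protocol: 70/30 train/test
#' split, 10-fold cross-validation, and the OIRS 2.0 low-intensity
#' exclusion on the interaction surface.
#'
#' @param generator A [generator_config()] (carries its own seed).
#' @param train_fraction Training fraction in `(0, 1)`; default 0.7.
#' @param split_seed Integer seed of the train/test partition.
#' @param grid A [hyperparameter_grid()].
#' @param cv_folds Cross-validation folds; default 10.
#' @param cv_seed Integer seed of the fold assignment.
#' @param resolution Surface grid resolution; default 50.
#' @param min_oi_sum Surface masking threshold; default 2.0 OIRS.
#' @param output_dir Directory receiving all artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator, train_fraction = 0.7, split_seed,
                       grid = hyperparameter_grid(), cv_folds = 10,
                       cv_seed, resolution = 50, min_oi_sum = 2.0,
                       output_dir = tempfile("odormix_run_")) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(grid, "hyperparameter_grid"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("train_fraction must lie strictly inside (0, 1)")
  }
  fill_seed <- function(seed, what) {
    if (missing(seed) || is.null(seed)) {
      seed <- sample.int(10^6, 1)
      message("auto-filled ", what, " = ", seed)
    }
    as.integer(seed)
  }
  if (resolution < 2) stop("resolution must be >= 2")
  structure(list(
    generator = generator,
    split = list(train_fraction = train_fraction,
                 seed = fill_seed(split_seed, "split seed")),
    model = list(grid = grid, cv_folds = as.integer(cv_folds),
                 seed = fill_seed(cv_seed, "cv seed")),
    surface = list(resolution = as.integer(resolution),
                   min_oi_sum = min_oi_sum),
    output_dir = output_dir
  ), class = "run_config")
}

run_config_to_list <- function(config) {
  gen <- unclass(config$generator)
  gen$x_levels <- as.numeric(gen$x_levels)
  list(
    generator = gen,
    split = config$split,
    model = list(grid = unclass(config$model$grid),
                 cv_folds = config$model$cv_folds,
                 seed = config$model$seed),
    surface = config$surface,
    output_dir = config$output_dir
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The format is chosen by file extension (`.yaml`/`.yml` vs `.json`).
#' Generator fields and the generator seed must be explicit; split and
#' CV seeds are auto-filled (and echoed) when omitted.
#'
#' @param path Configuration file.
#' @param registry Odorant registry.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, registry = default_odorant_registry()) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unrecognized config extension '.", ext, "' (use yaml or json)"))
  g <- raw$generator
  if (is.null(g) || is.null(g$seed)) {
    stop("config must contain a generator block with an explicit seed")
  }
  gen <- generator_config(
    odorant_a = g$odorant_a %||% "EA",
    odorant_b = g$odorant_b %||% "BA",
    seed = g$seed,
    rho_max = g$rho_max,
    shape_p = g$shape_p %||% 1,
    noise_sigma = g$noise_sigma %||% 0.3,
    n_samples = g$n_samples %||% 30,
    x_levels = g$x_levels %||% seq(0.1, 0.9, by = 0.1),
    total_lnoav_range = unlist(g$total_lnoav_range %||% c(3, 10)),
    min_oi_sum = g$min_oi_sum %||% 2.0,
    oi_clip = if (!is.null(g$oi_clip)) unlist(g$oi_clip) else c(0, 8),
    registry = registry
  )
  grid_raw <- raw$model$grid
  grid <- hyperparameter_grid(
    c_values = unlist(grid_raw$c_values %||% 2^seq(-5, 15, by = 2)),
    gamma_values = unlist(grid_raw$gamma_values %||% 2^seq(-15, 3, by = 2)),
    epsilon = grid_raw$epsilon %||% 0.1
  )
  args <- list(
    generator = gen,
    train_fraction = raw$split$train_fraction %||% 0.7,
    grid = grid,
    cv_folds = raw$model$cv_folds %||% 10,
    resolution = raw$surface$resolution %||% 50,
    min_oi_sum = raw$surface$min_oi_sum %||% 2.0,
    output_dir = raw$output_dir %||% tempfile("odormix_run_")
  )
  if (!is.null(raw$split$seed)) args$split_seed <- raw$split$seed
  if (!is.null(raw$model$seed)) args$cv_seed <- raw$model$seed
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end odor-interaction pipeline
#'
#' Executes generate, split, fit, evaluate, surface, scatter and
#' summarize, writing every artifact under `config$output_dir`:
#' `dataset.csv`, `model.rds`, `evaluation.json`, `surface.csv`,
#' `scatter.csv`, `summary.json`, `figure_surface.png`,
#' `figure_scatter.png` and `run.log`. Rerunning with an identical
#' config reproduces all numeric artifacts.
#'
#' @param config A [run_config()].
#' @param registry Odorant registry.
#' @param figures Write PNG figures (default TRUE).
#' @return Invisibly, a list with the in-memory results (`dataset`,
#'   `model`, `evaluation`, `surface`, `scatter`, `summary`) and the
#'   vector of artifact `paths`.
#' @export
run_pipeline <- function(config, registry = default_odorant_registry(),
                         figures = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dataset <- stage("generate",
                   generate_panel_dataset(config$generator, registry))
  stage("write-dataset", write_dataset(dataset, out("dataset.csv")))

  parts <- stage("split",
                 split_dataset(dataset, config$split$train_fraction,
                               config$split$seed))
  model <- stage("fit",
                 fit_intensity_model(parts$train, config$model$grid,
                                     config$model$cv_folds,
                                     config$model$seed))
  stage("save-model", save_intensity_model(model, out("model.rds")))

  evaluation <- stage("evaluate",
                      evaluate_model(model, parts$train, parts$test))
  jsonlite::write_json(unclass(evaluation), out("evaluation.json"),
                       auto_unbox = TRUE, digits = NA)

  surface <- stage("surface",
                   simulate_interaction_surface(
                     model, dataset, config$surface$resolution,
                     config$surface$min_oi_sum))
  stage("write-surface",
        write_surface_csv(surface, out("surface.csv"), registry))

  scatter <- stage("scatter", ratio_scatter(dataset, surface))
  stage("write-scatter", write_scatter_csv(scatter, out("scatter.csv")))

  summary <- stage("summarize", summarize_surface(scatter))
  jsonlite::write_json(unclass(summary), out("summary.json"),
                       auto_unbox = TRUE, digits = NA)

  if (figures) {
    stage("figures", {
      grDevices::png(out("figure_surface.png"), width = 1400, height = 1100,
                     res = 160)
      print(plot_interaction_surface(surface))
      grDevices::dev.off()
      grDevices::png(out("figure_scatter.png"), width = 1400, height = 1000,
                     res = 160)
      print(plot_ratio_scatter(scatter))
      grDevices::dev.off()
    })
  }

  log_lines <- c(
    "# odormix pipeline run",
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    "",
    "## resolved configuration",
    yaml::as.yaml(run_config_to_list(config)),
    "## selected hyperparameters",
    sprintf("selected_c: %g", model$selected_c),
    sprintf("selected_gamma: %g", model$selected_gamma),
    sprintf("epsilon: %g", model$epsilon),
    "",
    "## seeds",
    sprintf("generator_seed: %d", config$generator$seed),
    sprintf("split_seed: %d", config$split$seed),
    sprintf("cv_seed: %d", config$model$seed)
  )
  writeLines(log_lines, out("run.log"))

  invisible(list(
    dataset = dataset, model = model, evaluation = evaluation,
    surface = surface, scatter = scatter, summary = summary,
    paths = vapply(c("dataset.csv", "model.rds", "evaluation.json",
                     "surface.csv", "scatter.csv", "summary.json",
                     "run.log"), out, character(1))
  ))
}
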