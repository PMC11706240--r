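#' Run configuration
#'
#' One configuration object drives simulation and benchmarking end to end,
#' serializable to YAML so runs are reproducible from a single file.
#' Human and model sources are either paths to CSV tables or synthetic
#' specifications; a global seed is mandatory whenever any synthetic source
#' is present, and every stochastic stage (observer simulation, model
#' simulation, imputation) draws a child seed derived from it.
#'
#' @param seed Global integer seed.
#' @param design An [experiment_design()].
#' @param humans List: either `list(source = "synthetic", n_observers =,
#'   experiment =)` or `list(source = "path", path = <dir of trial CSVs>)`.
#' @param models List of model entries: `list(id =, source = "synthetic",
#'   profile =)` or `list(id =, source = "path", path = <prediction CSV>)`.
#' @param imputation `"random"` or `"drop"`.
#' @param normalization `"experiment"` (one untimed baseline per
#'   experiment, the default), `"observer"` (per-observer baselines), or
#'   `"none"`.
#' @param timestep_mapping `"index"` or `"affine"` (see [map_timesteps()]).
#' @param metrics A [benchmark_config()] or list of its arguments.
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       design = experiment_design(),
                       humans = list(source = "synthetic", n_observers = 8L,
                                     experiment = "gray_noise"),
                       models = list(
                         list(id = "gradual_wide", source = "synthetic",
                              profile = "gradual_wide"),
                         list(id = "steep_saturating", source = "synthetic",
                              profile = "steep_saturating"),
                         list(id = "shallow_low_range", source = "synthetic",
                              profile = "shallow_low_range")),
                       imputation = c("random", "drop"),
                       normalization = c("experiment", "observer", "none"),
                       timestep_mapping = c("index", "affine"),
                       metrics = benchmark_config(),
                       out_dir = "satbench_out") {
  if (!inherits(metrics, "benchmark_config"))
    metrics <- do.call(benchmark_config, as.list(metrics))
  if (!inherits(design, "experiment_design"))
    design <- do.call(experiment_design, as.list(design))
  cfg <- list(seed = if (is.null(seed)) NULL else as.integer(seed),
              design = design, humans = humans, models = models,
              imputation = match.arg(imputation),
              normalization = match.arg(normalization),
              timestep_mapping = match.arg(timestep_mapping),
              metrics = metrics, out_dir = out_dir)
  synthetic <- identical(humans$source, "synthetic") ||
    any(vapply(models, function(m) identical(m$source, "synthetic"),
               logical(1)))
  if (synthetic && is.null(cfg$seed))
    stop("a seed is required when any synthetic source is present")
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(run_config))
  extra <- setdiff(names(raw), allowed)
  if (length(extra))
    stop("unknown run_config fields: ", paste(extra, collapse = ", "))
  do.call(run_config, raw)
}

note <- function(fmt, ...) message(sprintf(fmt, ...))

# ---- source resolution ------------------------------------------------------

load_human_tables <- function(config) {
  h <- config$humans
  design <- config$design
  if (identical(h$source, "synthetic")) {
    n <- as.integer(h$n_observers %||% 8L)
    seeds <- derive_seeds(config$seed, n)
    tabs <- lapply(seq_len(n), function(i) {
      spec <- observer_spec(observer_id = sprintf("synth_obs_%02d", i),
                            experiment = h$experiment %||% "gray_noise",
                            seed = seeds[i])
      simulate_observer(spec, design)
    })
    names(tabs) <- sprintf("synth_obs_%02d", seq_len(n))
    tabs
  } else {
    files <- sort(list.files(h$path, pattern = "\\.csv$", full.names = TRUE))
    if (length(files) == 0L)
      stop("human input: no trial CSV files found in ", h$path)
    tabs <- lapply(files, read_trials, design = design,
                   col_map = h$col_map %||% NULL)
    names(tabs) <- vapply(tabs, function(tt) tt$observer_id[1L], character(1))
    tabs
  }
}

load_model_tables <- function(config) {
  design <- config$design
  seeds <- derive_seeds(config$seed %||% 1L, length(config$models) + 1000L)
  tabs <- list()
  for (i in seq_along(config$models)) {
    m <- config$models[[i]]
    if (is.null(m$id)) stop("every model entry needs an id")
    if (identical(m$source, "synthetic")) {
      spec <- model_observer_spec(
        model_id = m$id, profile = m$profile %||% "gradual_wide",
        experiment = m$experiment %||% config$humans$experiment %||%
          "gray_noise",
        n_images = m$n_images %||% 200L, seed = seeds[1000L + i])
      tabs[[m$id]] <- simulate_model_observer(spec, design)
    } else {
      tabs[[m$id]] <- read_model_predictions(m$path, design)
    }
  }
  tabs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- pipeline stages --------------------------------------------------------

# QC + imputation + curve construction for a set of human trial tables.
# Returns benchmark-ready entries plus stage counts and baselines.
prepare_humans <- function(tables, config) {
  design <- config$design
  all_trials <- do.call(rbind, tables)
  n_total <- length(unique(all_trials$observer_id))

  qc <- filter_observers(all_trials, design)
  kept <- qc$kept
  note("observers: %d total, %d kept, %d excluded", n_total,
       length(unique(kept$observer_id)), length(qc$excluded))
  if (length(unique(kept$observer_id)) == 0L)
    stop("all observers excluded by the acceptance-window rule")

  n_before <- nrow(kept)
  kept <- discard_warmup(kept, design)
  n_warmup <- n_before - nrow(kept)
  note("warm-up discard: %d trials removed", n_warmup)

  n_missing <- sum(kept$phase == "timed" & is.na(kept$response_category))
  # child-seed slots: humans take 1..n_observers, models 1001.., imputation 901
  imp_seed <- derive_seeds(config$seed %||% 1L, 901L)[901L]
  kept <- impute_missing(kept, mode = config$imputation, seed = imp_seed,
                         design = design)
  note("imputation (%s): %d missing responses handled", config$imputation,
       n_missing)

  baselines <- untimed_accuracy(kept, by = c("observer_id", "experiment"))
  exp_baseline <- untimed_accuracy(kept, by = "experiment")

  entries <- list()
  for (oid in unique(kept$observer_id)) {
    sub <- kept[kept$observer_id == oid, , drop = FALSE]
    expname <- sub$experiment[1L]
    baseline <- switch(config$normalization,
      none = NA_real_,
      experiment = exp_baseline$untimed_accuracy[
        exp_baseline$experiment == expname],
      observer = baselines$untimed_accuracy[
        baselines$observer_id == oid & baselines$experiment == expname])
    level_curves <- compute_curves(sub, design)
    cat_curves <- compute_curves(sub, design, by_category = TRUE)
    raw_family <- to_family(level_curves)
    if (config$normalization != "none" && config$metrics$use_normalized) {
      level_curves <- lapply(level_curves, normalize_curve, baseline)
      cat_curves <- lapply(cat_curves, normalize_curve, baseline)
    }
    entries[[oid]] <- list(family = to_family(level_curves),
                           category_curves = cat_curves,
                           raw_family = raw_family,
                           baseline = baseline)
  }
  pooled <- compute_curves(kept, design, per_observer = FALSE)
  list(entries = entries, excluded = qc$excluded,
       baselines = exp_baseline, pooled_curves = pooled,
       counts = list(observers_total = n_total,
                     observers_kept = length(entries),
                     observers_excluded = length(qc$excluded),
                     warmup_discarded = n_warmup,
                     missing_handled = n_missing))
}

# Model prediction tables -> benchmark-ready entries on the human time axis.
prepare_models <- function(tables, humans_prep, config) {
  design <- config$design
  entries <- list()
  for (mid in names(tables)) {
    level_curves <- prediction_curves(tables[[mid]], design, id = mid)
    cat_curves <- prediction_curves(tables[[mid]], design, id = mid,
                                    by_category = TRUE)
    map_one <- function(cv) {
      if (config$timestep_mapping == "index")
        return(map_timesteps(cv, design, mode = "index"))
      ref <- Filter(function(p) isTRUE(all.equal(p$level, cv$level)) &&
                      identical(p$kind, cv$kind), humans_prep$pooled_curves)
      ref <- if (length(ref)) ref[[1L]] else humans_prep$pooled_curves[[1L]]
      map_timesteps(cv, design, mode = "affine", reference = ref)
    }
    level_curves <- lapply(level_curves, map_one)
    cat_curves <- lapply(cat_curves, map_one)
    raw_family <- to_family(level_curves)
    if (config$normalization != "none" && config$metrics$use_normalized) {
      expname <- config$humans$experiment %||%
        humans_prep$baselines$experiment[1L]
      baseline <- humans_prep$baselines$untimed_accuracy[
        humans_prep$baselines$experiment == expname]
      if (length(baseline) == 0L)
        baseline <- humans_prep$baselines$untimed_accuracy[1L]
      level_curves <- lapply(level_curves, normalize_curve, baseline)
      cat_curves <- lapply(cat_curves, normalize_curve, baseline)
    }
    entries[[mid]] <- list(family = to_family(level_curves),
                           category_curves = cat_curves,
                           raw_family = raw_family)
  }
  entries
}

#' Simulate configured inputs to disk
#'
#' Writes one trial CSV per synthetic human observer and one prediction CSV
#' per synthetic model, plus `manifest.json` recording the design, specs
#' and derived seeds; rerunning with the same manifest reproduces the files
#' byte for byte.
#'
#' @param config A [run_config()].
#' @return Invisibly, the output directory.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(file.path(out, "humans"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "models"), recursive = TRUE, showWarnings = FALSE)
  humans <- load_human_tables(config)
  models <- load_model_tables(config)
  for (oid in names(humans))
    write_trials(humans[[oid]], file.path(out, "humans",
                                          paste0(oid, ".csv")), config$design)
  for (mid in names(models))
    write_model_predictions(models[[mid]],
                            file.path(out, "models", paste0(mid, ".csv")),
                            config$design)
  manifest <- list(seed = config$seed,
                   design = unclass(config$design),
                   humans = config$humans, models = config$models,
                   files = list(humans = paste0(names(humans), ".csv"),
                                models = paste0(names(models), ".csv")))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  note("wrote %d human and %d model tables to %s", length(humans),
       length(models), out)
  invisible(out)
}

#' Run the full benchmark pipeline
#'
#' Loads (or simulates) human trial tables and model prediction tables,
#' applies observer exclusion, warm-up discard and imputation, builds
#' normalized SAT curves and curve families, maps model timesteps onto the
#' reaction-time axis, computes the three comparison metrics via
#' [benchmark()], and writes the report (comparisons and steepness CSVs,
#' summaries JSON, and a human-readable `summary.txt` with per-stage record
#' counts) to `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return The `metric_report`, invisibly.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "run_config"))
  human_tables <- load_human_tables(config)
  model_tables <- load_model_tables(config)
  hp <- prepare_humans(human_tables, config)
  mp <- prepare_models(model_tables, hp, config)
  report <- benchmark(mp, hp$entries, config$design, config$metrics)

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_metric_report(report, out)
  lines <- c("SAT benchmark run",
             sprintf("seed: %s", config$seed %||% "none"),
             sprintf("observers: %d total = %d kept + %d excluded",
                     hp$counts$observers_total, hp$counts$observers_kept,
                     hp$counts$observers_excluded),
             sprintf("missing responses handled (%s): %d",
                     config$imputation, hp$counts$missing_handled),
             sprintf("untimed baselines: %s",
                     paste(sprintf("%s=%.3f", hp$baselines$experiment,
                                   hp$baselines$untimed_accuracy),
                           collapse = ", ")),
             "", utils::capture.output(print(report)))
  writeLines(lines, file.path(out, "summary.txt"))
  note("report written to %s", out)
  invisible(report)
}
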