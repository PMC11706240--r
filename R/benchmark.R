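#' Benchmark configuration
#'
#' Metric defaults for [benchmark()] and the end-to-end pipeline.
#'
#' @param use_normalized Compare curve families and category curves in
#'   normalized units (fractions of untimed human accuracy); raw units
#'   otherwise.
#' @param steepness_scale `"loglog"` or `"linear"` (see [steepness()]).
#' @param steepness_grid_n Grid size for the curvature evaluation.
#' @param fix_gamma Fix the Weibull guess rate at chance when fitting.
#' @param human_steepness `"pooled"` fits the average (pooled) human curve
#'   per level; `"per_observer"` fits each observer and averages the
#'   steepness values.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(use_normalized = TRUE,
                             steepness_scale = "loglog",
                             steepness_grid_n = 101L,
                             fix_gamma = TRUE,
                             human_steepness = c("pooled", "per_observer")) {
  cfg <- list(use_normalized = isTRUE(use_normalized),
              steepness_scale = match.arg(steepness_scale,
                                          c("loglog", "linear")),
              steepness_grid_n = as.integer(steepness_grid_n),
              fix_gamma = isTRUE(fix_gamma),
              human_steepness = match.arg(human_steepness))
  class(cfg) <- "benchmark_config"
  cfg
}

# Mean of curve-family matrices sharing axes -> the "average observer".
average_family <- function(families) {
  stopifnot(length(families) >= 1L)
  ref <- families[[1L]]
  for (f in families[-1L]) {
    if (!identical(dim(f$c), dim(ref$c)) ||
        !isTRUE(all.equal(f$times, ref$times)) ||
        !isTRUE(all.equal(f$perturbation_levels, ref$perturbation_levels)))
      stop("families must share axes to be averaged")
  }
  avg <- ref
  avg$c <- Reduce(`+`, lapply(families, `[[`, "c")) / length(families)
  avg
}

# Element-wise average of aligned per-category curve lists.
average_category_curves <- function(curve_lists) {
  flats <- lapply(curve_lists, flatten_category_curves)
  cats <- flats[[1L]]$categories
  for (f in flats[-1L])
    if (!identical(f$categories, cats)) stop("category sets differ")
  template <- curve_lists[[1L]]
  template <- template[order(vapply(template, function(cv) cv$category,
                                    character(1)))]
  npt <- length(strip_anchor(template[[1L]])$times)
  avg_vals <- Reduce(`+`, lapply(flats, `[[`, "values")) / length(flats)
  lapply(seq_along(cats), function(i) {
    cv <- strip_anchor(template[[i]])
    cv$id <- "human_average"
    cv$accuracies <- avg_vals[((i - 1L) * npt + 1L):(i * npt)]
    cv
  })
}

steepness_of_family <- function(family, id, design, cfg) {
  rows <- lapply(seq_len(nrow(family$c)), function(p) {
    cv <- sat_curve(id = id, times = family$times,
                    accuracies = pmin(family$c[p, ], 1),
                    n_trials = rep(0L, length(family$times)),
                    se = rep(NA_real_, length(family$times)),
                    level = family$perturbation_levels[p])
    fit <- fit_weibull(cv, design, fix_gamma = cfg$fix_gamma)
    data.frame(id = id, perturbation_level = family$perturbation_levels[p],
               steepness = if (fit$degenerate) NA_real_ else
                 steepness(fit$params, range(family$times),
                           cfg$steepness_grid_n, cfg$steepness_scale),
               tau = fit$params$tau, beta = fit$params$beta,
               lam = fit$params$lam, degenerate = fit$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

summarize_comparisons <- function(comparisons) {
  keys <- unique(comparisons[c("model_id", "metric")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- comparisons[comparisons$model_id == keys$model_id[i] &
                         comparisons$metric == keys$metric[i], ]
    vals <- sub$value[!sub$degenerate]
    n_deg <- sum(sub$degenerate)
    if (length(vals) == 0L)
      return(data.frame(model_id = keys$model_id[i],
                        metric = keys$metric[i], n = 0L,
                        n_degenerate = n_deg, median = NA_real_,
                        q1 = NA_real_, q3 = NA_real_,
                        n_outliers = 0L, stringsAsFactors = FALSE))
    q <- stats::quantile(vals, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3L] - q[1L]
    out <- vals < q[1L] - 1.5 * iqr | vals > q[3L] + 1.5 * iqr
    data.frame(model_id = keys$model_id[i], metric = keys$metric[i],
               n = length(vals), n_degenerate = n_deg,
               median = q[2L], q1 = q[1L], q3 = q[3L],
               n_outliers = sum(out), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benchmark model observers against human observers
#'
#' Assembles the three comparison metrics into one report.  For every
#' (model, observer) pair the curve-fit error [rmse_fit_error()] over the
#' perturbation family and, where per-category curves are supplied, the
#' [categorywise_correlation()] are computed.  A `"human"` baseline row
#' compares the average human family (and average per-category curves) to
#' each individual observer — the irreducible inter-observer disagreement a
#' model cannot be expected to beat.  Steepness is computed per curve and
#' perturbation level from Weibull fits to the raw families.  Summaries
#' give median, quartiles and 1.5 x IQR outlier counts per model and
#' metric; degenerate values are excluded and counted.
#'
#' @param models Named list; each element has `family` (a `curve_family`
#'   in the units selected by `config`), optional `category_curves` (list
#'   of per-category [sat_curve()]s), and optional `raw_family` (raw
#'   units, used for steepness; defaults to `family` when that is raw).
#' @param humans Named list of the same structure, one element per
#'   observer.
#' @param design An [experiment_design()].
#' @param config A [benchmark_config()].
#' @return An object of class `metric_report` with `comparisons`,
#'   `summaries`, and `steepness_table` data frames.
#' @export
benchmark <- function(models, humans, design = experiment_design(),
                      config = benchmark_config()) {
  if (length(models) == 0L) stop("no model observers supplied")
  if (length(humans) == 0L) stop("no human observers supplied")
  if (is.null(names(models)) || is.null(names(humans)))
    stop("models and humans must be named lists")

  have_cats <- !is.null(models[[1L]]$category_curves) &&
    !is.null(humans[[1L]]$category_curves)

  human_avg <- average_family(lapply(humans, `[[`, "family"))
  entries <- c(models, list(human = list(
    family = human_avg,
    category_curves = if (have_cats)
      average_category_curves(lapply(humans, `[[`, "category_curves")))))

  rows <- list()
  for (mid in names(entries)) {
    m <- entries[[mid]]
    for (oid in names(humans)) {
      h <- humans[[oid]]
      e <- rmse_fit_error(m$family, h$family)
      rows[[length(rows) + 1L]] <- data.frame(
        model_id = mid, observer_id = oid, metric = "rmse",
        value = as.numeric(e), degenerate = is_degenerate(e),
        stringsAsFactors = FALSE)
      if (have_cats && !is.null(m$category_curves)) {
        r <- categorywise_correlation(m$category_curves, h$category_curves)
        rows[[length(rows) + 1L]] <- data.frame(
          model_id = mid, observer_id = oid, metric = "spearman",
          value = as.numeric(r), degenerate = is_degenerate(r),
          stringsAsFactors = FALSE)
      }
    }
  }
  comparisons <- do.call(rbind, rows)

  raw_of <- function(entry, fallback) {
    if (!is.null(entry$raw_family)) return(entry$raw_family)
    if (!entry$family$normalized) return(entry$family)
    fallback
  }
  steep <- list()
  for (mid in names(models)) {
    fam <- raw_of(models[[mid]], NULL)
    if (!is.null(fam))
      steep[[length(steep) + 1L]] <-
        steepness_of_family(fam, mid, design, config)
  }
  human_raws <- lapply(humans, raw_of, fallback = NULL)
  human_raws <- human_raws[!vapply(human_raws, is.null, logical(1))]
  if (length(human_raws)) {
    if (config$human_steepness == "pooled") {
      steep[[length(steep) + 1L]] <-
        steepness_of_family(average_family(human_raws), "human_average",
                            design, config)
    } else {
      per_obs <- do.call(rbind, lapply(names(human_raws), function(oid)
        steepness_of_family(human_raws[[oid]], oid, design, config)))
      agg <- stats::aggregate(steepness ~ perturbation_level, per_obs, mean)
      agg <- data.frame(id = "human_average",
                        perturbation_level = agg$perturbation_level,
                        steepness = agg$steepness, tau = NA_real_,
                        beta = NA_real_, lam = NA_real_, degenerate = FALSE,
                        stringsAsFactors = FALSE)
      steep[[length(steep) + 1L]] <- rbind(per_obs, agg)
    }
  }
  steepness_table <- if (length(steep)) do.call(rbind, steep) else NULL
  if (!is.null(steepness_table)) rownames(steepness_table) <- NULL

  report <- list(comparisons = comparisons,
                 summaries = summarize_comparisons(comparisons),
                 steepness_table = steepness_table,
                 config = config)
  class(report) <- "metric_report"
  report
}

#' @export
print.metric_report <- function(x, ...) {
  cat("SAT benchmark report\n\nSummaries (per model and metric):\n")
  print(x$summaries, row.names = FALSE, digits = 4)
  if (!is.null(x$steepness_table)) {
    cat("\nSteepness (per curve and perturbation level):\n")
    print(x$steepness_table, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Write a metric report to disk
#'
#' Writes `comparisons.csv` and `steepness.csv` (long format) plus
#' `summaries.json` into a directory.
#'
#' @param report A `metric_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_metric_report <- function(report, dir) {
  stopifnot(inherits(report, "metric_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE, na = "NA")
  if (!is.null(report$steepness_table))
    utils::write.csv(report$steepness_table, file.path(dir, "steepness.csv"),
                     row.names = FALSE, na = "NA")
  jsonlite::write_json(report$summaries, file.path(dir, "summaries.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}
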