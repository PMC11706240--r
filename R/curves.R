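#' Speed-accuracy trade-off curve
#'
#' One SAT curve: accuracy as a function of reaction time (humans) or
#' timestep (model observers) for a single condition.  Times must be
#' strictly increasing and all per-point vectors equally long.  The optional
#' chance anchor at time 0 is flagged via `anchored` and is ignored by every
#' metric operation.
#'
#' @param id Observer or model identifier.
#' @param times Strictly increasing reaction times (ms) or timestep indices.
#' @param accuracies Fraction correct per point (raw curves lie in \[0, 1\];
#'   normalized curves may exceed 1).
#' @param n_trials Integer trial counts per point.
#' @param se Standard error per point (`sqrt(a (1 - a) / n)` for raw
#'   binomial curves).
#' @param kind,level Perturbation kind and level of the condition.
#' @param category Optional category label for per-category curves.
#' @param experiment Experiment label.
#' @param normalized Logical: accuracies expressed as a fraction of untimed
#'   baseline accuracy.
#' @param anchored Logical: a chance point at time 0 is attached.
#' @return An object of class `sat_curve`.
#' @export
sat_curve <- function(id, times, accuracies, n_trials = rep(0L, length(times)),
                      se = rep(NA_real_, length(times)),
                      kind = NA_character_, level = NA_real_,
                      category = NA_character_, experiment = NA_character_,
                      normalized = FALSE, anchored = FALSE) {
  times <- as.numeric(times)
  accuracies <- as.numeric(accuracies)
  if (length(times) != length(accuracies) ||
      length(times) != length(n_trials) || length(times) != length(se))
    stop("times, accuracies, n_trials and se must have equal length")
  if (length(times) == 0L) stop("a curve needs at least one point")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (!normalized && any(accuracies < 0 | accuracies > 1))
    stop("raw accuracies must lie in [0, 1]")
  curve <- list(id = id, times = times, accuracies = accuracies,
                n_trials = as.integer(n_trials), se = as.numeric(se),
                kind = kind, level = as.numeric(level), category = category,
                experiment = experiment, normalized = isTRUE(normalized),
                anchored = isTRUE(anchored))
  class(curve) <- "sat_curve"
  curve
}

#' @export
print.sat_curve <- function(x, ...) {
  cat(sprintf("SAT curve [%s] %s level %g%s%s%s\n", x$id,
              ifelse(is.na(x$kind), "?", x$kind),
              ifelse(is.na(x$level), 0, x$level),
              if (!is.na(x$category)) paste0(" category ", x$category) else "",
              if (x$normalized) " (normalized)" else "",
              if (x$anchored) " (anchored)" else ""))
  print(data.frame(time = x$times, accuracy = round(x$accuracies, 4),
                   n = x$n_trials, se = round(x$se, 4)))
  invisible(x)
}

# Drop the visualization-only chance anchor before any metric computation.
strip_anchor <- function(curve) {
  if (!inherits(curve, "sat_curve")) stop("not a sat_curve")
  if (!curve$anchored) return(curve)
  keep <- -1L
  curve$times <- curve$times[keep]
  curve$accuracies <- curve$accuracies[keep]
  curve$n_trials <- curve$n_trials[keep]
  curve$se <- curve$se[keep]
  curve$anchored <- FALSE
  curve
}

#' Exclude observers with too many off-beep responses
#'
#' Applies the observer-level quality rule of the beep paradigm: an observer
#' is excluded when the fraction of their timed trials falling outside the
#' acceptance window around the beep (missing responses count as outside)
#' reaches `design$exclusion_outside_fraction`.  The boundary is inclusive:
#' exactly 50% outside under the default design means exclusion.
#'
#' @param trials A trial data frame.
#' @param design An [experiment_design()].
#' @return A list with `kept` (trials of retained observers, unchanged),
#'   `excluded` (character vector of excluded observer ids), and
#'   `outside_fraction` (named vector of per-observer fractions).
#' @export
filter_observers <- function(trials, design = experiment_design()) {
  validate_trials(trials, design)
  timed <- trials[trials$phase == "timed", , drop = FALSE]
  if (nrow(timed) == 0L)
    return(list(kept = trials, excluded = character(),
                outside_fraction = stats::setNames(numeric(), character())))
  outside <- is.na(timed$response_time_ms) |
    abs(timed$response_time_ms - timed$beep_latency_ms) >
      design$acceptance_window_ms
  frac <- tapply(outside, timed$observer_id, mean)
  excluded <- names(frac)[frac >= design$exclusion_outside_fraction]
  kept <- trials[!trials$observer_id %in% excluded, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded = excluded,
       outside_fraction = stats::setNames(as.numeric(frac), names(frac)))
}

#' Discard warm-up trials
#'
#' Removes the first `design$warmup_discard` trials of every timed block;
#' observers are assumed to use them to adapt to the block's beep timing.
#' Training trials are untouched.
#'
#' @inheritParams filter_observers
#' @return The reduced trial data frame.
#' @export
discard_warmup <- function(trials, design = experiment_design()) {
  validate_trials(trials, design)
  drop <- trials$phase == "timed" & trials$trial_index <= design$warmup_discard
  out <- trials[!drop, , drop = FALSE]
  if (any(trials$phase == "timed") && design$warmup_discard > 0) {
    timed <- trials[trials$phase == "timed", , drop = FALSE]
    sizes <- table(interaction(timed$observer_id, timed$block_index,
                               drop = TRUE))
    if (any(sizes <= design$warmup_discard))
      warning("some timed blocks are empty after warm-up discard")
  }
  rownames(out) <- NULL
  out
}

#' Handle missing responses
#'
#' Implements the two treatments of trials where the observer failed to
#' respond: `"random"` replaces each missing response with a uniformly
#' drawn category (the imputation used for the main analysis; it biases
#' measured accuracy toward chance by a known amount), and `"drop"` removes
#' those trials.  Imputed trials get a nominal response time equal to the
#' beep latency, recording that no actual response occurred at a measured
#' time.
#'
#' @inheritParams filter_observers
#' @param mode `"random"` or `"drop"`.
#' @param seed Integer seed for the random draws (required for `"random"`
#'   reproducibility).
#' @return The trial data frame with no missing responses.
#' @export
impute_missing <- function(trials, mode = c("random", "drop"), seed = NULL,
                           design = experiment_design()) {
  mode <- match.arg(mode)
  validate_trials(trials, design)
  miss <- which(trials$phase == "timed" & is.na(trials$response_category))
  if (length(miss) == 0L) return(trials)
  if (mode == "drop") {
    out <- trials[-miss, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  with_seed(seed, {
    trials$response_category[miss] <-
      sample(design$categories, length(miss), replace = TRUE)
    trials$response_time_ms[miss] <- trials$beep_latency_ms[miss]
    trials
  })
}

#' Untimed (training) accuracy
#'
#' Fraction of correct responses on training trials, where no response
#' deadline applies.  This is the normalization baseline of SAT curves:
#' timed accuracies are expressed as a fraction of it.
#'
#' @inheritParams filter_observers
#' @param by Optional character vector of grouping columns (e.g.
#'   `"experiment"`, `"observer_id"`).
#' @return A single fraction, or a data frame with one row per group and an
#'   `untimed_accuracy` column when `by` is given.
#' @export
untimed_accuracy <- function(trials, by = NULL) {
  training <- trials[trials$phase == "training", , drop = FALSE]
  if (nrow(training) == 0L) stop("no training trials present")
  correct <- training$response_category == training$true_category
  if (is.null(by)) return(mean(correct))
  stopifnot(all(by %in% names(training)))
  agg <- stats::aggregate(correct,
                          by = training[, by, drop = FALSE],
                          FUN = mean)
  names(agg)[ncol(agg)] <- "untimed_accuracy"
  agg
}

#' Build SAT curves from timed trials
#'
#' Aggregates QC'd, imputed timed trials into SAT curves: at every beep
#' latency the accuracy is the fraction of correct responses, with binomial
#' standard error `sqrt(a (1 - a) / n)`.  By default one curve is produced
#' per perturbation condition; with `by_category = TRUE` one curve is
#' produced per true category instead, pooling over perturbation conditions
#' (the grouping used by the category-wise correlation metric, which keeps
#' per-point trial counts workable).  Latencies with no trials in a group
#' are omitted with a warning; empty groups are dropped.
#'
#' @inheritParams filter_observers
#' @param by_category Split curves by true category (pooling conditions)
#'   instead of by perturbation condition.
#' @param per_observer One curve per observer (default); otherwise trials
#'   are pooled over observers into a single group curve per condition.
#' @return A list of [sat_curve()] objects.
#' @export
compute_curves <- function(trials, design = experiment_design(),
                           by_category = FALSE, per_observer = TRUE) {
  validate_trials(trials, design)
  timed <- trials[trials$phase == "timed", , drop = FALSE]
  if (nrow(timed) == 0L) stop("no timed trials present")
  if (anyNA(timed$response_category))
    stop("missing responses present; run impute_missing() first")
  id <- if (per_observer) timed$observer_id else "pooled"
  keys <- data.frame(id = id, experiment = timed$experiment,
                     stringsAsFactors = FALSE)
  if (by_category) {
    keys$kind <- NA_character_
    keys$level <- NA_real_
    keys$category <- timed$true_category
  } else {
    keys$kind <- timed$perturbation_kind
    keys$level <- timed$perturbation_level
  }
  key_str <- do.call(paste, c(keys, sep = "\r"))
  groups <- split(seq_len(nrow(timed)), key_str)
  curves <- lapply(groups, function(idx) {
    sub <- timed[idx, , drop = FALSE]
    k <- keys[idx[1L], , drop = FALSE]
    lat <- design$beep_latencies_ms
    acc <- n <- numeric(length(lat))
    for (i in seq_along(lat)) {
      at <- sub[sub$beep_latency_ms == lat[i], , drop = FALSE]
      n[i] <- nrow(at)
      acc[i] <- if (n[i] > 0)
        mean(at$response_category == at$true_category) else NA_real_
    }
    present <- n > 0
    if (!any(present)) return(NULL)
    if (!all(present))
      warning(sprintf("group %s has no trials at latencies %s; points omitted",
                      paste(unlist(k), collapse = "/"),
                      paste(lat[!present], collapse = ", ")))
    acc <- acc[present]; n <- n[present]; lat <- lat[present]
    sat_curve(id = k$id, times = lat, accuracies = acc, n_trials = n,
              se = sqrt(acc * (1 - acc) / n),
              kind = k$kind, level = k$level,
              category = if (by_category) k$category else NA_character_,
              experiment = k$experiment)
  })
  curves <- curves[!vapply(curves, is.null, logical(1))]
  ord <- order(vapply(curves, function(cv) cv$id, character(1)),
               vapply(curves, function(cv) cv$level, numeric(1)),
               vapply(curves, function(cv) cv$category, character(1)))
  unname(curves[ord])
}

#' Per-timestep accuracy curves of a model observer
#'
#' Aggregates a prediction table into one curve per condition (and
#' optionally per category) over timesteps, the analog of [compute_curves()]
#' for model observers.  Times are timestep indices until mapped to
#' reaction times with [map_timesteps()].
#'
#' @param predictions A prediction data frame (see [trial-table]).
#' @param design An [experiment_design()].
#' @param id Model identifier attached to the curves.
#' @param by_category Split by true category (pooling over perturbation
#'   conditions) instead of by condition.
#' @param experiment Experiment label attached to the curves.
#' @return A list of [sat_curve()] objects.
#' @export
prediction_curves <- function(predictions, design = experiment_design(),
                              id = "model", by_category = FALSE,
                              experiment = NA_character_) {
  validate_model_predictions(predictions, design)
  if (nrow(predictions) == 0L) stop("no predictions present")
  if (by_category) {
    keys <- data.frame(kind = NA_character_, level = NA_real_,
                       category = predictions$true_category,
                       stringsAsFactors = FALSE)
  } else {
    keys <- data.frame(kind = predictions$perturbation_kind,
                       level = predictions$perturbation_level,
                       stringsAsFactors = FALSE)
  }
  key_str <- do.call(paste, c(keys, sep = "\r"))
  groups <- split(seq_len(nrow(predictions)), key_str)
  curves <- lapply(groups, function(idx) {
    sub <- predictions[idx, , drop = FALSE]
    k <- keys[idx[1L], , drop = FALSE]
    ts <- sort(unique(sub$timestep))
    acc <- n <- numeric(length(ts))
    for (i in seq_along(ts)) {
      at <- sub[sub$timestep == ts[i], , drop = FALSE]
      n[i] <- nrow(at)
      acc[i] <- mean(at$predicted_category == at$true_category)
    }
    sat_curve(id = id, times = ts, accuracies = acc, n_trials = n,
              se = sqrt(acc * (1 - acc) / pmax(n, 1)),
              kind = k$kind, level = k$level,
              category = if (by_category) k$category else NA_character_,
              experiment = experiment)
  })
  ord <- order(vapply(curves, function(cv) cv$level, numeric(1)),
               vapply(curves, function(cv) cv$category, character(1)))
  unname(curves[ord])
}

#' Normalize a curve by untimed accuracy
#'
#' Divides accuracies and standard errors by a baseline (the untimed human
#' accuracy of the matching experiment), so curves read as fractions of
#' untimed performance and may exceed 1.
#'
#' @param curve A [sat_curve()].
#' @param baseline Positive baseline accuracy (see [untimed_accuracy()]).
#' @return The normalized curve.
#' @export
normalize_curve <- function(curve, baseline) {
  stopifnot(inherits(curve, "sat_curve"))
  if (!is.numeric(baseline) || length(baseline) != 1L || baseline <= 0)
    stop("baseline must be a single positive number")
  curve$accuracies <- curve$accuracies / baseline
  curve$se <- curve$se / baseline
  curve$normalized <- TRUE
  curve
}

#' Attach the chance anchor at time zero
#'
#' Prepends a visualization-only point at time/timestep 0 with accuracy
#' equal to chance (6.25% for the 16-way task; divided by `baseline` for
#' normalized curves).  The point is flagged and ignored by every metric
#' operation.
#'
#' @param curve A [sat_curve()].
#' @param design An [experiment_design()].
#' @param baseline Baseline used when the curve is normalized.
#' @return The anchored curve.
#' @export
add_chance_anchor <- function(curve, design = experiment_design(),
                              baseline = NULL) {
  stopifnot(inherits(curve, "sat_curve"))
  if (curve$anchored) stop("curve is already anchored")
  anchor <- chance_accuracy(design)
  if (curve$normalized) {
    if (is.null(baseline))
      stop("baseline required to anchor a normalized curve")
    anchor <- anchor / baseline
  }
  curve$times <- c(0, curve$times)
  curve$accuracies <- c(anchor, curve$accuracies)
  curve$n_trials <- c(0L, curve$n_trials)
  curve$se <- c(0, curve$se)
  curve$anchored <- TRUE
  curve
}

#' Map model timesteps to reaction times
#'
#' Places a model curve defined over timestep indices on the human
#' reaction-time axis.  With `mode = "index"` (the default) timestep *i*
#' simply receives the *i*-th beep latency, which is well defined because
#' the number of timesteps equals the number of timed blocks.  With
#' `mode = "affine"` the mapping is `time = a * i + b` with `a > 0`, and
#' `(a, b)` chosen to minimize the squared error between the model
#' accuracies and the reference curve linearly interpolated at the mapped
#' times — an unconstrained linear mapping in both processing speed and
#' onset delay.  A flat reference leaves the fit unidentified; the function
#' then falls back to index mapping with a warning.
#'
#' @param model_curve A [sat_curve()] over timestep indices.
#' @param design An [experiment_design()].
#' @param mode `"index"` or `"affine"`.
#' @param reference Reference (human) [sat_curve()] over reaction times;
#'   required for `mode = "affine"`.
#' @return The curve with `times` in milliseconds.
#' @export
map_timesteps <- function(model_curve, design = experiment_design(),
                          mode = c("index", "affine"), reference = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model_curve, "sat_curve"))
  curve <- strip_anchor(model_curve)
  if (mode == "index") {
    if (length(curve$times) != design$n_timed_blocks)
      stop(sprintf("index mapping needs exactly %d timesteps, got %d",
                   design$n_timed_blocks, length(curve$times)))
    curve$times <- design$beep_latencies_ms
    return(curve)
  }
  if (is.null(reference)) stop("affine mapping requires a reference curve")
  ref <- strip_anchor(reference)
  if (stats::sd(ref$accuracies) < 1e-10) {
    warning("flat reference curve; falling back to index mapping")
    return(map_timesteps(curve, design, mode = "index"))
  }
  idx <- seq_along(curve$times)
  obj <- function(par) {
    a <- par[1L]; b <- par[2L]
    pred <- stats::approx(ref$times, ref$accuracies, xout = a * idx + b,
                          rule = 2)$y
    sum((curve$accuracies - pred)^2)
  }
  span <- diff(range(design$beep_latencies_ms)) /
    max(1L, length(idx) - 1L)
  starts <- rbind(
    c(span, design$beep_latencies_ms[1L] - span),
    c(span / 2, design$beep_latencies_ms[1L]),
    c(2 * span, 0))
  fits <- apply(starts, 1L, function(s) {
    stats::optim(s, obj, method = "L-BFGS-B",
                 lower = c(1e-6, -Inf), upper = c(Inf, Inf))
  })
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best_val <- min(vals)
  near <- which(vals <= best_val + 1e-9)
  slopes <- vapply(fits[near], function(f) f$par[1L], numeric(1))
  best <- fits[[near[which.min(slopes)]]]
  curve$times <- best$par[1L] * idx + best$par[2L]
  curve
}

#' Curve family over perturbation levels
#'
#' Assembles per-level curves sharing one time axis into the
#' `N_p x N_t` accuracy matrix `c[p, t]` that the curve-fit error consumes.
#' The unperturbed level-0 condition must be part of the family, matching
#' the analysis convention that noise 0 (gray) and blur 0 (color) belong to
#' the noise and blur families.
#'
#' @param curves List of [sat_curve()] objects, one per perturbation level,
#'   with identical time axes (anchors are stripped).
#' @return An object of class `curve_family` with fields
#'   `perturbation_levels`, `times`, and matrix `c`.
#' @export
to_family <- function(curves) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "sat_curve")))
  curves <- lapply(curves, strip_anchor)
  times <- curves[[1L]]$times
  for (cv in curves)
    if (!isTRUE(all.equal(cv$times, times)))
      stop("mismatched time axes across family curves")
  levels <- vapply(curves, function(cv) cv$level, numeric(1))
  if (anyNA(levels)) stop("every family curve needs a perturbation level")
  if (anyDuplicated(levels)) stop("duplicate perturbation level in family")
  if (!any(levels == 0))
    stop("family must include the unperturbed level-0 curve")
  ord <- order(levels)
  mat <- do.call(rbind, lapply(curves[ord], function(cv) cv$accuracies))
  fam <- list(perturbation_levels = levels[ord], times = times,
              c = mat, normalized = curves[[1L]]$normalized)
  class(fam) <- "curve_family"
  fam
}

#' @export
print.curve_family <- function(x, ...) {
  cat(sprintf("Curve family: %d levels x %d times%s\n",
              nrow(x$c), ncol(x$c),
              if (x$normalized) " (normalized)" else ""))
  m <- round(x$c, 4)
  dimnames(m) <- list(paste0("level=", x$perturbation_levels),
                      paste0("t=", x$times))
  print(m)
  invisible(x)
}

#' Serialize a curve family to long-format CSV
#'
#' @param family A `curve_family`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_family <- function(family, path) {
  stopifnot(inherits(family, "curve_family"))
  long <- expand.grid(level = family$perturbation_levels,
                      time = family$times, KEEP.OUT.ATTRS = FALSE)
  long$accuracy <- as.vector(family$c)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_family
#' @param path CSV path with columns `level`, `time`, `accuracy`.
#' @export
read_family <- function(path) {
  long <- utils::read.csv(path)
  stopifnot(all(c("level", "time", "accuracy") %in% names(long)))
  levels <- sort(unique(long$level))
  times <- sort(unique(long$time))
  mat <- matrix(NA_real_, length(levels), length(times))
  for (i in seq_len(nrow(long))) {
    mat[match(long$level[i], levels), match(long$time[i], times)] <-
      long$accuracy[i]
  }
  if (anyNA(mat)) stop("family CSV does not cover the full level x time grid")
  fam <- list(perturbation_levels = levels, times = times, c = mat,
              normalized = NA)
  class(fam) <- "curve_family"
  fam
}
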