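#' @name trial-table
#' @title Trial and model-prediction table schemas
#' @description
#' Trial tables are plain data frames with one row per behavioral trial and
#' columns `observer_id`, `experiment` (`color_gray`, `gray_noise`,
#' `color_blur`), `phase` (`training`, `timed`), `block_index` (0 for
#' training, 1..K for timed blocks), `beep_latency_ms` (NA for training),
#' `perturbation_kind` (`color`, `gray`, `noise`, `blur`),
#' `perturbation_level` (0 for color/gray), `true_category`,
#' `response_category` (NA when no response was recorded within the beep
#' latency plus grace period), `response_time_ms` (NA iff the response is
#' missing), `trial_index` (1-based within block), and `image_id`.
#'
#' Model prediction tables have one row per (timestep, image) with columns
#' `timestep` (contiguous integers starting at 1), `perturbation_kind`,
#' `perturbation_level`, `image_id`, `true_category`, `predicted_category`.
#'
#' On disk both are comma-separated UTF-8 with a header row and the sentinel
#' `NA` for missing values.
NULL

trial_columns <- function() {
  c("observer_id", "experiment", "phase", "block_index", "beep_latency_ms",
    "perturbation_kind", "perturbation_level", "true_category",
    "response_category", "response_time_ms", "trial_index", "image_id")
}

prediction_columns <- function() {
  c("timestep", "perturbation_kind", "perturbation_level", "image_id",
    "true_category", "predicted_category")
}

row_err <- function(rows, msg) {
  stop(sprintf("%s (row%s %s)", msg, if (length(rows) > 1) "s" else "",
               paste(utils::head(rows, 5L), collapse = ", ")), call. = FALSE)
}

#' Validate a trial table
#'
#' Checks every invariant of the trial schema (see [trial-table]) against a
#' design: closed category vocabulary, enum columns, beep latencies drawn
#' from the design, block indices consistent with phase, and missing
#' responses encoded jointly in `response_category` and `response_time_ms`.
#' Errors name the first offending rows.
#'
#' @param trials A trial data frame.
#' @param design An [experiment_design()].
#' @return The validated data frame, invisibly.
#' @export
validate_trials <- function(trials, design = experiment_design()) {
  stopifnot(is.data.frame(trials))
  missing_cols <- setdiff(trial_columns(), names(trials))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(trials) == 0L) return(invisible(trials))

  bad <- which(!trials$experiment %in% experiment_levels())
  if (length(bad)) row_err(bad, "unknown experiment label")
  bad <- which(!trials$phase %in% phase_levels())
  if (length(bad)) row_err(bad, "unknown phase label")
  bad <- which(!trials$perturbation_kind %in% perturbation_kinds())
  if (length(bad)) row_err(bad, "unknown perturbation kind")
  bad <- which(!trials$true_category %in% design$categories)
  if (length(bad)) row_err(bad, "unknown true_category label")
  bad <- which(!is.na(trials$response_category) &
                 !trials$response_category %in% design$categories)
  if (length(bad)) row_err(bad, "unknown response_category label")

  timed <- trials$phase == "timed"
  bad <- which(timed & !trials$beep_latency_ms %in% design$beep_latencies_ms)
  if (length(bad)) row_err(bad, "beep latency not in design")
  bad <- which(timed & !trials$block_index %in% seq_len(design$n_timed_blocks))
  if (length(bad)) row_err(bad, "timed block_index out of range")
  bad <- which(!timed & trials$block_index != 0L)
  if (length(bad)) row_err(bad, "training trials must have block_index 0")
  bad <- which(is.na(trials$response_category) != is.na(trials$response_time_ms))
  if (length(bad))
    row_err(bad, "response_category and response_time_ms must be missing together")
  bad <- which(!is.na(trials$response_time_ms) & trials$response_time_ms < 0)
  if (length(bad)) row_err(bad, "negative response_time_ms")
  bad <- which(is.na(trials$trial_index) | trials$trial_index < 1L)
  if (length(bad)) row_err(bad, "trial_index must be >= 1")
  bad <- which(trials$perturbation_level < 0)
  if (length(bad)) row_err(bad, "negative perturbation_level")
  bad <- which(trials$perturbation_kind %in% c("color", "gray") &
                 trials$perturbation_level != 0)
  if (length(bad)) row_err(bad, "color/gray trials must have perturbation_level 0")
  invisible(trials)
}

#' Read and write trial tables
#'
#' CSV readers/writers for the trial schema (see [trial-table]).  Reading
#' validates every invariant against `design`; row order is preserved and
#' `write_trials()` followed by `read_trials()` is the identity.
#'
#' @param path CSV file path.
#' @param design An [experiment_design()] used for validation.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, for datasets published under a
#'   different header (e.g. `c(observer_id = "subject")`).
#' @param trials A validated trial data frame.
#' @return `read_trials()` returns the trial data frame; `write_trials()`
#'   returns `path` invisibly.
#' @export
read_trials <- function(path, design = experiment_design(), col_map = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(raw))
      if (is.na(idx)) stop("col_map column not found in file: ", col_map[[canon]])
      names(raw)[idx] <- canon
    }
  }
  missing_cols <- setdiff(trial_columns(), names(raw))
  if (length(missing_cols))
    stop("trial file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[trial_columns()]
  raw$block_index <- as.integer(raw$block_index)
  raw$trial_index <- as.integer(raw$trial_index)
  raw$beep_latency_ms <- as.numeric(raw$beep_latency_ms)
  raw$response_time_ms <- as.numeric(raw$response_time_ms)
  raw$perturbation_level <- as.numeric(raw$perturbation_level)
  validate_trials(raw, design)
  raw
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path, design = experiment_design()) {
  validate_trials(trials, design)
  utils::write.csv(trials[trial_columns()], path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and write model prediction tables
#'
#' CSV readers/writers for per-timestep predictions of a dynamic-network
#' model observer (see [trial-table]).  Timesteps must be contiguous
#' integers starting at 1 and each (timestep, image) pair may appear once.
#'
#' @param path CSV file path.
#' @param predictions A prediction data frame.
#' @param design An [experiment_design()]; categories are validated against
#'   its vocabulary.
#' @return `read_model_predictions()` returns the prediction data frame;
#'   `write_model_predictions()` returns `path` invisibly.
#' @export
read_model_predictions <- function(path, design = experiment_design()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  if (nrow(raw) == 0L) {
    warning("empty model prediction file: ", path)
    out <- as.data.frame(stats::setNames(
      list(integer(), character(), numeric(), character(), character(),
           character()), prediction_columns()))
    return(out)
  }
  missing_cols <- setdiff(prediction_columns(), names(raw))
  if (length(missing_cols))
    stop("prediction file ", path, " lacks columns: ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[prediction_columns()]
  raw$timestep <- as.integer(raw$timestep)
  raw$perturbation_level <- as.numeric(raw$perturbation_level)
  validate_model_predictions(raw, design)
  raw
}

#' @rdname read_model_predictions
#' @export
validate_model_predictions <- function(predictions, design = experiment_design()) {
  stopifnot(is.data.frame(predictions))
  missing_cols <- setdiff(prediction_columns(), names(predictions))
  if (length(missing_cols))
    stop("prediction table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(predictions) == 0L) return(invisible(predictions))
  ts <- sort(unique(predictions$timestep))
  if (!identical(ts, seq_len(max(ts))))
    stop("non-contiguous timesteps: found {", paste(ts, collapse = ", "),
         "}, expected 1..", max(ts))
  dup <- duplicated(predictions[c("timestep", "image_id")])
  if (any(dup)) row_err(which(dup), "duplicate (timestep, image_id)")
  bad <- which(!predictions$true_category %in% design$categories)
  if (length(bad)) row_err(bad, "unknown true_category label")
  bad <- which(!predictions$predicted_category %in% design$categories)
  if (length(bad)) row_err(bad, "unknown predicted_category label")
  bad <- which(!predictions$perturbation_kind %in% perturbation_kinds())
  if (length(bad)) row_err(bad, "unknown perturbation kind")
  invisible(predictions)
}

#' @rdname read_model_predictions
#' @export
write_model_predictions <- function(predictions, path,
                                    design = experiment_design()) {
  validate_model_predictions(predictions, design)
  utils::write.csv(predictions[prediction_columns()], path,
                   row.names = FALSE, na = "NA")
  invisible(path)
}
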