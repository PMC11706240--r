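#' The 16 object categories
#'
#' The fixed closed vocabulary of higher-level object categories used by the
#' 16-way categorization task.  All trial and prediction tables are validated
#' against this set; labels are lowercase.
#'
#' @return Character vector of length 16, alphabetically ordered.
#' @export
#' @examples
#' sat_categories()
sat_categories <- function() {
  c("airplane", "bear", "bicycle", "bird", "boat", "bottle", "car", "cat",
    "chair", "clock", "dog", "elephant", "keyboard", "knife", "oven", "truck")
}

#' Experiment design for the timed beep paradigm
#'
#' Describes one session of the timed-response categorization experiment: an
#' untimed training block followed by a series of timed blocks, each tied to a
#' single beep latency.  Observers must respond at the beep; a short grace
#' period after the beep still counts as a response, and a symmetric
#' acceptance window around the beep defines which responses are considered
#' on time for observer-level quality control.
#'
#' @param n_training_trials Number of untimed training trials (default 50).
#' @param trials_per_block Trials in each timed block (default 210).
#' @param warmup_discard Number of leading trials of every timed block dropped
#'   before analysis, assumed to be used by observers to adapt to the block's
#'   beep timing (default 10).
#' @param beep_latencies_ms Strictly increasing beep latencies in
#'   milliseconds, one per timed block (default 500, 900, 1100, 1300, 1500).
#' @param grace_ms Extra milliseconds after the beep during which a response
#'   is still recorded (default 200).
#' @param acceptance_window_ms Half-width of the on-time window around the
#'   beep, in milliseconds (default 100): a response at time \eqn{r} for beep
#'   latency \eqn{b} is within the window iff \eqn{|r - b| \le} this value.
#' @param exclusion_outside_fraction Observers whose fraction of timed trials
#'   outside the acceptance window is at least this value are excluded
#'   (default 0.5; the boundary is inclusive).
#' @param categories Character vector of category labels
#'   (default [sat_categories()]).
#'
#' @return An object of class `experiment_design` (a validated list).  The
#'   number of timed blocks equals `length(beep_latencies_ms)`.
#' @export
#' @examples
#' d <- experiment_design()
#' d$beep_latencies_ms
#' n_session_trials(d)   # 50 + 5 * 210
experiment_design <- function(n_training_trials = 50L,
                              trials_per_block = 210L,
                              warmup_discard = 10L,
                              beep_latencies_ms = c(500L, 900L, 1100L, 1300L, 1500L),
                              grace_ms = 200L,
                              acceptance_window_ms = 100L,
                              exclusion_outside_fraction = 0.5,
                              categories = sat_categories()) {
  design <- list(
    n_training_trials = as.integer(n_training_trials),
    n_timed_blocks = length(beep_latencies_ms),
    trials_per_block = as.integer(trials_per_block),
    warmup_discard = as.integer(warmup_discard),
    beep_latencies_ms = as.numeric(beep_latencies_ms),
    grace_ms = as.numeric(grace_ms),
    acceptance_window_ms = as.numeric(acceptance_window_ms),
    exclusion_outside_fraction = as.numeric(exclusion_outside_fraction),
    categories = as.character(categories),
    n_categories = length(categories)
  )
  class(design) <- "experiment_design"
  validate_design(design)
  design
}

validate_design <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  with(design, {
    if (n_training_trials < 0L) stop("n_training_trials must be >= 0")
    if (trials_per_block < 1L) stop("trials_per_block must be >= 1")
    if (warmup_discard < 0L || warmup_discard >= trials_per_block)
      stop("warmup_discard must be in [0, trials_per_block)")
    if (length(beep_latencies_ms) < 1L || any(beep_latencies_ms <= 0))
      stop("beep_latencies_ms must be positive")
    if (is.unsorted(beep_latencies_ms, strictly = TRUE))
      stop("beep_latencies_ms must be strictly increasing")
    if (grace_ms < 0) stop("grace_ms must be >= 0")
    if (acceptance_window_ms <= 0) stop("acceptance_window_ms must be > 0")
    if (exclusion_outside_fraction <= 0 || exclusion_outside_fraction > 1)
      stop("exclusion_outside_fraction must be in (0, 1]")
    if (n_categories < 2L) stop("need at least 2 categories")
    if (anyDuplicated(categories)) stop("duplicate category labels")
  })
  invisible(design)
}

#' @rdname experiment_design
#' @param design An `experiment_design`.
#' @export
n_session_trials <- function(design) {
  design$n_training_trials + design$n_timed_blocks * design$trials_per_block
}

#' Chance accuracy under the design
#'
#' Uniform-guessing accuracy, `1 / n_categories`; 6.25% for the default
#' 16-way task.  Used as the lower asymptote of the psychometric function and
#' as the timestep-0 anchor of model curves.
#'
#' @param design An `experiment_design`.
#' @return A probability.
#' @export
chance_accuracy <- function(design = experiment_design()) {
  1 / design$n_categories
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Timed-beep experiment design\n")
  cat(sprintf("  training trials : %d\n", x$n_training_trials))
  cat(sprintf("  timed blocks    : %d x %d trials (discard first %d)\n",
              x$n_timed_blocks, x$trials_per_block, x$warmup_discard))
  cat(sprintf("  beep latencies  : %s ms\n",
              paste(x$beep_latencies_ms, collapse = ", ")))
  cat(sprintf("  grace / window  : +%g ms / +/-%g ms\n",
              x$grace_ms, x$acceptance_window_ms))
  cat(sprintf("  categories      : %d-way\n", x$n_categories))
  invisible(x)
}

#' Read or write an experiment design as YAML
#'
#' @param path File path.
#' @param design An `experiment_design`.
#' @return `read_design()` returns an `experiment_design`;
#'   `write_design()` returns `path` invisibly.
#' @export
read_design <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(experiment_design))
  extra <- setdiff(names(raw), c(allowed, "n_timed_blocks", "n_categories"))
  if (length(extra))
    stop("unknown design fields in ", path, ": ", paste(extra, collapse = ", "))
  raw <- raw[intersect(names(raw), allowed)]
  do.call(experiment_design, raw)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  validate_design(design)
  out <- design[setdiff(names(design), c("n_timed_blocks", "n_categories"))]
  yaml::write_yaml(out, path)
  invisible(path)
}

# Experiments and the perturbation kinds their trials may carry.
experiment_levels <- function() c("color_gray", "gray_noise", "color_blur")
perturbation_kinds <- function() c("color", "gray", "noise", "blur")
phase_levels <- function() c("training", "timed")

# Evaluate an expression with a temporary RNG state seeded by `seed`,
# restoring the caller's .Random.seed afterwards.  All stochastic code in the
# package routes through this so that simulations never disturb (and are
# never disturbed by) the session RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream of child seeds from one parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
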