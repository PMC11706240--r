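# Shared fixtures for the test suite.  Everything is built in code; no
# stored data files.

# A design with small blocks so simulated sessions stay fast.
small_design <- function(trials_per_block = 40L, warmup = 4L) {
  experiment_design(n_training_trials = 16L,
                    trials_per_block = trials_per_block,
                    warmup_discard = warmup)
}

# Hand-built trial rows with sensible defaults; override any column.
make_trials <- function(n = 1L, observer_id = "obs1", phase = "timed",
                        block_index = 1L, beep_latency_ms = 500,
                        perturbation_kind = "gray", perturbation_level = 0,
                        true_category = "dog", response_category = "dog",
                        response_time_ms = 500, trial_index = seq_len(n),
                        experiment = "gray_noise", image_id = NULL) {
  if (is.null(image_id)) image_id <- sprintf("img%04d", seq_len(n))
  if (n == 0L) {
    out <- make_trials(1L)[0L, ]
    rownames(out) <- NULL
    return(out)
  }
  data.frame(observer_id = observer_id, experiment = experiment,
             phase = phase, block_index = block_index,
             beep_latency_ms = beep_latency_ms,
             perturbation_kind = perturbation_kind,
             perturbation_level = perturbation_level,
             true_category = true_category,
             response_category = response_category,
             response_time_ms = response_time_ms,
             trial_index = trial_index, image_id = image_id,
             stringsAsFactors = FALSE)
}

# A family with given accuracy matrix over default latencies.
make_family <- function(mat, levels = seq_len(nrow(mat)) - 1,
                        times = seq(500, by = 200,
                                    length.out = ncol(mat))) {
  curves <- lapply(seq_len(nrow(mat)), function(p)
    sat_curve(id = "x", times = times, accuracies = mat[p, ],
              level = levels[p], kind = "noise"))
  to_family(curves)
}

# Per-category curve lists from a categories x times accuracy matrix.
make_category_curves <- function(mat, categories = rownames(mat),
                                 times = seq(500, by = 200,
                                             length.out = ncol(mat)),
                                 id = "x") {
  lapply(seq_along(categories), function(i)
    sat_curve(id = id, times = times, accuracies = mat[i, ],
              category = categories[i]))
}

# Exact binomial confidence bounds used as simulation oracles.
binom_ci <- function(k, n, level = 0.999) {
  stats::binom.test(k, n, conf.level = level)$conf.int
}
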