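#' Default perturbation conditions per experiment
#'
#' The generator's perturbation grid.  Each experiment pairs an unperturbed
#' reference condition (level 0: gray at low contrast for the noise
#' experiment, color for the blur experiment) with increasing perturbation
#' levels: Gaussian pixel noise standard deviations for grayscale images and
#' Gaussian blur standard deviations for color images.  `asym_scale` scales
#' the dynamic range of accuracy above chance (perturbations lower the
#' attainable asymptote) and `tau_mult` multiplies the Weibull time scale
#' (perturbed images take longer to recognize).
#'
#' @param experiment One of `"color_gray"`, `"gray_noise"`, `"color_blur"`.
#' @return Data frame with columns `perturbation_kind`, `perturbation_level`,
#'   `asym_scale`, `tau_mult`.
#' @export
default_conditions <- function(experiment = c("gray_noise", "color_gray",
                                              "color_blur")) {
  experiment <- match.arg(experiment)
  switch(experiment,
    color_gray = data.frame(
      perturbation_kind = c("color", "gray"),
      perturbation_level = c(0, 0),
      asym_scale = c(1, 0.9),
      tau_mult = c(1, 1.1)),
    gray_noise = data.frame(
      perturbation_kind = c("gray", "noise", "noise"),
      perturbation_level = c(0, 0.04, 0.16),
      asym_scale = c(1, 0.55, 0.35),
      tau_mult = c(1, 1.3, 1.6)),
    color_blur = data.frame(
      perturbation_kind = c("color", "blur", "blur"),
      perturbation_level = c(0, 3, 10),
      asym_scale = c(1, 0.6, 0.4),
      tau_mult = c(1, 1.25, 1.5)))
}

#' Specification of a synthetic human observer
#'
#' Generative parameters for one simulated observer of the timed beep
#' paradigm.  Accuracy at beep latency \eqn{t} follows the cumulative
#' Weibull of `base_params` with condition- and category-specific
#' adjustments: the per-condition `asym_scale` multiplies the dynamic range
#' \eqn{1 - \gamma - \lambda} and `tau_mult` (condition) times the
#' category's `category_tau_multipliers` entry multiplies \eqn{\tau}.
#' Responses jitter around the beep with Gaussian noise truncated to the
#' recordable interval, and are missing with a latency-dependent
#' probability (misses are most common at the shortest beep latency, where
#' many observers cannot respond in time).
#'
#' @param observer_id Identifier string.
#' @param experiment Which experiment the observer ran; fixes the
#'   perturbation conditions (see [default_conditions()]).
#' @param base_params A [weibull_params()]; the default gives chance-to-75%
#'   accuracy growth over the design's latency range.
#' @param category_tau_multipliers Named positive vector over the design
#'   categories (difficulty; > 1 slows a category).  Default all 1.
#' @param conditions Data frame as returned by [default_conditions()].
#' @param rt_jitter_sd_ms SD of response-time jitter around the beep (ms).
#' @param miss_prob Either a single probability or a named vector keyed by
#'   beep latency giving the per-trial probability of recording no response.
#' @param block_order `"ascending"`, `"descending"`, or `NULL` to draw one
#'   of the two with equal probability (as in the counterbalanced design).
#' @param seed Integer seed; every stochastic draw for this observer flows
#'   from it.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(observer_id = "synthetic_obs",
                          experiment = "gray_noise",
                          base_params = weibull_params(gamma = 1 / 16,
                                                       lam = 0.25,
                                                       tau = 900, beta = 1.6),
                          category_tau_multipliers = NULL,
                          conditions = default_conditions(experiment),
                          rt_jitter_sd_ms = 50,
                          miss_prob = c("500" = 0.15, "900" = 0.05,
                                        "1100" = 0.02, "1300" = 0.02,
                                        "1500" = 0.02),
                          block_order = NULL,
                          seed = 1L) {
  stopifnot(experiment %in% experiment_levels())
  validate_weibull_params(base_params)
  stopifnot(is.data.frame(conditions),
            all(c("perturbation_kind", "perturbation_level", "asym_scale",
                  "tau_mult") %in% names(conditions)))
  if (any(conditions$asym_scale <= 0 | conditions$asym_scale > 1))
    stop("asym_scale must be in (0, 1]")
  if (any(conditions$tau_mult < 1)) stop("tau_mult must be >= 1")
  if (!is.null(category_tau_multipliers) &&
      any(category_tau_multipliers <= 0))
    stop("category_tau_multipliers must be > 0")
  if (any(miss_prob < 0 | miss_prob > 1)) stop("miss_prob must be in [0, 1]")
  if (rt_jitter_sd_ms < 0) stop("rt_jitter_sd_ms must be >= 0")
  if (!is.null(block_order))
    block_order <- match.arg(block_order, c("ascending", "descending"))
  spec <- list(observer_id = observer_id, experiment = experiment,
               base_params = base_params,
               category_tau_multipliers = category_tau_multipliers,
               conditions = conditions, rt_jitter_sd_ms = rt_jitter_sd_ms,
               miss_prob = miss_prob, block_order = block_order,
               seed = as.integer(seed))
  class(spec) <- "observer_spec"
  spec
}

miss_prob_at <- function(spec, latency) {
  mp <- spec$miss_prob
  if (length(mp) == 1L && is.null(names(mp))) return(unname(mp))
  out <- mp[as.character(latency)]
  if (any(is.na(out))) stop("miss_prob has no entry for latency ", latency)
  unname(out)
}

# Equal-as-possible allocation of n trials over categories: each category
# gets floor(n / k); the remainder goes to categories drawn at random.
balanced_categories <- function(n, categories) {
  k <- length(categories)
  base <- rep(categories, n %/% k)
  rem <- n %% k
  if (rem > 0L) base <- c(base, sample(categories, rem))
  sample(base)
}

# Gaussian jitter truncated (by inverse-CDF sampling) to [lo, hi].
rtruncnorm <- function(n, sd, lo, hi) {
  if (sd == 0) return(rep(0, n))
  plo <- stats::pnorm(lo / sd)
  phi <- stats::pnorm(hi / sd)
  stats::qnorm(stats::runif(n, plo, phi)) * sd
}

#' Simulate one observer session
#'
#' Generates a full session of the timed beep paradigm for a synthetic
#' observer: an untimed training block in which accuracy equals the
#' per-condition asymptote of the generating Weibull, followed by the timed
#' blocks in ascending or descending latency order.  Each timed trial is
#' missing with the spec's latency-dependent probability; otherwise the
#' response is correct with probability given by the adjusted cumulative
#' Weibull at the beep latency and uniform over the remaining categories
#' when incorrect, and the response time is the beep latency plus truncated
#' Gaussian jitter.  Category counts are as equal as possible within every
#' block.  The output is byte-identical across runs for a fixed
#' (spec, design) pair.
#'
#' @param spec An [observer_spec()].
#' @param design An [experiment_design()].
#' @return A validated trial data frame (see [trial-table]).
#' @export
#' @examples
#' trials <- simulate_observer(observer_spec(seed = 42), experiment_design())
#' nrow(trials)  # 50 + 5 * 210
simulate_observer <- function(spec, design = experiment_design()) {
  stopifnot(inherits(spec, "observer_spec"))
  validate_design(design)
  p <- spec$base_params
  cats <- design$categories
  cat_mult <- spec$category_tau_multipliers
  if (is.null(cat_mult)) cat_mult <- stats::setNames(rep(1, length(cats)), cats)

  with_seed(spec$seed, {
    order_dir <- spec$block_order
    if (is.null(order_dir))
      order_dir <- sample(c("ascending", "descending"), 1L)
    latencies <- design$beep_latencies_ms
    if (order_dir == "descending") latencies <- rev(latencies)

    make_block <- function(n, phase, block_index, latency) {
      cond_idx <- sample(rep_len(seq_len(nrow(spec$conditions)), n))
      cond <- spec$conditions[cond_idx, , drop = FALSE]
      true_cat <- balanced_categories(n, cats)
      range_p <- 1 - p$gamma - p$lam
      if (phase == "training") {
        acc <- p$gamma + cond$asym_scale * range_p
      } else {
        tau_eff <- p$tau * cond$tau_mult * unname(cat_mult[true_cat])
        acc <- p$gamma + cond$asym_scale * range_p *
          (1 - exp(-(latency / tau_eff)^p$beta))
      }
      correct <- stats::runif(n) < acc
      resp <- true_cat
      wrong <- which(!correct)
      if (length(wrong)) {
        resp[wrong] <- vapply(true_cat[wrong], function(tc)
          sample(setdiff(cats, tc), 1L), character(1))
      }
      if (phase == "training") {
        miss <- rep(FALSE, n)
        rt <- stats::runif(n, 800, 2500)
      } else {
        miss <- stats::runif(n) < miss_prob_at(spec, latency)
        rt <- latency + rtruncnorm(n, spec$rt_jitter_sd_ms,
                                   -latency, design$grace_ms)
        resp[miss] <- NA_character_
        rt[miss] <- NA_real_
      }
      data.frame(
        observer_id = spec$observer_id,
        experiment = spec$experiment,
        phase = phase,
        block_index = block_index,
        beep_latency_ms = if (phase == "training") NA_real_ else latency,
        perturbation_kind = cond$perturbation_kind,
        perturbation_level = cond$perturbation_level,
        true_category = true_cat,
        response_category = resp,
        response_time_ms = rt,
        trial_index = seq_len(n),
        image_id = sprintf("img_b%d_%04d", block_index, seq_len(n)),
        stringsAsFactors = FALSE)
    }

    blocks <- vector("list", 1L + length(latencies))
    blocks[[1L]] <- make_block(design$n_training_trials, "training", 0L, NA)
    for (b in seq_along(latencies))
      blocks[[b + 1L]] <- make_block(design$trials_per_block, "timed",
                                     b, latencies[b])
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    validate_trials(out, design)
    out
  })
}

#' Specification of a synthetic dynamic-network model observer
#'
#' Generative parameters for a per-timestep prediction table mimicking the
#' output of an anytime/early-exit network evaluated at a fixed number of
#' computational budgets.  The built-in profiles reproduce the qualitative
#' curve shapes seen across dynamic-network families: `gradual_wide` rises
#' smoothly over a wide accuracy range (cascaded networks),
#' `steep_saturating` jumps to its asymptote after the first timestep with
#' the same endpoints as `gradual_wide` (multi-scale early-exit networks),
#' and `shallow_low_range` rises slowly over a narrow range (scanning
#' networks).  A `custom` profile supplies the full accuracy table.
#'
#' @param model_id Identifier string.
#' @param profile One of `"gradual_wide"`, `"steep_saturating"`,
#'   `"shallow_low_range"`, `"custom"`.
#' @param experiment Experiment whose condition grid the model is evaluated
#'   on (see [default_conditions()]).
#' @param accuracy For `profile = "custom"`: data frame with columns
#'   `perturbation_kind`, `perturbation_level`, `timestep`, `accuracy`
#'   covering every (condition, timestep) cell; accuracies in \[1/16, 1\].
#' @param n_timesteps Number of timesteps (default 5, matching the number
#'   of timed blocks).
#' @param n_images Images per condition (default 200).
#' @param conditions Condition grid; defaults to the experiment's.
#' @param seed Integer seed.
#' @return An object of class `model_observer_spec` with the resolved
#'   accuracy table in `$accuracy`.
#' @export
model_observer_spec <- function(model_id = "synthetic_model",
                                profile = c("gradual_wide", "steep_saturating",
                                            "shallow_low_range", "custom"),
                                experiment = "gray_noise",
                                accuracy = NULL,
                                n_timesteps = 5L,
                                n_images = 200L,
                                conditions = default_conditions(experiment),
                                seed = 1L) {
  profile <- match.arg(profile)
  stopifnot(experiment %in% experiment_levels())
  n_timesteps <- as.integer(n_timesteps)
  if (profile == "custom") {
    if (is.null(accuracy)) stop("custom profile requires an accuracy table")
  } else {
    if (n_timesteps != 5L)
      stop("built-in profiles are defined for 5 timesteps")
    rise <- switch(profile,
      gradual_wide = c(0.25, 0.55, 0.72, 0.88, 1.00),
      steep_saturating = c(0.25, 0.97, 0.99, 1.00, 1.00),
      shallow_low_range = c(0.20, 0.40, 0.60, 0.80, 1.00))
    range_p <- switch(profile,
      gradual_wide = 0.65,
      steep_saturating = 0.65,
      shallow_low_range = 0.12)
    gamma <- 1 / 16
    accuracy <- do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
      data.frame(perturbation_kind = conditions$perturbation_kind[i],
                 perturbation_level = conditions$perturbation_level[i],
                 timestep = seq_len(n_timesteps),
                 accuracy = gamma + conditions$asym_scale[i] * range_p * rise)
    }))
  }
  stopifnot(is.data.frame(accuracy),
            all(c("perturbation_kind", "perturbation_level", "timestep",
                  "accuracy") %in% names(accuracy)))
  if (any(accuracy$accuracy < 1 / 16 - 1e-12 | accuracy$accuracy > 1))
    stop("per-timestep accuracy must lie in [1/16, 1]")
  key <- interaction(accuracy$perturbation_kind, accuracy$perturbation_level,
                     drop = TRUE)
  for (k in levels(key)) {
    ts <- sort(accuracy$timestep[key == k])
    if (!identical(as.integer(ts), seq_len(n_timesteps)))
      stop("accuracy table must cover timesteps 1..", n_timesteps,
           " for every condition")
  }
  spec <- list(model_id = model_id, profile = profile,
               experiment = experiment, accuracy = accuracy,
               n_timesteps = n_timesteps, n_images = as.integer(n_images),
               seed = as.integer(seed))
  class(spec) <- "model_observer_spec"
  spec
}

#' Simulate a model observer's prediction table
#'
#' Draws `n_images` stimuli per condition (balanced over categories) and,
#' for every timestep, emits one prediction per image that is correct with
#' the spec's per-timestep accuracy and uniform over the remaining
#' categories otherwise.  Deterministic for a fixed spec.
#'
#' @param spec A [model_observer_spec()].
#' @param design An [experiment_design()] (supplies the category
#'   vocabulary).
#' @return A validated prediction data frame (see [trial-table]).
#' @export
simulate_model_observer <- function(spec, design = experiment_design()) {
  stopifnot(inherits(spec, "model_observer_spec"))
  validate_design(design)
  cats <- design$categories
  acc_tab <- spec$accuracy
  conds <- unique(acc_tab[c("perturbation_kind", "perturbation_level")])

  with_seed(spec$seed, {
    out <- vector("list", nrow(conds) * spec$n_timesteps)
    slot <- 1L
    for (ci in seq_len(nrow(conds))) {
      kind <- conds$perturbation_kind[ci]
      level <- conds$perturbation_level[ci]
      true_cat <- balanced_categories(spec$n_images, cats)
      image_id <- sprintf("img_%s%g_%04d", kind, level,
                          seq_len(spec$n_images))
      for (t in seq_len(spec$n_timesteps)) {
        a <- acc_tab$accuracy[acc_tab$perturbation_kind == kind &
                                acc_tab$perturbation_level == level &
                                acc_tab$timestep == t]
        correct <- stats::runif(spec$n_images) < a
        pred <- true_cat
        wrong <- which(!correct)
        if (length(wrong))
          pred[wrong] <- vapply(true_cat[wrong], function(tc)
            sample(setdiff(cats, tc), 1L), character(1))
        out[[slot]] <- data.frame(
          timestep = t, perturbation_kind = kind, perturbation_level = level,
          image_id = image_id, true_category = true_cat,
          predicted_category = pred, stringsAsFactors = FALSE)
        slot <- slot + 1L
      }
    }
    res <- do.call(rbind, out)
    res <- res[order(res$timestep), ]
    rownames(res) <- NULL
    validate_model_predictions(res, design)
    res
  })
}
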