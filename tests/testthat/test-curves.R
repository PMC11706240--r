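test_that("observer exclusion follows the inclusive 50%-outside rule", {
  d <- experiment_design()
  # 10 timed trials all exactly at the beep -> kept
  at_beep <- make_trials(10, observer_id = "good",
                         response_time_ms = 500)
  # every response missing -> excluded
  all_miss <- make_trials(10, observer_id = "miss",
                          response_category = NA, response_time_ms = NA)
  # exactly half outside the +/-100 ms window -> excluded (boundary incl.)
  half <- make_trials(10, observer_id = "half",
                      response_time_ms = rep(c(500, 650), 5))
  res <- filter_observers(rbind(at_beep, all_miss, half), d)
  expect_setequal(res$excluded, c("miss", "half"))
  expect_setequal(unique(res$kept$observer_id), "good")
  expect_equal(unname(res$outside_fraction["half"]), 0.5)

  # a response at exactly the window edge counts as inside
  edge <- make_trials(10, observer_id = "edge", response_time_ms = 600)
  expect_length(filter_observers(edge, d)$excluded, 0L)
})

test_that("warm-up discard removes exactly the first trials of timed blocks", {
  d <- experiment_design()
  spec <- observer_spec(seed = 3)
  trials <- simulate_observer(spec, d)
  out <- discard_warmup(trials, d)
  timed <- out[out$phase == "timed", ]
  expect_equal(unname(c(table(timed$block_index))), rep(200L, 5))
  expect_true(all(timed$trial_index > d$warmup_discard))
  expect_equal(sum(out$phase == "training"), d$n_training_trials)

  d0 <- experiment_design(warmup_discard = 0L)
  expect_identical(discard_warmup(trials, d0), trials)

  tiny <- make_trials(5)
  expect_warning(discard_warmup(tiny, d), "empty after warm-up")
})

test_that("warm-up discard and observer exclusion commute on simulated cohorts", {
  d <- small_design()
  specs <- list(observer_spec("keepme", seed = 41),
                observer_spec("dropme", miss_prob = 0.9, seed = 42))
  trials <- do.call(rbind, lapply(specs, simulate_observer, design = d))
  a <- discard_warmup(filter_observers(trials, d)$kept, d)
  b <- filter_observers(discard_warmup(trials, d), d)$kept
  expect_equal(a, b)
  expect_equal(filter_observers(trials, d)$excluded, "dropme")
})

test_that("imputation modes behave as specified", {
  d <- experiment_design()
  clean <- make_trials(6)
  expect_identical(impute_missing(clean, "random", seed = 1, design = d),
                   clean)
  expect_identical(impute_missing(clean, "drop", design = d), clean)

  n <- 3200
  all_miss <- make_trials(n, response_category = NA, response_time_ms = NA)
  expect_equal(nrow(impute_missing(all_miss, "drop", design = d)), 0L)

  imp <- impute_missing(all_miss, "random", seed = 7, design = d)
  expect_false(anyNA(imp$response_category))
  expect_equal(imp$response_time_ms, imp$beep_latency_ms)
  k <- sum(imp$response_category == imp$true_category)
  ci <- binom_ci(k, n)
  expect_gt(1 / 16, ci[1]); expect_lt(1 / 16, ci[2])
  # seeded: reproducible
  expect_identical(imp, impute_missing(all_miss, "random", seed = 7,
                                       design = d))
})

test_that("curve aggregation computes binomial accuracy and standard error", {
  d <- experiment_design()
  resp <- rep(c("dog", "cat"), times = c(150, 50))
  tr <- make_trials(200, response_category = resp)
  # single-latency fixture: other design latencies are reported as omitted
  expect_warning(cv <- compute_curves(tr, d)[[1]], "points omitted")
  expect_equal(cv$accuracies[1], 0.75)
  expect_equal(cv$n_trials[1], 200L)
  expect_equal(cv$se[1], sqrt(0.75 * 0.25 / 200))

  perfect <- make_trials(50)
  expect_warning(cv <- compute_curves(perfect, d)[[1]], "points omitted")
  expect_equal(cv$accuracies[1], 1)
  expect_equal(cv$se[1], 0)
})

test_that("per-category curves partition the ungrouped trial counts", {
  d <- small_design()
  trials <- impute_missing(simulate_observer(observer_spec(seed = 6), d),
                           "random", seed = 2, design = d)
  overall <- compute_curves(trials, d, by_category = TRUE)
  pooled_n <- sum(vapply(overall, function(cv) sum(cv$n_trials), numeric(1)))
  expect_equal(pooled_n, sum(trials$phase == "timed"))
})

test_that("untimed accuracy summarizes training trials", {
  tr <- rbind(make_trials(40, phase = "training", block_index = 0L,
                          beep_latency_ms = NA),
              make_trials(10, phase = "training", block_index = 0L,
                          beep_latency_ms = NA, response_category = "cat"))
  expect_equal(untimed_accuracy(tr), 0.8)
  expect_error(untimed_accuracy(make_trials(5)), "no training trials")

  tr2 <- tr
  tr2$experiment[1:25] <- "color_blur"
  by_exp <- untimed_accuracy(tr2, by = "experiment")
  expect_equal(nrow(by_exp), 2L)
  expect_equal(sort(by_exp$untimed_accuracy * c(25, 25)),
               sort(c(sum(tr2$response_category[1:25] ==
                            tr2$true_category[1:25]),
                      sum(tr2$response_category[26:50] ==
                            tr2$true_category[26:50]))))
})

test_that("normalization rescales accuracies and standard errors", {
  cv <- sat_curve("o", times = c(500, 900), accuracies = c(0.2, 0.4),
                  n_trials = c(10L, 10L), se = c(0.05, 0.06))
  out <- normalize_curve(cv, 0.8)
  expect_equal(out$accuracies, c(0.25, 0.5))
  expect_equal(out$se, c(0.0625, 0.075))
  expect_true(out$normalized)
  expect_equal(normalize_curve(cv, 1)$accuracies, cv$accuracies)
  expect_error(normalize_curve(cv, 0), "positive")
})

test_that("the chance anchor is attached once and excluded from metrics", {
  d <- experiment_design()
  cv <- sat_curve("o", times = c(500, 900, 1100, 1300, 1500),
                  accuracies = c(0.1, 0.3, 0.5, 0.6, 0.65), level = 0,
                  kind = "gray")
  anch <- add_chance_anchor(cv, d)
  expect_equal(anch$times[1], 0)
  expect_equal(anch$accuracies[1], 0.0625)
  expect_true(anch$anchored)
  expect_error(add_chance_anchor(anch, d), "already anchored")

  d2 <- experiment_design(categories = c("cat", "dog"))
  expect_equal(add_chance_anchor(cv, d2)$accuracies[1], 0.5)

  # metrics ignore the anchor entirely
  fam_plain <- to_family(list(cv))
  fam_anch <- to_family(list(anch))
  expect_identical(fam_plain$c, fam_anch$c)
  fit_plain <- fit_weibull(cv, d)
  fit_anch <- fit_weibull(anch, d)
  expect_equal(fit_plain$params$tau, fit_anch$params$tau)
})

test_that("index mapping places timesteps on the design latencies", {
  d <- experiment_design()
  cv <- sat_curve("m", times = 1:5, accuracies = seq(0.1, 0.6, length.out = 5))
  out <- map_timesteps(cv, d, mode = "index")
  expect_equal(out$times, c(500, 900, 1100, 1300, 1500))
  short <- sat_curve("m", times = 1:4, accuracies = c(0.1, 0.2, 0.3, 0.4))
  expect_error(map_timesteps(short, d, mode = "index"), "exactly 5")
})

test_that("affine mapping recovers a linear latency grid exactly and falls back on flat references", {
  d_lin <- experiment_design(beep_latencies_ms = seq(500, 1500, by = 250))
  p <- weibull_params(lam = 0.2, tau = 900, beta = 1.8)
  ref <- sat_curve("h", times = d_lin$beep_latencies_ms,
                   accuracies = weibull_accuracy(d_lin$beep_latencies_ms, p))
  model <- sat_curve("m", times = 1:5, accuracies = ref$accuracies)
  out <- map_timesteps(model, d_lin, mode = "affine", reference = ref)
  expect_equal(out$times, d_lin$beep_latencies_ms, tolerance = 1e-3)

  # default (non-linear) latency grid: recovered times approximate the beeps
  d <- experiment_design()
  ref2 <- sat_curve("h", times = d$beep_latencies_ms,
                    accuracies = weibull_accuracy(d$beep_latencies_ms, p))
  model2 <- sat_curve("m", times = 1:5, accuracies = ref2$accuracies)
  out2 <- map_timesteps(model2, d, mode = "affine", reference = ref2)
  expect_true(all(diff(out2$times) > 0))
  expect_lt(max(abs(out2$times - d$beep_latencies_ms)), 250)

  flat <- sat_curve("h", times = d$beep_latencies_ms,
                    accuracies = rep(0.5, 5))
  expect_warning(out3 <- map_timesteps(model2, d, mode = "affine",
                                       reference = flat), "flat reference")
  expect_equal(out3$times, d$beep_latencies_ms)
})

test_that("curve families validate axes and include the unperturbed level", {
  times <- c(500, 900, 1100, 1300, 1500)
  mk <- function(level, acc) sat_curve("x", times, acc, level = level,
                                       kind = "noise")
  fam <- to_family(list(mk(0, seq(0.2, 0.6, length.out = 5)),
                        mk(0.04, seq(0.1, 0.4, length.out = 5)),
                        mk(0.16, seq(0.08, 0.3, length.out = 5))))
  expect_equal(dim(fam$c), c(3L, 5L))
  expect_equal(fam$perturbation_levels, c(0, 0.04, 0.16))

  expect_error(to_family(list(mk(0.04, seq(0.1, 0.4, length.out = 5)))),
               "level-0")
  expect_error(to_family(list(mk(0, 1:5 / 10), mk(0, 1:5 / 10))),
               "duplicate")
  other <- sat_curve("x", times + 1, 1:5 / 10, level = 0.04)
  expect_error(to_family(list(mk(0, 1:5 / 10), other)), "time axes")

  single <- to_family(list(mk(0, c(0.1, 0.2, 0.3, 0.4, 0.5))))
  expect_equal(dim(single$c), c(1L, 5L))
  # one level: the family error degenerates to plain RMSE
  single2 <- to_family(list(mk(0, c(0.1, 0.2, 0.3, 0.4, 0.45))))
  expect_equal(rmse_fit_error(single, single2),
               sqrt(mean((single$c - single2$c)^2)))
})

test_that("families round-trip through long-format CSV", {
  fam <- make_family(matrix(runif(15), 3), levels = c(0, 0.04, 0.16))
  path <- withr::local_tempfile(fileext = ".csv")
  write_family(fam, path)
  back <- read_family(path)
  expect_equal(back$c, fam$c)
  expect_equal(back$perturbation_levels, fam$perturbation_levels)
  expect_equal(back$times, fam$times)
})

test_that("measured accuracy equals the generating curve corrected for imputation bias", {
  # end-to-end parameter recovery: QC -> warm-up -> imputation -> curves
  d <- experiment_design(n_training_trials = 10L, trials_per_block = 210L,
                         warmup_discard = 10L)
  p <- weibull_params(gamma = 1 / 16, lam = 0.15, tau = 800, beta = 2)
  m <- 0.1
  spec <- observer_spec(
    base_params = p,
    conditions = data.frame(perturbation_kind = "gray",
                            perturbation_level = 0, asym_scale = 1,
                            tau_mult = 1),
    miss_prob = m, rt_jitter_sd_ms = 30, seed = 77)
  trials <- simulate_observer(spec, d)
  kept <- filter_observers(trials, d)$kept
  kept <- discard_warmup(kept, d)
  kept <- impute_missing(kept, "random", seed = 78, design = d)
  cv <- compute_curves(kept, d)[[1]]
  for (i in seq_along(cv$times)) {
    a_true <- weibull_accuracy(cv$times[i], p)
    expected <- (1 - m) * a_true + m / 16
    se <- sqrt(expected * (1 - expected) / cv$n_trials[i])
    expect_lt(abs(cv$accuracies[i] - expected), 3.5 * se)
  }
})
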