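# Independent oracle: the curve-fit error written as explicit double loops.
rmse_oracle <- function(m1, m2) {
  np <- nrow(m1); nt <- ncol(m1)
  total <- 0
  for (p in seq_len(np)) {
    ss <- 0
    for (t in seq_len(nt)) ss <- ss + (m1[p, t] - m2[p, t])^2
    total <- total + sqrt(ss / nt)
  }
  total / np
}

# Independent oracle: Spearman as rank-then-Pearson with average ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

test_that("curve-fit error matches hand-computed values", {
  f0 <- make_family(matrix(c(0, 0), 1), levels = 0,
                    times = c(500, 900))
  f1 <- make_family(matrix(c(0.3, 0.4), 1), levels = 0,
                    times = c(500, 900))
  expect_equal(rmse_fit_error(f0, f1), sqrt(0.125))
  expect_equal(rmse_fit_error(f0, f0), 0)

  # per-level RMSEs 0.1 and 0.3 average to 0.2
  a <- make_family(rbind(rep(0, 3), rep(0, 3)), levels = c(0, 1),
                   times = c(1, 2, 3) * 100)
  b <- make_family(rbind(rep(0.1, 3), rep(0.3, 3)), levels = c(0, 1),
                   times = c(1, 2, 3) * 100)
  expect_equal(rmse_fit_error(a, b), 0.2)

  bad <- make_family(matrix(0.5, 1, 3), levels = 0, times = c(100, 200, 300))
  expect_error(rmse_fit_error(f0, bad), "shapes")
})

test_that("curve-fit error equals the brute-force oracle and is a metric", {
  for (seed in 1:50) {
    withr::with_seed(seed, {
      np <- sample(1:5, 1); nt <- sample(2:7, 1)
      m1 <- matrix(runif(np * nt), np)
      m2 <- matrix(runif(np * nt), np)
      m3 <- matrix(runif(np * nt), np)
      lv <- c(0, sort(runif(np - 1, 0.01, 1)))
      tm <- sort(sample(100:2000, nt))
      f1 <- make_family(m1, lv, tm); f2 <- make_family(m2, lv, tm)
      f3 <- make_family(m3, lv, tm)
      e12 <- rmse_fit_error(f1, f2)
      expect_equal(e12, rmse_oracle(m1, m2), tolerance = 1e-12)
      expect_gte(e12, 0)
      expect_equal(e12, rmse_fit_error(f2, f1))
      expect_equal(rmse_fit_error(f1, f1), 0)
      expect_lte(rmse_fit_error(f1, f3),
                 e12 + rmse_fit_error(f2, f3) + 1e-12)
    })
  }
})

test_that("category-wise correlation matches the rank-then-Pearson oracle", {
  cats <- c("bear", "cat", "dog", "oven")
  for (seed in 1:50) {
    withr::with_seed(seed, {
      nt <- sample(3:6, 1)
      # round to one decimal to inject ties
      m <- matrix(round(runif(4 * nt), 1), 4, dimnames = list(cats))
      h <- matrix(round(runif(4 * nt), 1), 4, dimnames = list(cats))
      if (sd(m) > 0 && sd(h) > 0) {
        tm <- seq(500, by = 200, length.out = nt)
        val <- categorywise_correlation(make_category_curves(m, cats, tm),
                                        make_category_curves(h, cats, tm))
        expect_equal(val, spearman_oracle(as.vector(t(m)), as.vector(t(h))),
                     tolerance = 1e-12)
      }
    })
  }
})

test_that("monotone-related vectors give exactly +/-1 and mismatches error", {
  cats <- c("bear", "cat")
  m <- matrix(c(0.1, 0.4, 0.5, 0.2, 0.3, 0.6), 2, byrow = TRUE,
              dimnames = list(cats))
  up <- m^3 + 0.01 * m          # strictly increasing transform
  down <- 1 - sqrt(m)           # strictly decreasing transform
  tm <- c(500, 900, 1100)
  mc <- make_category_curves(m, cats, tm)
  expect_equal(categorywise_correlation(mc,
                                        make_category_curves(up, cats, tm)), 1)
  expect_equal(categorywise_correlation(mc,
                                        make_category_curves(down, cats, tm)),
               -1)

  other <- make_category_curves(m, c("airplane", "cat"), tm)
  expect_error(categorywise_correlation(mc, other), "category sets")

  const <- matrix(0.5, 2, 3, dimnames = list(cats))
  res <- categorywise_correlation(mc, make_category_curves(const, cats, tm))
  expect_true(is_degenerate(res))
  expect_true(is.na(res))
})

test_that("single-category correlation matches the oracle and flags constants", {
  tm <- c(500, 900, 1100, 1300, 1500)
  h <- sat_curve("h", tm, c(0.1, 0.3, 0.4, 0.5, 0.6), category = "dog")
  expect_equal(per_category_correlation(h, h), 1)

  swapped <- sat_curve("m", tm, c(0.1, 0.4, 0.3, 0.5, 0.6),
                       category = "dog")
  expect_equal(per_category_correlation(swapped, h),
               spearman_oracle(swapped$accuracies, h$accuracies))

  flat <- sat_curve("m", tm, rep(0.2, 5), category = "dog")
  expect_true(is_degenerate(per_category_correlation(flat, h)))
})

test_that("Weibull fits recover noise-free generating parameters within 1%", {
  d <- experiment_design()
  for (seed in c(2, 9, 31)) {
    p <- withr::with_seed(seed, weibull_params(
      gamma = 1 / 16, lam = runif(1, 0.05, 0.35),
      tau = runif(1, 600, 1400), beta = runif(1, 0.8, 3)))
    cv <- sat_curve("x", d$beep_latencies_ms,
                    weibull_accuracy(d$beep_latencies_ms, p))
    fit <- fit_weibull(cv, d)
    expect_true(fit$converged)
    expect_false(fit$degenerate)
    expect_lt(abs(fit$params$tau - p$tau) / p$tau, 0.01)
    expect_lt(abs(fit$params$beta - p$beta) / p$beta, 0.01)
    expect_lt(abs(fit$params$lam - p$lam), 0.01)
    # landmark: fitted value at t = tau
    expect_equal(weibull_accuracy(fit$params$tau, fit$params),
                 p$gamma + (1 - p$gamma - p$lam) * (1 - exp(-1)),
                 tolerance = 0.01)
  }
})

test_that("flat curves are flagged as degenerate fits", {
  d <- experiment_design()
  flat <- sat_curve("x", d$beep_latencies_ms, rep(0.8, 5))
  fit <- fit_weibull(flat, d)
  expect_true(fit$degenerate)
  at_chance <- sat_curve("x", d$beep_latencies_ms, rep(1 / 16, 5))
  expect_true(fit_weibull(at_chance, d)$degenerate)
  expect_error(fit_weibull(sat_curve("x", c(500, 900), c(0.1, 0.2)), d),
               "at least 3")
})

test_that("mean curvature is zero for lines and closed-form for parabolas", {
  x <- seq(0, 2, length.out = 101)
  expect_lt(mean_curvature(x, 3 * x + 1), 1e-10)
  # y = x^2: central differences give y' = 2x and y'' = 2 exactly
  interior <- x[2:100]
  expect_equal(mean_curvature(x, x^2),
               mean(2 / (1 + 4 * interior^2)^1.5), tolerance = 1e-8)
  expect_error(mean_curvature(c(0, 1, 3), c(0, 1, 2)), "uniformly spaced")
})

test_that("steepness grows with the Weibull shape and respects its scale contract", {
  vals <- vapply(seq(0.5, 8, by = 0.5), function(b)
    steepness(weibull_params(lam = 0.2, tau = 900, beta = b),
              t_range = c(500, 1500)), numeric(1))
  expect_true(all(diff(vals) >= -1e-12))

  # log-log steepness is invariant to rescaling all times (tau alongside)
  p <- weibull_params(lam = 0.2, tau = 900, beta = 2)
  s1 <- steepness(p, c(500, 1500), scale = "loglog")
  p10 <- weibull_params(lam = 0.2, tau = 9000, beta = 2)
  s10 <- steepness(p10, c(5000, 15000), scale = "loglog")
  expect_equal(s1, s10, tolerance = 1e-10)

  expect_error(steepness(p, c(-10, 100), scale = "loglog"), "positive")
})

test_that("timestep-FLOP correlation follows the textbook Pearson formula", {
  expect_equal(timestep_flop_correlation(c(10, 20, 30, 40, 50)), 1)

  flops <- c(1, 2, 4, 8, 16)
  t <- 1:5
  hand <- sum((t - mean(t)) * (flops - mean(flops))) /
    sqrt(sum((t - mean(t))^2) * sum((flops - mean(flops))^2))
  expect_equal(timestep_flop_correlation(flops), hand)
  expect_equal(timestep_flop_correlation(rev(flops)), -hand)

  expect_true(is_degenerate(timestep_flop_correlation(c(5, 5, 5))))
  expect_error(timestep_flop_correlation(c(1, 2)), "at least 3")
  expect_error(timestep_flop_correlation(c(1, 2, 3), T = 5), "equal")
})
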