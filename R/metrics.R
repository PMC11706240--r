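degenerate_value <- function(reason) {
  structure(NA_real_, degenerate = TRUE, reason = reason)
}

#' Is a metric value degenerate?
#'
#' Metric operations flag undefined results (zero-variance vectors,
#' unidentifiable fits) instead of silently coercing them to a number.
#' Degenerate values carry `NA` with a `degenerate` attribute and are
#' excluded from report summaries, which count them.
#'
#' @param x A metric return value.
#' @return Logical.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

#' Curve-fit error between two curve families
#'
#' The curve-fit error between two accuracy matrices defined over the same
#' perturbation levels and times: the root-mean-square error over time,
#' computed separately for each perturbation curve and then averaged over
#' curves,
#' \deqn{e_{RMSE}(c_1, c_2) = \frac{1}{N_p} \sum_{p=1}^{N_p}
#'   \sqrt{\frac{1}{N_t} \sum_{t=1}^{N_t} (c_1[p,t] - c_2[p,t])^2}.}
#' This gives a single number for how well one observer's family of SAT
#' curves matches another's across all perturbation strengths.  It is
#' symmetric, nonnegative, zero iff the families are identical, and (being
#' an average of per-level RMSEs, each a metric) satisfies the triangle
#' inequality.
#'
#' @param c1,c2 `curve_family` objects of identical shape with identical
#'   level and time axes.
#' @return Nonnegative scalar.
#' @export
rmse_fit_error <- function(c1, c2) {
  stopifnot(inherits(c1, "curve_family"), inherits(c2, "curve_family"))
  if (!identical(dim(c1$c), dim(c2$c)))
    stop("curve families have different shapes")
  if (!isTRUE(all.equal(c1$perturbation_levels, c2$perturbation_levels)))
    stop("curve families have different perturbation levels")
  if (!isTRUE(all.equal(c1$times, c2$times)))
    stop("curve families have different time axes")
  d <- c1$c - c2$c
  mean(sqrt(rowMeans(d^2)))
}

# Spearman rho via average ranks, exact +/-1 for perfectly concordant or
# discordant vectors (stats::cor can return 1 - eps there).
spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (identical(rx, ry)) return(1)
  if (identical(rx + ry, rep(length(rx) + 1, length(rx)))) return(-1)
  stats::cor(rx, ry)
}

flatten_category_curves <- function(curves) {
  cats <- vapply(curves, function(cv) cv$category, character(1))
  if (anyNA(cats)) stop("curves must carry category labels")
  if (anyDuplicated(cats)) stop("duplicate category curves")
  ord <- order(cats)
  list(categories = cats[ord],
       values = unlist(lapply(curves[ord], function(cv) {
         cv <- strip_anchor(cv)
         cv$accuracies[order(cv$times)]
       })))
}

#' Category-wise rank correlation between observers
#'
#' Compares how accuracy varies jointly over categories and time between a
#' model and a human observer: the per-category SAT curves of each side are
#' flattened into one vector (categories in alphabetical order, then time
#' ascending) and Spearman's rank correlation is computed, with ties
#' resolved by average ranks.  Chance anchors are excluded.
#'
#' @param model,human Lists of per-category [sat_curve()] objects covering
#'   the same category set and time axis.
#' @return Correlation in \[-1, 1\], or a degenerate flag (see
#'   [is_degenerate()]) when either flattened vector has zero variance.
#' @export
categorywise_correlation <- function(model, human) {
  fm <- flatten_category_curves(model)
  fh <- flatten_category_curves(human)
  if (!identical(fm$categories, fh$categories))
    stop("category sets differ between model and human curves")
  if (length(fm$values) != length(fh$values))
    stop("flattened vectors have different lengths")
  if (stats::sd(fm$values) == 0 || stats::sd(fh$values) == 0)
    return(degenerate_value("zero-variance flattened vector"))
  spearman_rho(fm$values, fh$values)
}

#' Rank correlation for a single category
#'
#' Spearman correlation between a model's and a human's SAT curve for one
#' category (anchors excluded).  Negative values are preserved; any
#' clipping is a display decision, not part of the metric.
#'
#' @param model,human [sat_curve()] objects for the same category over the
#'   same time axis.
#' @return Correlation in \[-1, 1\], or a degenerate flag when either curve
#'   is constant.
#' @export
per_category_correlation <- function(model, human) {
  m <- strip_anchor(model); h <- strip_anchor(human)
  if (length(m$times) != length(h$times))
    stop("curves have different numbers of points")
  if (stats::sd(m$accuracies) == 0 || stats::sd(h$accuracies) == 0)
    return(degenerate_value("constant curve"))
  spearman_rho(m$accuracies, h$accuracies)
}

#' Fit the cumulative Weibull psychometric function to a curve
#'
#' Bounded least-squares fit of [weibull_accuracy()] to a curve's
#' (time, accuracy) points, anchor excluded.  The guess rate is fixed at
#' chance by default (the standard choice for an n-alternative forced
#' choice task); the lapse rate is bounded in \[0, 0.5), the scale in
#' \[min time / 10, 100 x max time\] and the shape in \[0.05, 50\].  The
#' optimizer is restarted from a fixed grid of (tau, beta) initializations
#' and the best residual wins, with ties broken toward the smaller shape.
#'
#' @param curve A [sat_curve()] with at least 3 non-anchor points at
#'   positive times, in raw accuracy units (values must not exceed 1).
#' @param design An [experiment_design()] supplying the chance level.
#' @param fix_gamma Fix the guess rate at chance (default) or fit it in
#'   \[0, 0.5\].
#' @param weighted Weight squared residuals by inverse variance
#'   (`1 / se^2`) where standard errors are available.
#' @return An object of class `weibull_fit`: `params` ([weibull_params()]),
#'   `residual_norm` (root mean squared residual), `converged`, and
#'   `degenerate` (`TRUE` for flat curves, where the shape is
#'   unidentifiable; the returned parameters are then not interpretable).
#' @export
fit_weibull <- function(curve, design = experiment_design(),
                        fix_gamma = TRUE, weighted = FALSE) {
  stopifnot(inherits(curve, "sat_curve"))
  curve <- strip_anchor(curve)
  t <- curve$times
  a <- curve$accuracies
  if (length(t) < 3L) stop("need at least 3 points to fit")
  if (any(t <= 0)) stop("times must be positive")
  if (any(a > 1 + 1e-9))
    stop("accuracies exceed 1; fit the raw (unnormalized) curve")
  a <- pmin(a, 1)
  gamma0 <- chance_accuracy(design)
  degenerate <- stats::sd(a) < 1e-9

  w <- rep(1, length(t))
  if (weighted && all(is.finite(curve$se)) && all(curve$se > 0))
    w <- 1 / curve$se^2

  lo_tau <- min(t) / 10; hi_tau <- 100 * max(t)
  obj <- function(par) {
    if (fix_gamma) {
      g <- gamma0; lam <- par[1L]; tau <- par[2L]; beta <- par[3L]
    } else {
      g <- par[1L]; lam <- par[2L]; tau <- par[3L]; beta <- par[4L]
    }
    if (g + lam >= 1) return(1e10)
    pred <- g + (1 - g - lam) * (1 - exp(-(t / tau)^beta))
    sum(w * (a - pred)^2)
  }
  lam0 <- min(max(1 - max(a), 0), 0.45)
  tau_grid <- exp(seq(log(max(min(t), lo_tau * 10)),
                      log(max(t) * 4), length.out = 5L))
  beta_grid <- c(0.5, 1, 2, 4, 8)
  lower <- c(0, lo_tau, 0.05)
  upper <- c(0.499, hi_tau, 50)
  if (!fix_gamma) { lower <- c(0, lower); upper <- c(0.5, upper) }

  best <- NULL
  for (tau0 in tau_grid) for (beta0 in beta_grid) {
    start <- c(lam0, tau0, beta0)
    if (!fix_gamma) start <- c(gamma0, start)
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-12 ||
        (abs(fit$value - best$value) <= 1e-12 &&
           fit$par[length(fit$par)] < best$par[length(best$par)]))
      best <- fit
  }
  if (is.null(best)) stop("Weibull fit failed from every initialization")
  par <- best$par
  params <- if (fix_gamma)
    weibull_params(gamma = gamma0, lam = par[1L], tau = par[2L],
                   beta = par[3L])
  else
    weibull_params(gamma = par[1L], lam = par[2L], tau = par[3L],
                   beta = par[4L])
  out <- list(params = params,
              residual_norm = sqrt(best$value / length(t)),
              converged = best$convergence == 0L,
              degenerate = degenerate)
  class(out) <- "weibull_fit"
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  residual norm %.4g; converged: %s%s\n", x$residual_norm,
              x$converged, if (x$degenerate) "; DEGENERATE (flat curve)" else ""))
  invisible(x)
}

#' Mean curvature of a sampled plane curve
#'
#' Average of the unsigned plane-curve curvature
#' \eqn{\kappa = |y''| / (1 + y'^2)^{3/2}} over the interior points of a
#' uniformly spaced grid, with derivatives estimated by central
#' differences.  The building block of the steepness statistic; exposed so
#' the curvature of any sampled curve can be computed directly.
#'
#' @param x Strictly increasing, uniformly spaced abscissa.
#' @param y Ordinates, same length.
#' @return Nonnegative scalar (mean curvature over interior points).
#' @export
mean_curvature <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 3L)
  h <- diff(x)
  if (max(h) - min(h) > 1e-8 * mean(h))
    stop("x must be uniformly spaced")
  h <- mean(h)
  i <- 2:(n - 1L)
  d1 <- (y[i + 1L] - y[i - 1L]) / (2 * h)
  d2 <- (y[i + 1L] - 2 * y[i] + y[i - 1L]) / h^2
  mean(abs(d2) / (1 + d1^2)^1.5)
}

#' Steepness of a fitted SAT curve
#'
#' Quantifies how abruptly accuracy rises with time: the fitted cumulative
#' Weibull is evaluated on a uniform grid of `grid_n` points spanning
#' `t_range` on the chosen scale's abscissa, and the mean plane-curve
#' curvature over interior grid points is returned.  Under the default
#' `"loglog"` scale both axes are logarithmic, which makes the statistic
#' invariant to a common rescaling of all times (with the Weibull scale
#' rescaled along) and to multiplicative normalization of the accuracies.
#' Gradual curves score low; step-like curves score high.
#'
#' @param params A [weibull_params()] (typically from [fit_weibull()]).
#' @param t_range Length-2 vector `(t_min, t_max)` in ms, `t_min < t_max`;
#'   defaults to the design's beep-latency range.
#' @param grid_n Number of grid points (default 101).
#' @param scale `"loglog"` (log abscissa and ordinate) or `"linear"`.
#' @return Nonnegative scalar.
#' @export
steepness <- function(params, t_range = c(500, 1500), grid_n = 101L,
                      scale = c("loglog", "linear")) {
  scale <- match.arg(scale)
  validate_weibull_params(params)
  stopifnot(length(t_range) == 2L, t_range[1L] < t_range[2L], grid_n >= 3L)
  if (scale == "loglog") {
    if (t_range[1L] <= 0) stop("log-log scale requires positive times")
    x <- seq(log(t_range[1L]), log(t_range[2L]), length.out = grid_n)
    acc <- weibull_accuracy(exp(x), params)
    if (any(acc <= 0)) stop("nonpositive accuracy on log scale")
    y <- log(acc)
  } else {
    x <- seq(t_range[1L], t_range[2L], length.out = grid_n)
    y <- weibull_accuracy(x, params)
  }
  mean_curvature(x, y)
}

#' Correlation between timesteps and computational cost
#'
#' Pearson correlation between the ordinal timesteps `1..T` of a dynamic
#' network and the floating-point operation counts of its successive
#' outputs.  High values indicate that the network's timestep is a
#' near-linear proxy for computational time, justifying its use as the
#' analog of human reaction time.
#'
#' @param flops Positive FLOP counts, one per network output.
#' @param T Number of timesteps; must equal `length(flops)` and be at
#'   least 3.
#' @return Correlation in \[-1, 1\], or a degenerate flag when `flops` is
#'   constant.
#' @export
timestep_flop_correlation <- function(flops, T = length(flops)) {
  if (length(flops) != T) stop("length(flops) must equal T")
  if (T < 3L) stop("need at least 3 timesteps")
  if (any(flops <= 0)) stop("flops must be positive")
  if (stats::sd(flops) == 0) return(degenerate_value("constant flops"))
  stats::cor(seq_len(T), flops)
}
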