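#' Coalescent skyline effective population size of a clade
#'
#' Classic/generalized skyline estimator on the coalescence times of
#' an expanded clade. For an inter-coalescent interval with `k`
#' extant lineages and duration `dt` years, the effective population
#' size (in HSC x years, i.e. census size times generation time) is
#' `k * (k - 1) * dt / 2`. Adjacent intervals are pooled until each
#' pool spans at least `smoothing_epsilon` years (generalized
#' skyline); a pool of `m` coalescences estimates `N_eff` by the mean
#' of `m` exponential interval contributions, giving a log-scale
#' variance of `trigamma(m)`. Points are flagged high-variance when
#' `log(var) > flag_log_var`; with the closed-form skyline the
#' log-scale variance is bounded for `m >= 1`, so the flag matters
#' mainly for externally supplied trajectories whose variance
#' explodes in data-poor regions.
#'
#' @param clade a `clade` from [detect_clades()], or `NULL` to use
#'   the whole tree as one clade.
#' @param time_tree the [scale_tree_to_time()] result it came from.
#' @param smoothing_epsilon minimum pooled interval span in years
#'   (default 1).
#' @param flag_log_var high-variance flag threshold on the log of
#'   the interval-model variance (default 5).
#' @return object of class `neff_trajectory`: data frame with
#'   columns `time` (years, pooled-interval midpoint), `neff`
#'   (HSC x years), `var_log` (variance of log N_eff), `n_coal`,
#'   `high_variance`.
#' @export
skyline_neff <- function(clade, time_tree, smoothing_epsilon = 1,
                         flag_log_var = 5) {
  stopifnot(inherits(time_tree, "time_tree"))
  tr <- time_tree$tree
  ntip <- length(tr$tip.label)
  if (is.null(clade)) {
    clade <- structure(list(tips = tr$tip.label, mrca = ntip + 1L,
                            onset_lower = NA, onset_upper = NA,
                            driver = NA, n_tips = ntip,
                            clonal_fraction = 1),
                       class = "clade")
  }
  stopifnot(inherits(clade, "clade"))
  ## coalescence times inside the clade: every internal node of the
  ## subtree contributes (children - 1) coalescences at its time
  sub_nodes <- clade$mrca
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  stack <- clade$mrca; internal <- integer(0)
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    ch <- kids[[as.character(v)]]
    if (length(ch)) {
      internal <- c(internal, v)
      stack <- c(stack, ch)
    }
  }
  coal_times <- unlist(lapply(internal, function(v)
    rep(time_tree$node_times[v], length(kids[[as.character(v)]]) - 1L)))
  n_tips <- clade$n_tips
  if (length(coal_times) < 1L)
    stop("clade has no coalescences; need >= 2 tips", call. = FALSE)
  stopifnot(length(coal_times) == n_tips - 1L)   # skyline conservation

  age <- time_tree$age_at_sampling
  ts <- sort(coal_times, decreasing = TRUE)      # present -> past
  k <- n_tips
  t_hi <- age
  contrib <- dt <- numeric(length(ts))
  for (i in seq_along(ts)) {
    dt[i] <- t_hi - ts[i]
    contrib[i] <- k * (k - 1) * dt[i] / 2
    t_hi <- ts[i]; k <- k - 1L
  }
  ## generalized-skyline pooling: extend each pool until its span
  ## reaches epsilon; a trailing short pool merges into the previous
  pool <- integer(length(ts)); p <- 1L; span <- 0
  for (i in seq_along(ts)) {
    pool[i] <- p
    span <- span + dt[i]
    if (span >= smoothing_epsilon && i < length(ts)) { p <- p + 1L; span <- 0 }
  }
  if (p > 1L && sum(dt[pool == p]) < smoothing_epsilon)
    pool[pool == p] <- p - 1L
  upper <- c(age, ts[-length(ts)])
  agg <- function(f, x) as.numeric(tapply(x, pool, f))
  m <- agg(length, dt)
  neff <- agg(sum, contrib) / m
  t_top <- agg(max, upper); t_bot <- agg(min, ts)
  out <- data.frame(time = (t_top + t_bot) / 2,
                    neff = neff,
                    var_log = trigamma(m),
                    n_coal = m,
                    high_variance = log(trigamma(m)) > flag_log_var)
  attr(out, "clade") <- clade
  attr(out, "n_tips") <- n_tips
  attr(out, "epsilon") <- smoothing_epsilon
  class(out) <- c("neff_trajectory", "data.frame")
  out
}

#' @export
plot.neff_trajectory <- function(x, fit = NULL, ...) {
  graphics::plot(x$time, x$neff, log = "y", type = "b",
                 pch = ifelse(x$high_variance, 1, 16),
                 xlab = "age (years)", ylab = "N_eff (HSC x years)",
                 ...)
  if (!is.null(fit)) {
    tt <- seq(min(x$time), max(x$time), length.out = 100)
    yy <- fit$intercept + ifelse(tt < fit$breakpoint,
                                 fit$early_rate * (tt - fit$breakpoint),
                                 fit$late_rate * (tt - fit$breakpoint))
    graphics::lines(tt, exp(yy), col = 2, lwd = 2)
  }
  invisible(x)
}

#' Biphasic log-linear growth fit to an N_eff trajectory
#'
#' Continuous two-segment least squares on `log(N_eff)` versus time:
#' an early and a late exponential growth rate joined at a
#' breakpoint chosen by grid search over interior trajectory times
#' (at least two points per segment; SSE ties broken to the earliest
#' candidate). High-variance and non-positive points are excluded.
#'
#' @param traj a [skyline_neff()] trajectory (or any data frame with
#'   `time`, `neff` and optionally `high_variance`).
#' @return object of class `biphasic_fit`: `breakpoint` (years),
#'   `early_rate`, `late_rate` (per year on log N_eff),
#'   `intercept` (log N_eff at the breakpoint), `sse`, and the
#'   fitted `points`.
#' @export
fit_biphasic <- function(traj) {
  usable <- traj$neff > 0
  if (!is.null(traj$high_variance)) usable <- usable & !traj$high_variance
  t <- traj$time[usable]; y <- log(traj$neff[usable])
  o <- order(t); t <- t[o]; y <- y[o]
  n <- length(t)
  if (n < 4L)
    stop("need at least 4 usable (non-flagged, positive) points",
         call. = FALSE)
  best <- NULL
  for (i in 2:(n - 2L)) {
    cb <- t[i]
    X <- cbind(1, pmin(t - cb, 0), pmax(t - cb, 0))
    f <- stats::lm.fit(X, y)
    sse <- sum(f$residuals^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(breakpoint = cb,
                   intercept = unname(f$coefficients[1]),
                   early_rate = unname(f$coefficients[2]),
                   late_rate = unname(f$coefficients[3]),
                   sse = sse)
    }
  }
  best$points <- data.frame(time = t, log_neff = y)
  class(best) <- "biphasic_fit"
  best
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat(sprintf("Biphasic fit: early %.3f/yr, late %.3f/yr, breakpoint %.1f yr (SSE %.3g)\n",
              x$early_rate, x$late_rate, x$breakpoint, x$sse))
  invisible(x)
}

#' Clonal deceleration metrics
#'
#' Quantifies deceleration of an expanded clade two ways. The
#' *size ratio* compares the observed clone size (clonal fraction in
#' the phylogeny scaled by the carrying capacity, in HSC x years)
#' with the size expected if early growth had continued to the
#' sampling age (extrapolation of the early biphasic segment,
#' computed in log space). The *growth ratio* compares the late
#' biphasic rate with the expected growth coefficient of a logistic
#' (sigmoidal) fit to the N_eff trajectory at fixed carrying
#' capacity; a ratio of 1 means no deceleration beyond saturation,
#' below 1 means the clone slowed.
#'
#' @param fit a [fit_biphasic()] result.
#' @param clade the `clade` the trajectory came from.
#' @param capacity HSC carrying capacity in HSC x years
#'   (default 200,000).
#' @param sampling_age age at sampling in years.
#' @return object of class `deceleration_report`: `expected_size`,
#'   `observed_size`, `size_ratio` (observed / expected),
#'   `expected_growth`, `growth_ratio` (late / expected),
#'   `log_expected_size`.
#' @export
deceleration_metrics <- function(fit, clade, capacity = 200000,
                                 sampling_age) {
  stopifnot(inherits(fit, "biphasic_fit"), inherits(clade, "clade"))
  stopifnot_scalar(capacity, "capacity", positive = TRUE)
  stopifnot_scalar(sampling_age, "sampling_age", positive = TRUE)
  log_expected <- fit$intercept +
    fit$early_rate * (sampling_age - fit$breakpoint)
  observed <- clade$clonal_fraction * capacity
  size_ratio <- exp(log(observed) - log_expected)

  ## logistic N(t) = K / (1 + exp(-rho (t - tm))) at fixed K,
  ## least squares on log N_eff
  t <- fit$points$time; y <- fit$points$log_neff
  obj <- function(par) {
    rho <- par[1]; tm <- par[2]
    yy <- log(capacity) - log1p(exp(pmin(-rho * (t - tm), 30)))
    sum((y - yy)^2)
  }
  ini <- c(max(fit$early_rate, 0.05), fit$breakpoint)
  op <- stats::optim(ini, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000))
  expected_growth <- op$par[1]
  structure(list(expected_size = exp(log_expected),
                 log_expected_size = log_expected,
                 observed_size = observed,
                 size_ratio = size_ratio,
                 expected_growth = expected_growth,
                 growth_ratio = fit$late_rate / expected_growth,
                 capacity = capacity,
                 sampling_age = sampling_age),
            class = "deceleration_report")
}

#' @export
print.deceleration_report <- function(x, ...) {
  cat(sprintf("Deceleration: observed size %.3g vs expected %.3g (ratio %.3g)\n",
              x$observed_size, x$expected_size, x$size_ratio))
  cat(sprintf("  late rate / expected growth = %.3f\n", x$growth_ratio))
  invisible(x)
}
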