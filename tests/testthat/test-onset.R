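test_that("onset closed forms reproduce hand-computed values", {
  ## scalar oracle: t0 = (log(1/n) - u)/b; adjustment
  ## log(g/b)/b - 1/b, evaluated by hand for two parameter sets
  o1 <- age_at_onset(0.2, -15, n_hsc = 50000, g = 2)
  t0_1 <- (log(1 / 50000) + 15) / 0.2
  adj_1 <- t0_1 + log(2 / 0.2) / 0.2 - 1 / 0.2
  expect_equal(o1$t0, t0_1, tolerance = 1e-9)
  expect_equal(o1$t0_adjusted, adj_1, tolerance = 1e-9)
  expect_equal(o1$t0, 20.9011, tolerance = 1e-4)
  expect_equal(o1$t0_adjusted, 27.4140, tolerance = 1e-4)

  o2 <- age_at_onset(0.1, -12)
  expect_equal(o2$t0, 11.8022, tolerance = 1e-4)
  expect_equal(o2$t0_adjusted, 31.7595, tolerance = 1e-4)
  expect_true(o1$feasible && o2$feasible)
})

test_that("when b equals g the adjustment reduces to -1/b", {
  b <- 2
  o <- age_at_onset(b, -14, g = 2)
  expect_equal(o$t0_adjusted, o$t0 - 1 / b, tolerance = 1e-12)
})

test_that("onset errors and monotonicity behave as the model implies", {
  expect_error(age_at_onset(0, -10), class = "clonaldyn_onset_error")
  expect_error(age_at_onset(-0.1, -10),
               class = "clonaldyn_onset_error")
  ## a larger offset u means a larger clone at birth, hence an
  ## earlier onset: t0_adjusted is strictly decreasing in u
  us <- seq(-20, -6, by = 1)
  t_adj <- age_at_onset(rep(0.15, length(us)), us)$t0_adjusted
  expect_true(all(diff(t_adj) < 0))
  ## and decreases with n at fixed (b, u)
  ns <- c(10000, 50000, 100000, 200000, 600000)
  t_n <- vapply(ns, function(n)
    age_at_onset(0.15, -12, n_hsc = n)$t0_adjusted, 0)
  expect_true(all(diff(t_n) < 0))
  ## smooth across the g grid: no jumps above numerical drift
  gs <- c(1, 2, 5, 10, 13, 20)
  t_g <- vapply(gs, function(g)
    age_at_onset(0.15, -12, g = g)$t0_adjusted, 0)
  expect_true(all(is.finite(t_g)))
  expect_true(all(abs(diff(t_g)) < 20))
})

test_that("minimal historical growth matches a fine-grid oracle", {
  hg <- minimal_historical_growth(0.2, 70, 0.05)
  expect_true(hg$capped)
  expect_gt(hg$minimal_historical_rate, 0.105)
  expect_lt(hg$minimal_historical_rate, 0.106)
  ## independent oracle: exhaustive fine grid on the onset equation
  ## 71 b + log(2 / b) = log(1/n) - logit(0.2) - 1  (n = 50,000)
  target <- -(log(1 / 50000) - logit_(0.2) - 1)
  bs <- seq(0.08, 0.14, by = 1e-6)
  b_star <- bs[which.min(abs(71 * bs + log(2 / bs) - target))]
  expect_lt(abs(hg$minimal_historical_rate - b_star), 1e-4)
  expect_lt(hg$ratio, 1)
})

test_that("feasible clones pass through unchanged", {
  hg <- minimal_historical_growth(0.2, 70, 0.3)
  expect_false(hg$capped)
  expect_equal(hg$minimal_historical_rate, 0.3)
  expect_equal(hg$ratio, 1)
  ## capping never places onset after the observation age
  hg2 <- minimal_historical_growth(0.2, 70, 0.05)
  o <- age_at_onset(hg2$minimal_historical_rate,
                    logit_(0.2) - hg2$minimal_historical_rate * 70)
  expect_equal(o$t0_adjusted, -1, tolerance = 1e-3)
  expect_lt(o$t0_adjusted, 70)
})

test_that("inconsistent historical-growth inputs are rejected", {
  expect_error(minimal_historical_growth(1.2, 70, 0.05), "latest_vaf")
  expect_error(minimal_historical_growth(0.2, -3, 0.05), "age_T")
})

test_that("detection latency matches its scalar oracle and shrinks with b", {
  ## t_detect solves ilogit(b t + u) = 0.002; logit(0.002) = -6.2126
  lat <- detection_latency(0.2, -15)
  t_det <- (logit_(0.002) + 15) / 0.2
  adj <- age_at_onset(0.2, -15)$t0_adjusted
  expect_equal(lat, t_det - adj, tolerance = 1e-9)
  expect_equal(lat, 16.523, tolerance = 1e-3)
  ## doubling b with u rescaled to keep t_detect fixed shrinks latency
  bs <- c(0.1, 0.2, 0.4)
  t_fix <- 50
  lats <- vapply(bs, function(b) {
    u <- logit_(0.002) - b * t_fix
    detection_latency(b, u)
  }, 0)
  expect_true(all(diff(lats) < 0))
  expect_error(detection_latency(0.1, -9, threshold_vaf = 0.7),
               "threshold_vaf")
})

test_that("posterior onset tables propagate draws per clone", {
  d <- make_clone_data(0.2, -15, depth = 5000L, beta_od = 150,
                       seed = 41)
  fit <- fit_clonal_growth(d, c(150, 15), iter = 1500, warmup = 750,
                           chains = 1, seed = 42)
  on <- clone_onsets(fit)
  expect_equal(nrow(on), 1)
  expect_lt(abs(on$t0_adjusted - 27.4), 6)
  expect_true(on$t0_adjusted_low < on$t0_adjusted)
  expect_true(on$t0_adjusted < on$t0_adjusted_high)
  expect_equal(on$growth_ratio, 1, tolerance = 1e-9)  # feasible clone
  expect_gt(on$latency, 5)
})
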