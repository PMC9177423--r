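test_that("a single coalescence gives the closed-form estimate", {
  ## 2 tips coalescing T years before sampling: N_eff = 2*1*T/2 = T
  T_ <- 13.5
  tr <- ape::read.tree(text = sprintf("(t1:%f,t2:%f)r;", T_, T_))
  tt <- as_time_tree(tr, age_at_sampling = 60)
  traj <- skyline_neff(NULL, tt)
  expect_equal(nrow(traj), 1)
  expect_equal(traj$neff, T_, tolerance = 1e-9)
  expect_equal(traj$n_coal, 1)
})

test_that("skyline consumes exactly tips - 1 coalescences", {
  set.seed(61)
  tr <- sim_const_coal_tree(30, 500)
  traj <- skyline_neff(NULL, as_time_tree(tr),
                       smoothing_epsilon = 20)
  expect_equal(sum(traj$n_coal), 29)
  expect_true(all(traj$neff >= 0))
  ## pooled spans respect the epsilon floor (except possibly none)
  expect_true(all(traj$var_log == trigamma(traj$n_coal)))
})

test_that("constant-size coalescent trees are recovered within 2x", {
  set.seed(62)
  ests <- replicate(50, {
    tr <- sim_const_coal_tree(50, 1e5)
    traj <- skyline_neff(NULL, as_time_tree(tr),
                         smoothing_epsilon =
                           diff(range(ape::branching.times(tr))) / 20)
    median(traj$neff)
  })
  expect_gt(median(ests), 0.5e5)
  expect_lt(median(ests), 2e5)
})

test_that("exponential growth rate is recovered within 25%", {
  set.seed(63)
  r <- 0.15
  slopes <- replicate(40, {
    tr <- sim_exp_coal_tree(50, 2000, r)
    tt <- as_time_tree(tr)
    traj <- skyline_neff(NULL, tt,
                         smoothing_epsilon =
                           diff(range(tt$node_times)) / 15)
    keep <- traj$neff > 0
    unname(coef(lm(log(traj$neff[keep]) ~ traj$time[keep]))[2])
  })
  expect_lt(abs(median(slopes) / r - 1), 0.25)
})

test_that("biphasic fit is exact on noiseless segments", {
  ## single line: both rates equal the slope; earliest tie wins
  t <- seq(10, 60, by = 5)
  traj1 <- data.frame(time = t, neff = exp(2 + 0.3 * t))
  f1 <- fit_biphasic(traj1)
  expect_equal(f1$early_rate, 0.3, tolerance = 1e-9)
  expect_equal(f1$late_rate, 0.3, tolerance = 1e-9)
  expect_equal(f1$breakpoint, t[2])      # earliest interior candidate
  expect_lt(f1$sse, 1e-18)

  ## two segments: slope 0.3 before t = 40, 0.05 after
  y <- ifelse(t <= 40, 0.3 * (t - 40), 0.05 * (t - 40)) + 5
  f2 <- fit_biphasic(data.frame(time = t, neff = exp(y)))
  expect_equal(f2$breakpoint, 40, tolerance = 1e-9)
  expect_equal(f2$early_rate, 0.3, tolerance = 1e-9)
  expect_equal(f2$late_rate, 0.05, tolerance = 1e-9)
})

test_that("biphasic fit tolerates log-scale noise", {
  set.seed(64)
  t <- seq(5, 75, length.out = 30)
  ok <- replicate(60, {
    y <- ifelse(t <= 40, 0.3 * (t - 40), 0.05 * (t - 40)) + 6 +
      rnorm(length(t), 0, 0.1)
    f <- fit_biphasic(data.frame(time = t, neff = exp(y)))
    abs(f$early_rate - 0.3) < 0.05 && abs(f$late_rate - 0.05) < 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("flagged points are excluded and scarcity errors", {
  t <- seq(10, 40, by = 5)
  traj <- data.frame(time = t, neff = exp(0.2 * t),
                     high_variance = c(FALSE, FALSE, TRUE, FALSE,
                                       FALSE, TRUE, FALSE))
  f <- fit_biphasic(traj)
  expect_equal(nrow(f$points), 5)
  all_bad <- data.frame(time = t, neff = exp(0.2 * t),
                        high_variance = TRUE)
  expect_error(fit_biphasic(all_bad), "usable")
})

test_that("deceleration ratios match their scalar oracle", {
  ## early 0.3/yr from size 1 at age 10, sampling at 70: expected
  ## size e^18; observed 0.5 x 200,000 = 1e5; ratio ~ 1.5e-3
  t <- seq(10, 30, length.out = 8)
  fit <- structure(list(breakpoint = 10, intercept = 0,
                        early_rate = 0.3, late_rate = 0.3, sse = 0,
                        points = data.frame(time = t,
                                            log_neff = 0.3 * (t - 10))),
                   class = "biphasic_fit")
  clade <- structure(list(tips = paste0("t", 1:48), mrca = 50L,
                          onset_lower = 5, onset_upper = 12,
                          driver = NA, n_tips = 48,
                          clonal_fraction = 0.5),
                     class = "clade")
  dec <- deceleration_metrics(fit, clade, capacity = 2e5,
                              sampling_age = 70)
  expect_equal(dec$log_expected_size, 18, tolerance = 1e-9)
  expect_equal(dec$observed_size, 1e5)
  expect_equal(dec$size_ratio, 1e5 / exp(18), tolerance = 1e-6)
  expect_equal(dec$size_ratio, 1.5e-3, tolerance = 0.02)

  ## single-phase extrapolation hitting the observed size: ratio 1
  log_obs <- log(0.5 * 2e5)
  fit1 <- fit
  fit1$intercept <- log_obs - 0.3 * 60
  dec1 <- deceleration_metrics(fit1, clade, capacity = 2e5,
                               sampling_age = 70)
  expect_equal(dec1$size_ratio, 1, tolerance = 1e-9)
})
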