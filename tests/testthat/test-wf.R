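test_that("wf_config validates its inputs", {
  expect_error(wf_config(n_hsc = 5, total_years = 10), "at least 10")
  expect_error(wf_config(total_years = 10,
                         drivers = list(list(label = "A", s = -1.5,
                                             onset_generation = 1))),
               "> -1")
  expect_error(wf_config(total_years = 10,
                         drivers = list(list(label = "A", s = 0.1,
                                             onset_generation = 99))),
               "onset_generation")
  expect_error(wf_config(n_hsc = 100, total_years = 10,
                         drivers = list(list(label = "A", s = 0,
                                             onset_generation = 0,
                                             init_cells = 200))),
               "exceed")
})

test_that("neutral drift is a martingale: mean fraction stays flat", {
  ## one clone seeded at 10% of a small compartment, s = 0
  finals <- vapply(1:300, function(s) {
    cfg <- wf_config(n_hsc = 500, generations_per_year = 2,
                     total_years = 15,
                     drivers = list(list(label = "A", s = 0,
                                         onset_generation = 0,
                                         init_cells = 50)),
                     seed = s)
    h <- simulate_wf(cfg)
    h$fractions[nrow(h$fractions), 1]
  }, 0)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.1), 3 * se)
})

test_that("establishment frequency increases with fitness, below 1", {
  est <- vapply(c(0.05, 0.2), function(s) {
    mean(vapply(1:150, function(sd_) {
      cfg <- wf_config(n_hsc = 2000, generations_per_year = 2,
                       total_years = 40,
                       drivers = list(list(label = "A", s = s,
                                           onset_generation = 0)),
                       seed = 5000 + sd_ + round(1e4 * s))
      simulate_wf(cfg)$established[["A"]]
    }, TRUE))
  }, 0)
  expect_lt(est[1], est[2])
  expect_lt(est[2], 1)
  expect_gt(est[1], 0)
})

test_that("conditional on establishment, logit fraction grows at log(1+s)", {
  s <- 0.15; slopes <- numeric(0); seed <- 100
  while (length(slopes) < 25) {
    seed <- seed + 1
    cfg <- wf_config(n_hsc = 10000, generations_per_year = 2,
                     total_years = 150,
                     drivers = list(list(label = "A", s = s,
                                         onset_generation = 0)),
                     seed = seed)
    h <- tryCatch(simulate_wf(cfg, condition_on = "A", max_tries = 40),
                  error = function(e) NULL)
    if (is.null(h)) next
    f <- h$fractions[, 1]
    win <- which(f > 0.02 & f < 0.5)
    if (length(win) < 10) next
    slopes <- c(slopes, unname(coef(lm(logit_(f[win]) ~ win))[2]))
  }
  expect_lt(abs(mean(slopes) / log(1 + s) - 1), 0.10)
})

test_that("a saturating clone keeps log-odds growth linear", {
  ## deterministic logistic map check: f' = f(1+s)/(1+fs) advances
  ## logit(f) by exactly log(1+s); a large saturating WF clone should
  ## track that within drift noise
  s <- 0.2
  cfg <- wf_config(n_hsc = 50000, generations_per_year = 2,
                   total_years = 60,
                   drivers = list(list(label = "A", s = s,
                                       onset_generation = 0,
                                       init_cells = 500)),
                   seed = 4)
  h <- simulate_wf(cfg, condition_on = "A")
  f <- h$fractions[, 1]
  win <- which(f > 0.2 & f < 0.9)
  inc <- diff(logit_(f))[win[-length(win)]]
  expect_lt(abs(mean(inc) - log(1 + s)), 0.1 * log(1 + s))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("fractions are multiples of 1/n and clones sum below 1", {
  cfg <- wf_config(n_hsc = 1000, generations_per_year = 2,
                   total_years = 25,
                   drivers = list(list(label = "A", s = 0.2,
                                       onset_generation = 0),
                                  list(label = "B", s = 0.1,
                                       onset_generation = 10)),
                   seed = 9)
  h <- simulate_wf(cfg)
  expect_true(all(abs(h$fractions * 1000 -
                        round(h$fractions * 1000)) < 1e-9))
  expect_true(all(rowSums(h$fractions) <= 1 + 1e-12))
  ## zero before onset
  expect_true(all(h$fractions[h$generations < 10, "B"] == 0))
  ## identical seed reproduces bit-identically
  h2 <- simulate_wf(cfg)
  expect_identical(h$cells, h2$cells)
})
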