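test_that("a noiseless logistic trajectory is recovered tightly", {
  d <- make_clone_data(0.2, -12, depth = 10000L)
  fit <- fit_clonal_growth(d, overdispersion = c(1000, 100),
                           iter = 2000, warmup = 1000, chains = 2,
                           seed = 1)
  b <- fit$draws$b_total[, "c1"]
  expect_lt(abs(mean(b) - 0.2), 0.02)
  h <- hpdi(b, 0.90)
  expect_true(h[["lower"]] <= 0.2 && 0.2 <= h[["upper"]])
  expect_lt(abs(mean(fit$draws$u[, "c1"]) + 12), 1)
})

test_that("a flat trajectory yields an HPDI containing zero", {
  d <- make_clone_data(0, -3, depth = 5000L, beta_od = 100, seed = 2)
  fit <- fit_clonal_growth(d, overdispersion = c(100, 10),
                           iter = 1500, warmup = 750, chains = 1,
                           seed = 3)
  h <- hpdi(fit$draws$b_total[, "c1"], 0.90)
  expect_true(h[["lower"]] <= 0 && 0 <= h[["upper"]])
})

test_that("the MCMC posterior matches deterministic grid integration", {
  ## independent oracle: 3-D quadrature over (b_total, u, beta) for a
  ## single clone; the (gene, clone) split collapses to a normal
  ## prior on their sum
  d <- make_clone_data(0.15, -10, depth = 2000L, beta_od = 100,
                       seed = 4)
  mu_od <- 100; sd_od <- 5
  bs <- seq(0.05, 0.30, length.out = 81)
  us <- seq(-16, -5, length.out = 81)
  betas <- seq(85, 115, length.out = 9)
  sd_b <- sqrt(0.1^2 + 0.05^2)
  loglik <- function(b, u, beta) {
    q <- ilogit_(b * d$age_years + u)
    a <- beta * q / (1 - q)
    sum(lchoose(d$depth, d$alt_count) +
          lbeta(d$alt_count + a, d$depth - d$alt_count + beta) -
          lbeta(a, beta))
  }
  lp <- array(NA_real_, c(length(bs), length(us), length(betas)))
  for (i in seq_along(bs)) for (j in seq_along(us))
    for (k in seq_along(betas))
      lp[i, j, k] <- loglik(bs[i], us[j], betas[k]) +
        dnorm(bs[i], 0, sd_b, log = TRUE) +
        dnorm(us[j], -8, 5, log = TRUE) +
        dnorm(betas[k], mu_od, sd_od, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  b_grid <- sum(sweep(w, 1, bs, "*"))
  u_grid <- sum(sweep(w, 2, us, "*"))

  fit <- fit_clonal_growth(d, overdispersion = c(mu_od, sd_od),
                           iter = 4000, warmup = 2000, chains = 2,
                           seed = 5)
  expect_lt(abs(mean(fit$draws$b_total[, "c1"]) - b_grid), 0.01)
  expect_lt(abs(mean(fit$draws$u[, "c1"]) - u_grid), 0.6)
})

test_that("growth is invariant to translating the age axis", {
  d1 <- make_clone_data(0.12, -9, depth = 4000L, beta_od = 100,
                        seed = 6)
  d2 <- d1; d2$age_years <- d2$age_years + 7
  f1 <- fit_clonal_growth(d1, c(100, 10), iter = 2000, warmup = 1000,
                          chains = 1, seed = 7)
  f2 <- fit_clonal_growth(d2, c(100, 10), iter = 2000, warmup = 1000,
                          chains = 1, seed = 7)
  b1 <- mean(f1$draws$b_total); b2 <- mean(f2$draws$b_total)
  expect_lt(abs(b1 - b2), 0.015)
  ## the offset absorbs the shift: u2 ~ u1 - 7 b
  expect_lt(abs(mean(f2$draws$u) - (mean(f1$draws$u) - 7 * b1)), 0.7)
})

test_that("recurrent-site and single-site-gene rules shape the model", {
  set.seed(8)
  mk <- function(ind, gene, site, consequence, b, u, clone = NULL) {
    ages <- c(60, 65, 70)
    q <- ilogit_(b * ages + u)
    data.frame(individual_id = ind,
               clone_id = clone %||% paste0(ind, "_", gene),
               gene = gene, site = site, consequence = consequence,
               age_years = ages, depth = 2000L,
               alt_count = rbetabinom(3, 2000L, 100 * q / (1 - q), 100),
               stringsAsFactors = FALSE)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  d <- rbind(mk("i1", "SRSF2", "P95H", "missense", 0.2, -15),
             mk("i2", "SRSF2", "P95H", "missense", 0.2, -14),
             mk("i3", "SRSF2", "P101L", "missense", 0.1, -9),
             mk("i4", "TP53", NA, "missense", 0.05, -6),
             mk("i5", "TP53", NA, "truncating", 0, -5),
             mk("i6", "JAK2", "V617F", "missense", 0.1, -9),
             mk("i7", "JAK2", "V617F", "missense", 0.1, -10))
  prep <- clonaldyn:::ch_prepare_data(d, 2)
  expect_setequal(prep$gene_labels, c("SRSF2", "TP53:M", "TP53:T"))
  expect_setequal(prep$site_labels, c("SRSF2 P95H", "JAK2 V617F"))
  ## JAK2 is single-recurrent-site: no gene effect
  expect_equal(prep$clones$gene_par[prep$clones$gene == "JAK2"],
               c(0L, 0L))
  ## dropping one P95H individual de-recurs the site
  d2 <- d[d$individual_id != "i2", ]
  prep2 <- clonaldyn:::ch_prepare_data(d2, 2)
  expect_false("SRSF2 P95H" %in% prep2$site_labels)
  ## JAK2 stays recurrent, still site-only
  expect_true("JAK2 V617F" %in% prep2$site_labels)
})

test_that("b_total draws equal the sum of their components", {
  dat <- simulate_cohort(gene_effects = c(TET2 = 0.1, DNMT3A = 0.05),
                         clones_per_gene = 3, seed = 9)
  fit <- fit_clonal_growth(dat, c(100, 10), iter = 600, warmup = 300,
                           chains = 1, seed = 10)
  cl <- fit$prep$clones
  for (i in seq_len(nrow(cl))) {
    expec <- fit$draws$b_gene[, cl$gene_label[i]] +
      fit$draws$b_clone[, cl$clone_id[i]]
    expect_equal(unname(fit$draws$b_total[, cl$clone_id[i]]),
                 unname(expec), tolerance = 1e-12)
  }
  ## every clone has exactly one offset column
  expect_equal(colnames(fit$draws$u), cl$clone_id)
})

test_that("degenerate inputs are rejected or flagged", {
  d <- make_clone_data(0.1, -9)
  expect_error(fit_clonal_growth(d[1, ], c(100, 10)), "2 timepoints")
  d_bad <- d; d_bad$alt_count[1] <- d_bad$depth[1] + 1L
  expect_error(fit_clonal_growth(d_bad, c(100, 10)), "depth")
  d_tie <- rbind(d, d[3, ])
  expect_error(fit_clonal_growth(d_tie, c(100, 10)),
               "strictly increasing")
  ## all-zero clone is fitted but flagged uninformative
  d0 <- make_clone_data(0.1, -30, depth = 500L)
  d0$alt_count <- 0L
  fit <- fit_clonal_growth(d0, c(100, 10), iter = 400, warmup = 200,
                           chains = 1, seed = 11)
  expect_true(fit$prep$clones$uninformative[1])
})
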