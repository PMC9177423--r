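## a hand-buildable caterpillar tree in mutation counts: four tips at
## depth 1,315 (55 pre-birth + 18/yr x 70 yr), inner node at 687
cater_tree <- function() {
  ape::read.tree(text = paste0(
    "((t1:628,(t2:314,t3:314)n2:314)n1:687,t4:1315)r;"))
}

test_that("the molecular-to-time map hits its anchor points", {
  tr <- cater_tree()
  mt <- structure(list(tree = tr,
                       metadata = list(age_at_sampling = 70,
                                       mutation_rate_per_year = 18,
                                       prebirth_mutations = 55,
                                       sensitivity = 1),
                       drivers = data.frame(node_label = "n1",
                                            driver = "SF3B1"),
                       node_times = NULL),
                  class = "mutation_tree")
  tt <- scale_tree_to_time(mt)
  ntip <- 4
  lab <- c(tr$tip.label, tr$node.label)
  tm <- setNames(tt$node_times, lab)
  ## tips at the sampling age, root at conception
  expect_equal(unname(tm[paste0("t", 1:4)]), rep(70, 4))
  expect_equal(unname(tm["r"]), -0.75)
  ## node at depth 687: (687 - 55) / (1315 - 55) * 70 = 35.11
  expect_equal(unname(tm["n1"]), (687 - 55) / 1260 * 70,
               tolerance = 1e-9)
  expect_equal(unname(tm["n1"]), 35.111, tolerance = 1e-3)
  ## node at depth 55 maps exactly to birth
  tr2 <- ape::read.tree(text = "((t1:1260,t2:1260)n1:55,t3:1315)r;")
  tt2 <- scale_tree_to_time(structure(list(
    tree = tr2, metadata = list(age_at_sampling = 70,
                                mutation_rate_per_year = 18,
                                prebirth_mutations = 55,
                                sensitivity = 1),
    drivers = data.frame(node_label = character(0),
                         driver = character(0)),
    node_times = NULL), class = "mutation_tree"))
  lab2 <- c(tr2$tip.label, tr2$node.label)
  expect_equal(unname(setNames(tt2$node_times, lab2)["n1"]), 0,
               tolerance = 1e-9)
})

test_that("sensitivity scaling equals pre-scaling the counts", {
  tr <- cater_tree()
  base <- list(age_at_sampling = 70, mutation_rate_per_year = 18,
               prebirth_mutations = 55, sensitivity = 1)
  mk <- function(tree, meta) structure(
    list(tree = tree, metadata = meta,
         drivers = data.frame(node_label = character(0),
                              driver = character(0)),
         node_times = NULL), class = "mutation_tree")
  tt_sens <- scale_tree_to_time(mk(tr, base), sensitivity = 0.85)
  tr_pre <- tr; tr_pre$edge.length <- tr$edge.length / 0.85
  tt_pre <- scale_tree_to_time(mk(tr_pre, base))
  expect_equal(tt_sens$node_times, tt_pre$node_times,
               tolerance = 1e-9)
  ## tip times are anchored at the sampling age either way
  expect_equal(tt_sens$node_times[1:4], rep(70, 4))

  ## joint rescale of counts and the pre-birth budget is exact
  trc <- tr; trc$edge.length <- tr$edge.length * 3
  m3 <- base; m3$prebirth_mutations <- 55 * 3
  tt3 <- scale_tree_to_time(mk(trc, m3))
  tt1 <- scale_tree_to_time(mk(tr, base))
  expect_equal(tt3$node_times, tt1$node_times, tolerance = 1e-9)
})

test_that("calibration rejects bad inputs", {
  tr <- cater_tree()
  mt <- structure(list(tree = tr,
                       metadata = list(age_at_sampling = 70,
                                       mutation_rate_per_year = 18,
                                       prebirth_mutations = 55,
                                       sensitivity = 1),
                       drivers = data.frame(node_label = character(0),
                                            driver = character(0)),
                       node_times = NULL), class = "mutation_tree")
  expect_error(scale_tree_to_time(mt, sensitivity = 1.2),
               "sensitivity")
  expect_error(scale_tree_to_time(mt, sensitivity = 0),
               "sensitivity")
  trn <- tr; trn$edge.length[2] <- -1
  mtn <- mt; mtn$tree <- trn
  expect_error(scale_tree_to_time(mtn), "non-negative")
})

test_that("clade rules: driver overrides size, thresholds bind", {
  ## ultrametric 14-tip tree, depth 30: A = 7 tips / stem 10 (size
  ## rule); nested x4 = 5 tips / stem 5 (qualifies but is inside A);
  ## B = 3 tips / stem 2 with a driver (driver rule only);
  ## C = 3 tips / stem 18 (long stem but too few tips)
  nwk <- paste0(
    "(((a1:10,a2:10)x1:10,((a3:10,a4:10)x2:5,(a5:10,a6:10)x3:5,",
    "a7:15)x4:5)A:10,",
    "((b1:20,b2:20)y1:8,b3:28)B:2,",
    "(c1:12,(c2:9,c3:9)z1:3)C:18,d1:30)r;")
  tr <- ape::read.tree(text = nwk)
  tt <- as_time_tree(tr, age_at_sampling = 30)
  ntip <- length(tr$tip.label)
  node_of <- function(lab) ntip + match(lab, tr$node.label)
  tt$drivers <- data.frame(node = node_of("B"), driver = "JAK2")
  cl <- detect_clades(tt, min_tips = 5, depth_fraction = 0.1)
  got <- vapply(cl, function(x) x$mrca, 0L)
  expect_true(node_of("A") %in% got)
  expect_true(node_of("B") %in% got)
  expect_false(node_of("C") %in% got)
  cl_b <- cl[[which(got == node_of("B"))]]
  expect_equal(cl_b$driver, "JAK2")
  expect_equal(cl_b$n_tips, 3)
  ## onset bounds are the stem-branch endpoints
  cl_a <- cl[[which(got == node_of("A"))]]
  expect_lt(cl_a$onset_lower, cl_a$onset_upper)
  expect_equal(cl_a$onset_upper,
               tt$node_times[node_of("A")], tolerance = 1e-9)
  expect_equal(cl_a$clonal_fraction, 7 / 14)

  ## the long-stem 3-tip clade appears once min_tips allows it
  cl3 <- detect_clades(tt, min_tips = 3, depth_fraction = 0.1)
  expect_true(node_of("C") %in% vapply(cl3, function(x) x$mrca, 0L))

  ## maximality: the nested qualifying clade x4 is not reported
  expect_false(node_of("x4") %in% got)
})

test_that("clade detection round-trips a simulated expansion", {
  cfg <- wf_config(n_hsc = 2000, generations_per_year = 2,
                   total_years = 40,
                   drivers = list(list(label = "D", s = 0.12,
                                       onset_generation = 20)),
                   seed = 51)
  h <- simulate_wf(cfg, condition_on = "D")
  f <- h$fractions[nrow(h$fractions), 1]
  mt <- sample_colony_tree(h, n_colonies = 60, seed = 52)
  tt <- scale_tree_to_time(mt)
  cl <- detect_clades(tt)
  drv <- Filter(function(x) !is.null(x$driver) && !is.na(x$driver), cl)
  expect_gte(length(drv), 1)
  frac <- drv[[1]]$clonal_fraction
  expect_lt(abs(frac - f), 3 * sqrt(f * (1 - f) / 60) + 0.05)
})
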