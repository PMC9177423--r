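## shared fixtures, all generated in code

logit_ <- function(p) log(p / (1 - p))
ilogit_ <- function(x) 1 / (1 + exp(-x))

## exact-logistic serial VAF data for one clone
make_clone_data <- function(b, u, ages = c(55, 60, 65, 70, 75),
                            depth = 10000L, beta_od = NULL,
                            clone = "c1", gene = "TET2", seed = NULL) {
  q <- ilogit_(b * ages + u)
  if (is.null(beta_od)) {
    alt <- as.integer(round(q * depth))
  } else {
    if (!is.null(seed)) set.seed(seed)
    alt <- rbetabinom(length(q), depth, beta_od * q / (1 - q), beta_od)
  }
  data.frame(individual_id = paste0("i_", clone), clone_id = clone,
             gene = gene, site = NA_character_,
             consequence = "missense", age_years = ages,
             depth = depth, alt_count = alt, stringsAsFactors = FALSE)
}

## independent coalescent simulators (oracles for the skyline)
sim_const_coal_tree <- function(n_tips, neff) {
  tr <- ape::rcoal(n_tips)
  tr$edge.length <- tr$edge.length * neff
  tr
}

sim_exp_coal_tree <- function(n_tips, n0, r) {
  tau <- 0; k <- n_tips; times <- numeric(0)
  while (k > 1) {
    E <- stats::rexp(1)
    tau <- log(exp(r * tau) + 2 * n0 * r * E / (k * (k - 1))) / r
    times <- c(times, tau); k <- k - 1
  }
  nodes <- as.list(paste0("t", seq_len(n_tips)))
  hts <- rep(0, n_tips)
  for (tm in times) {
    i <- sample(length(nodes), 2)
    nw <- sprintf("(%s:%f,%s:%f)", nodes[[i[1]]], tm - hts[i[1]],
                  nodes[[i[2]]], tm - hts[i[2]])
    nodes[[i[1]]] <- nw; hts[i[1]] <- tm
    nodes <- nodes[-i[2]]; hts <- hts[-i[2]]
  }
  ape::read.tree(text = paste0(nodes[[1]], ";"))
}

## wrap an ultrametric year-scaled phylo plus optional driver edges
make_time_tree <- function(tree, age = NULL, drivers = NULL) {
  tt <- as_time_tree(tree, age)
  if (!is.null(drivers)) tt$drivers <- drivers
  tt
}
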