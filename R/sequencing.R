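#' Sample longitudinal sequencing counts from a clone history
#'
#' Turns a simulated clone-fraction history into the serial
#' deep-sequencing table the longitudinal model consumes. Each driver
#' clone is heterozygous, so its expected allele fraction at age `t`
#' is `q = f(t) / 2`; read counts are beta-binomial around `q` with
#' technical overdispersion `beta_od`
#' (`alt ~ BB(depth, beta_od * q / (1 - q), beta_od)`).
#'
#' @param history a [simulate_wf()] result.
#' @param schedule ages (years) at which samples are drawn; must lie
#'   within the simulated span.
#' @param depth sequencing depth (reads) per observation, recycled.
#' @param beta_od technical overdispersion (beta-binomial
#'   concentration); `Inf` gives pure binomial noise.
#' @param seed integer seed.
#' @param individual_id label for the simulated individual.
#' @return a longitudinal data frame with columns `individual_id`,
#'   `clone_id`, `gene`, `site`, `consequence`, `age_years`, `depth`,
#'   `alt_count`, plus a `truth` attribute (per-clone data frame with
#'   the generative per-generation fitness `s`, the equivalent annual
#'   logit growth `b_annual = g * log(1 + s)` and `onset_age`).
#' @examples
#' cfg <- wf_config(n_hsc = 1000, total_years = 60,
#'                  drivers = list(list(label = "TET2", s = 0.1,
#'                                      onset_generation = 20)))
#' h <- simulate_wf(cfg, condition_on = "TET2")
#' sample_sequencing(h, schedule = c(50, 55, 60), depth = 2000,
#'                   beta_od = 100, seed = 7)
#' @export
sample_sequencing <- function(history, schedule, depth = 2000,
                              beta_od = 100, seed = 1L,
                              individual_id = "sim1") {
  stopifnot(inherits(history, "wf_history"))
  cfg <- history$config
  if (any(schedule < 0 | schedule > cfg$total_years + 1e-9))
    stop("'schedule' must lie within the simulated span", call. = FALSE)
  if (any(depth < 1)) stop("'depth' must be >= 1", call. = FALSE)
  stopifnot_scalar(beta_od, "beta_od", positive = TRUE, allow_inf = TRUE)
  schedule <- sort(schedule)
  depth <- rep_len(as.integer(depth), length(schedule))
  set.seed(seed)
  labels <- colnames(history$fractions)
  g <- cfg$generations_per_year
  rows <- list()
  for (j in seq_along(labels)) {
    f <- wf_fraction_at(history, schedule, j)
    q <- f / 2
    if (any(q >= 1)) stop("allele fraction q must be < 1", call. = FALSE)
    alt <- integer(length(q))
    pos <- q > 0
    if (any(pos)) {
      if (is.finite(beta_od)) {
        alt[pos] <- rbetabinom(sum(pos), depth[pos],
                               beta_od * q[pos] / (1 - q[pos]), beta_od)
      } else {
        alt[pos] <- stats::rbinom(sum(pos), depth[pos], q[pos])
      }
    }
    rows[[j]] <- data.frame(individual_id = individual_id,
                            clone_id = paste0(individual_id, "_", labels[j]),
                            gene = labels[j],
                            site = NA_character_,
                            consequence = "missense",
                            age_years = schedule,
                            depth = depth,
                            alt_count = alt,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  s <- vapply(cfg$drivers, `[[`, 0, "s")
  attr(out, "truth") <- data.frame(
    clone_id = paste0(individual_id, "_", labels),
    s = s,
    b_annual = g * log(1 + s),
    onset_age = vapply(cfg$drivers, `[[`, 0, "onset_generation") / g,
    stringsAsFactors = FALSE)
  out
}

#' Generate technical replicate sets for overdispersion calibration
#'
#' Emulates dilution-series or triplicate re-sequencing: groups of
#' `k` technical replicates share one true VAF and differ only by
#' beta-binomial sequencing noise.
#'
#' @param vafs true VAFs, one group per entry (0 allowed: a verified
#'   wild-type dilution point, which yields all-zero counts).
#' @param depth sequencing depth per replicate (recycled per group).
#' @param beta_od true technical overdispersion used to generate.
#' @param k replicates per group (>= 2).
#' @param seed integer seed.
#' @param groups_per_vaf how many independent groups to draw at each
#'   VAF (default 1).
#' @return data frame with columns `group_id`, `true_vaf`, `depth`,
#'   `alt_count`; `beta_od` is recorded in the `true_beta` attribute.
#' @examples
#' generate_replicates(c(0.05, 0.02, 0.01, 0.005, 0), depth = 2000,
#'                     beta_od = 100, k = 3, seed = 1)
#' @export
generate_replicates <- function(vafs, depth = 2000, beta_od = 100,
                                k = 3L, seed = 1L, groups_per_vaf = 1L) {
  if (any(vafs < 0 | vafs >= 1))
    stop("'vafs' must lie in [0, 1)", call. = FALSE)
  if (k < 2) stop("need k >= 2 replicates per group", call. = FALSE)
  stopifnot_scalar(beta_od, "beta_od", positive = TRUE, allow_inf = TRUE)
  set.seed(seed)
  vafs <- rep(vafs, each = groups_per_vaf)
  depth <- rep_len(as.integer(depth), length(vafs))
  rows <- lapply(seq_along(vafs), function(i) {
    q <- vafs[i]
    alt <- if (q == 0) integer(k)
           else if (is.finite(beta_od))
             rbetabinom(k, depth[i], beta_od * q / (1 - q), beta_od)
           else stats::rbinom(k, depth[i], q)
    data.frame(group_id = sprintf("grp%03d", i), true_vaf = q,
               depth = depth[i], alt_count = alt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "true_beta") <- beta_od
  out
}

#' Simulate a longitudinal cohort directly from the growth model
#'
#' Draws serial VAF observations exactly from the hierarchical
#' logistic beta-binomial model: each clone follows
#' `q(t) = ilogit(b_total * t + u)` with
#' `b_total = b_gene + b_site + b_clone`, and counts are
#' beta-binomial around `q(t)`. This is the generative-recovery
#' companion to the Wright-Fisher route of [sample_sequencing()]:
#' it matches the fitted model family exactly, so posterior coverage
#' can be assessed without simulator/model mismatch.
#'
#' Defaults mirror an elderly longitudinal cohort: observation
#' windows inside ages 55-81, 4-5 timepoints per clone, depths around
#' 1,700x, one clone per individual, first-timepoint VAFs spread over
#' 0.5-10 percent.
#'
#' @param gene_effects named numeric vector of annual logit-scale
#'   gene growth effects; each clone is assigned a gene (balanced).
#' @param clones_per_gene clones simulated per gene.
#' @param sd_clone SD of the per-clone unknown-cause effect
#'   (default 0.05/yr, the model prior scale).
#' @param ages_base timepoint ages before per-clone jitter.
#' @param depth mean sequencing depth.
#' @param beta_od technical overdispersion used to generate counts.
#' @param vaf0_range range of first-timepoint VAFs (uniform on the
#'   logit scale between these).
#' @param seed integer seed.
#' @return longitudinal data frame (same schema as
#'   [sample_sequencing()]) with a `truth` attribute holding
#'   per-clone `b_gene`, `b_clone`, `b_total` and `u`.
#' @export
simulate_cohort <- function(gene_effects = c(DNMT3A = 0.05, TET2 = 0.10,
                                             SF3B1 = 0.15, SRSF2 = 0.20),
                            clones_per_gene = 10L, sd_clone = 0.05,
                            ages_base = c(58, 62, 66, 70, 74),
                            depth = 1700, beta_od = 100,
                            vaf0_range = c(0.005, 0.10), seed = 1L) {
  set.seed(seed)
  rows <- list(); truth <- list(); idx <- 0L
  for (g in names(gene_effects)) {
    for (r in seq_len(clones_per_gene)) {
      idx <- idx + 1L
      ind <- sprintf("ind%03d", idx)
      cid <- sprintf("%s_%s", ind, g)
      ages <- ages_base + stats::runif(1, -2, 2)
      b_clone <- stats::rnorm(1, 0, sd_clone)
      b_total <- gene_effects[[g]] + b_clone
      q0 <- exp(stats::runif(1, log(vaf0_range[1]), log(vaf0_range[2])))
      u <- logit(q0) - b_total * ages[1]
      q <- ilogit(b_total * ages + u)
      dp <- pmax(200L, as.integer(round(stats::rnorm(length(ages),
                                                     depth, depth / 8))))
      alt <- rbetabinom(length(q), dp, beta_od * q / (1 - q), beta_od)
      rows[[idx]] <- data.frame(individual_id = ind, clone_id = cid,
                                gene = g, site = NA_character_,
                                consequence = "missense",
                                age_years = ages, depth = dp,
                                alt_count = alt, stringsAsFactors = FALSE)
      truth[[idx]] <- data.frame(clone_id = cid, gene = g,
                                 b_gene = gene_effects[[g]],
                                 b_clone = b_clone, b_total = b_total,
                                 u = u, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "truth") <- do.call(rbind, truth)
  out
}
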