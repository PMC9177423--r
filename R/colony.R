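#' Sample a single-colony phylogeny from a Wright-Fisher history
#'
#' Emulates whole-genome sequencing of single-cell-derived colonies:
#' `n_colonies` cells are drawn (without replacement) from the final
#' generation in proportion to clone sizes, and their genealogy is
#' built by a backward-in-time Wright-Fisher coalescent through the
#' recorded per-generation clone sizes (lineages in the same clone
#' pick parents uniformly among that clone's cells one generation
#' back; a clone's founder lineage rejoins the wild-type pool at the
#' clone's onset). Before birth the population is grown from a single
#' cell at conception (-0.75 years) by successive doublings, which
#' concentrates the earliest coalescences between conception and
#' birth. Branch lengths are somatic mutation counts: Poisson with
#' rate `mutation_rate_per_year` after birth, plus `prebirth_mutations`
#' expected on the conception-to-birth segment of each lineage.
#'
#' @param history a [simulate_wf()] result.
#' @param n_colonies number of colonies (tips), `>= 2` and at most
#'   `n_hsc`.
#' @param mutation_rate_per_year somatic mutations per year per
#'   lineage after birth (default 18).
#' @param prebirth_mutations expected mutations acquired between
#'   conception and birth (default 55).
#' @param seed integer seed.
#' @return an object of class `mutation_tree`: list with `tree`
#'   (an [ape::phylo] with branch lengths in mutation counts and
#'   labelled nodes), `metadata` (age at sampling, rates, sensitivity
#'   = 1), `drivers` (data frame `node_label`, `driver`: the branch on
#'   which each sampled driver clone arose), and `node_times` (true
#'   node times in years, named by node label -- simulation truth for
#'   validation).
#' @examples
#' cfg <- wf_config(n_hsc = 500, total_years = 40,
#'                  drivers = list(list(label = "SF3B1", s = 0.15,
#'                                      onset_generation = 20)))
#' h <- simulate_wf(cfg, condition_on = "SF3B1")
#' mt <- sample_colony_tree(h, n_colonies = 24, seed = 3)
#' mt$tree
#' @export
sample_colony_tree <- function(history, n_colonies,
                               mutation_rate_per_year = 18,
                               prebirth_mutations = 55, seed = 1L) {
  stopifnot(inherits(history, "wf_history"))
  cfg <- history$config
  if (n_colonies < 2) stop("need n_colonies >= 2", call. = FALSE)
  if (n_colonies > cfg$n_hsc)
    stop("n_colonies exceeds n_hsc", call. = FALSE)
  stopifnot_scalar(mutation_rate_per_year, "mutation_rate_per_year",
                   positive = TRUE)
  if (prebirth_mutations < 0)
    stop("prebirth_mutations must be >= 0", call. = FALSE)
  set.seed(seed)

  n_gen <- cfg$n_generations
  gpy <- cfg$generations_per_year
  age <- n_gen / gpy
  k_drv <- ncol(history$cells)
  onset <- vapply(cfg$drivers, function(d) as.integer(round(d$onset_generation)), 0L)
  clone_size <- function(gen, j) {        # cells of class j at generation gen
    if (j == 0L) cfg$n_hsc - sum(history$cells[gen + 1L, ])
    else history$cells[gen + 1L, j]
  }

  ## -- tips: multivariate-hypergeometric clone assignment ------------
  final <- history$cells[n_gen + 1L, ]
  pool <- rep.int(0:k_drv, c(cfg$n_hsc - sum(final), final))
  tip_clone <- sample(pool, n_colonies)

  ## node store ------------------------------------------------------
  node_time <- numeric(0); node_children <- list(); node_label <- character(0)
  new_node <- function(time, children, label) {
    node_time[length(node_time) + 1L] <<- time
    node_children[[length(node_time)]] <<- children
    node_label[length(node_time)] <<- label
    length(node_time)
  }
  for (i in seq_len(n_colonies))
    new_node(age, integer(0), sprintf("t%d", i))

  lin_node <- seq_len(n_colonies)         # active lineages
  lin_clone <- tip_clone
  n_internal <- 0L
  driver_node <- stats::setNames(rep(NA_character_, k_drv),
                                 colnames(history$cells))

  ## one backward WF step for one clone class: lineages pick parents
  ## uniformly among the class's N parent cells; groups sharing a
  ## parent merge into a new node at p_time.
  step_class <- function(p_time, cls, N) {
    members <- which(lin_clone == cls)
    if (length(members) <= 1L) return(invisible(NULL))
    par <- sample.int(N, length(members), replace = TRUE)
    drop <- integer(0)
    for (p in unique(par)) {
      grp <- members[par == p]
      if (length(grp) >= 2L) {
        n_internal <<- n_internal + 1L
        nd <- new_node(p_time, lin_node[grp], sprintf("n%d", n_internal))
        lin_node[grp[1L]] <<- nd
        drop <- c(drop, grp[-1L])
      }
    }
    if (length(drop)) {
      lin_node <<- lin_node[-drop]
      lin_clone <<- lin_clone[-drop]
    }
    invisible(NULL)
  }

  ## -- postnatal phase: parent generations n_gen-1 .. 0 --------------
  for (g in seq(n_gen, 1L)) {
    p <- g - 1L                           # parent generation
    p_time <- p / gpy
    for (j in 0:k_drv) {
      if (j > 0L && !any(lin_clone == j)) next
      N <- clone_size(p, j)
      if (j > 0L && N == 0L) next         # handled at onset below
      if (j == 0L && !any(lin_clone == 0L)) next
      step_class(p_time, j, max(N, 1L))
    }
    ## clones at their onset generation: the (now single) founder
    ## lineage rejoins the wild-type pool; its stem carries the driver
    for (j in seq_len(k_drv)) {
      if (p == onset[j] || (p < onset[j] && any(lin_clone == j))) {
        members <- which(lin_clone == j)
        if (length(members) == 0L) next
        if (length(members) > 1L) {
          ## force-merge at the founder cell
          n_internal <- n_internal + 1L
          nd <- new_node(p_time, lin_node[members],
                         sprintf("n%d", n_internal))
          lin_node[members[1L]] <- nd
          lin_node <- lin_node[-members[-1L]]
          lin_clone <- lin_clone[-members[-1L]]
          members <- members[1L]
        }
        driver_node[j] <- node_label[lin_node[members]]
        lin_clone[members] <- 0L
      }
    }
  }

  ## -- embryonic phase: doubling from 1 cell at conception -----------
  E <- max(1L, ceiling(log2(cfg$n_hsc)))
  for (e in seq(E - 1L, 0L)) {
    if (length(lin_node) <= 1L) break
    p_time <- -0.75 * (E - e) / E
    N <- max(1L, min(cfg$n_hsc, 2L^e))
    members <- seq_along(lin_clone)
    par <- sample.int(N, length(members), replace = TRUE)
    drop <- integer(0)
    for (p in unique(par)) {
      grp <- members[par == p]
      if (length(grp) >= 2L) {
        n_internal <- n_internal + 1L
        nd <- new_node(p_time, lin_node[grp], sprintf("n%d", n_internal))
        lin_node[grp[1L]] <- nd
        drop <- c(drop, grp[-1L])
      }
    }
    if (length(drop)) {
      lin_node <- lin_node[-drop]; lin_clone <- lin_clone[-drop]
    }
  }
  if (length(lin_node) > 1L) {            # guarantee a single root
    n_internal <- n_internal + 1L
    rt <- new_node(-0.75, lin_node, sprintf("n%d", n_internal))
    lin_node <- rt
  }
  root <- lin_node[1L]

  ## -- mutations and newick assembly ---------------------------------
  mut_rate_prebirth <- prebirth_mutations / 0.75
  edge_mutations <- function(t_parent, t_child) {
    post <- max(0, t_child - max(t_parent, 0))
    pre <- max(0, min(t_child, 0) - t_parent)
    stats::rpois(1L, mutation_rate_per_year * post) +
      stats::rpois(1L, mut_rate_prebirth * pre)
  }
  build <- function(id) {
    kids <- node_children[[id]]
    if (length(kids) == 0L) return(node_label[id])
    parts <- vapply(kids, function(k)
      sprintf("%s:%d", build(k), edge_mutations(node_time[id],
                                                node_time[k])),
      "")
    sprintf("(%s)%s", paste(parts, collapse = ","), node_label[id])
  }
  old <- options(expressions = 500000L); on.exit(options(old))
  ## if the sample's MRCA postdates conception (for example a complete
  ## clonal sweep), keep the trunk's mutations as a root edge so the
  ## somatic mutation budget from conception is preserved
  trunk <- if (node_time[root] > -0.75 + 1e-9)
    edge_mutations(-0.75, node_time[root]) else 0L
  nwk <- if (trunk > 0L) sprintf("%s:%d;", build(root), trunk)
         else sprintf("%s;", build(root))
  tree <- ape::read.tree(text = nwk)

  drv <- data.frame(node_label = unname(driver_node),
                    driver = names(driver_node),
                    stringsAsFactors = FALSE)
  drv <- drv[!is.na(drv$node_label), , drop = FALSE]
  structure(list(tree = tree,
                 metadata = list(age_at_sampling = age,
                                 mutation_rate_per_year = mutation_rate_per_year,
                                 prebirth_mutations = prebirth_mutations,
                                 sensitivity = 1),
                 drivers = drv,
                 node_times = stats::setNames(node_time, node_label)),
            class = "mutation_tree")
}

#' @export
print.mutation_tree <- function(x, ...) {
  cat(sprintf("Colony mutation tree: %d tips, age at sampling %.1f yr\n",
              length(x$tree$tip.label), x$metadata$age_at_sampling))
  cat(sprintf("  mutation rate %.1f /yr, %.0f pre-birth mutations\n",
              x$metadata$mutation_rate_per_year,
              x$metadata$prebirth_mutations))
  if (nrow(x$drivers))
    cat("  drivers:", paste(sprintf("%s@%s", x$drivers$driver,
                                    x$drivers$node_label),
                            collapse = ", "), "\n")
  invisible(x)
}
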