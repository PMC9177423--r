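#' Time-calibrate a colony mutation tree
#'
#' Converts a rooted phylogeny with branch lengths in somatic
#' mutation counts into a time tree in years. Branch lengths are
#' first corrected for variant-calling sensitivity (divided by
#' `sensitivity`), the tree is made ultrametric by proportional
#' per-tip path stretching (each node's calibrated molecular depth is
#' the mean, over its descendant tips, of its fractional position on
#' the root-to-tip path, scaled to the mean tip depth), and the
#' molecular axis is mapped to age in two phases: the first
#' `prebirth_mutations` (default 55) mutations span conception
#' (-0.75 years) to birth (time 0), and depths beyond that map
#' linearly onto (0, age at sampling].
#'
#' @param x a `mutation_tree` from [sample_colony_tree()] /
#'   [read_colony_tree()], or an [ape::phylo] (then
#'   `age_at_sampling` is required).
#' @param sensitivity variant-calling sensitivity in (0, 1];
#'   observed branch lengths are scaled by `1/sensitivity`.
#' @param age_at_sampling,prebirth_mutations,conception calibration
#'   constants; taken from the `mutation_tree` metadata when present.
#' @return object of class `time_tree`: list with `tree` (phylo,
#'   branch lengths in years), `node_times` (years, indexed by phylo
#'   node number; tips at `age_at_sampling`, root at conception),
#'   `mol_depths` (calibrated molecular depths), `age_at_sampling`,
#'   `conception`, and `drivers` (data frame `node`, `driver`).
#' @examples
#' cfg <- wf_config(n_hsc = 500, total_years = 40,
#'                  drivers = list(list(label = "SF3B1", s = 0.15,
#'                                      onset_generation = 10)))
#' h <- simulate_wf(cfg, condition_on = "SF3B1")
#' tt <- scale_tree_to_time(sample_colony_tree(h, 20, seed = 2))
#' range(tt$node_times)
#' @export
scale_tree_to_time <- function(x, sensitivity = NULL,
                               age_at_sampling = NULL,
                               prebirth_mutations = NULL,
                               conception = -0.75) {
  if (inherits(x, "mutation_tree")) {
    tr <- x$tree
    age_at_sampling <- age_at_sampling %||% x$metadata$age_at_sampling
    prebirth_mutations <- prebirth_mutations %||%
      x$metadata$prebirth_mutations
    sensitivity <- sensitivity %||% x$metadata$sensitivity %||% 1
    drivers <- x$drivers
  } else if (inherits(x, "phylo")) {
    tr <- x
    drivers <- data.frame(node_label = character(0),
                          driver = character(0))
    sensitivity <- sensitivity %||% 1
  } else stop("'x' must be a mutation_tree or phylo", call. = FALSE)
  prebirth_mutations <- prebirth_mutations %||% 55
  if (is.null(age_at_sampling) || age_at_sampling <= 0)
    stop("'age_at_sampling' must be a positive number of years",
         call. = FALSE)
  if (sensitivity <= 0 || sensitivity > 1)
    stop("'sensitivity' must lie in (0, 1]", call. = FALSE)
  if (is.null(tr$edge.length) || any(tr$edge.length < 0))
    stop("tree must have non-negative branch lengths", call. = FALSE)
  ntip <- length(tr$tip.label)
  if (ntip < 2) stop("need >= 2 tips", call. = FALSE)

  tr$edge.length <- tr$edge.length / sensitivity
  depth <- ape::node.depth.edgelength(tr)       # mutations from root
  ## a root edge (trunk above the sample MRCA) shifts all depths so
  ## they are measured from conception
  if (!is.null(tr$root.edge) && tr$root.edge > 0)
    depth <- depth + tr$root.edge / sensitivity
  tips <- seq_len(ntip)
  D <- mean(depth[tips])
  if (D <= prebirth_mutations)
    stop("mean tip depth must exceed prebirth_mutations", call. = FALSE)

  ## mean over descendant tips of (node depth / tip depth), postorder
  nnode <- ntip + tr$Nnode
  inv_sum <- numeric(nnode); n_desc <- numeric(nnode)
  inv_sum[tips] <- 1 / depth[tips]; n_desc[tips] <- 1
  eo <- ape::reorder.phylo(tr, "postorder")$edge
  for (e in seq_len(nrow(eo))) {
    p <- eo[e, 1]; ch <- eo[e, 2]
    inv_sum[p] <- inv_sum[p] + inv_sum[ch]
    n_desc[p] <- n_desc[p] + n_desc[ch]
  }
  mol <- D * depth * inv_sum / n_desc
  root <- ntip + 1L
  ## enforce root-to-tip monotonicity (preorder pass)
  eo2 <- ape::reorder.phylo(tr, "cladewise")$edge
  for (e in seq_len(nrow(eo2)))
    mol[eo2[e, 2]] <- max(mol[eo2[e, 2]], mol[eo2[e, 1]])
  mol[tips] <- D                                 # ultrametric anchor

  P <- prebirth_mutations
  tm <- ifelse(mol >= P,
               (mol - P) / (D - P) * age_at_sampling,
               conception * (1 - mol / P))
  tr_y <- tr
  tr_y$edge.length <- tm[tr$edge[, 2]] - tm[tr$edge[, 1]]

  drv <- data.frame(node = integer(0), driver = character(0))
  if (nrow(drivers)) {
    lab2node <- function(lab) {
      i <- match(lab, tr$tip.label)
      if (!is.na(i)) return(i)
      j <- match(lab, tr$node.label)
      if (!is.na(j)) return(ntip + j)
      NA_integer_
    }
    drv <- data.frame(node = vapply(drivers$node_label, lab2node, 0L),
                      driver = drivers$driver,
                      stringsAsFactors = FALSE)
    drv <- drv[!is.na(drv$node), , drop = FALSE]
  }
  structure(list(tree = tr_y, node_times = tm, mol_depths = mol,
                 age_at_sampling = age_at_sampling,
                 conception = conception,
                 prebirth_mutations = P, sensitivity = sensitivity,
                 drivers = drv),
            class = "time_tree")
}

#' Wrap an already-calibrated ultrametric tree as a time tree
#'
#' For trees whose branch lengths are already in years (for example
#' coalescent simulations), bypassing the mutation-count calibration
#' of [scale_tree_to_time()]. Tips are placed at `age_at_sampling`.
#'
#' @param tree an ultrametric [ape::phylo] with branch lengths in
#'   years.
#' @param age_at_sampling tip age in years (default: tree height).
#' @return a `time_tree`.
#' @export
as_time_tree <- function(tree, age_at_sampling = NULL) {
  stopifnot(inherits(tree, "phylo"))
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  height <- max(depth[seq_len(ntip)])
  age_at_sampling <- age_at_sampling %||% height
  tm <- depth - height + age_at_sampling
  structure(list(tree = tree, node_times = tm, mol_depths = depth,
                 age_at_sampling = age_at_sampling,
                 conception = min(tm),
                 prebirth_mutations = NA, sensitivity = 1,
                 drivers = data.frame(node = integer(0),
                                      driver = character(0))),
            class = "time_tree")
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("Time-calibrated tree: %d tips at age %.1f yr, root at %.2f yr\n",
              length(x$tree$tip.label), x$age_at_sampling,
              min(x$node_times)))
  invisible(x)
}

#' Detect expanded clades in a time-calibrated colony tree
#'
#' A clade (a set of colonies sharing a most recent common ancestor,
#' the proxy for an expanded HSC clone) qualifies if either a driver
#' mutation is annotated on the branch leading to its MRCA, or that
#' stem branch spans more than `depth_fraction` of the tree depth and
#' the clade has at least `min_tips` tips. Only maximal (outermost)
#' qualifying clades are returned. The onset bounds of the expansion
#' are the two ends of the MRCA's stem branch.
#'
#' @param time_tree a [scale_tree_to_time()] result.
#' @param min_tips minimum clade size for the driverless rule
#'   (default 5).
#' @param depth_fraction stem-span fraction of tree depth (default
#'   0.1).
#' @param depth_measure `"time"` (stem span in years over total time
#'   depth, the default) or `"molecular"` (mutation counts).
#' @return list of class `clade_set`; each element (class `clade`)
#'   has `tips`, `mrca`, `onset_lower`, `onset_upper`, `driver`,
#'   `n_tips`, `clonal_fraction`.
#' @export
detect_clades <- function(time_tree, min_tips = 5,
                          depth_fraction = 0.1,
                          depth_measure = c("time", "molecular")) {
  stopifnot(inherits(time_tree, "time_tree"))
  depth_measure <- match.arg(depth_measure)
  tr <- time_tree$tree
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  parent <- integer(ntip + tr$Nnode)
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  coord <- if (depth_measure == "time") time_tree$node_times
           else time_tree$mol_depths
  total_depth <- max(coord) - min(coord)

  ## descendant tip counts and tip lists
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  tip_sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) tip_sets[[i]] <- i
  eo <- ape::reorder.phylo(tr, "postorder")$edge
  for (e in seq_len(nrow(eo)))
    tip_sets[[eo[e, 1]]] <- c(tip_sets[[eo[e, 1]]], tip_sets[[eo[e, 2]]])

  drv_by_node <- stats::setNames(time_tree$drivers$driver,
                                 time_tree$drivers$node)
  qualifies <- function(v) {
    if (v == root) return(FALSE)
    drv <- !is.na(drv_by_node[as.character(v)])
    stem <- coord[v] - coord[parent[v]]
    drv || (stem > depth_fraction * total_depth &&
              length(tip_sets[[v]]) >= min_tips)
  }
  ## outermost qualifying clades: preorder, skip inside accepted ones
  accepted <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    if (v != root && qualifies(v)) {
      accepted <- c(accepted, v)
    } else {
      stack <- c(stack, kids[[as.character(v)]])
    }
  }
  out <- lapply(accepted, function(v) {
    structure(list(tips = tr$tip.label[tip_sets[[v]]], mrca = v,
                   onset_lower = time_tree$node_times[parent[v]],
                   onset_upper = time_tree$node_times[v],
                   driver = unname(drv_by_node[as.character(v)]),
                   n_tips = length(tip_sets[[v]]),
                   clonal_fraction = length(tip_sets[[v]]) / ntip),
              class = "clade")
  })
  structure(out, class = "clade_set")
}

#' @export
print.clade_set <- function(x, ...) {
  cat(sprintf("%d expanded clade(s):\n", length(x)))
  for (cl in x)
    cat(sprintf("  node %d: %d tips (fraction %.2f), onset %.1f-%.1f yr%s\n",
                cl$mrca, cl$n_tips, cl$clonal_fraction,
                cl$onset_lower, cl$onset_upper,
                if (!is.na(cl$driver %||% NA))
                  paste0(", driver ", cl$driver) else ""))
  invisible(x)
}

#' @export
as.data.frame.clade_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(cl)
    data.frame(mrca = cl$mrca, n_tips = cl$n_tips,
               clonal_fraction = cl$clonal_fraction,
               onset_lower = cl$onset_lower,
               onset_upper = cl$onset_upper,
               driver = cl$driver %||% NA_character_,
               tips = paste(cl$tips, collapse = ","),
               stringsAsFactors = FALSE)))
}
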