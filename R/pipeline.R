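#' Validate pipeline input files
#'
#' Schema-checks the longitudinal TSV, replicate TSV and colony tree
#' files before a run. All problems are collected and returned in
#' one table rather than thrown one at a time.
#'
#' @param longitudinal_tsv,replicate_tsv paths to the sequencing
#'   tables (optional).
#' @param tree_stem path stem of a colony tree written by
#'   [write_colony_tree()] (optional).
#' @return data frame with columns `file`, `where`, `message`;
#'   zero rows when everything is well formed.
#' @export
validate_inputs <- function(longitudinal_tsv = NULL,
                            replicate_tsv = NULL, tree_stem = NULL) {
  errs <- list()
  add <- function(file, where, message)
    errs[[length(errs) + 1L]] <<- data.frame(file = file,
                                             where = where,
                                             message = message,
                                             stringsAsFactors = FALSE)
  if (!is.null(longitudinal_tsv)) {
    if (!file.exists(longitudinal_tsv)) {
      add(longitudinal_tsv, "-", "file does not exist")
    } else {
      d <- tryCatch(read_longitudinal_tsv(longitudinal_tsv),
                    error = function(e) e)
      if (inherits(d, "error")) {
        add(longitudinal_tsv, "-", conditionMessage(d))
      } else {
        req <- c("individual_id", "clone_id", "gene", "site",
                 "consequence", "age_years", "depth", "alt_count")
        for (m in setdiff(req, names(d)))
          add(longitudinal_tsv, "header", paste("missing column", m))
        if (all(req %in% names(d))) {
          if (!is.numeric(d$depth) || any(d$depth != round(d$depth)))
            add(longitudinal_tsv, "depth", "non-integer depth")
          if (!is.numeric(d$alt_count) ||
              any(d$alt_count != round(d$alt_count)))
            add(longitudinal_tsv, "alt_count", "non-integer counts")
          bad <- which(d$alt_count > d$depth)
          for (r in bad)
            add(longitudinal_tsv, paste("row", r),
                "alt_count exceeds depth")
          for (cid in unique(d$clone_id)) {
            a <- d$age_years[d$clone_id == cid]
            if (length(a) < 2L)
              add(longitudinal_tsv, cid, "fewer than 2 timepoints")
            else if (any(diff(sort(a)) <= 0) || is.unsorted(a))
              add(longitudinal_tsv, cid,
                  "ages not strictly increasing")
          }
        }
      }
    }
  }
  if (!is.null(replicate_tsv)) {
    if (!file.exists(replicate_tsv)) {
      add(replicate_tsv, "-", "file does not exist")
    } else {
      d <- utils::read.table(replicate_tsv, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
      for (m in setdiff(c("group_id", "depth", "alt_count"), names(d)))
        add(replicate_tsv, "header", paste("missing column", m))
      if (all(c("group_id", "depth", "alt_count") %in% names(d))) {
        bad <- which(d$alt_count > d$depth)
        for (r in bad)
          add(replicate_tsv, paste("row", r), "alt_count exceeds depth")
        k <- table(d$group_id)
        for (g in names(k)[k < 2])
          add(replicate_tsv, g, "fewer than 2 replicates")
      }
    }
  }
  if (!is.null(tree_stem)) {
    nwk <- paste0(tree_stem, ".nwk")
    if (!file.exists(nwk)) {
      add(nwk, "-", "file does not exist")
    } else {
      tr <- tryCatch(ape::read.tree(nwk), error = function(e) e)
      if (inherits(tr, "error") || is.null(tr)) {
        add(nwk, "-", "Newick does not parse")
      } else {
        if (!ape::is.rooted(tr)) add(nwk, "-", "tree is not rooted")
        neg <- which(tr$edge.length < 0)
        for (e in neg)
          add(nwk, paste("branch to node", tr$edge[e, 2]),
              "negative branch length")
      }
      meta <- paste0(tree_stem, ".yaml")
      if (!file.exists(meta)) {
        add(meta, "-", "metadata YAML missing")
      } else {
        md <- yaml::read_yaml(meta)
        for (f in c("age_at_sampling", "mutation_rate_per_year",
                    "prebirth_mutations"))
          if (is.null(md[[f]])) add(meta, f, "missing metadata field")
      }
    }
  }
  if (length(errs)) do.call(rbind, errs)
  else data.frame(file = character(0), where = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Configure a full pipeline run
#'
#' Bundles the model constants, MCMC settings, stage toggles and the
#' master seed for [run_pipeline()]. Every stochastic stage receives
#' a seed derived from the master seed, recorded in the run manifest.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed.
#' @param stages character subset of
#'   `c("simulate", "fit", "onset", "phylo")`.
#' @param n_hsc,generations_per_year,capacity,prebirth_mutations,conception,threshold_vaf,outlier_cutoff,hpdi_mass
#'   model constants (see the module documentation for each).
#' @param iter,warmup,chains MCMC settings for the growth fit.
#' @param gene_effects,clones_per_gene,beta_od synthetic cohort
#'   settings (see [simulate_cohort()]).
#' @param n_colonies colonies sampled for the phylodynamic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "fit", "onset",
                                       "phylo"),
                            n_hsc = 50000, generations_per_year = 2,
                            capacity = 200000,
                            prebirth_mutations = 55,
                            conception = -1, threshold_vaf = 0.002,
                            outlier_cutoff = 0.025, hpdi_mass = 0.90,
                            iter = 2000L, warmup = 1000L, chains = 2L,
                            gene_effects = c(DNMT3A = 0.05,
                                             TET2 = 0.10,
                                             SRSF2 = 0.20),
                            clones_per_gene = 2L, beta_od = 100,
                            n_colonies = 96L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full clonal dynamics pipeline
#'
#' Orchestrates simulate -> overdispersion -> growth fit -> outliers
#' -> onset -> phylodynamics on a synthetic cohort, writing every
#' stage's table plus a manifest (config and derived seeds) to
#' `config$out_dir`. Identical config and seed reproduce identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results and
#'   the written paths.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- list(paths = character(0))
  wr <- function(d, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(d, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <<- c(out$paths, p)
    p
  }
  seeds <- list(cohort = derive_seed(config$seed, 11L),
                replicates = derive_seed(config$seed, 12L),
                od = derive_seed(config$seed, 13L),
                fit = derive_seed(config$seed, 14L),
                wf = derive_seed(config$seed, 15L),
                tree = derive_seed(config$seed, 16L))

  if ("simulate" %in% config$stages) {
    say("simulating cohort")
    out$data <- simulate_cohort(gene_effects = config$gene_effects,
                                clones_per_gene = config$clones_per_gene,
                                beta_od = config$beta_od,
                                seed = seeds$cohort)
    wr(out$data, "longitudinal.tsv")
    out$replicates <- generate_replicates(
      rep(c(0.05, 0.02, 0.01, 0.005, 0), 4),
      depth = 2000, beta_od = config$beta_od, k = 3L,
      seed = seeds$replicates)
    wr(out$replicates, "replicates.tsv")
  }
  if ("fit" %in% config$stages) {
    say("estimating overdispersion and fitting trajectories")
    out$od <- estimate_overdispersion(out$replicates,
                                      mode = "dilution",
                                      seed = seeds$od)
    out$fit <- fit_clonal_growth(out$data, out$od,
                                 iter = config$iter,
                                 warmup = config$warmup,
                                 chains = config$chains,
                                 seed = seeds$fit)
    sm <- summary(out$fit, mass = config$hpdi_mass)
    wr(format(sm, digits = 10), "posterior_summary.tsv")
    out$outliers <- flag_outliers(out$fit,
                                  cutoff = config$outlier_cutoff)
    wr(format(out$outliers$observations, digits = 10), "outliers.tsv")
  }
  if ("onset" %in% config$stages) {
    say("onset back-extrapolation")
    out$onsets <- clone_onsets(out$fit, n_hsc = config$n_hsc,
                               g = config$generations_per_year,
                               conception = config$conception,
                               threshold_vaf = config$threshold_vaf,
                               mass = config$hpdi_mass)
    wr(format(out$onsets, digits = 10), "onset.tsv")
  }
  if ("phylo" %in% config$stages) {
    say("phylodynamics")
    drv <- list(list(label = "SF3B1", s = 0.12,
                     onset_generation = 40L))
    cfg <- wf_config(n_hsc = config$n_hsc,
                     generations_per_year = config$generations_per_year,
                     total_years = 70, drivers = drv, seed = seeds$wf)
    h <- simulate_wf(cfg, condition_on = "SF3B1")
    mt <- sample_colony_tree(h, n_colonies = config$n_colonies,
                             prebirth_mutations = config$prebirth_mutations,
                             seed = seeds$tree)
    write_colony_tree(mt, file.path(config$out_dir, "colony_tree"))
    tt <- scale_tree_to_time(mt)
    cl <- detect_clades(tt)
    if (length(cl)) {
      wr(as.data.frame(cl), "clades.tsv")
      traj <- skyline_neff(cl[[1]], tt)
      wr(format(as.data.frame(traj), digits = 10),
         "neff_trajectory.tsv")
      bf <- tryCatch(fit_biphasic(traj), error = function(e) NULL)
      if (!is.null(bf)) {
        dec <- deceleration_metrics(bf, cl[[1]],
                                    capacity = config$capacity,
                                    sampling_age = tt$age_at_sampling)
        wr(data.frame(expected_size = dec$expected_size,
                      observed_size = dec$observed_size,
                      size_ratio = dec$size_ratio,
                      expected_growth = dec$expected_growth,
                      growth_ratio = dec$growth_ratio),
           "deceleration.tsv")
        out$deceleration <- dec
      }
      out$trajectory <- traj
      out$clades <- cl
    }
  }
  manifest <- list(config = lapply(
    config[setdiff(names(config), "out_dir")],
    function(x) if (is.numeric(x) || is.character(x) ||
                    is.logical(x)) x else as.list(x)),
    seeds = seeds,
    package_version = as.character(utils::packageVersion("clonaldyn")))
  yaml::write_yaml(manifest, file.path(config$out_dir,
                                       "manifest.yaml"))
  invisible(out)
}
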