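#' Read and write the longitudinal sequencing table
#'
#' Plain TSV with header columns `individual_id`, `clone_id`,
#' `gene`, `site`, `consequence`, `age_years`, `depth`, `alt_count`.
#'
#' @param data longitudinal data frame.
#' @param path file path.
#' @return `read_longitudinal_tsv` returns the data frame;
#'   `write_longitudinal_tsv` returns `path` invisibly.
#' @export
write_longitudinal_tsv <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_longitudinal_tsv
#' @export
read_longitudinal_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE,
                    colClasses = c(site = "character"))
}

#' Write and read a colony mutation tree
#'
#' The tree goes to Newick (branch lengths in mutation counts),
#' driver annotations to a sidecar TSV (`node_label`, `driver`) and
#' calibration metadata (age at sampling, mutation rate, pre-birth
#' mutations, sensitivity) to YAML.
#'
#' @param x a `mutation_tree`.
#' @param stem path stem; writes `<stem>.nwk`, `<stem>_drivers.tsv`,
#'   `<stem>.yaml`.
#' @return `write_colony_tree` returns the three paths invisibly;
#'   `read_colony_tree` the reassembled `mutation_tree` (without the
#'   simulation-truth node times).
#' @export
write_colony_tree <- function(x, stem) {
  stopifnot(inherits(x, "mutation_tree"))
  paths <- c(tree = paste0(stem, ".nwk"),
             drivers = paste0(stem, "_drivers.tsv"),
             meta = paste0(stem, ".yaml"))
  ape::write.tree(x$tree, paths[["tree"]])
  utils::write.table(x$drivers, paths[["drivers"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  yaml::write_yaml(x$metadata, paths[["meta"]])
  invisible(paths)
}

#' @rdname write_colony_tree
#' @export
read_colony_tree <- function(stem) {
  tree <- ape::read.tree(paste0(stem, ".nwk"))
  drivers <- utils::read.table(paste0(stem, "_drivers.tsv"),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(paste0(stem, ".yaml"))
  structure(list(tree = tree, metadata = meta, drivers = drivers,
                 node_times = NULL),
            class = "mutation_tree")
}
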