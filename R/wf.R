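#' Configure a Wright-Fisher clone simulation
#'
#' Describes a haematopoietic stem cell (HSC) compartment of fixed
#' size evolving by discrete-generation Wright-Fisher resampling, with
#' one or more driver clones that arise as single cells at given
#' generations and carry a per-generation selective advantage.
#'
#' @param n_hsc HSC population size (cells); default 50,000.
#' @param generations_per_year symmetric-division generations per
#'   year; default 2. Together these give the compartment's
#'   `N * tau` of 25,000 HSC x years.
#' @param total_years span of the simulation in years (age at final
#'   generation; generation 0 is birth).
#' @param drivers list of driver descriptions, each a list with
#'   `label` (character), `s` (fitness advantage per generation,
#'   `> -1`), `onset_generation` (generation at which the clone
#'   arises as `init_cells` cells), and optionally `s_late` and
#'   `switch_generation` for a mid-life fitness change, and
#'   `init_cells` (default 1).
#' @param seed integer seed; every simulation is reproducible.
#' @return an object of class `wf_config`.
#' @examples
#' cfg <- wf_config(total_years = 75,
#'                  drivers = list(list(label = "DNMT3A", s = 0.05,
#'                                      onset_generation = 40)))
#' @export
wf_config <- function(n_hsc = 50000, generations_per_year = 2,
                      total_years, drivers = list(), seed = 1L) {
  stopifnot_scalar(n_hsc, "n_hsc", positive = TRUE)
  stopifnot_scalar(generations_per_year, "generations_per_year",
                   positive = TRUE)
  stopifnot_scalar(total_years, "total_years", positive = TRUE)
  if (n_hsc < 10) stop("'n_hsc' must be at least 10", call. = FALSE)
  n_gen <- floor(total_years * generations_per_year)
  init_total <- 0
  for (d in drivers) {
    if (is.null(d$label) || !nzchar(d$label))
      stop("every driver needs a non-empty 'label'", call. = FALSE)
    if (is.null(d$s) || d$s <= -1)
      stop("driver fitness 's' must be > -1", call. = FALSE)
    og <- d$onset_generation
    if (is.null(og) || og < 0 || og > n_gen)
      stop(sprintf("driver '%s': onset_generation must lie in [0, %d]",
                   d$label, n_gen), call. = FALSE)
    init_total <- init_total + (d$init_cells %||% 1L)
  }
  if (init_total > n_hsc)
    stop("summed initial clone cells exceed n_hsc", call. = FALSE)
  structure(list(n_hsc = as.integer(n_hsc),
                 generations_per_year = generations_per_year,
                 total_years = total_years,
                 n_generations = as.integer(n_gen),
                 drivers = drivers, seed = as.integer(seed)),
            class = "wf_config")
}

#' Simulate Wright-Fisher clone fraction histories
#'
#' Exact multinomial resampling of `n_hsc` cells each generation.
#' A driver clone's expected offspring weight is `(1 + s)` relative
#' to wild type; clone fractions are recorded on the full generation
#' grid. A clone is `established` if it is still present at the
#' final generation.
#'
#' @param config a [wf_config()].
#' @param condition_on list of driver labels that must be established;
#'   the simulation is rerun (with fresh randomness from the same
#'   stream) until all of them survive drift, up to `max_tries`.
#' @param max_tries maximum reruns when conditioning (default 1,000).
#' @return an object of class `wf_history`: list with `config`,
#'   `generations` (0..n), `ages` (years), `fractions` (matrix,
#'   generations x drivers, multiples of `1/n_hsc`), `cells`
#'   (integer matrix of clone cell counts) and `established`
#'   (named logical).
#' @examples
#' cfg <- wf_config(n_hsc = 1000, total_years = 30,
#'                  drivers = list(list(label = "A", s = 0.1,
#'                                      onset_generation = 5)))
#' h <- simulate_wf(cfg)
#' h$established
#' @export
simulate_wf <- function(config, condition_on = character(),
                        max_tries = 1000L) {
  stopifnot(inherits(config, "wf_config"))
  condition_on <- as.character(condition_on)
  set.seed(config$seed)
  for (try in seq_len(max(1L, max_tries))) {
    h <- wf_run_once(config)
    if (length(condition_on) == 0L || all(h$established[condition_on]))
      return(h)
  }
  stop(sprintf("no run with clones {%s} established after %d tries",
               paste(condition_on, collapse = ", "), max_tries),
       call. = FALSE)
}

wf_run_once <- function(config) {
  n <- config$n_hsc
  n_gen <- config$n_generations
  drivers <- config$drivers
  k <- length(drivers)
  labels <- vapply(drivers, `[[`, "", "label")
  onset <- vapply(drivers, function(d) as.integer(round(d$onset_generation)),
                  0L)
  s0 <- vapply(drivers, `[[`, 0, "s")
  s_late <- vapply(drivers, function(d) d$s_late %||% d$s, 0)
  sw <- vapply(drivers, function(d)
    as.integer(d$switch_generation %||% (config$n_generations + 1L)), 0L)
  init <- vapply(drivers, function(d) as.integer(d$init_cells %||% 1L), 0L)

  cells <- matrix(0L, nrow = n_gen + 1L, ncol = k,
                  dimnames = list(NULL, labels))
  cur <- integer(k)                      # clone cells; wt = n - sum(cur)
  for (g in 0:n_gen) {
    born <- which(onset == g)
    for (j in born) {
      need <- init[j]
      if (n - sum(cur) < need)
        stop("no wild-type cells left to seed clone ", labels[j],
             call. = FALSE)
      cur[j] <- cur[j] + need
    }
    cells[g + 1L, ] <- cur
    if (g == n_gen) break
    s_now <- ifelse(g >= sw, s_late, s0)
    w <- c(n - sum(cur), cur * (1 + s_now))
    if (all(cur == 0L)) next             # nothing stochastic yet
    cur <- stats::rmultinom(1L, n, w / sum(w))[-1L, 1L]
  }
  structure(list(config = config,
                 generations = 0:n_gen,
                 ages = (0:n_gen) / config$generations_per_year,
                 fractions = cells / n,
                 cells = cells,
                 established = stats::setNames(cells[n_gen + 1L, ] > 0L,
                                               labels)),
            class = "wf_history")
}

#' @export
print.wf_history <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Wright-Fisher history: %d HSCs, %g gen/yr, %g years (%d generations)\n",
              cfg$n_hsc, cfg$generations_per_year, cfg$total_years,
              cfg$n_generations))
  fin <- x$fractions[nrow(x$fractions), , drop = TRUE]
  for (lab in colnames(x$fractions))
    cat(sprintf("  %-12s final fraction %.4f  established: %s\n",
                lab, fin[[lab]], x$established[[lab]]))
  invisible(x)
}

#' @export
plot.wf_history <- function(x, log_odds = FALSE, ...) {
  f <- x$fractions
  if (log_odds) {
    y <- log(f / (1 - f)); ylab <- "log odds clone fraction"
  } else {
    y <- f; ylab <- "clone fraction"
  }
  graphics::matplot(x$ages, y, type = "l", lty = 1,
                    xlab = "age (years)", ylab = ylab, ...)
  graphics::legend("topleft", legend = colnames(f), lty = 1,
                   col = seq_len(ncol(f)), bty = "n")
  invisible(x)
}

## Clone fraction at given ages (nearest generation).
wf_fraction_at <- function(history, ages, driver = 1L) {
  g <- round(ages * history$config$generations_per_year)
  g <- pmin(pmax(g, 0), history$config$n_generations)
  history$fractions[g + 1L, driver]
}
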