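#' Estimate technical VAF overdispersion from replicate sequencing
#'
#' Fits a shared beta-binomial concentration parameter `beta` to
#' groups of technical replicates that share one (unknown) true VAF:
#' within group `g`, `alt ~ BB(depth, beta * q_g / (1 - q_g), beta)`
#' with a free logit-scale mean per group. `beta` is parameterized as
#' `beta = exp(r)` with `r` unconstrained and no prior; the posterior
#' mean and SD of `beta` are the `(mu_od, sigma_od)` plugged into
#' [fit_clonal_growth()] as the overdispersion prior.
#'
#' In a `dilution` series the true VAF of each group is known by
#' design (the serial dilution factors), so the group means are fixed
#' at the `true_vaf` column and only `beta` is inferred -- this
#' avoids the incidental-parameter bias that arises when 2-3
#' replicates must also estimate their own mean. Verified wild-type
#' (VAF 0) groups carry no overdispersion information and are
#' excluded exactly. In `triplicate` mode (re-sequencing of cohort
#' samples at unknown VAFs) each group gets a free logit-scale mean;
#' with few replicates per group this is mildly conservative (beta
#' biased upward), which is the safe direction for the downstream
#' prior. All-zero groups are dropped in both modes.
#'
#' @param replicates data frame with columns `group_id`, `depth`,
#'   `alt_count` (e.g. from [generate_replicates()]); each group
#'   needs `k >= 2` rows.
#' @param mode `"dilution"` or `"triplicate"` (bookkeeping only; see
#'   Details).
#' @param iter,warmup MCMC iterations and warm-up (defaults give
#'   2,000 posterior draws; at least 1,000 are kept).
#' @param seed integer seed.
#' @return object of class `overdispersion_estimate`: list with
#'   `mu_od`, `sigma_od`, `n_posterior`, `draws` (posterior `beta`
#'   draws) and `group_vaf` (posterior-mean VAF per group).
#' @examples
#' reps <- generate_replicates(rep(c(0.05, 0.02, 0.01), 5),
#'                             depth = 2000, beta_od = 100, k = 3)
#' estimate_overdispersion(reps, iter = 1500, warmup = 500)
#' @export
estimate_overdispersion <- function(replicates,
                                    mode = c("dilution", "triplicate"),
                                    iter = 4000L, warmup = 2000L,
                                    seed = 1L) {
  mode <- match.arg(mode)
  req <- c("group_id", "depth", "alt_count")
  if (!all(req %in% names(replicates)))
    stop("replicates need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(replicates$alt_count > replicates$depth) ||
      any(replicates$alt_count < 0))
    stop("alt_count must lie in [0, depth]", call. = FALSE)
  grp <- split(replicates[c("depth", "alt_count")], replicates$group_id)
  if (any(vapply(grp, nrow, 0L) < 2L))
    stop("every replicate group needs k >= 2 replicates", call. = FALSE)
  nonzero <- vapply(grp, function(g) any(g$alt_count > 0), TRUE)
  if (!any(nonzero))
    stop("all replicate groups have zero alt counts; ",
         "overdispersion is not estimable", call. = FALSE)
  fixed_q <- NULL
  if (mode == "dilution") {
    if (!"true_vaf" %in% names(replicates))
      stop("dilution mode needs the known dilution VAFs in a ",
           "'true_vaf' column", call. = FALSE)
    fq <- tapply(replicates$true_vaf, replicates$group_id, `[`, 1L)
    fixed_q <- as.numeric(fq[names(grp)])[nonzero]
  }
  grp <- grp[nonzero]
  if (length(grp) < 3L)
    stop("need at least 3 informative replicate groups", call. = FALSE)

  G <- length(grp)
  depth <- lapply(grp, `[[`, "depth")
  alt <- lapply(grp, `[[`, "alt_count")
  loglik_group <- function(g, eta, beta) {
    q <- ilogit(eta)
    sum(dbetabinom(alt[[g]], depth[[g]], beta * q / (1 - q), beta,
                   log = TRUE))
  }

  set.seed(seed)
  eta <- if (is.null(fixed_q))
    vapply(seq_len(G), function(g)
      logit(min(max(sum(alt[[g]]) / sum(depth[[g]]), 1e-5), 0.99)), 0)
  else logit(fixed_q)
  r <- log(100)
  ll_g <- vapply(seq_len(G), function(g) loglik_group(g, eta[g], exp(r)), 0)
  ls_eta <- rep(log(0.3), G); ls_r <- log(0.5)
  acc_eta <- numeric(G); acc_r <- 0
  keep_r <- numeric(iter - warmup)
  keep_eta <- matrix(0, iter - warmup, G)

  for (it in seq_len(iter)) {
    beta <- exp(r)
    if (is.null(fixed_q)) {
      for (g in seq_len(G)) {
        prop <- eta[g] + stats::rnorm(1, 0, exp(ls_eta[g]))
        llp <- loglik_group(g, prop, beta)
        if (log(stats::runif(1)) < llp - ll_g[g]) {
          eta[g] <- prop; ll_g[g] <- llp; acc_eta[g] <- acc_eta[g] + 1
        }
      }
    }
    prop_r <- r + stats::rnorm(1, 0, exp(ls_r))
    llp_g <- vapply(seq_len(G), function(g)
      loglik_group(g, eta[g], exp(prop_r)), 0)
    if (log(stats::runif(1)) < sum(llp_g) - sum(ll_g)) {
      r <- prop_r; ll_g <- llp_g; acc_r <- acc_r + 1
    }
    if (it <= warmup && it %% 50L == 0L) {   # Robbins-Monro adaptation
      step <- 2 / sqrt(it / 50)
      ls_eta <- ls_eta + step * (acc_eta / 50 - 0.44)
      ls_r <- ls_r + step * (acc_r / 50 - 0.44)
      acc_eta[] <- 0; acc_r <- 0
    }
    if (it > warmup) {
      keep_r[it - warmup] <- r
      keep_eta[it - warmup, ] <- eta
    }
  }

  draws <- exp(keep_r)
  structure(list(mu_od = mean(draws), sigma_od = stats::sd(draws),
                 n_posterior = length(draws), draws = draws,
                 group_vaf = stats::setNames(colMeans(ilogit(keep_eta)),
                                             names(grp)),
                 mode = mode),
            class = "overdispersion_estimate")
}

#' @export
print.overdispersion_estimate <- function(x, ...) {
  cat(sprintf("Technical overdispersion (%s replicates): beta = %.1f (SD %.1f), %d posterior draws\n",
              x$mode, x$mu_od, x$sigma_od, x$n_posterior))
  invisible(x)
}
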