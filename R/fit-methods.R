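#' @export
print.clonal_growth <- function(x, ...) {
  cat(sprintf("Hierarchical clonal growth fit: %d clones, %d observations\n",
              nrow(x$prep$clones), nrow(x$prep$data)))
  cat(sprintf("  %d gene effects, %d recurrent-site effects\n",
              length(x$prep$gene_labels), length(x$prep$site_labels)))
  cat(sprintf("  %d chains x %d iterations (%d warm-up); %d kept draws\n",
              x$chains, x$iter, x$warmup, nrow(x$draws$b_total)))
  rh <- x$diagnostics$rhat
  if (length(rh))
    cat(sprintf("  max split R-hat: %.3f\n", max(rh, na.rm = TRUE)))
  cat(sprintf("  posterior beta_od: %.1f\n", mean(x$draws$beta)))
  invisible(x)
}

#' Posterior summaries of a clonal growth fit
#'
#' One row per model entity (gene effect, recurrent-site effect,
#' per-clone total growth and offset, overdispersion) with posterior
#' mean, median and HPDI.
#'
#' @param object a [fit_clonal_growth()] result.
#' @param mass HPDI mass (default 0.90).
#' @param ... unused.
#' @return data frame with columns `entity`, `type`, `mean`,
#'   `median`, `hpdi_low`, `hpdi_high`.
#' @export
summary.clonal_growth <- function(object, mass = 0.90, ...) {
  one <- function(m, type) {
    if (is.null(m) || ncol(m) == 0L) return(NULL)
    do.call(rbind, lapply(colnames(m), function(nm) {
      h <- hpdi(m[, nm], mass)
      data.frame(entity = nm, type = type, mean = mean(m[, nm]),
                 median = stats::median(m[, nm]),
                 hpdi_low = h[["lower"]], hpdi_high = h[["upper"]],
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(one(object$draws$b_gene, "gene"),
               one(object$draws$b_site, "site"),
               one(object$draws$b_total, "clone"),
               one(object$draws$u, "offset"),
               one(object$draws$beta, "overdispersion"))
  rownames(out) <- NULL
  attr(out, "mass") <- mass
  class(out) <- c("summary.clonal_growth", "data.frame")
  out
}

#' @export
print.summary.clonal_growth <- function(x, ...) {
  cat(sprintf("Posterior summary (%d%% HPDI):\n",
              round(100 * attr(x, "mass"))))
  top <- x[x$type %in% c("gene", "site", "overdispersion"), ]
  print.data.frame(top, digits = 3, row.names = FALSE)
  ncl <- sum(x$type == "clone")
  if (ncl) cat(sprintf("... plus %d per-clone growth and offset rows\n",
                       ncl))
  invisible(x)
}

#' Extract posterior-mean growth effects
#'
#' @param object a [fit_clonal_growth()] result.
#' @param type `"clone"` (posterior-mean annual `b_total` per clone,
#'   the default), `"gene"` or `"site"`.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.clonal_growth <- function(object,
                               type = c("clone", "gene", "site"), ...) {
  type <- match.arg(type)
  m <- switch(type, clone = object$draws$b_total,
              gene = object$draws$b_gene, site = object$draws$b_site)
  colMeans(m)
}

## per-clone draws of (b_total, u) in the age-0 logistic frame used
## by the onset algebra; the ceiling rescale folds into u.
ch_clone_draws <- function(object, clone_id) {
  i <- match(clone_id, colnames(object$draws$b_total))
  if (is.na(i)) stop("unknown clone_id: ", clone_id, call. = FALSE)
  list(b = object$draws$b_total[, i],
       u = object$draws$u[, i],
       beta = object$draws$beta[, 1])
}

#' Posterior predictive VAF of a clone at a given age
#'
#' Extrapolates a fitted clonal trajectory: returns the posterior
#' mean of `q(age)` and its HPDI per requested (clone, age) pair.
#'
#' @param object a [fit_clonal_growth()] result.
#' @param newdata data frame with columns `clone_id` and `age_years`;
#'   alternatively give `clone_id` and `age_years` directly.
#' @param clone_id,age_years used when `newdata` is missing.
#' @param mass HPDI mass (default 0.90).
#' @param ... unused.
#' @return data frame with `clone_id`, `age_years`, `vaf` (posterior
#'   predictive mean), `hpdi_low`, `hpdi_high`.
#' @export
predict.clonal_growth <- function(object, newdata = NULL,
                                  clone_id = NULL, age_years = NULL,
                                  mass = 0.90, ...) {
  if (is.null(newdata)) {
    if (is.null(clone_id) || is.null(age_years))
      stop("give 'newdata' or both 'clone_id' and 'age_years'",
           call. = FALSE)
    newdata <- data.frame(clone_id = clone_id, age_years = age_years)
  }
  out <- newdata[c("clone_id", "age_years")]
  out$vaf <- out$hpdi_low <- out$hpdi_high <- NA_real_
  for (i in seq_len(nrow(out))) {
    dr <- ch_clone_draws(object, out$clone_id[i])
    q <- object$vaf_ceiling * ilogit(dr$b * out$age_years[i] + dr$u)
    h <- hpdi(q, mass)
    out$vaf[i] <- mean(q)
    out$hpdi_low[i] <- h[["lower"]]; out$hpdi_high[i] <- h[["upper"]]
  }
  out
}

#' Held-out prediction error
#'
#' Mean absolute error, in VAF percentage points, between posterior
#' predictive VAFs and observed `alt_count / depth` on a held-out
#' table.
#'
#' @param object a [fit_clonal_growth()] result.
#' @param holdout data frame with `clone_id`, `age_years`, `depth`,
#'   `alt_count`.
#' @return MAE in VAF percentage points (scalar).
#' @export
prediction_mae <- function(object, holdout) {
  pred <- predict(object, holdout)
  100 * mean(abs(pred$vaf - holdout$alt_count / holdout$depth))
}

#' Posterior predictive simulation from a fitted model
#'
#' Draws replicate datasets from the fitted beta-binomial model at
#' the observed (clone, age, depth) design: for each replicate one
#' posterior draw is selected and counts are sampled from
#' `BB(depth, alpha(t), beta)`.
#'
#' @param object a [fit_clonal_growth()] result.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return a list of `nsim` data frames (the input schema with
#'   regenerated `alt_count`).
#' @export
simulate.clonal_growth <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$prep$data
  idx <- match(d$clone_id, colnames(object$draws$b_total))
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    k <- sample.int(nrow(object$draws$b_total), 1)
    b <- object$draws$b_total[k, idx]
    u <- object$draws$u[k, idx]
    beta <- object$draws$beta[k, 1]
    q <- object$vaf_ceiling * ilogit(b * d$age_years + u)
    dd <- d
    dd$alt_count <- ifelse(q > 0,
                           rbetabinom(nrow(d), d$depth,
                                      beta * q / (1 - q), beta),
                           0L)
    out[[s]] <- dd
  }
  out
}

## posterior-averaged two-sided tail probabilities per observation
ch_tail_probs <- function(object, data, n_draws = 100L) {
  nd <- nrow(object$draws$b_total)
  ks <- unique(round(seq(1, nd, length.out = min(n_draws, nd))))
  idx <- match(data$clone_id, colnames(object$draws$b_total))
  if (anyNA(idx))
    stop("data contains clones absent from the fit: ",
         paste(unique(data$clone_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  lo <- hi <- numeric(nrow(data))
  for (i in seq_len(nrow(data))) {
    b <- object$draws$b_total[ks, idx[i]]
    u <- object$draws$u[ks, idx[i]]
    beta <- object$draws$beta[ks, 1]
    q <- object$vaf_ceiling * ilogit(b * data$age_years[i] + u)
    q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
    a <- beta * q / (1 - q)
    t2 <- vapply(seq_along(ks), function(j)
      bb_tails(data$alt_count[i], data$depth[i], a[j], beta[j]),
      c(lower = 0, upper = 0))
    lo[i] <- mean(t2["lower", ]); hi[i] <- mean(t2["upper", ])
  }
  data.frame(lower_tail = lo, upper_tail = hi,
             tail_prob = pmin(lo, hi))
}

#' Flag outlying observations under the fitted growth model
#'
#' For every observation, computes the posterior-averaged two-sided
#' beta-binomial tail probability of the observed count under the
#' fitted trajectory; observations with a tail probability below
#' `cutoff` (default 2.5%) are outliers. A clone with no outliers is
#' growing at a fixed exponential rate over the observation period.
#' The cohort-level fixed-rate proportion is reported with a
#' beta-distributed (Jeffreys) confidence interval.
#'
#' @param object a [fit_clonal_growth()] result.
#' @param data observations to score (default: the fitted data).
#'   Ages outside the fitted range are scored by extrapolation.
#' @param cutoff two-sided tail cut-off (default 0.025).
#' @param n_draws posterior draws averaged for the tails.
#' @param ci_mass mass of the fixed-rate proportion CI (default 0.90).
#' @return object of class `outlier_report`: list with
#'   `observations` (per-row tails and flags), `clones` (per-clone
#'   `fixed_rate`), `fixed_rate_proportion` and its `ci`.
#' @export
flag_outliers <- function(object, data = NULL, cutoff = 0.025,
                          n_draws = 100L, ci_mass = 0.90) {
  stopifnot(inherits(object, "clonal_growth"))
  if (is.null(data)) data <- object$prep$data
  tails <- ch_tail_probs(object, data, n_draws)
  obs <- cbind(data[c("clone_id", "age_years", "depth", "alt_count")],
               tails)
  obs$outlier <- obs$tail_prob < cutoff
  fixed <- tapply(obs$outlier, obs$clone_id, function(x) !any(x))
  k <- sum(fixed); n <- length(fixed)
  alpha <- (1 - ci_mass) / 2
  ci <- stats::qbeta(c(alpha, 1 - alpha), k + 0.5, n - k + 0.5)
  structure(list(observations = obs,
                 clones = data.frame(clone_id = names(fixed),
                                     fixed_rate = as.logical(fixed),
                                     stringsAsFactors = FALSE),
                 fixed_rate_proportion = k / n,
                 ci = stats::setNames(ci, c("lower", "upper")),
                 ci_mass = ci_mass, cutoff = cutoff),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("Outlier report (tail cut-off %.1f%%):\n", 100 * x$cutoff))
  cat(sprintf("  %d / %d observations flagged\n",
              sum(x$observations$outlier), nrow(x$observations)))
  cat(sprintf("  fixed-rate clones: %.1f%% (%d/%d), %d%% CI [%.1f%%, %.1f%%]\n",
              100 * x$fixed_rate_proportion, sum(x$clones$fixed_rate),
              nrow(x$clones), round(100 * x$ci_mass),
              100 * x$ci[["lower"]], 100 * x$ci[["upper"]]))
  invisible(x)
}

#' @export
residuals.clonal_growth <- function(object, data = NULL,
                                    n_draws = 100L, ...) {
  if (is.null(data)) data <- object$prep$data
  tails <- ch_tail_probs(object, data, n_draws)
  ## signed tail residual: negative where the count falls low
  ifelse(tails$lower_tail < tails$upper_tail,
         -tails$tail_prob, tails$tail_prob)
}

#' Plot fitted clonal trajectories
#'
#' Observed VAFs (points; crosses where flagged as outliers if an
#' [flag_outliers()] report is supplied) with the posterior mean
#' trajectory and HPDI band per clone.
#'
#' @param x a [fit_clonal_growth()] result.
#' @param clone_id clones to draw (default: up to 6).
#' @param outliers optional `outlier_report`.
#' @param mass HPDI mass.
#' @param ... passed to [graphics::plot()].
#' @export
plot.clonal_growth <- function(x, clone_id = NULL, outliers = NULL,
                               mass = 0.90, ...) {
  ids <- clone_id %||% utils::head(colnames(x$draws$b_total), 6)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(ids)))
  on.exit(graphics::par(op))
  for (cid in ids) {
    d <- x$prep$data[x$prep$data$clone_id == cid, ]
    ages <- seq(min(d$age_years) - 2, max(d$age_years) + 2,
                length.out = 40)
    pr <- predict(x, clone_id = rep(cid, length(ages)),
                  age_years = ages, mass = mass)
    obs_v <- d$alt_count / d$depth
    graphics::plot(NA, xlim = range(ages),
                   ylim = range(0, obs_v, pr$hpdi_high),
                   xlab = "age (years)", ylab = "VAF", main = cid, ...)
    graphics::polygon(c(ages, rev(ages)),
                      c(pr$hpdi_low, rev(pr$hpdi_high)),
                      col = grDevices::grey(0.9), border = NA)
    graphics::lines(ages, pr$vaf, lwd = 2)
    pch <- rep(16, nrow(d))
    if (!is.null(outliers)) {
      fl <- outliers$observations
      flagged <- fl$outlier[match(paste(d$clone_id, d$age_years),
                                  paste(fl$clone_id, fl$age_years))]
      pch[which(flagged)] <- 4
    }
    graphics::points(d$age_years, obs_v, pch = pch)
  }
  invisible(x)
}
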