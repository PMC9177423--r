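#' Fit the hierarchical clonal growth model to serial VAF data
#'
#' Fits the Bayesian hierarchical beta-binomial logistic growth model
#' for clonal haematopoiesis trajectories. For clone `c` of
#' individual `j` observed at ages `t`, variant read counts are
#' modelled as
#' `alt ~ BetaBinomial(depth, alpha(t), beta)` with
#' `alpha(t) = beta * q(t) / (1 - q(t))` and
#' `q(t) = ilogit((b_gene + b_site + b_clone) * t + u)`.
#' `b_gene ~ N(0, 0.1)` and `b_site ~ N(0, 0.1)` are annual
#' logit-scale growth effects shared across clones with the same
#' driver gene (split into truncating/missense classes where a gene
#' carries both) or the same recurrent site; `b_clone ~ N(0, 0.05)`
#' is the residual, clone-specific "unknown-cause" growth; `u` is a
#' per-clone offset (age 0 frame) locating clone onset; and `beta`
#' is the technical overdispersion with prior
#' `N(mu_od, sigma_od)` (truncated positive) taken from
#' [estimate_overdispersion()].
#'
#' Site effects are included only for *recurrent* sites (a missense
#' site mutated in `>= recurrent_min_individuals` individuals). A
#' gene whose mutations all fall on one recurrent site (the
#' JAK2-V617F situation) is modelled at the site level only, to keep
#' gene and site effects identifiable.
#'
#' Sampling uses an adaptive Metropolis-within-Gibbs scheme on the
#' exact marginal beta-binomial likelihood: per-clone parameters are
#' centred at each clone's mean observation age, and dedicated
#' "ridge" moves translate mass between a gene (or site) effect and
#' its member clone effects without changing the likelihood, which
#' removes the hierarchical non-identifiability ridge that otherwise
#' cripples single-site updates. Proposal scales adapt during
#' warm-up only. Convergence is monitored by split R-hat across
#' chains; values above 1.05 on growth parameters trigger a warning.
#'
#' @param data longitudinal data frame with columns `individual_id`,
#'   `clone_id`, `gene`, `site`, `consequence`, `age_years`, `depth`,
#'   `alt_count` (the schema written by [sample_sequencing()] /
#'   [simulate_cohort()]). Every clone needs `>= 2` timepoints.
#' @param overdispersion an `overdispersion_estimate`, or a numeric
#'   vector `c(mu_od, sigma_od)`.
#' @param iter,warmup total MCMC iterations per chain and warm-up
#'   iterations discarded (defaults 5,000 and half).
#' @param chains number of independent chains (default 2).
#' @param seed integer seed.
#' @param vaf_ceiling saturation ceiling for `q(t)`: 1 implements
#'   the logistic formula as written; 0.5 caps the VAF of a
#'   heterozygous sweep at 50%.
#' @param recurrent_min_individuals individuals required to call a
#'   site recurrent (default 2).
#' @param u_prior mean and SD of the diffuse normal prior on the
#'   offset `u` (default `c(-15, 15)` on the logit scale). The SD is
#'   deliberately wide: a clone growing at 0.5/yr first detected at
#'   age 60 has a birth-frame offset near -35, which a tighter prior
#'   would shrink (and with it the growth estimate).
#' @param prior_sd named numeric: prior SDs for `gene`, `site`,
#'   `clone` effects; defaults `c(gene = 0.1, site = 0.1,
#'   clone = 0.05)`.
#' @return an object of class `clonal_growth`; see
#'   [summary.clonal_growth()], [coef.clonal_growth()],
#'   [predict.clonal_growth()], [flag_outliers()], [clone_onsets()].
#' @examples
#' dat <- simulate_cohort(gene_effects = c(TET2 = 0.1),
#'                        clones_per_gene = 3, seed = 2)
#' fit <- fit_clonal_growth(dat, overdispersion = c(100, 10),
#'                          iter = 600, warmup = 300, chains = 1)
#' summary(fit)
#' @export
fit_clonal_growth <- function(data, overdispersion,
                              iter = 5000L, warmup = floor(iter / 2),
                              chains = 2L, seed = 1L, vaf_ceiling = 1,
                              recurrent_min_individuals = 2L,
                              u_prior = c(-15, 15),
                              prior_sd = c(gene = 0.1, site = 0.1,
                                           clone = 0.05)) {
  od <- if (inherits(overdispersion, "overdispersion_estimate"))
    c(overdispersion$mu_od, overdispersion$sigma_od)
  else as.numeric(overdispersion)
  if (length(od) != 2L || any(!is.finite(od)) || any(od <= 0))
    stop("'overdispersion' must give positive (mu_od, sigma_od)",
         call. = FALSE)
  if (!vaf_ceiling %in% c(0.5, 1) && (vaf_ceiling <= 0 || vaf_ceiling > 1))
    stop("'vaf_ceiling' must be in (0, 1]", call. = FALSE)
  if (warmup >= iter) stop("'warmup' must be < 'iter'", call. = FALSE)

  prep <- ch_prepare_data(data, recurrent_min_individuals)
  chains_out <- vector("list", chains)
  for (ch in seq_len(chains)) {
    chains_out[[ch]] <- ch_run_chain(prep, od, iter = iter,
                                     warmup = warmup,
                                     seed = derive_seed(seed, ch),
                                     jitter = (ch - 1) * 0.5,
                                     ceiling = vaf_ceiling,
                                     u_prior = u_prior,
                                     prior_sd = prior_sd)
  }

  draws <- list()
  for (nm in c("b_total", "b_clone", "u", "b_gene", "b_site", "beta")) {
    mats <- lapply(chains_out, `[[`, nm)
    draws[[nm]] <- do.call(rbind, mats)
  }
  rhat <- ch_rhat(chains_out)
  bad <- rhat[rhat > 1.05 & !is.na(rhat)]
  if (length(bad) && chains > 1L)
    warning(sprintf("possible non-convergence: R-hat > 1.05 for %s",
                    paste(sprintf("%s (%.3f)", names(bad), bad),
                          collapse = ", ")), call. = FALSE)

  structure(list(draws = draws, prep = prep,
                 overdispersion = od, vaf_ceiling = vaf_ceiling,
                 u_prior = u_prior, prior_sd = prior_sd,
                 iter = iter, warmup = warmup, chains = chains,
                 seed = seed,
                 diagnostics = list(
                   rhat = rhat,
                   acceptance = lapply(chains_out, `[[`, "acceptance"))),
            class = "clonal_growth")
}

## ---------------------------------------------------------------------
## data preparation: effect structure per the recurrent-site and
## single-site-gene identifiability rules
ch_prepare_data <- function(data, recurrent_min_individuals = 2L) {
  req <- c("individual_id", "clone_id", "gene", "site", "consequence",
           "age_years", "depth", "alt_count")
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop("data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  data <- as.data.frame(data)[req]
  if (any(data$alt_count < 0 | data$alt_count > data$depth))
    stop("alt_count must lie in [0, depth]", call. = FALSE)
  data <- data[order(data$clone_id, data$age_years), ]
  sp <- split(seq_len(nrow(data)), data$clone_id)
  for (idx in sp) {
    a <- data$age_years[idx]
    if (length(a) < 2L)
      stop("every clone needs >= 2 timepoints (clone ",
           data$clone_id[idx[1]], ")", call. = FALSE)
    if (any(diff(a) <= 0))
      stop("ages must be strictly increasing within clone ",
           data$clone_id[idx[1]], call. = FALSE)
  }

  clones <- data[!duplicated(data$clone_id),
                 c("clone_id", "individual_id", "gene", "site",
                   "consequence")]
  rownames(clones) <- NULL
  cls <- ifelse(grepl("^trunc", clones$consequence, ignore.case = TRUE),
                "T", "M")

  ## recurrent sites: missense site carried by >= k individuals
  has_site <- !is.na(clones$site) & nzchar(clones$site) & cls == "M"
  site_key <- ifelse(has_site, paste(clones$gene, clones$site), NA)
  site_n_ind <- tapply(clones$individual_id[has_site],
                       site_key[has_site],
                       function(x) length(unique(x)))
  recurrent <- names(site_n_ind)[site_n_ind >= recurrent_min_individuals]
  clones$site_label <- ifelse(!is.na(site_key) & site_key %in% recurrent,
                              site_key, NA)

  ## gene labels: split T/M where a gene carries both classes
  both <- tapply(cls, clones$gene, function(x) length(unique(x)) > 1)
  clones$gene_label <- as.character(ifelse(both[clones$gene],
                                           paste(clones$gene, cls,
                                                 sep = ":"),
                                           clones$gene))
  ## single-recurrent-site genes are modelled at site level only
  site_only <- vapply(unique(clones$gene), function(g) {
    i <- clones$gene == g
    s <- unique(clones$site_label[i])
    length(s) == 1L && !is.na(s[1L])
  }, TRUE)
  clones$gene_label[site_only[clones$gene]] <- NA

  gene_labels <- sort(unique(stats::na.omit(clones$gene_label)))
  site_labels <- sort(unique(stats::na.omit(clones$site_label)))
  clones$gene_par <- match(clones$gene_label, gene_labels, nomatch = 0L)
  clones$site_par <- match(clones$site_label, site_labels, nomatch = 0L)
  clones$uninformative <- vapply(clones$clone_id, function(cid)
    all(data$alt_count[data$clone_id == cid] == 0L), TRUE)

  obs_clone <- match(data$clone_id, clones$clone_id)
  tbar <- vapply(split(data$age_years, obs_clone), mean, 0)
  list(data = data, clones = clones,
       gene_labels = gene_labels, site_labels = site_labels,
       obs_clone = obs_clone, tbar = tbar,
       obs_by_clone = split(seq_len(nrow(data)), obs_clone))
}

## ---------------------------------------------------------------------
## one MCMC chain (adaptive Metropolis-within-Gibbs + ridge moves)
ch_run_chain <- function(prep, od, iter, warmup, seed, jitter = 0,
                         ceiling = 1, u_prior = c(-15, 15),
                         prior_sd = c(gene = 0.1, site = 0.1,
                                      clone = 0.05)) {
  set.seed(seed)
  d <- prep$data
  C <- nrow(prep$clones); G <- length(prep$gene_labels)
  S <- length(prep$site_labels)
  n_obs <- nrow(d)
  depth <- d$depth; alt <- d$alt_count
  lch <- lchoose(depth, alt)
  oc <- prep$obs_clone
  tc <- d$age_years - prep$tbar[oc]        # centred ages
  obs_by_clone <- prep$obs_by_clone
  gene_par <- prep$clones$gene_par; site_par <- prep$clones$site_par
  clones_by_gene <- lapply(seq_len(G), function(g) which(gene_par == g))
  clones_by_site <- lapply(seq_len(S), function(s) which(site_par == s))
  obs_by_gene <- lapply(clones_by_gene, function(cs)
    unlist(obs_by_clone[cs], use.names = FALSE))
  obs_by_site <- lapply(clones_by_site, function(cs)
    unlist(obs_by_clone[cs], use.names = FALSE))

  sd_g <- prior_sd[["gene"]]; sd_s <- prior_sd[["site"]]
  sd_c <- prior_sd[["clone"]]
  mu_u <- u_prior[1]; sd_u <- u_prior[2]

  ll_fun <- function(idx, eta, beta) {
    e <- pmin(pmax(eta, -12), 12)
    q <- ceiling / (1 + exp(-e))
    a <- beta * q / (1 - q)
    lch[idx] + lbeta(alt[idx] + a, depth[idx] - alt[idx] + beta) -
      lbeta(a, beta)
  }

  ## crude per-clone init from a logit-VAF regression
  v <- numeric(C); bslope <- numeric(C)
  for (c_ in seq_len(C)) {
    idx <- obs_by_clone[[c_]]
    y <- logit(pmin(pmax(alt[idx] / depth[idx] / ceiling, 1e-4),
                    1 - 1e-4))
    fitl <- stats::lm.fit(cbind(1, tc[idx]), y)
    v[c_] <- fitl$coefficients[1]
    bslope[c_] <- min(max(fitl$coefficients[2], -0.5), 1)
  }
  bg <- numeric(G); bs <- numeric(S)
  for (g in seq_len(G))
    bg[g] <- mean(bslope[clones_by_gene[[g]]]) * 0.5
  for (s in seq_len(S))
    bs[s] <- mean(bslope[clones_by_site[[s]]]) * 0.25
  gidx <- ifelse(gene_par > 0, gene_par, G + 1L)   # pad index: effect 0
  sidx <- ifelse(site_par > 0, site_par, S + 1L)
  bc <- bslope - c(bg, 0)[gidx] - c(bs, 0)[sidx]
  bc <- pmin(pmax(bc, -0.2), 0.2)
  if (jitter > 0) {
    v <- v + stats::rnorm(C, 0, jitter)
    bc <- bc + stats::rnorm(C, 0, 0.02 * jitter)
    if (G) bg <- bg + stats::rnorm(G, 0, 0.02 * jitter)
    if (S) bs <- bs + stats::rnorm(S, 0, 0.02 * jitter)
  }
  beta <- max(od[1], 1e-3); lbet <- log(beta)

  Bc <- c(bg, 0)[gidx] + c(bs, 0)[sidx] + bc
  eta <- v[oc] + Bc[oc] * tc
  u <- v - Bc * prep$tbar
  ll <- ll_fun(seq_len(n_obs), eta, beta)

  ## adaptive scales
  ls_v <- rep(log(0.2), C); ls_bc <- rep(log(0.02), C)
  ls_bg <- rep(log(0.01), max(G, 1)); ls_bs <- rep(log(0.01), max(S, 1))
  ls_rg <- rep(log(0.03), max(G, 1)); ls_rs <- rep(log(0.03), max(S, 1))
  ls_b <- log(0.3)
  av <- numeric(C); abc <- numeric(C); abg <- numeric(max(G, 1))
  abs_ <- numeric(max(S, 1)); arg <- numeric(max(G, 1))
  ars <- numeric(max(S, 1)); ab <- 0

  n_keep <- iter - warmup
  K_b_total <- matrix(0, n_keep, C); K_bc <- matrix(0, n_keep, C)
  K_u <- matrix(0, n_keep, C)
  K_bg <- matrix(0, n_keep, max(G, 1)); K_bs <- matrix(0, n_keep, max(S, 1))
  K_beta <- numeric(n_keep)

  lprior_u <- function(uu) stats::dnorm(uu, mu_u, sd_u, log = TRUE)

  for (it in seq_len(iter)) {
    ## per-clone level v (value of logit q at the clone's mean age)
    dv <- stats::rnorm(C, 0, exp(ls_v))
    for (c_ in seq_len(C)) {
      idx <- obs_by_clone[[c_]]
      eta_p <- eta[idx] + dv[c_]
      llp <- ll_fun(idx, eta_p, beta)
      lr <- sum(llp) - sum(ll[idx]) +
        lprior_u(u[c_] + dv[c_]) - lprior_u(u[c_])
      if (log(stats::runif(1)) < lr) {
        v[c_] <- v[c_] + dv[c_]; u[c_] <- u[c_] + dv[c_]
        eta[idx] <- eta_p; ll[idx] <- llp; av[c_] <- av[c_] + 1
      }
    }
    ## per-clone slope residual b_clone
    db <- stats::rnorm(C, 0, exp(ls_bc))
    for (c_ in seq_len(C)) {
      idx <- obs_by_clone[[c_]]
      eta_p <- eta[idx] + db[c_] * tc[idx]
      llp <- ll_fun(idx, eta_p, beta)
      u_p <- u[c_] - db[c_] * prep$tbar[c_]
      lr <- sum(llp) - sum(ll[idx]) +
        stats::dnorm(bc[c_] + db[c_], 0, sd_c, log = TRUE) -
        stats::dnorm(bc[c_], 0, sd_c, log = TRUE) +
        lprior_u(u_p) - lprior_u(u[c_])
      if (log(stats::runif(1)) < lr) {
        bc[c_] <- bc[c_] + db[c_]; Bc[c_] <- Bc[c_] + db[c_]
        u[c_] <- u_p; eta[idx] <- eta_p; ll[idx] <- llp
        abc[c_] <- abc[c_] + 1
      }
    }
    ## gene effects
    for (g in seq_len(G)) {
      dg <- stats::rnorm(1, 0, exp(ls_bg[g]))
      cs <- clones_by_gene[[g]]; idx <- obs_by_gene[[g]]
      eta_p <- eta[idx] + dg * tc[idx]
      llp <- ll_fun(idx, eta_p, beta)
      u_p <- u[cs] - dg * prep$tbar[cs]
      lr <- sum(llp) - sum(ll[idx]) +
        stats::dnorm(bg[g] + dg, 0, sd_g, log = TRUE) -
        stats::dnorm(bg[g], 0, sd_g, log = TRUE) +
        sum(lprior_u(u_p)) - sum(lprior_u(u[cs]))
      if (log(stats::runif(1)) < lr) {
        bg[g] <- bg[g] + dg; Bc[cs] <- Bc[cs] + dg; u[cs] <- u_p
        eta[idx] <- eta_p; ll[idx] <- llp; abg[g] <- abg[g] + 1
      }
      ## ridge move: likelihood-invariant translation gene <-> clones
      dg <- stats::rnorm(1, 0, exp(ls_rg[g]))
      lr <- stats::dnorm(bg[g] + dg, 0, sd_g, log = TRUE) -
        stats::dnorm(bg[g], 0, sd_g, log = TRUE) +
        sum(stats::dnorm(bc[cs] - dg, 0, sd_c, log = TRUE)) -
        sum(stats::dnorm(bc[cs], 0, sd_c, log = TRUE))
      if (log(stats::runif(1)) < lr) {
        bg[g] <- bg[g] + dg; bc[cs] <- bc[cs] - dg
        arg[g] <- arg[g] + 1
      }
    }
    ## site effects
    for (s in seq_len(S)) {
      ds <- stats::rnorm(1, 0, exp(ls_bs[s]))
      cs <- clones_by_site[[s]]; idx <- obs_by_site[[s]]
      eta_p <- eta[idx] + ds * tc[idx]
      llp <- ll_fun(idx, eta_p, beta)
      u_p <- u[cs] - ds * prep$tbar[cs]
      lr <- sum(llp) - sum(ll[idx]) +
        stats::dnorm(bs[s] + ds, 0, sd_s, log = TRUE) -
        stats::dnorm(bs[s], 0, sd_s, log = TRUE) +
        sum(lprior_u(u_p)) - sum(lprior_u(u[cs]))
      if (log(stats::runif(1)) < lr) {
        bs[s] <- bs[s] + ds; Bc[cs] <- Bc[cs] + ds; u[cs] <- u_p
        eta[idx] <- eta_p; ll[idx] <- llp; abs_[s] <- abs_[s] + 1
      }
      ds <- stats::rnorm(1, 0, exp(ls_rs[s]))
      lr <- stats::dnorm(bs[s] + ds, 0, sd_s, log = TRUE) -
        stats::dnorm(bs[s], 0, sd_s, log = TRUE) +
        sum(stats::dnorm(bc[cs] - ds, 0, sd_c, log = TRUE)) -
        sum(stats::dnorm(bc[cs], 0, sd_c, log = TRUE))
      if (log(stats::runif(1)) < lr) {
        bs[s] <- bs[s] + ds; bc[cs] <- bc[cs] - ds
        ars[s] <- ars[s] + 1
      }
    }
    ## overdispersion beta (log-scale walk, truncated-normal prior)
    dl <- stats::rnorm(1, 0, exp(ls_b))
    beta_p <- exp(lbet + dl)
    llp <- ll_fun(seq_len(n_obs), eta, beta_p)
    lr <- sum(llp) - sum(ll) +
      stats::dnorm(beta_p, od[1], od[2], log = TRUE) -
      stats::dnorm(beta, od[1], od[2], log = TRUE) +
      log(beta_p) - log(beta)              # Jacobian of log transform
    if (is.finite(lr) && log(stats::runif(1)) < lr) {
      lbet <- lbet + dl; beta <- beta_p; ll <- llp; ab <- ab + 1
    }

    if (it <= warmup && it %% 50L == 0L) {
      step <- 2 / sqrt(it / 50)
      ls_v <- ls_v + step * (av / 50 - 0.44)
      ls_bc <- ls_bc + step * (abc / 50 - 0.44)
      if (G) ls_bg <- ls_bg + step * (abg / 50 - 0.44)
      if (S) ls_bs <- ls_bs + step * (abs_ / 50 - 0.44)
      if (G) ls_rg <- ls_rg + step * (arg / 50 - 0.44)
      if (S) ls_rs <- ls_rs + step * (ars / 50 - 0.44)
      ls_b <- ls_b + step * (ab / 50 - 0.44)
      av[] <- 0; abc[] <- 0; abg[] <- 0; abs_[] <- 0
      arg[] <- 0; ars[] <- 0; ab <- 0
    }
    if (it > warmup) {
      k <- it - warmup
      K_b_total[k, ] <- Bc; K_bc[k, ] <- bc; K_u[k, ] <- u
      if (G) K_bg[k, ] <- bg
      if (S) K_bs[k, ] <- bs
      K_beta[k] <- beta
    }
  }

  colnames(K_b_total) <- colnames(K_bc) <- colnames(K_u) <-
    prep$clones$clone_id
  colnames(K_bg) <- if (G) prep$gene_labels else "none"
  colnames(K_bs) <- if (S) prep$site_labels else "none"
  list(b_total = K_b_total, b_clone = K_bc, u = K_u,
       b_gene = K_bg[, seq_len(G), drop = FALSE],
       b_site = K_bs[, seq_len(S), drop = FALSE],
       beta = matrix(K_beta, ncol = 1,
                     dimnames = list(NULL, "beta_od")),
       acceptance = c(v = mean(av), b_clone = mean(abc),
                      beta = ab))
}

## split R-hat over chains for growth parameters and beta
ch_rhat <- function(chains_out) {
  collect <- function(nm) {
    mats <- lapply(chains_out, `[[`, nm)
    if (ncol(mats[[1]]) == 0L) return(NULL)
    mats
  }
  out <- c()
  for (nm in c("b_total", "b_gene", "b_site", "beta")) {
    mats <- collect(nm)
    if (is.null(mats)) next
    for (j in seq_len(ncol(mats[[1]]))) {
      halves <- unlist(lapply(mats, function(m) {
        x <- m[, j]; n2 <- floor(length(x) / 2)
        list(x[seq_len(n2)], x[n2 + seq_len(n2)])
      }), recursive = FALSE)
      means <- vapply(halves, mean, 0)
      vars <- vapply(halves, stats::var, 0)
      m <- length(halves); n <- length(halves[[1]])
      W <- mean(vars); B <- n * stats::var(means)
      r <- if (W <= 0) NA_real_ else sqrt(((n - 1) / n * W + B / n) / W)
      out[paste0(nm, "[", colnames(mats[[1]])[j], "]")] <- r
    }
  }
  out
}
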