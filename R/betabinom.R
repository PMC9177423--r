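#' Beta-binomial distribution
#'
#' Density, distribution function and random generation for the
#' beta-binomial distribution with size `size` and shape parameters
#' `alpha` and `beta`. This is the sequencing-noise model used
#' throughout the package: a read count at true allele fraction `q`
#' with technical overdispersion `beta` is beta-binomial with
#' `alpha = beta * q / (1 - q)`, so that the mean is `size * q` and
#' the concentration `alpha + beta` controls the extra-binomial
#' variance.
#'
#' @param x,q_ vector of counts.
#' @param size number of trials (sequencing depth).
#' @param alpha,beta positive shape parameters.
#' @param n number of random draws.
#' @param log,log.p logical; return log probabilities.
#' @param lower.tail logical; if `TRUE` (default) probabilities are
#'   `P(X <= x)`, otherwise `P(X >= x)` (note: inclusive upper tail,
#'   the convention used by the outlier test).
#' @return `dbetabinom` the (log) probability mass, `pbetabinom` the
#'   (log) tail probability, `rbetabinom` integer draws.
#' @examples
#' dbetabinom(5, 100, alpha = 2, beta = 38)
#' rbetabinom(3, 1000, alpha = 100 * 0.1 / 0.9, beta = 100)
#' @export
dbetabinom <- function(x, size, alpha, beta, log = FALSE) {
  ll <- lchoose(size, x) + lbeta(x + alpha, size - x + beta) -
    lbeta(alpha, beta)
  ll[x < 0 | x > size | x != round(x)] <- -Inf
  if (log) ll else exp(ll)
}

#' @rdname dbetabinom
#' @export
pbetabinom <- function(q_, size, alpha, beta, lower.tail = TRUE,
                       log.p = FALSE) {
  n <- max(length(q_), length(size), length(alpha), length(beta))
  q_ <- rep_len(q_, n); size <- rep_len(size, n)
  alpha <- rep_len(alpha, n); beta <- rep_len(beta, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- floor(q_[i])
    if (lower.tail) {
      if (x < 0) { out[i] <- 0; next }
      if (x >= size[i]) { out[i] <- 1; next }
      ks <- 0:x
    } else {
      x <- ceiling(q_[i])
      if (x <= 0) { out[i] <- 1; next }
      if (x > size[i]) { out[i] <- 0; next }
      ks <- x:size[i]
    }
    out[i] <- sum(dbetabinom(ks, size[i], alpha[i], beta[i]))
  }
  out <- pmin(pmax(out, 0), 1)
  if (log.p) log(out) else out
}

#' @rdname dbetabinom
#' @export
rbetabinom <- function(n, size, alpha, beta) {
  p <- stats::rbeta(n, alpha, beta)
  stats::rbinom(n, size, p)
}

## Both tails of BB(size, alpha, beta) at x, summing over the shorter
## side so cost is O(min(x, size - x)). Returns c(lower, upper),
## inclusive at x on both sides.
bb_tails <- function(x, size, alpha, beta) {
  if (x <= size / 2) {
    lo <- sum(dbetabinom(0:x, size, alpha, beta))
    hi <- 1 - lo + dbetabinom(x, size, alpha, beta)
  } else {
    hi <- sum(dbetabinom(x:size, size, alpha, beta))
    lo <- 1 - hi + dbetabinom(x, size, alpha, beta)
  }
  c(lower = min(max(lo, 0), 1), upper = min(max(hi, 0), 1))
}
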