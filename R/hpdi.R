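#' Highest posterior density interval
#'
#' Shortest contiguous interval over the sorted sample containing at
#' least `mass` of the draws. Ties between equally short windows are
#' broken to the earliest (left-most) window.
#'
#' @param samples numeric vector of posterior draws (>= 10).
#' @param mass interval probability mass, in (0, 1); default 0.90.
#' @return named numeric vector `c(lower, upper)` with attribute
#'   `mass`.
#' @examples
#' hpdi(rnorm(1e4))          # about c(-1.64, 1.64)
#' hpdi(1:100, mass = 0.5)   # width-49 window, earliest: c(1, 50)
#' @export
hpdi <- function(samples, mass = 0.90) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("'mass' must be a single number in (0, 1)", call. = FALSE)
  samples <- samples[is.finite(samples)]
  n <- length(samples)
  if (n < 10L)
    stop("need at least 10 finite samples for an HPDI", call. = FALSE)
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) {
    out <- c(lower = s[1L], upper = s[n])
  } else {
    widths <- s[(m):n] - s[seq_len(n - m + 1L)]
    i <- which.min(widths)             # which.min takes the earliest tie
    out <- c(lower = s[i], upper = s[i + m - 1L])
  }
  attr(out, "mass") <- mass
  out
}
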