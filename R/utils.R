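#' @keywords internal
"_PACKAGE"

## logit/ilogit with clamping: logistic trajectories routinely visit
## eta beyond +-30 where ilogit under/overflows to exactly 0/1.
logit <- function(p) log(p) - log1p(-p)

ilogit <- function(x) {
  x <- pmin(pmax(x, -30), 30)
  1 / (1 + exp(-x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Derive a stream-specific 32-bit seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12553L) %% 2147483647L
}

stopifnot_scalar <- function(x, name, positive = FALSE,
                             allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L &&
    (is.finite(x) || (allow_inf && is.infinite(x) && x > 0))
  if (!ok)
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
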