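#' Round half away from zero
#'
#' Fixed-point rounding with halves rounded up (away from zero), the
#' convention used for reported segregation ratios. Base \code{round()} uses
#' banker's rounding, which would turn 16.865 into 16.86 or 16.87 depending on
#' binary representation; reports here always round half up.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to \code{digits} decimals.
#' @examples
#' roundHalfUp(16.865, 2)
#' @export
roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Derive a stage seed from a global seed; kept well below 2^31.
.stageSeed <- function(seed, stage) {
  (as.integer(seed) %% 1000000L) * 1009L + stage * 101L
}

.msg <- function(verbose, ...) if (isTRUE(verbose)) message(...)

## Reduce an integer vector to its smallest integer ratio.
.simplifyRatio <- function(x) {
  stopifnot(all(x == as.integer(x)), any(x > 0))
  g <- Reduce(function(a, b) {
    while (b != 0) { t <- b; b <- a %% b; a <- t }
    a
  }, x[x > 0])
  as.integer(x / g)
}
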