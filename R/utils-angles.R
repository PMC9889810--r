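#' @keywords internal
#' @import methods
#' @importFrom stats rnorm runif sd median quantile t.test cor.test
#'   dgamma convolve filter lm.fit setNames
#' @importFrom utils read.delim write.table
"_PACKAGE"

## Angular helpers. All public-facing angles are degrees, counterclockwise
## from the positive x-axis (the fixed reference frame of the arena plane).

wrapDegrees <- function(x) {
  out <- x %% 360
  out[out == 360] <- 0
  out
}

## minor angular separation, in [0, 180]
angularSeparation <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

## chord length subtended by a separation of `sep` degrees on a circle
chordFromSeparation <- function(sep, radius) {
  2 * radius * sin(sep * pi / 360)
}

angleToXY <- function(angle, radius) {
  cbind(x = radius * cos(angle * pi / 180),
        y = radius * sin(angle * pi / 180))
}

## wrap an orientation into the fundamental domain [0, 360/n)
wrapFundamental <- function(phi, n) {
  dom <- 360 / n
  out <- phi %% dom
  out[out == dom] <- 0
  out
}

## circular difference of two orientations defined modulo 360/n, in
## [0, 180/n]
fundamentalDifference <- function(a, b, n) {
  dom <- 360 / n
  d <- abs(a - b) %% dom
  pmin(d, dom - d)
}

degToRad <- function(x) x * pi / 180
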