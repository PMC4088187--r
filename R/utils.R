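#' @useDynLib smrphase, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rnorm runif rexp sd lm pf pt coef fft
#'   kmeans ks.test pnorm dbinom
#' @importFrom utils write.table read.table
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Wrap angles to the half-open interval (-pi, pi]
#'
#' @param x numeric vector/array of angles in radians.
#' @return angles wrapped to (-pi, pi], same shape as `x`.
#' @export
wrap_angle <- function(x) {
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w <= -pi] <- pi
  w
}

#' Circular mean of a set of angles
#'
#' Four-quadrant arctangent of the summed sines and cosines. When the
#' resultant vector length is (numerically) zero the mean direction is
#' undefined; by convention 0 is returned and the `degenerate` attribute of
#' the result is set.
#'
#' @param x angles in radians.
#' @param eps resultant-length threshold below which the mean is flagged
#'   degenerate.
#' @return scalar angle in (-pi, pi] with attributes `resultant` (mean
#'   resultant length in \[0, 1\]) and `degenerate` (logical).
#' @export
circular_mean <- function(x, eps = 1e-8) {
  s <- sum(sin(x)); c <- sum(cos(x))
  r <- sqrt(s^2 + c^2) / length(x)
  out <- if (r < eps) 0 else wrap_angle(atan2(s, c))
  attr(out, "resultant") <- r
  attr(out, "degenerate") <- r < eps
  out
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a stream of independent sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
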