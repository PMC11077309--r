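# Shared helpers: angle wrapping, geometric-mean normalisation, seed streams.

#' Wrap angles in degrees onto the half-open interval [-180, 180)
#'
#' Values of exactly +180 map to -180, so the interval is genuinely
#' half-open. Used on ingest and whenever angles are shifted.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in `[-180, 180)`.
#' @export
wrap_degrees <- function(x) {
  (x + 180) %% 360 - 180
}

# Geometric mean of a positive vector.
geom_mean <- function(x) exp(mean(log(x)))

# Draw n independent sub-seeds from one top-level seed, so that each
# stochastic stage (or gene) gets its own reproducible stream.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

# Wrapped-normal draws on the circle, degrees.
rwrapnorm <- function(n, mean_deg, sd_deg) {
  wrap_degrees(stats::rnorm(n, mean_deg, sd_deg))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
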