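# Shared numeric helpers.

#' Centered moving average with shrinking edge windows
#'
#' Smooths a regularly sampled series with a centered moving-average window.
#' Near the edges the window is truncated to the available samples, so the
#' effective window shrinks toward the boundaries rather than padding.
#'
#' @param x numeric series sampled on a regular grid.
#' @param n window length in samples (coerced to an odd count by using the
#'   half-width `floor(n/2)` on each side).
#' @return numeric vector of the same length as `x`.
#' @export
moving_average <- function(x, n) {
  stopifnot(is.numeric(x), n >= 1)
  h <- floor(n / 2)
  if (h == 0L || length(x) == 0L) return(x)
  cs <- cumsum(c(0, x))
  idx <- seq_along(x)
  lo <- pmax(idx - h, 1L)
  hi <- pmin(idx + h, length(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Membership of time points in a set of half-open intervals
#'
#' @param t numeric times.
#' @param starts,ends interval bounds; membership is `starts <= t < ends`.
#' @return logical vector, TRUE where `t` falls in any interval.
#' @keywords internal
in_any_interval <- function(t, starts, ends) {
  if (length(starts) == 0L) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_along(starts)) {
    out <- out | (t >= starts[i] & t < ends[i])
  }
  out
}

# Distance from each time point to the nearest point of any closed interval.
# Inf when no intervals are given.
dist_to_intervals <- function(t, starts, ends) {
  if (length(starts) == 0L) return(rep(Inf, length(t)))
  d <- rep(Inf, length(t))
  for (i in seq_along(starts)) {
    di <- pmax(pmax(starts[i] - t, t - ends[i]), 0)
    d <- pmin(d, di)
  }
  d
}

# Derive a 32-bit-safe substream seed from a master seed and a stream index.
# Deterministic and independent of how many other streams exist.
substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647)
}
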