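# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
.trapz <- function(x, y) {
  if (length(x) < 2L) return(NA_real_)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

# Trapezoidal integral of a piecewise-linear profile over [0, z0].
# The shallowest sample is extended as a constant to the surface; the
# integration is capped at the deepest sample. Returns the integral and the
# depth actually integrated to.
#' @noRd
.profileIntegral <- function(depth, value, z0) {
  ok <- is.finite(depth) & is.finite(value)
  depth <- depth[ok]
  value <- value[ok]
  if (length(depth) < 2L || z0 <= 0) {
    return(list(integral = NA_real_, zmax = NA_real_, n_above = sum(depth < z0)))
  }
  if (depth[1L] > 0) {
    depth <- c(0, depth)
    value <- c(value[1L], value)
  }
  zmax <- min(z0, depth[length(depth)])
  vz <- stats::approx(depth, value, xout = zmax, ties = "ordered")$y
  keep <- depth < zmax
  xs <- c(depth[keep], zmax)
  ys <- c(value[keep], vz)
  list(integral = .trapz(xs, ys), zmax = zmax, n_above = sum(keep))
}

# Depth-weighted mean of a profile over [0, z0] (surface-extended, capped).
#' @noRd
.profileMean <- function(depth, value, z0) {
  res <- .profileIntegral(depth, value, z0)
  if (!is.finite(res$integral) || res$zmax <= 0) return(NA_real_)
  res$integral / res$zmax
}

# Linear interpolation over interior NA gaps, constant extension at ends.
#' @noRd
.fillGaps <- function(x, y) {
  ok <- is.finite(y)
  if (!any(ok)) return(y)
  if (all(ok)) return(y)
  zoo::na.approx(y, x = x, na.rm = FALSE, rule = 2)
}

#' Day of year on a fixed 365-day cycle
#'
#' Converts calendar dates to day-of-year 1-365. February 29 observations are
#' folded onto day 365 so that every year maps onto the same fixed-length
#' cycle.
#'
#' @param time a `Date`, `POSIXct`, or anything coercible via [as.Date()].
#' @return integer vector of day-of-year values in 1-365.
#' @export
dayOfYear <- function(time) {
  d <- as.Date(time)
  doy <- as.POSIXlt(d)$yday + 1L
  pmin(doy, 365L)
}

# x(t - lag) on a circular series.
#' @noRd
.circularShift <- function(x, lag) {
  n <- length(x)
  x[((seq_len(n) - 1L - lag) %% n) + 1L]
}

# Centered circular moving average over `window` points (forced odd),
# NA-tolerant.
#' @noRd
.circularSmooth <- function(x, window) {
  n <- length(x)
  half <- floor(window / 2)
  if (half == 0L) return(x)
  idx <- outer(seq_len(n) - 1L, -half:half, `+`) %% n + 1L
  m <- matrix(x[idx], nrow = n)
  rowMeans(m, na.rm = TRUE)
}

#' @noRd
.isoTime <- function(time) format(time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
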