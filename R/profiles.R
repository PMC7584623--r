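#' Running-median smoothing of a vertical profile
#'
#' Applies a centered running-median filter of odd width to a depth-resolved
#' series, the standard despiking step for float optical channels. The window
#' is truncated at the profile ends and missing values are excluded from each
#' window's median.
#'
#' @details At the profile ends the window shrinks symmetrically (Tukey's
#'   end rule), which keeps the filter idempotent on monotone profiles.
#'
#' @param values numeric vector, one value per depth sample.
#' @param window odd integer window width (default 7).
#' @return numeric vector of the same length.
#' @export
smoothProfileVertical <- function(values, window = 7L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  n <- length(values)
  if (n == 0L) return(values)
  half <- window %/% 2L
  if (!anyNA(values) && n >= window) {
    return(as.numeric(stats::runmed(values, window, endrule = "median")))
  }
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    k <- min(half, i - 1L, n - i)
    w <- values[(i - k):(i + k)]
    w <- w[is.finite(w)]
    out[i] <- if (length(w)) stats::median(w) else NA_real_
  }
  out
}

#' Seawater density at atmospheric pressure (EOS-80)
#'
#' UNESCO 1983 one-atmosphere equation of state: density (kg m-3) as a
#' polynomial in practical salinity and temperature at 0 dbar. Used as the
#' potential density (sigma-0) for mixed-layer depth detection; at a surface
#' reference the distinction between in-situ and potential temperature is
#' negligible for upper-ocean work.
#'
#' @param psal practical salinity.
#' @param temp temperature, degrees C.
#' @return density in kg m-3.
#' @export
seawaterDensity <- function(psal, temp) {
  t <- temp
  s <- psal
  rho_w <- 999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 +
    1.001685e-4 * t^3 - 1.120083e-6 * t^4 + 6.536332e-9 * t^5
  a <- 8.24493e-1 - 4.0899e-3 * t + 7.6438e-5 * t^2 -
    8.2467e-7 * t^3 + 5.3875e-9 * t^4
  b <- -5.72466e-3 + 1.0227e-4 * t - 1.6546e-6 * t^2
  c0 <- 4.8314e-4
  rho_w + a * s + b * s^1.5 + c0 * s^2
}

#' Mixed layer depth from a density threshold
#'
#' Shallowest depth at which potential density exceeds its value at a
#' reference depth by `threshold` (the widely used Argo convention:
#' 0.03 kg m-3 relative to 10 m). The crossing is located by linear
#' interpolation between samples. If the threshold is never exceeded the
#' deepest sampled depth is returned with `not_reached = TRUE`.
#'
#' @param depth,temp,psal numeric vectors describing one cast.
#' @param threshold density criterion, kg m-3.
#' @param ref_depth reference depth, m.
#' @return list with `mld` (m) and `not_reached` (logical).
#' @export
estimateMLD <- function(depth, temp, psal, threshold = 0.03, ref_depth = 10) {
  ok <- is.finite(depth) & is.finite(temp) & is.finite(psal)
  if (sum(ok) < 2L) {
    stop("unusable cast: need temperature and salinity at >= 2 depths", call. = FALSE)
  }
  z <- depth[ok]
  sigma <- seawaterDensity(psal[ok], temp[ok])
  if (max(z) < ref_depth) {
    stop("unusable cast: profile does not span the reference depth", call. = FALSE)
  }
  sigma_ref <- stats::approx(z, sigma, xout = max(ref_depth, z[1L]),
                             ties = "ordered", rule = 2)$y
  target <- sigma_ref + threshold
  below <- z >= ref_depth
  zb <- z[below]
  sb <- sigma[below]
  exceeded <- which(sb >= target)
  if (length(exceeded) == 0L) {
    return(list(mld = max(z), not_reached = TRUE))
  }
  i <- exceeded[1L]
  if (i == 1L) {
    return(list(mld = zb[1L], not_reached = FALSE))
  }
  frac <- (target - sb[i - 1L]) / (sb[i] - sb[i - 1L])
  list(mld = zb[i - 1L] + frac * (zb[i] - zb[i - 1L]), not_reached = FALSE)
}

#' Euphotic depth (1 % light level) from the chlorophyll-dependent attenuation
#'
#' Depth at which downwelling PAR falls to 1 % of its surface value, using
#' the same chlorophyll-dependent diffuse attenuation model as the growth
#' model ([attenuationFromChl()]), so light-based quantities are mutually
#' consistent. Capped at the deepest sample. A zero surface PAR (polar night,
#' under ice) returns depth 0 with `dark = TRUE`.
#'
#' @param depth,chl numeric vectors for one cast (chl in mg m-3, screened).
#' @param surface_par surface PAR, E m-2 d-1.
#' @param params a [growthParams()] list (for the attenuation coefficients).
#' @return list with `zeu` (m), `dark` (logical), `capped` (logical).
#' @export
euphoticDepth <- function(depth, chl, surface_par, params = growthParams()) {
  if (!is.finite(surface_par) || surface_par < 0) {
    stop("`surface_par` must be a nonnegative number", call. = FALSE)
  }
  if (surface_par == 0) {
    return(list(zeu = 0, dark = TRUE, capped = FALSE))
  }
  chl <- .fillGaps(depth, chl)
  ok <- is.finite(depth) & is.finite(chl)
  z <- depth[ok]
  kd <- attenuationFromChl(chl[ok], params)
  if (length(z) < 2L) {
    return(list(zeu = NA_real_, dark = FALSE, capped = FALSE))
  }
  if (z[1L] > 0) {
    z <- c(0, z)
    kd <- c(kd[1L], kd)
  }
  tau <- c(0, cumsum(diff(z) * (kd[-length(kd)] + kd[-1L]) / 2))
  target <- log(100)
  if (max(tau) < target) {
    return(list(zeu = max(z), dark = FALSE, capped = TRUE))
  }
  zeu <- stats::approx(tau, z, xout = target, ties = "ordered")$y
  list(zeu = zeu, dark = FALSE, capped = FALSE)
}

#' Mixed-layer mean and vertically integrated phytoplankton carbon
#'
#' Depth-weighted (trapezoidal) statistics of a phytoplankton-carbon profile:
#' the mixed-layer mean concentration and the integral from the surface to
#' the mixed layer depth and to the integration horizon (max of mixed layer
#' and euphotic depth). The shallowest sample is extended as a constant to
#' 0 m; integration is capped at the deepest sample.
#'
#' @param depth,cphyto numeric vectors for one cast (mg C m-3).
#' @param mld mixed layer depth, m.
#' @param horizon integration horizon, m (defaults to `mld`).
#' @return list with `pbar` (mg C m-3), `pint_mld`, `pint_horizon`
#'   (mg C m-2).
#' @export
mixedLayerStats <- function(depth, cphyto, mld, horizon = mld) {
  if (!is.finite(mld) || mld <= 0 || !is.finite(horizon) || horizon <= 0) {
    stop("`mld` and `horizon` must be positive", call. = FALSE)
  }
  ok <- is.finite(depth) & is.finite(cphyto)
  if (sum(depth[ok] < mld) < 2L) {
    stop("unusable cast: fewer than 2 phytoplankton-carbon samples above the mixed layer depth",
         call. = FALSE)
  }
  int_mld <- .profileIntegral(depth[ok], cphyto[ok], mld)
  int_hor <- .profileIntegral(depth[ok], cphyto[ok], horizon)
  list(
    pbar = int_mld$integral / int_mld$zmax,
    pint_mld = int_mld$integral,
    pint_horizon = int_hor$integral
  )
}
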