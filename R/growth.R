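#' Parameters of the carbon-based growth model
#'
#' A photoacclimation-based division-rate model: mu(z) = mu_max x NSI(z) x
#' LSI(z), where the nutrient saturation index (NSI) is diagnosed from the
#' local Chl:C ratio relative to its nutrient-replete maximum at the local
#' light level, and the light saturation index is LSI(z) = 1 - exp(-5 PAR(z)).
#'
#' @param mu_max maximum potential division rate, d-1 (default 2).
#' @param chlc_mu0 Chl:C ratio at zero growth, mg Chl (mg C)-1 (default
#'   3e-4).
#' @param lsi_rate light-saturation exponent, (E m-2 d-1)-1 (default 5).
#' @param chlc_max_coeffs floor, ceiling and light-decay rate of the
#'   nutrient-replete maximum Chl:C as a function of local PAR:
#'   chlc_max(PAR) = floor + (ceiling - floor) exp(-decay x PAR).
#' @param kd_coeffs pure-water floor (m-1), chlorophyll coefficient and
#'   exponent of the scalar diffuse attenuation Kd = kd0 + kd1 x Chl^kd_exp
#'   (Morel-type coefficients).
#' @return a named list of class `GrowthParams`.
#' @export
growthParams <- function(mu_max = 2,
                         chlc_mu0 = 3e-4,
                         lsi_rate = 5,
                         chlc_max_coeffs = c(floor = 0.022, ceiling = 0.045, decay = 3),
                         kd_coeffs = c(kd0 = 0.0166, kd1 = 0.0773, kd_exp = 0.672)) {
  stopifnot(
    mu_max > 0, lsi_rate > 0,
    chlc_mu0 > 0, chlc_mu0 < chlc_max_coeffs[["floor"]],
    chlc_max_coeffs[["ceiling"]] > chlc_max_coeffs[["floor"]],
    kd_coeffs[["kd0"]] > 0, kd_coeffs[["kd1"]] >= 0
  )
  structure(
    list(
      mu_max = mu_max,
      chlc_mu0 = chlc_mu0,
      lsi_rate = lsi_rate,
      chlc_max_coeffs = chlc_max_coeffs,
      kd_coeffs = kd_coeffs
    ),
    class = "GrowthParams"
  )
}

#' Diffuse attenuation coefficient from chlorophyll
#'
#' Scalar-PAR diffuse attenuation Kd (m-1) as a function of chlorophyll,
#' with a pure-water floor at Chl = 0.
#'
#' @param chl chlorophyll, mg m-3 (screened, >= 0).
#' @param params a [growthParams()] list.
#' @return Kd, m-1, same length as `chl`.
#' @export
attenuationFromChl <- function(chl, params = growthParams()) {
  k <- params$kd_coeffs
  k[["kd0"]] + k[["kd1"]] * pmax(chl, 0)^k[["kd_exp"]]
}

#' Propagate surface PAR through the water column
#'
#' Exponential attenuation with a depth-varying Kd: the optical depth is the
#' trapezoidal integral of Kd from the surface (shallowest Kd extended to
#' 0 m), and PAR(z) = PAR(0) exp(-tau(z)).
#'
#' @param par0 surface PAR, E m-2 d-1.
#' @param kd per-depth attenuation, m-1.
#' @param depth depths, m.
#' @return list of class `LightField` with `par0`, `depth`, `kd`, `par_z`.
#' @export
propagatePar <- function(par0, kd, depth) {
  stopifnot(is.finite(par0), par0 >= 0, length(kd) == length(depth))
  z <- depth
  k <- kd
  if (length(z) && z[1L] > 0) {
    z <- c(0, z)
    k <- c(k[1L], k)
    drop_first <- TRUE
  } else {
    drop_first <- FALSE
  }
  tau <- c(0, cumsum(diff(z) * (k[-length(k)] + k[-1L]) / 2))
  par_z <- par0 * exp(-tau)
  if (drop_first) par_z <- par_z[-1L]
  structure(
    list(par0 = par0, depth = depth, kd = kd, par_z = par_z),
    class = "LightField"
  )
}

# chlc_max as a function of local PAR (nutrient-replete photoacclimation
# envelope): high Chl:C in dim light, decaying to a floor in bright light.
#' @rdname nutrientSaturationIndex
#' @export
chlcMax <- function(par_z, params = growthParams()) {
  cc <- params$chlc_max_coeffs
  cc[["floor"]] + (cc[["ceiling"]] - cc[["floor"]]) * exp(-cc[["decay"]] * pmax(par_z, 0))
}

#' Nutrient and light saturation indices
#'
#' `nutrientSaturationIndex()` is the relative position of the observed
#' Chl:C ratio between its zero-growth value and the nutrient-replete
#' maximum at the local light level, clamped to [0, 1].
#' `lightSaturationIndex()` is 1 - exp(-lsi_rate x PAR), in [0, 1).
#' `chlcMax()` is the light-dependent nutrient-replete Chl:C envelope.
#'
#' @param chlc observed Chl:C, mg Chl (mg C)-1.
#' @param chlc_max_local nutrient-replete maximum Chl:C at the local light
#'   level (from `chlcMax()`).
#' @param par_z PAR at depth, E m-2 d-1.
#' @param params a [growthParams()] list.
#' @return dimensionless index (vector).
#' @export
nutrientSaturationIndex <- function(chlc, chlc_max_local, params = growthParams()) {
  if (any(chlc_max_local <= params$chlc_mu0, na.rm = TRUE)) {
    stop("chlc_max_local must exceed chlc_mu0", call. = FALSE)
  }
  nsi <- (chlc - params$chlc_mu0) / (chlc_max_local - params$chlc_mu0)
  pmin(pmax(nsi, 0), 1)
}

#' @rdname nutrientSaturationIndex
#' @export
lightSaturationIndex <- function(par_z, params = growthParams()) {
  if (any(par_z < 0, na.rm = TRUE)) {
    stop("`par_z` must be >= 0", call. = FALSE)
  }
  1 - exp(-params$lsi_rate * par_z)
}

#' Division-rate profile
#'
#' mu(z) = mu_max x NSI(z) x LSI(z), with the Chl:C ratio computed per depth
#' as chl/cphyto. Depths where cphyto is zero or missing return NA (flagged
#' by the count of such depths).
#'
#' @param chl,cphyto per-depth series (screened; mg m-3 and mg C m-3).
#' @param light a `LightField` from [propagatePar()].
#' @param params a [growthParams()] list.
#' @return list with `mu` (d-1 per depth), `nsi`, `lsi`, `chlc`, and
#'   `n_undefined` (depths where Chl:C could not be formed).
#' @export
divisionRateProfile <- function(chl, cphyto, light, params = growthParams()) {
  stopifnot(length(chl) == length(cphyto), length(chl) == length(light$par_z))
  chlc <- ifelse(is.finite(cphyto) & cphyto > 0 & is.finite(chl), chl / cphyto, NA_real_)
  cmax <- chlcMax(light$par_z, params)
  nsi <- nutrientSaturationIndex(chlc, cmax, params)
  lsi <- lightSaturationIndex(pmax(light$par_z, 0), params)
  mu <- params$mu_max * nsi * lsi
  list(
    mu = mu, nsi = nsi, lsi = lsi, chlc = chlc,
    n_undefined = sum(!is.finite(chlc))
  )
}

#' Vertically integrated primary production of one cast
#'
#' Trapezoidal integral of mu(z) x C_phyto(z) from the surface to the
#' integration horizon (mg C m-2 d-1). The climatological scalar form
#' (mu x integrated biomass) is used by the perturbation experiment.
#'
#' @param depth,mu,cphyto per-depth series.
#' @param horizon integration horizon, m.
#' @return NPP, mg C m-2 d-1.
#' @export
nppProfile <- function(depth, mu, cphyto, horizon) {
  prod <- mu * cphyto
  .profileIntegral(depth, prod, horizon)$integral
}
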