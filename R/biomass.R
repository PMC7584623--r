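#' Parameters of the optics-to-carbon conversion
#'
#' The empirical relations converting particulate backscattering at 700 nm
#' to particulate organic carbon (POC = 3.12e4 x bbp(700) + 3.0, mg m-3) and
#' POC to phytoplankton carbon (C_phyto = 0.19 x POC). The published
#' uncertainty terms of these fits (+-2.47e3 on the slope, +-6.8 on the
#' intercept, +-8.7 on C_phyto) are carried as metadata only; the pipeline
#' uses point estimates.
#'
#' @param poc_slope mg m-3 per m-1.
#' @param poc_intercept mg m-3.
#' @param cphyto_fraction dimensionless fraction of POC that is
#'   phytoplankton carbon.
#' @param deep_ref_range two depths (m) bounding the deep reference layer
#'   used to zero the C_phyto profile at depth.
#' @return a named list of class `BiomassParams`.
#' @export
biomassParams <- function(poc_slope = 3.12e4, poc_intercept = 3.0,
                          cphyto_fraction = 0.19,
                          deep_ref_range = c(900, 2000)) {
  stopifnot(
    poc_slope > 0,
    cphyto_fraction > 0, cphyto_fraction < 1,
    length(deep_ref_range) == 2L,
    all(deep_ref_range > 0), deep_ref_range[1L] < deep_ref_range[2L]
  )
  structure(
    list(
      poc_slope = poc_slope,
      poc_intercept = poc_intercept,
      cphyto_fraction = cphyto_fraction,
      deep_ref_range = deep_ref_range,
      uncertainty = list(poc_slope = 2.47e3, poc_intercept = 6.8, cphyto = 8.7)
    ),
    class = "BiomassParams"
  )
}

#' Particulate organic carbon from particulate backscattering
#'
#' Linear conversion of bbp(700) (m-1) to POC (mg m-3). Negative input
#' values are propagated (and produce a warning); screening bad optics is an
#' upstream quality-control responsibility.
#'
#' @param bbp700 numeric vector, m-1.
#' @param params a [biomassParams()] list.
#' @return POC, mg m-3.
#' @export
pocFromBbp <- function(bbp700, params = biomassParams()) {
  if (any(bbp700 < 0, na.rm = TRUE)) {
    warning("negative bbp700 values propagated into POC (upstream QC?)", call. = FALSE)
  }
  params$poc_slope * bbp700 + params$poc_intercept
}

#' Phytoplankton carbon from particulate organic carbon
#'
#' @param poc numeric vector, mg m-3.
#' @param params a [biomassParams()] list.
#' @return C_phyto, mg C m-3.
#' @export
cphytoFromPoc <- function(poc, params = biomassParams()) {
  params$cphyto_fraction * poc
}

#' Deep-reference offset correction of a phytoplankton-carbon profile
#'
#' Subtracts the mean C_phyto between the deep reference depths (default
#' 900-2000 m) from the entire profile, forcing phytoplankton carbon to
#' asymptote to zero at depth (any deep signal is non-algal background). A
#' profile with no samples in the reference layer is passed through
#' unchanged with `no_deep_reference = TRUE`.
#'
#' @param cphyto,depth numeric vectors for one cast.
#' @param params a [biomassParams()] list.
#' @return list with `cphyto` (corrected), `offset` (mg C m-3) and
#'   `no_deep_reference` (logical).
#' @export
correctDeepOffset <- function(cphyto, depth, params = biomassParams()) {
  rng <- params$deep_ref_range
  sel <- depth >= rng[1L] & depth <= rng[2L] & is.finite(cphyto)
  if (!any(sel)) {
    return(list(cphyto = cphyto, offset = 0, no_deep_reference = TRUE))
  }
  offset <- mean(cphyto[sel])
  list(cphyto = cphyto - offset, offset = offset, no_deep_reference = FALSE)
}

#' Screen negative concentrations
#'
#' Masks (sets to NA) negative values of a concentration series — the deep
#' offset correction and sensor noise can push C_phyto or Chl below zero,
#' and negative concentrations would corrupt the growth model's Chl:C ratio.
#'
#' @param values numeric vector.
#' @return list with `values` (negatives masked), `n_removed`, and
#'   `all_negative` (logical; such a cast is unusable).
#' @export
screenNegatives <- function(values) {
  neg <- is.finite(values) & values < 0
  out <- values
  out[neg] <- NA_real_
  list(
    values = out,
    n_removed = sum(neg),
    all_negative = sum(neg) > 0 && !any(is.finite(out))
  )
}
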