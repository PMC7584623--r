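#' Per-cast derivation pipeline
#'
#' Processes every cast of a [FloatProfileSet-class] through the standard
#' order of operations: vertical running-median smoothing of the optical
#' channels, conversion of bbp(700) to POC and phytoplankton carbon,
#' deep-reference offset correction, negative-value screening, mixed layer
#' depth from the density threshold, euphotic depth from the
#' chlorophyll-dependent attenuation, mixed-layer biomass statistics, and —
#' where a surface-PAR matchup exists — the underwater light field and the
#' division-rate profile with its mixed-layer mean and vertically
#' integrated production. Casts with fewer than `min_samples` valid
#' samples in the upper 200 m, with unusable T/S, or with all-negative
#' carbon are dropped and logged.
#'
#' @param object a [FloatProfileSet-class].
#' @param par_matchups data.frame with `cast_id`, `par0` (E m-2 d-1; NA for
#'   casts without a matchup), e.g. from [matchPar()]. `NULL` means no
#'   light-dependent quantities are computed.
#' @param biomass a [biomassParams()] list.
#' @param growth a [growthParams()] list.
#' @param mld_threshold,mld_ref_depth density criterion passed to
#'   [estimateMLD()].
#' @param min_samples minimum valid samples in the upper 200 m for a cast
#'   to be usable (default 5).
#' @param integrate_to `"horizon"` (default) integrates biomass to
#'   max(MLD, euphotic depth); both `pint_mld` and `pint_horizon` are
#'   always reported.
#' @return a [DerivedProfileSet-class].
#' @export
processProfiles <- function(object, par_matchups = NULL,
                            biomass = biomassParams(),
                            growth = growthParams(),
                            mld_threshold = 0.03, mld_ref_depth = 10,
                            min_samples = 5L,
                            integrate_to = c("horizon", "mld")) {
  integrate_to <- match.arg(integrate_to)
  stopifnot(is(object, "FloatProfileSet"))
  cast_tab <- casts(object)
  smp <- samples(object)
  by_cast <- split(smp, smp$cast_id)
  par0_map <- if (!is.null(par_matchups)) {
    stats::setNames(par_matchups$par0, par_matchups$cast_id)
  }
  rows <- vector("list", nrow(cast_tab))
  dropped <- list()
  for (ci in seq_len(nrow(cast_tab))) {
    meta <- cast_tab[ci, ]
    s <- by_cast[[as.character(meta$cast_id)]]
    drop <- function(reason) {
      dropped[[length(dropped) + 1L]] <<- data.frame(
        cast_id = meta$cast_id, float_id = meta$float_id, reason = reason
      )
    }
    if (is.null(s) ||
        sum(s$depth <= 200 & is.finite(s$bbp700)) < min_samples) {
      drop("too_few_samples")
      next
    }
    bbp_s <- smoothProfileVertical(s$bbp700)
    chl_s <- smoothProfileVertical(s$chl)
    cph <- cphytoFromPoc(pocFromBbp(bbp_s, biomass), biomass)
    off <- correctDeepOffset(cph, s$depth, biomass)
    scr <- screenNegatives(off$cphyto)
    if (scr$all_negative) {
      drop("all_negative_cphyto")
      next
    }
    cph <- scr$values
    chl_scr <- screenNegatives(chl_s)
    chl_use <- chl_scr$values
    if (!any(is.finite(chl_use))) {
      drop("no_chl")
      next
    }
    mld_fit <- tryCatch(
      estimateMLD(s$depth, s$temp, s$psal, mld_threshold, mld_ref_depth),
      error = function(e) NULL
    )
    if (is.null(mld_fit)) {
      drop("unusable_ts")
      next
    }
    par0 <- if (!is.null(par0_map)) {
      unname(par0_map[as.character(meta$cast_id)])
    } else {
      NA_real_
    }
    chl_fill <- .fillGaps(s$depth, chl_use)
    zeu <- NA_real_
    dark <- NA
    if (is.finite(par0)) {
      ze <- euphoticDepth(s$depth, chl_fill, par0, growth)
      zeu <- ze$zeu
      dark <- ze$dark
    }
    horizon <- max(mld_fit$mld, zeu, na.rm = TRUE)
    st <- tryCatch(
      mixedLayerStats(s$depth, cph, mld_fit$mld, horizon),
      error = function(e) NULL
    )
    if (is.null(st)) {
      drop("too_few_ml_samples")
      next
    }
    par_ml <- mu_ml <- nsi_ml <- lsi_ml <- npp <- NA_real_
    if (is.finite(par0)) {
      kd <- attenuationFromChl(chl_fill, growth)
      light <- propagatePar(par0, kd, s$depth)
      dr <- divisionRateProfile(chl_use, cph, light, growth)
      par_ml <- .profileMean(s$depth, light$par_z, mld_fit$mld)
      mu_ml <- .profileMean(s$depth, dr$mu, mld_fit$mld)
      nsi_ml <- .profileMean(s$depth, dr$nsi, mld_fit$mld)
      lsi_ml <- .profileMean(s$depth, dr$lsi, mld_fit$mld)
      npp <- nppProfile(s$depth, dr$mu, cph, horizon)
    }
    rows[[ci]] <- data.frame(
      cast_id = meta$cast_id, float_id = meta$float_id, time = meta$time,
      lat = meta$lat, lon = meta$lon, under_ice = meta$under_ice,
      zone = assignZone(meta$lat)[1L],
      mld = mld_fit$mld, mld_not_reached = mld_fit$not_reached,
      zeu = zeu, dark = dark, horizon = horizon,
      pbar = st$pbar, pint_mld = st$pint_mld, pint_horizon = st$pint_horizon,
      par0 = par0, par_ml = par_ml, mu_ml = mu_ml, nsi_ml = nsi_ml,
      lsi_ml = lsi_ml, npp = npp,
      deep_offset = off$offset, no_deep_reference = off$no_deep_reference,
      n_neg_removed = scr$n_removed + chl_scr$n_removed
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  empty_drop <- data.frame(cast_id = integer(), float_id = character(),
                           reason = character())
  new("DerivedProfileSet",
    table = if (length(rows)) do.call(rbind, rows) else
      stop("no usable casts in the profile set", call. = FALSE),
    dropped = if (length(dropped)) do.call(rbind, dropped) else empty_drop
  )
}

#' Build a day-of-year climatology from derived casts and rate series
#'
#' Pools per-cast quantities (mixed-layer mean and integrated biomass,
#' mixed-layer division rate, mixed layer depth, integration horizon) and
#' midpoint net-rate observations by day of year, forms weekly bin means,
#' circularly smooths them over ~`smooth_window_days`, and interpolates to
#' daily cycles (see [weeklyClimatology()]).
#'
#' @param derived a [DerivedProfileSet-class].
#' @param rates a [RateSeries-class] (from [netRateOfChange()]).
#' @param zone optional zone name to filter casts by (see [assignZone()]);
#'   `NULL` pools everything.
#' @param smooth_window_days circular smoothing window (default 60).
#' @return a [Climatology-class].
#' @export
buildClimatology <- function(derived, rates, zone = NULL,
                             smooth_window_days = 60) {
  tab <- derivedTable(derived)
  rt <- rateTable(rates)
  if (!is.null(zone)) {
    keep <- !is.na(tab$zone) & tab$zone == zone
    tab <- tab[keep, , drop = FALSE]
    rt <- rt[rt$float_id %in% unique(tab$float_id), , drop = FALSE]
  }
  if (!nrow(tab)) stop("no casts in the requested zone", call. = FALSE)
  doy <- dayOfYear(tab$time)
  doy_r <- dayOfYear(rt$midpoint_time)
  cl <- function(doy_i, x) weeklyClimatology(doy_i, x, smooth_window_days)
  pbar <- cl(doy, tab$pbar)
  pint <- cl(doy, tab$pint_horizon)
  mu <- cl(doy, tab$mu_ml)
  mld <- cl(doy, tab$mld)
  horizon <- cl(doy, tab$horizon)
  r <- cl(doy_r, rt$r)
  weekly <- data.frame(
    week = 1:52, day_center = weeklyBinCenters(),
    pbar = pbar$weekly$mean, pint = pint$weekly$mean, mu = mu$weekly$mean,
    r = r$weekly$mean, mld = mld$weekly$mean, horizon = horizon$weekly$mean,
    n_obs = pbar$weekly$n_obs
  )
  daily <- data.frame(
    day = 1:365, pbar = pbar$daily, pint = pint$daily, mu = mu$daily,
    r = r$daily, mld = mld$daily, horizon = horizon$daily
  )
  new("Climatology", zone = zone %||% "ALL", weekly = weekly, daily = daily,
      smooth_window_days = smooth_window_days)
}
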