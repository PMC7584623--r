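#' Bloom phenology from a daily cycle of the net biomass rate of change
#'
#' The blooming phase is the period where r > 0. Among all circular runs of
#' positive r, the longest is labeled the primary bloom: bloom initiation
#' (BI) is the negative-to-positive crossing starting it and bloom
#' termination (BT) the positive-to-negative crossing ending it (secondary
#' runs, e.g. autumn blooms, are reported in `runs`). The r minimum (rM) is
#' the day of minimum r within the negative phase immediately preceding BI —
#' the moment of peak net biomass loss in autumn/winter. Zero-crossing days
#' are located by linear interpolation and reported as integer days.
#'
#' @param r_clim numeric vector of length 365 (daily cycle of r, d-1).
#' @return list with `bi_day`, `bt_day`, `rm_day` (integer day-of-year or NA),
#'   `blooming_mask` (365 logicals), `runs` (data.frame of all positive runs:
#'   start, end, length, primary), `no_bloom`, `diagnostic`.
#' @export
detectBloomEvents <- function(r_clim) {
  stopifnot(length(r_clim) == 365L)
  mask <- r_clim > 0
  no_bloom <- function(msg) {
    list(
      bi_day = NA_integer_, bt_day = NA_integer_, rm_day = NA_integer_,
      blooming_mask = mask,
      runs = data.frame(start = integer(), end = integer(),
                        length = integer(), primary = logical()),
      no_bloom = TRUE, diagnostic = msg
    )
  }
  if (all(mask)) return(no_bloom("r is positive all year: no initiation/termination"))
  if (!any(mask)) return(no_bloom("r is never positive: no blooming phase"))

  n <- 365L
  # rotate so the cycle starts in a non-blooming day, making runs contiguous
  origin <- which(!mask)[1L]
  rot <- ((origin - 1L + seq_len(n) - 1L) %% n) + 1L
  rl <- rle(mask[rot])
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  pos <- which(rl$values)
  runs <- data.frame(
    start = ((origin - 1L + starts[pos] - 1L) %% n) + 1L,
    end = ((origin - 1L + ends[pos] - 1L) %% n) + 1L,
    length = rl$lengths[pos]
  )
  runs$primary <- seq_len(nrow(runs)) == which.max(runs$length)
  prim <- runs[runs$primary, ]

  interp_day <- function(d_before, d_after) {
    # linear zero crossing between adjacent days (circular)
    r1 <- r_clim[d_before]
    r2 <- r_clim[d_after]
    if (!is.finite(r1) || !is.finite(r2) || r2 == r1) return(d_after)
    frac <- (0 - r1) / (r2 - r1)
    day <- d_before + frac
    ((round(day) - 1L) %% n) + 1L
  }
  prev_day <- ((prim$start - 2L) %% n) + 1L
  next_day <- (prim$end %% n) + 1L
  bi <- interp_day(prev_day, prim$start)
  # the BT crossing lies between end (r > 0) and the following day (r <= 0)
  bt_from <- prim$end
  frac_bt <- r_clim[bt_from] / (r_clim[bt_from] - r_clim[next_day])
  if (!is.finite(frac_bt)) frac_bt <- 1
  bt <- ((round(bt_from + frac_bt) - 1L) %% n) + 1L

  # negative phase immediately preceding BI (circular walk backwards)
  d <- ((prim$start - 2L) %% n) + 1L
  neg_days <- integer()
  while (r_clim[d] <= 0 && length(neg_days) < n) {
    neg_days <- c(neg_days, d)
    d <- ((d - 2L) %% n) + 1L
  }
  rm_day <- NA_integer_
  if (length(neg_days)) {
    cand <- neg_days[which.min(r_clim[neg_days])]
    if (r_clim[cand] < 0) rm_day <- cand
  }
  list(
    bi_day = as.integer(bi), bt_day = as.integer(bt), rm_day = rm_day,
    blooming_mask = mask, runs = runs, no_bloom = FALSE, diagnostic = NA_character_
  )
}

#' Bloom magnitude: summer minus winter mean mixed-layer biomass
#'
#' Difference between the mean mixed-layer phytoplankton carbon over the
#' austral summer window (November 1 - January 31) and the austral winter
#' window (May 1 - July 31). Computable for a single float's series or for a
#' climatological cycle; may be negative.
#'
#' @param doy integer day-of-year per observation.
#' @param values mixed-layer mean phytoplankton carbon, mg C m-3.
#' @return list with `magnitude` (mg C m-3 or NA), `summer_mean`,
#'   `winter_mean`, `undefined` (TRUE when a seasonal window has no data).
#' @export
bloomMagnitude <- function(doy, values) {
  ok <- is.finite(values) & is.finite(doy)
  doy <- doy[ok]
  values <- values[ok]
  summer <- doy >= 305L | doy <= 31L   # Nov 1 (day 305) - Jan 31 (day 31)
  winter <- doy >= 121L & doy <= 212L  # May 1 (day 121) - Jul 31 (day 212)
  if (!any(summer) || !any(winter)) {
    return(list(magnitude = NA_real_, summer_mean = NA_real_,
                winter_mean = NA_real_, undefined = TRUE))
  }
  sm <- mean(values[summer])
  wm <- mean(values[winter])
  list(magnitude = sm - wm, summer_mean = sm, winter_mean = wm, undefined = FALSE)
}

#' Default latitude-band definitions of the Southern Ocean zones
#'
#' Subtropical Zone (STZ) 30-40 S, Subantarctic Zone (SAZ) 40-50 S, Polar
#' Antarctic Zone (PAZ) 50-60 S, Seasonal Ice Zone (SIZ) south of 60 S.
#' Zone boundaries in the field are frontal positions from hydrographic
#' climatologies; latitude bands are a reproducible approximation, and a
#' user-supplied definition (same columns) overrides.
#'
#' @return data.frame with columns `name`, `lat_south`, `lat_north`.
#' @export
zoneDefinitions <- function() {
  data.frame(
    name = c("SIZ", "PAZ", "SAZ", "STZ"),
    lat_south = c(-90, -60, -50, -40),
    lat_north = c(-60, -50, -40, -30)
  )
}

#' Assign casts to Southern Ocean zones
#'
#' Positions north of 30 S are outside the domain and return NA with a
#' `rejected` attribute count; missing positions return NA (kept only for
#' under-ice statistics). Each in-domain position maps to exactly one zone
#' (bands are half-open, the poleward boundary inclusive).
#'
#' @param lat,lon numeric degrees (lon unused by the latitude-band default
#'   but part of the interface for polygon-based definitions).
#' @param zones a zone table as from [zoneDefinitions()].
#' @return character vector of zone names (NA where unzoned/rejected).
#' @export
assignZone <- function(lat, lon = NULL, zones = zoneDefinitions()) {
  out <- rep(NA_character_, length(lat))
  for (i in seq_len(nrow(zones))) {
    sel <- is.finite(lat) & lat > zones$lat_south[i] & lat <= zones$lat_north[i]
    out[sel] <- zones$name[i]
  }
  out[is.finite(lat) & lat > -30] <- NA_character_
  attr(out, "rejected") <- sum(is.finite(lat) & lat > -30)
  out
}

#' Under-ice fraction of a group of casts
#'
#' Fraction of casts flagged as sampled under sea ice; a weekly bin is
#' marked "under ice" when at least 50 % of its casts are (inclusive
#' threshold).
#'
#' @param under_ice logical vector (one element per cast in the bin).
#' @return list with `fraction` and `marked` (logical; NA for empty bins).
#' @export
underIceFraction <- function(under_ice) {
  if (length(under_ice) == 0L) {
    return(list(fraction = NA_real_, marked = NA))
  }
  f <- mean(under_ice, na.rm = TRUE)
  list(fraction = f, marked = f >= 0.5)
}
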