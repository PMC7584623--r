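#' Read and write float profiles as flat CSV
#'
#' The interchange dialect is one row per depth sample with columns
#' `float_id`, `time` (ISO-8601, UTC), `lat`, `lon`, `depth_m`, `temp_C`,
#' `psal`, `bbp700_m-1`, `chl_mg_m-3`, `under_ice` (0/1). The round trip
#' write-then-read is lossless for all declared fields.
#'
#' @param object a [FloatProfileSet-class].
#' @param path file path.
#' @return `writeProfilesCsv()` returns `path` invisibly;
#'   `readProfilesCsv()` returns a [FloatProfileSet-class].
#' @export
writeProfilesCsv <- function(object, path) {
  stopifnot(is(object, "FloatProfileSet"))
  tab <- merge(casts(object), samples(object), by = "cast_id", sort = FALSE)
  tab <- tab[order(tab$cast_id, tab$depth), ]
  out <- data.frame(
    float_id = tab$float_id,
    time = .isoTime(tab$time),
    lat = tab$lat, lon = tab$lon,
    depth_m = tab$depth, temp_C = tab$temp, psal = tab$psal,
    `bbp700_m-1` = tab$bbp700, `chl_mg_m-3` = tab$chl,
    under_ice = as.integer(tab$under_ice),
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeProfilesCsv
#' @export
readProfilesCsv <- function(path) {
  if (!file.exists(path)) stop("cannot read profile file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE)
  need <- c("float_id", "time", "lat", "lon", "depth_m", "temp_C", "psal",
            "bbp700_m-1", "chl_mg_m-3", "under_ice")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("profile CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  time <- as.POSIXct(raw$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  key <- paste(raw$float_id, raw$time)
  cast_id <- match(key, unique(key))
  first <- !duplicated(cast_id)
  new("FloatProfileSet",
    casts = data.frame(
      cast_id = cast_id[first], float_id = raw$float_id[first],
      time = time[first], lat = raw$lat[first], lon = raw$lon[first],
      under_ice = raw$under_ice[first] == 1L
    ),
    samples = data.frame(
      cast_id = cast_id, depth = raw$depth_m, temp = raw$temp_C,
      psal = raw$psal, bbp700 = raw$`bbp700_m-1`, chl = raw$`chl_mg_m-3`
    )
  )
}

#' Write a climatology to CSV
#'
#' Daily cycles as one row per day of year, one column per variable; the
#' weekly table (with per-bin observation counts) goes to a companion file
#' when `weekly_path` is given.
#'
#' @param clim a [Climatology-class].
#' @param path destination for the daily cycles.
#' @param weekly_path optional destination for the weekly bins.
#' @return `path`, invisibly.
#' @export
writeClimatologyCsv <- function(clim, path, weekly_path = NULL) {
  stopifnot(is(clim, "Climatology"))
  d <- dailyCycle(clim)
  names(d)[names(d) == "day"] <- "day_of_year"
  utils::write.csv(d, path, row.names = FALSE)
  if (!is.null(weekly_path)) {
    utils::write.csv(weeklyBins(clim), weekly_path, row.names = FALSE)
  }
  invisible(path)
}

#' Match casts to a gridded daily surface-PAR field
#'
#' Same-day nearest-pixel matchup: each positioned cast receives the value
#' of the nearest grid cell on its calendar day; casts with a missing
#' position (under ice) or with no field value receive NA — matchups are
#' never imputed. The fraction of casts with a valid matchup is attached as
#' the `"coverage"` attribute.
#'
#' @param cast_table data.frame with `cast_id`, `time`, `lat`, `lon` (e.g.
#'   `casts(x)`).
#' @param par_field a `ParField` (see [simulateParField()] for the layout).
#' @return data.frame with `cast_id` and `par0` (E m-2 d-1 or NA), with
#'   attribute `coverage`.
#' @export
matchPar <- function(cast_table, par_field) {
  stopifnot(inherits(par_field, "ParField"))
  n <- nrow(cast_table)
  par0 <- rep(NA_real_, n)
  day <- as.Date(cast_table$time)
  ti <- match(day, par_field$time)
  for (i in seq_len(n)) {
    if (!is.finite(cast_table$lat[i]) || !is.finite(cast_table$lon[i]) ||
        is.na(ti[i])) next
    ilat <- which.min(abs(par_field$lat - cast_table$lat[i]))
    ilon <- which.min(abs(par_field$lon - cast_table$lon[i]))
    par0[i] <- par_field$values[ilat, ilon, ti[i]]
  }
  out <- data.frame(cast_id = cast_table$cast_id, par0 = par0)
  attr(out, "coverage") <- mean(is.finite(par0))
  out
}

#' Match casts to a sparse dissolved-iron database
#'
#' Climatological proximity matchup: the mean of all iron observations
#' within a great-circle radius of the cast (haversine distance, spherical
#' Earth of radius 6371 km), in the upper `max_depth` m, and taken during
#' the same calendar month (any year). Casts with no position or no
#' qualifying points receive NA.
#'
#' @param cast_table data.frame with `cast_id`, `time`, `lat`, `lon`.
#' @param iron_db data.frame with `lat`, `lon`, `depth_m`, `month`,
#'   `fe_nmol_kg` (see [simulateIronDb()]).
#' @param radius_km matchup radius (default 500).
#' @param max_depth deepest iron observation considered, m (default 200).
#' @return data.frame with `cast_id` and `fe` (nmol kg-1 or NA).
#' @export
matchIron <- function(cast_table, iron_db, radius_km = 500, max_depth = 200) {
  n <- nrow(cast_table)
  fe <- rep(NA_real_, n)
  month <- as.POSIXlt(cast_table$time)$mon + 1L
  shallow <- iron_db$depth_m <= max_depth
  for (i in seq_len(n)) {
    if (!is.finite(cast_table$lat[i]) || !is.finite(cast_table$lon[i])) next
    sel <- shallow & iron_db$month == month[i]
    if (!any(sel)) next
    d_km <- geosphere::distHaversine(
      c(cast_table$lon[i], cast_table$lat[i]),
      cbind(iron_db$lon[sel], iron_db$lat[sel]),
      r = 6371000
    ) / 1000
    hit <- d_km <= radius_km
    if (any(hit)) fe[i] <- mean(iron_db$fe_nmol_kg[sel][hit])
  }
  data.frame(cast_id = cast_table$cast_id, fe = fe)
}
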