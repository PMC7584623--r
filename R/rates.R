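#' Net biomass rate of change via the mixed-layer switching algorithm
#'
#' Computes r (d-1) between consecutive casts of each float by centered
#' differences, switching the tracked quantity with the mixed layer
#' tendency: when the mixed layer shoals, r is computed from the mixed-layer
#' mean concentration (detrainment leaves concentration unchanged); when it
#' deepens or is stationary, r is computed from the vertically integrated
#' inventory (entrainment of biomass-poor deep water dilutes concentration
#' but conserves the inventory). The switching removes variability in r not
#' caused by the ecological balance between division and loss:
#' r = (2/dt) (x2 - x1) / (x2 + x1), evaluated at the interval midpoint.
#'
#' @param derived a [DerivedProfileSet-class].
#' @param max_gap maximum gap (days) between consecutive casts; longer pairs
#'   are skipped and logged (floats cycle every 5-10 days, so the default 20
#'   tolerates one missed cycle).
#' @return a [RateSeries-class].
#' @export
netRateOfChange <- function(derived, max_gap = 20) {
  tab <- derivedTable(derived)
  out <- list()
  skip <- list()
  for (fid in unique(tab$float_id)) {
    sub <- tab[tab$float_id == fid, , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    if (nrow(sub) < 2L) next
    t_days <- as.numeric(sub$time) / 86400
    for (i in seq_len(nrow(sub) - 1L)) {
      dt <- t_days[i + 1L] - t_days[i]
      if (!is.finite(dt) || dt <= 0 || dt > max_gap) {
        skip[[length(skip) + 1L]] <- data.frame(
          float_id = fid, time = sub$time[i], reason = "gap"
        )
        next
      }
      shoaling <- (sub$mld[i + 1L] - sub$mld[i]) < 0
      if (shoaling) {
        x1 <- sub$pbar[i]
        x2 <- sub$pbar[i + 1L]
        branch <- "concentration"
      } else {
        x1 <- sub$pint_mld[i]
        x2 <- sub$pint_mld[i + 1L]
        branch <- "inventory"
      }
      if (!is.finite(x1) || !is.finite(x2) || (x1 + x2) <= 0) {
        skip[[length(skip) + 1L]] <- data.frame(
          float_id = fid, time = sub$time[i], reason = "undefined"
        )
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        float_id = fid,
        midpoint_time = sub$time[i] + (sub$time[i + 1L] - sub$time[i]) / 2,
        dt = dt,
        r = (2 / dt) * (x2 - x1) / (x2 + x1),
        branch = branch
      )
    }
  }
  empty <- data.frame(
    float_id = character(), midpoint_time = as.POSIXct(character()),
    dt = numeric(), r = numeric(), branch = character()
  )
  new("RateSeries",
    table = if (length(out)) do.call(rbind, out) else empty,
    skipped = if (length(skip)) {
      do.call(rbind, skip)
    } else {
      data.frame(float_id = character(), time = as.POSIXct(character()),
                 reason = character())
    }
  )
}

#' Two-stage smoothing of an irregular time series
#'
#' Centered moving average over a fixed time window, followed by a centered
#' moving average over a fixed number of consecutive points (the second pass
#' damps short-term variability that would otherwise propagate into temporal
#' derivatives). Windows are truncated at the series ends; output is sampled
#' at the input times.
#'
#' @param time numeric times (days) or POSIXct, need not be regular.
#' @param values numeric values.
#' @param window_days width of the time window (default 10).
#' @param window_points width of the point-count window (default 500).
#' @return numeric vector of smoothed values at the input times.
#' @export
smoothSeries <- function(time, values, window_days = 10, window_points = 500) {
  if (length(time) == 0L) return(numeric())
  t_days <- if (inherits(time, "POSIXct")) as.numeric(time) / 86400 else as.numeric(time)
  if (is.unsorted(t_days)) stop("`time` must be sorted", call. = FALSE)
  n <- length(values)
  half_t <- window_days / 2

  pass1 <- vapply(seq_len(n), function(i) {
    sel <- values[t_days >= t_days[i] - half_t & t_days <= t_days[i] + half_t]
    mean(sel, na.rm = TRUE)
  }, numeric(1L))

  half_p <- floor(window_points / 2)
  if (half_p == 0L) return(pass1)
  vapply(seq_len(n), function(i) {
    mean(pass1[max(1L, i - half_p):min(n, i + half_p)], na.rm = TRUE)
  }, numeric(1L))
}

#' Weekly climatology of one variable, smoothed and interpolated to daily
#'
#' Pools observations tagged by day-of-year into 52 weekly bins (days 1-7,
#' 8-14, ...; the 365th day is folded into week 52), averages within bins,
#' circularly smooths the bin means with a centered ~60-day moving window
#' (realized as the nearest odd number of weekly bins), and linearly
#' interpolates through the bin centers to a 365-day cycle (circular
#' wrap-around, so day 365 is adjacent to day 1).
#'
#' @param doy integer day-of-year (1-365) per observation (see
#'   [dayOfYear()]).
#' @param values numeric observations.
#' @param smooth_window_days width of the circular smoothing window
#'   (default 60).
#' @return list with `weekly` (data.frame: week, day_center, mean, n_obs)
#'   and `daily` (numeric length 365). Fewer than 26 populated bins trigger
#'   a low-coverage warning; all-empty bins are an error.
#' @export
weeklyClimatology <- function(doy, values, smooth_window_days = 60) {
  ok <- is.finite(values) & is.finite(doy)
  doy <- doy[ok]
  values <- values[ok]
  if (length(values) == 0L) stop("empty climatology: no observations", call. = FALSE)
  week <- pmin(52L, (as.integer(doy) - 1L) %/% 7L + 1L)
  m <- tapply(values, factor(week, levels = 1:52), mean)
  n <- tapply(values, factor(week, levels = 1:52), length)
  n[is.na(n)] <- 0L
  if (sum(n > 0) < 26L) {
    warning("low coverage: fewer than 26 of 52 weekly bins populated", call. = FALSE)
  }
  centers <- weeklyBinCenters()
  nbins <- max(1L, 2L * floor(smooth_window_days / 7 / 2) + 1L)
  smoothed <- .circularSmooth(as.numeric(m), nbins)
  smoothed[is.nan(smoothed)] <- NA_real_
  # with gaps wider than the smoothing window the cycle stays undefined
  # there; daily interpolation needs a complete smoothed cycle
  daily <- if (anyNA(smoothed)) rep(NA_real_, 365) else
    interpolateWeeklyToDaily(smoothed)
  list(
    weekly = data.frame(
      week = 1:52, day_center = centers,
      mean = as.numeric(m), smoothed = smoothed, n_obs = as.integer(n)
    ),
    daily = daily
  )
}

#' @rdname weeklyClimatology
#' @export
weeklyBinCenters <- function() {
  c((1:51) * 7 - 3, 361.5)  # week 52 spans days 358-365
}

#' Interpolate 52 weekly bin values to a 365-day circular cycle
#'
#' Linear interpolation through the weekly bin centers with circular
#' wrap-around; bin means are reproduced exactly at their center days.
#'
#' @param weekly numeric vector of 52 weekly values (NAs allowed only if
#'   bracketed by data after circular extension).
#' @return numeric vector of length 365.
#' @export
interpolateWeeklyToDaily <- function(weekly) {
  if (length(weekly) != 52L) stop("need 52 weekly values", call. = FALSE)
  if (anyNA(weekly)) {
    empty <- which(is.na(weekly))
    stop("incomplete weekly cycle; empty bins: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  centers <- weeklyBinCenters()
  x <- c(centers[52L] - 365, centers, centers[1L] + 365)
  y <- c(weekly[52L], weekly, weekly[1L])
  stats::approx(x, y, xout = 1:365, ties = "ordered")$y
}

#' Temporal derivative of a circular daily cycle
#'
#' Centered difference with circular wrap: dx/dt at day i is
#' (x(i+1) - x(i-1)) / 2, in units per day. The derivative sums to zero
#' around the cycle (telescoping).
#'
#' @param cycle numeric vector of length 365.
#' @return numeric vector of length 365.
#' @export
temporalDerivative <- function(cycle) {
  n <- length(cycle)
  if (n < 3L) stop("cycle too short", call. = FALSE)
  (cycle[c(2:n, 1L)] - cycle[c(n, 1:(n - 1L))]) / 2
}
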