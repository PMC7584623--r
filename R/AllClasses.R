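#' @import methods
NULL

#' FloatProfileSet: a set of vertical float casts
#'
#' Container for profiling-float observations. Cast-level metadata (position,
#' time, ice flag) live in `casts`; depth-resolved measurements live in
#' `samples`, keyed by `cast_id`. Depths are meters, positive downward, and
#' must be strictly increasing within each cast.
#'
#' @slot casts data.frame with columns `cast_id`, `float_id`, `time`
#'   (POSIXct, UTC), `lat`, `lon` (may be NA under ice), `under_ice`
#'   (logical).
#' @slot samples data.frame with columns `cast_id`, `depth`, `temp`, `psal`,
#'   `bbp700`, `chl`.
#' @export
setClass("FloatProfileSet", representation(
  casts = "data.frame",
  samples = "data.frame"
))

setValidity("FloatProfileSet", function(object) {
  msgs <- character()
  need_c <- c("cast_id", "float_id", "time", "lat", "lon", "under_ice")
  need_s <- c("cast_id", "depth", "temp", "psal", "bbp700", "chl")
  if (!all(need_c %in% names(object@casts))) {
    msgs <- c(msgs, paste("casts must have columns:", paste(need_c, collapse = ", ")))
  }
  if (!all(need_s %in% names(object@samples))) {
    msgs <- c(msgs, paste("samples must have columns:", paste(need_s, collapse = ", ")))
  }
  if (length(msgs) == 0L && nrow(object@samples) > 0L) {
    if (anyDuplicated(object@casts$cast_id)) {
      msgs <- c(msgs, "cast_id must be unique in casts")
    }
    bad_depth <- vapply(
      split(object@samples$depth, object@samples$cast_id),
      function(z) any(diff(z) <= 0) || z[1L] < 0,
      logical(1L)
    )
    if (any(bad_depth)) {
      msgs <- c(msgs, paste(
        "depth must be >= 0 and strictly increasing within casts:",
        paste(utils::head(names(bad_depth)[bad_depth], 3L), collapse = ", ")
      ))
    }
    if (any(object@samples$bbp700 < 0, na.rm = TRUE)) {
      msgs <- c(msgs, "bbp700 must be >= 0 after quality screening")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' DerivedProfileSet: per-cast derived scalars
#'
#' One row per usable cast: mixed layer depth, euphotic depth, integration
#' horizon, mixed-layer mean and integrated phytoplankton carbon, mixed-layer
#' PAR and division rate, with processing flags.
#'
#' @slot table data.frame, one row per cast.
#' @slot dropped data.frame describing casts dropped during processing and
#'   the reason.
#' @export
setClass("DerivedProfileSet", representation(
  table = "data.frame",
  dropped = "data.frame"
))

setValidity("DerivedProfileSet", function(object) {
  need <- c(
    "cast_id", "float_id", "time", "lat", "lon", "under_ice",
    "mld", "mld_not_reached", "zeu", "dark", "horizon",
    "pbar", "pint_mld", "pint_horizon", "par0", "par_ml", "mu_ml"
  )
  if (!all(need %in% names(object@table))) {
    return(paste("table must have columns:", paste(setdiff(need, names(object@table)), collapse = ", ")))
  }
  tab <- object@table
  if (nrow(tab)) {
    if (any(tab$mld <= 0, na.rm = TRUE)) return("mld must be > 0")
    h <- pmax(tab$mld, tab$zeu, na.rm = TRUE)
    if (any(abs(tab$horizon - h) > 1e-9, na.rm = TRUE)) {
      return("horizon must equal max(mld, zeu)")
    }
  }
  TRUE
})

#' RateSeries: net biomass rate of change between consecutive casts
#'
#' Midpoint-time series of r from the mixed-layer switching algorithm, with
#' the branch used (concentration during mixed-layer shoaling, inventory
#' during deepening or stationary mixed layers) recorded per interval.
#'
#' @slot table data.frame with columns `float_id`, `midpoint_time`, `dt`
#'   (days), `r` (per day), `branch` ("concentration" or "inventory").
#' @slot skipped data.frame of skipped cast pairs with reasons.
#' @export
setClass("RateSeries", representation(
  table = "data.frame",
  skipped = "data.frame"
))

setValidity("RateSeries", function(object) {
  need <- c("float_id", "midpoint_time", "dt", "r", "branch")
  if (!all(need %in% names(object@table))) {
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  }
  tab <- object@table
  if (nrow(tab)) {
    if (any(tab$dt <= 0)) return("dt must be > 0")
    if (!all(tab$branch %in% c("concentration", "inventory"))) {
      return("branch must be 'concentration' or 'inventory'")
    }
    if (any(abs(tab$r) > 2 / tab$dt + 1e-12)) {
      return("|r| must be <= 2/dt (bounded by construction)")
    }
  }
  TRUE
})

#' Climatology: day-of-year mean annual cycles for a region
#'
#' Weekly-binned means of mixed-layer biomass, integrated biomass, division
#' rate, net biomass rate of change and mixed layer depth, circularly
#' smoothed and linearly interpolated to a fixed 365-day cycle.
#'
#' @slot zone character scalar naming the region.
#' @slot weekly data.frame with 52 rows: `week`, `day_center`, the variable
#'   bin means, and `n_obs` per bin.
#' @slot daily data.frame with 365 rows: `day` plus daily cycles `pbar`,
#'   `pint`, `mu`, `r`, `mld`, `horizon`.
#' @slot smooth_window_days numeric, width of the circular smoothing window.
#' @export
setClass("Climatology", representation(
  zone = "character",
  weekly = "data.frame",
  daily = "data.frame",
  smooth_window_days = "numeric"
))

setValidity("Climatology", function(object) {
  if (nrow(object@daily) && nrow(object@daily) != 365L) {
    return("daily cycles must have 365 rows")
  }
  if (nrow(object@daily) && !all(object@daily$day == 1:365)) {
    return("daily$day must be 1:365")
  }
  TRUE
})

#' ScenarioResult: one division-rate perturbation run
#'
#' @slot s numeric, perturbation fraction in [0, 1].
#' @slot loss_lag integer days by which the loss rate lags the division rate.
#' @slot daily data.frame with 365 rows: `day`, `mu_pert`, `loss`, `r_model`,
#'   `p_model` (mg C m-3), `npp` (mg C m-2 d-1).
#' @slot bloom_magnitude numeric, summer (Nov-Jan) minus winter (May-Jul)
#'   mean modeled mixed-layer biomass (mg C m-3).
#' @slot bloom_range numeric, max minus min of the modeled biomass cycle.
#' @slot npp_annual_mean numeric (mg C m-2 d-1).
#' @export
setClass("ScenarioResult", representation(
  s = "numeric",
  loss_lag = "numeric",
  daily = "data.frame",
  bloom_magnitude = "numeric",
  bloom_range = "numeric",
  npp_annual_mean = "numeric"
))

setValidity("ScenarioResult", function(object) {
  d <- object@daily
  if (nrow(d)) {
    if (nrow(d) != 365L) return("daily must have 365 rows")
    if (any(d$p_model <= 0)) return("p_model must be > 0 (exponential stepping)")
    if (max(abs(d$r_model - (d$mu_pert - d$loss))) > 1e-10) {
      return("r_model must equal mu_pert - loss pointwise")
    }
  }
  TRUE
})
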