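#' Accessors for floatbloom containers
#'
#' `casts()` and `samples()` return the cast-level and depth-resolved tables
#' of a [FloatProfileSet-class]; `derivedTable()` the per-cast scalars of a
#' [DerivedProfileSet-class]; `rateTable()` the midpoint r series of a
#' [RateSeries-class]; `weeklyBins()` and `dailyCycle()` the two resolutions
#' of a [Climatology-class]; `scenarioDaily()` the daily cycles of a
#' [ScenarioResult-class].
#'
#' @param object a floatbloom S4 object.
#' @return a data.frame (see the class documentation for columns).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("casts", function(object) standardGeneric("casts"))

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("derivedTable", function(object) standardGeneric("derivedTable"))

#' @rdname accessors
#' @export
setGeneric("rateTable", function(object) standardGeneric("rateTable"))

#' @rdname accessors
#' @export
setGeneric("weeklyBins", function(object) standardGeneric("weeklyBins"))

#' @rdname accessors
#' @export
setGeneric("dailyCycle", function(object) standardGeneric("dailyCycle"))

#' @rdname accessors
#' @export
setGeneric("scenarioDaily", function(object) standardGeneric("scenarioDaily"))

#' @rdname accessors
#' @export
setMethod("casts", "FloatProfileSet", function(object) object@casts)

#' @rdname accessors
#' @export
setMethod("samples", "FloatProfileSet", function(object) object@samples)

#' @rdname accessors
#' @export
setMethod("derivedTable", "DerivedProfileSet", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("rateTable", "RateSeries", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("weeklyBins", "Climatology", function(object) object@weekly)

#' @rdname accessors
#' @export
setMethod("dailyCycle", "Climatology", function(object) object@daily)

#' @rdname accessors
#' @export
setMethod("scenarioDaily", "ScenarioResult", function(object) object@daily)

setMethod("show", "FloatProfileSet", function(object) {
  cat(
    "FloatProfileSet:", nrow(object@casts), "casts from",
    length(unique(object@casts$float_id)), "float(s),",
    nrow(object@samples), "depth samples\n"
  )
  if (nrow(object@casts)) {
    cat(
      "  time:", format(min(object@casts$time)), "to",
      format(max(object@casts$time)), "\n"
    )
    cat("  under-ice casts:", sum(object@casts$under_ice), "\n")
  }
  invisible(object)
})

setMethod("show", "DerivedProfileSet", function(object) {
  cat(
    "DerivedProfileSet:", nrow(object@table), "usable casts (",
    nrow(object@dropped), "dropped )\n"
  )
  if (nrow(object@table)) {
    cat(
      sprintf(
        "  MLD %.0f-%.0f m, pbar %.1f-%.1f mg C m-3\n",
        min(object@table$mld, na.rm = TRUE), max(object@table$mld, na.rm = TRUE),
        min(object@table$pbar, na.rm = TRUE), max(object@table$pbar, na.rm = TRUE)
      )
    )
  }
  invisible(object)
})

setMethod("show", "RateSeries", function(object) {
  cat(
    "RateSeries:", nrow(object@table), "intervals (",
    sum(object@table$branch == "concentration"), "concentration /",
    sum(object@table$branch == "inventory"), "inventory ),",
    nrow(object@skipped), "skipped\n"
  )
  invisible(object)
})

setMethod("show", "Climatology", function(object) {
  filled <- if (nrow(object@weekly)) sum(object@weekly$n_obs > 0) else 0L
  cat(
    "Climatology for zone", object@zone, ":", filled,
    "of 52 weekly bins populated;",
    if (nrow(object@daily)) "daily cycles present" else "daily cycles empty", "\n"
  )
  invisible(object)
})

setMethod("show", "ScenarioResult", function(object) {
  cat(sprintf(
    "ScenarioResult: s = %.2f, loss lag %d d, bloom magnitude %.2f mg C m-3, annual NPP %.1f mg C m-2 d-1\n",
    object@s, as.integer(object@loss_lag), object@bloom_magnitude,
    object@npp_annual_mean
  ))
  invisible(object)
})
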