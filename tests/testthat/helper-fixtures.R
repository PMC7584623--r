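# Shared fixtures built in code.

# A two-layer density cast: uniform surface layer, step at `jump_depth`.
twoLayerCast <- function(depths, jump_depth, dsigma = 0.1,
                         t_surf = 10, s_surf = 34) {
  # realize the density step through a temperature drop solved numerically
  dT <- stats::uniroot(
    function(dt) seawaterDensity(s_surf, t_surf - dt) -
      seawaterDensity(s_surf, t_surf) - dsigma,
    c(0, 15)
  )$root
  list(
    depth = depths,
    temp = ifelse(depths < jump_depth, t_surf, t_surf - dT),
    psal = rep(s_surf, length(depths))
  )
}

# A minimal one-cast FloatProfileSet.
makeProfileSet <- function(depth, temp, psal, bbp700, chl,
                           lat = -50, lon = 0, under_ice = FALSE,
                           time = as.POSIXct("2016-01-10", tz = "UTC")) {
  new("FloatProfileSet",
    casts = data.frame(
      cast_id = 1L, float_id = "F1", time = time,
      lat = lat, lon = lon, under_ice = under_ice
    ),
    samples = data.frame(
      cast_id = 1L, depth = depth, temp = temp, psal = psal,
      bbp700 = bbp700, chl = chl
    )
  )
}

# A DerivedProfileSet with a prescribed (time, mld, pbar, pint) sequence for
# exercising the switching algorithm directly.
makeDerivedSeries <- function(times_days, mld, pbar, pint,
                              float_id = "F1") {
  n <- length(times_days)
  tab <- data.frame(
    cast_id = seq_len(n), float_id = float_id,
    time = as.POSIXct("2016-01-01", tz = "UTC") + times_days * 86400,
    lat = -50, lon = 0, under_ice = FALSE, zone = "SAZ",
    mld = mld, mld_not_reached = FALSE,
    zeu = mld, dark = FALSE, horizon = mld,
    pbar = pbar, pint_mld = pint, pint_horizon = pint,
    par0 = 30, par_ml = 10, mu_ml = 0.5, nsi_ml = 0.5, lsi_ml = 0.9,
    npp = 100, deep_offset = 0, no_deep_reference = FALSE, n_neg_removed = 0L
  )
  new("DerivedProfileSet", table = tab,
      dropped = data.frame(cast_id = integer(), float_id = character(),
                           reason = character()))
}

# Small noise-free synthetic emission, cached per session (used by several
# test files).
noiseFreeEmission <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- truthConfig(n_floats = 2, years = 1, noise_bbp = 0, noise_chl = 0)
      cache <<- emitFloatProfiles(simulateTruth(cfg))
    }
    cache
  }
})
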