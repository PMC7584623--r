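test_that("invalid generator configurations name the offending fields", {
  expect_error(truthConfig(cadence_days = 7), "cadence_days")
  expect_error(truthConfig(mld_winter_max = 30, mld_summer_min = 50),
               "mld_winter_max")
  expect_error(truthConfig(p_init = -1), "p_init")
})

test_that("zero loss lag balances the budget under a constant mixed layer", {
  cfg <- truthConfig(n_floats = 1, years = 1, loss_lag_days = 0,
                     mld_winter_max = 80, mld_summer_min = 80,
                     noise_bbp = 0, noise_chl = 0)
  tr <- simulateTruth(cfg)
  expect_equal(tr$daily$r, rep(0, 365))
  expect_lt(diff(range(tr$daily$pbar)) / tr$daily$pbar[1], 1e-12)
})

test_that("deepening with mu = l dilutes concentration but conserves inventory", {
  cfg <- truthConfig(n_floats = 1, years = 1, loss_lag_days = 0,
                     noise_bbp = 0, noise_chl = 0)
  tr <- simulateTruth(cfg)
  d <- tr$daily
  deepening <- which(diff(d$mld) > 0)
  expect_true(all(abs(d$pint[deepening + 1] - d$pint[deepening]) < 1e-9))
  expect_true(all(d$pbar[deepening + 1] < d$pbar[deepening]))
  # and the downstream switching algorithm reads r = 0 off such casts
  em <- emitFloatProfiles(tr)
  dv <- processProfiles(em$profiles, em$par_matchups)
  rt <- rateTable(netRateOfChange(dv))
  # small residual from grid discretization of the measured pbar/pint
  expect_lt(max(abs(rt$r)), 1e-3)
})

test_that("the default bloom initiates while mu is accelerating", {
  tr <- simulateTruth(truthConfig())
  agg <- function(v) as.numeric(tapply(v, tr$daily$doy, mean))
  r <- agg(tr$daily$r)
  mu <- agg(tr$daily$mu)
  ev <- detectBloomEvents(r)
  dmu <- temporalDerivative(mu)
  expect_gt(dmu[ev$bi_day], 0)
  expect_true(ev$bi_day < which.max(mu))
})

test_that("noise-free emission honors the construction contracts", {
  em <- noiseFreeEmission()
  dv <- processProfiles(em$profiles, em$par_matchups)
  tt <- merge(derivedTable(dv), em$truth_casts, by = "cast_id")
  # MLD recovered within one grid spacing
  expect_lt(max(abs(tt$mld - tt$mld_truth)), 10)
  # mixed-layer biomass and division rate recovered
  expect_lt(max(abs(tt$pbar / tt$pbar_truth - 1)), 0.01)
  expect_lt(max(abs(tt$mu_ml / tt$mu_ml_truth - 1), na.rm = TRUE), 0.01)
})

test_that("emission is deterministic under a fixed seed", {
  cfg <- truthConfig(n_floats = 1, years = 1, seed = 77)
  a <- emitFloatProfiles(simulateTruth(cfg))
  b <- emitFloatProfiles(simulateTruth(cfg))
  expect_identical(samples(a$profiles), samples(b$profiles))
  expect_identical(casts(a$profiles), casts(b$profiles))
  cfg2 <- truthConfig(n_floats = 1, years = 1, seed = 78)
  c_ <- emitFloatProfiles(simulateTruth(cfg2))
  expect_false(identical(samples(a$profiles)$bbp700, samples(c_$profiles)$bbp700))
})

test_that("under-ice casts lack positions inside the ice window", {
  cfg <- truthConfig(n_floats = 1, years = 1, latitudes = -65,
                     noise_bbp = 0, noise_chl = 0)
  em <- emitFloatProfiles(simulateTruth(cfg))
  ct <- casts(em$profiles)
  doy <- dayOfYear(ct$time)
  in_window <- doy >= 172 & doy <= 265
  expect_true(all(ct$under_ice[in_window]))
  expect_true(all(is.na(ct$lat[ct$under_ice])))
  expect_true(all(is.finite(ct$lat[!ct$under_ice])))
  # missing position implies missing PAR matchup
  expect_true(all(is.na(em$par_matchups$par0[ct$under_ice])))
})

test_that("the iron database has zone-dependent means and respects filters", {
  db <- simulateIronDb(n_points = 2000, seed = 3)
  z <- assignZone(db$lat)
  for (zn in c("STZ", "SAZ", "PAZ", "SIZ")) {
    sel <- z == zn
    m <- mean(db$fe_nmol_kg[sel])
    target <- c(STZ = 0.40, SAZ = 0.18, PAZ = 0.12, SIZ = 0.25)[[zn]] * exp(0.3^2 / 2)
    se <- sd(db$fe_nmol_kg[sel]) / sqrt(sum(sel))
    expect_lt(abs(m - target), 2.5 * se + 0.02)
  }
  expect_gt(mean(db$fe_nmol_kg[z == "STZ"]), 0.2)
  expect_equal(nrow(simulateIronDb(n_points = 0)), 0L)
})

test_that("synthetic climatologies are internally consistent", {
  for (seed in 1:3) {
    clim <- syntheticClimatology(seed = seed, loss_lag = 2)
    d <- dailyCycle(clim)
    expect_equal(d$r, d$mu - floatbloom:::.circularShift(d$mu, 2))
    expect_equal(fitLossLag(d$mu, d$r)$lag, 2L)
    expect_true(all(d$pbar > 0))
  }
})
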