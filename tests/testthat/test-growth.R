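test_that("chlorophyll-dependent attenuation has a pure-water floor", {
  expect_equal(attenuationFromChl(0), 0.0166)
  expect_equal(attenuationFromChl(0.5), 0.0166 + 0.0773 * 0.5^0.672,
               tolerance = 1e-12)
  expect_equal(round(attenuationFromChl(0.5), 4), 0.0651)
  chl <- seq(0.1, 2, length.out = 20)
  expect_true(all(diff(attenuationFromChl(chl)) > 0))
})

test_that("PAR propagation matches the constant-Kd closed form", {
  z <- seq(0, 150, by = 0.5)
  kd <- rep(0.046, length(z))
  lf <- propagatePar(20, kd, z)
  expect_equal(lf$par_z[1], 20)
  # 1% depth for Kd = 0.046 is ln(100)/0.046 = 100.1 m
  i <- which.min(abs(z - log(100) / 0.046))
  expect_equal(lf$par_z[i] / 20, 0.01, tolerance = 0.01)
  expect_true(all(diff(lf$par_z) <= 0))
  # darkness
  expect_true(all(propagatePar(0, kd, z)$par_z == 0))
  # mixed-layer mean against the analytic (1 - exp(-K MLD)) / (K MLD) form
  mld <- 80
  num <- floatbloom:::.profileMean(z, lf$par_z, mld)
  expect_equal(num, 20 * (1 - exp(-0.046 * mld)) / (0.046 * mld),
               tolerance = 5e-3)
})

test_that("saturation indices follow their defining formulas", {
  expect_equal(nutrientSaturationIndex(3e-4, 0.03), 0)
  expect_equal(nutrientSaturationIndex(0.03, 0.03), 1)
  expect_equal(nutrientSaturationIndex(0.01, 0.03),
               (0.01 - 3e-4) / (0.03 - 3e-4), tolerance = 1e-12)
  expect_equal(round(nutrientSaturationIndex(0.01, 0.03), 4), 0.3266)
  expect_error(nutrientSaturationIndex(0.01, 2e-4), "chlc_max")
  expect_equal(lightSaturationIndex(0), 0)
  expect_equal(lightSaturationIndex(1), 1 - exp(-5), tolerance = 1e-12)
  # compensation light level ~0.04 E m-2 d-1
  expect_equal(lightSaturationIndex(0.04), 1 - exp(-0.2), tolerance = 1e-12)
})

test_that("division rate is the product mu_max x NSI x LSI with bounds", {
  z <- seq(5, 100, 5)
  light <- propagatePar(50, rep(1e-6, length(z)), z)  # effectively unattenuated
  # saturated: NSI = 1 (chlc at the local max), LSI ~ 1
  params <- growthParams()
  cmax <- chlcMax(light$par_z, params)
  dr <- divisionRateProfile(cmax * 10, rep(10, length(z)), light, params)
  expect_equal(dr$mu, rep(2, length(z)), tolerance = 1e-6)
  # the worked product: NSI 0.3266 x LSI(1) = 0.9933 at mu_max 2
  light1 <- propagatePar(1, rep(1e-9, 1), 0)
  dr1 <- divisionRateProfile(chl = 0.01 * 10, cphyto = 10, light = light1,
                             params = growthParams(chlc_max_coeffs =
                               c(floor = 0.03, ceiling = 0.0300001, decay = 0)))
  expect_equal(dr1$mu, 2 * 0.32660 * 0.99326, tolerance = 1e-3)
  # darkness
  dark <- propagatePar(0, rep(0.05, length(z)), z)
  drd <- divisionRateProfile(rep(0.5, length(z)), rep(10, length(z)), dark)
  expect_equal(drd$mu, rep(0, length(z)))
  # undefined where cphyto = 0
  dr0 <- divisionRateProfile(c(0.5, 0.5), c(10, 0), propagatePar(10, c(0.05, 0.05), c(5, 10)))
  expect_equal(dr0$n_undefined, 1L)
  expect_true(is.na(dr0$mu[2]))
})

test_that("saturation indices and mu stay in their ranges on random inputs", {
  set.seed(11)
  for (i in 1:25) {
    z <- seq(5, 200, 5)
    chl <- runif(length(z), 0, 3)
    cph <- runif(length(z), 1, 80)
    light <- propagatePar(runif(1, 0, 60), attenuationFromChl(chl), z)
    dr <- divisionRateProfile(chl, cph, light)
    expect_true(all(dr$nsi >= 0 & dr$nsi <= 1, na.rm = TRUE))
    # LSI < 1 analytically; saturates to 1 within floating-point precision
    expect_true(all(dr$lsi >= 0 & dr$lsi <= 1, na.rm = TRUE))
    expect_true(all(dr$mu >= 0 & dr$mu <= 2, na.rm = TRUE))
  }
})

test_that("mu increases with light and with Chl:C below the local maximum", {
  params <- growthParams()
  par_grid <- seq(0.01, 1.5, length.out = 50)
  lsi <- lightSaturationIndex(par_grid, params)
  expect_true(all(diff(lsi) > 0))
  chlc_grid <- seq(4e-4, 0.02, length.out = 50)
  nsi <- nutrientSaturationIndex(chlc_grid, 0.03, params)
  expect_true(all(diff(nsi) > 0))
})

test_that("integrated production follows the trapezoidal profile form", {
  z <- seq(0, 100, 5)
  expect_equal(nppProfile(z, rep(0.5, length(z)), rep(10, length(z)), 100), 500)
  expect_equal(nppProfile(z, rep(0, length(z)), rep(10, length(z)), 100), 0)
  expect_equal(nppProfile(z, 1 - z / 100, rep(10, length(z)), 100), 500)
})

test_that("growth module recovers truth mu from constructed profiles", {
  em <- noiseFreeEmission()
  dv <- processProfiles(em$profiles, em$par_matchups)
  tt <- merge(derivedTable(dv), em$truth_casts, by = "cast_id")
  rel <- abs(tt$mu_ml / tt$mu_ml_truth - 1)
  expect_lt(max(rel, na.rm = TRUE), 0.01)
})
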