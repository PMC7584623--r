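test_that("running median removes interior spikes and preserves structure", {
  expect_equal(smoothProfileVertical(c(1, 1, 9, 1, 1, 1, 1), 7), rep(1, 7))
  expect_equal(smoothProfileVertical(rep(3.2, 10)), rep(3.2, 10))
  # strictly increasing series: the fully windowed center point is unchanged
  expect_equal(smoothProfileVertical(1:7, 7)[4], 4)
  expect_error(smoothProfileVertical(1:5, 4), "odd")
  # missing values are excluded from each window
  x <- c(1, NA, 1, 1, 50, 1, 1)
  expect_equal(smoothProfileVertical(x, 7)[4], 1)
})

test_that("running median is idempotent on monotone series", {
  set.seed(42)
  for (i in 1:20) {
    x <- cumsum(abs(rnorm(30)))
    once <- smoothProfileVertical(x, 7)
    expect_equal(smoothProfileVertical(once, 7), once)
  }
})

test_that("EOS-80 density matches UNESCO check values", {
  expect_equal(seawaterDensity(35, 5), 1027.67547, tolerance = 1e-7)
  expect_equal(seawaterDensity(35, 25), 1023.34306, tolerance = 1e-7)
  expect_equal(seawaterDensity(0, 5), 999.96675, tolerance = 1e-7)
})

test_that("MLD is found at a two-layer density jump", {
  z <- seq(5, 200, by = 5)
  cast <- twoLayerCast(z, jump_depth = 50)
  fit <- estimateMLD(cast$depth, cast$temp, cast$psal)
  expect_false(fit$not_reached)
  expect_lt(abs(fit$mld - 50), 5)  # within one sample spacing
})

test_that("MLD on a uniform profile returns the deepest depth, flagged", {
  z <- c(seq(5, 100, 5), seq(150, 2000, 50))
  fit <- estimateMLD(z, rep(10, length(z)), rep(34, length(z)))
  expect_true(fit$not_reached)
  expect_equal(fit$mld, 2000)
})

test_that("MLD under a linear density gradient solves the threshold analytically", {
  # 0.001 kg m-3 per m below 10 m: crossing at 10 + 0.03/0.001 = 40 m.
  # Build the density ramp through salinity at constant T.
  z <- seq(0, 200, by = 2)
  t0 <- 10
  dsig_ds <- (seawaterDensity(34.5, t0) - seawaterDensity(34, t0)) / 0.5
  psal <- 34 + pmax(0, z - 10) * 0.001 / dsig_ds
  fit <- estimateMLD(z, rep(t0, length(z)), psal)
  expect_equal(fit$mld, 40, tolerance = 0.02)
})

test_that("MLD is invariant to vertical resampling of a two-layer profile", {
  for (dz in c(2, 5, 10)) {
    z <- seq(2, 300, by = dz)
    cast <- twoLayerCast(z, jump_depth = 87)
    fit <- estimateMLD(cast$depth, cast$temp, cast$psal)
    expect_lt(abs(fit$mld - 87), dz + 1e-9)
  }
})

test_that("MLD estimation rejects casts without usable T/S", {
  expect_error(estimateMLD(1:10, rep(NA_real_, 10), rep(34, 10)), "unusable")
})

test_that("euphotic depth is the 1% light level of the attenuation model", {
  z <- seq(1, 300, by = 1)
  chl <- rep(0.4, length(z))
  kd <- attenuationFromChl(0.4)
  res <- euphoticDepth(z, chl, surface_par = 30)
  expect_equal(res$zeu, log(100) / kd, tolerance = 1e-6)
  # doubling Kd halves the euphotic depth: emulate by scaling depth axis
  chl2 <- rep(0.4, length(z))
  params2 <- growthParams(kd_coeffs = c(kd0 = 2 * 0.0166, kd1 = 2 * 0.0773,
                                        kd_exp = 0.672))
  res2 <- euphoticDepth(z, chl2, 30, params2)
  expect_equal(res2$zeu, res$zeu / 2, tolerance = 1e-6)
  dark <- euphoticDepth(z, chl, 0)
  expect_true(dark$dark)
  expect_equal(dark$zeu, 0)
})

test_that("mixed-layer statistics integrate trapezoidally with surface extension", {
  z <- seq(5, 100, by = 5)
  uni <- mixedLayerStats(z, rep(10, length(z)), mld = 50)
  expect_equal(uni$pbar, 10)
  expect_equal(uni$pint_mld, 500)
  lin <- mixedLayerStats(seq(0, 100, 5), 10 - seq(0, 100, 5) / 10, mld = 100)
  expect_equal(lin$pbar, 5)
  expect_equal(lin$pint_mld, 500)
  expect_error(mixedLayerStats(c(60, 80, 100), c(1, 1, 1), mld = 50),
               "fewer than 2")
})

test_that("pint(mld) equals pbar x mld for uniform profiles on any grid", {
  set.seed(7)
  for (i in 1:20) {
    z <- sort(c(runif(2, 1, 15), runif(23, 16, 400)))
    mld <- runif(1, 20, 300)
    st <- mixedLayerStats(z, rep(8.5, 25), mld)
    expect_equal(st$pint_mld / mld, st$pbar, tolerance = 1e-9)
    expect_lt(abs(st$pbar - 8.5) / 8.5, 0.01)
  }
})

test_that("FloatProfileSet validity enforces profile invariants", {
  z <- seq(5, 100, 5)
  good <- makeProfileSet(z, rep(10, 20), rep(34, 20), rep(0.001, 20),
                         rep(0.3, 20))
  expect_s4_class(good, "FloatProfileSet")
  expect_error(
    makeProfileSet(rev(z), rep(10, 20), rep(34, 20), rep(0.001, 20),
                   rep(0.3, 20)),
    "strictly increasing"
  )
  expect_error(
    makeProfileSet(z, rep(10, 20), rep(34, 20), rep(-0.001, 20),
                   rep(0.3, 20)),
    "bbp700"
  )
})
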