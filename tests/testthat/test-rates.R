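test_that("switching algorithm computes centered-difference r per branch", {
  # shoaling with equal concentrations: r = 0
  dv <- makeDerivedSeries(c(0, 10), mld = c(100, 80),
                          pbar = c(12, 12), pint = c(1200, 960))
  rt <- rateTable(netRateOfChange(dv))
  expect_equal(rt$branch, "concentration")
  expect_equal(rt$r, 0)
  # deepening with inventory 100 -> 110 over 10 days
  dv <- makeDerivedSeries(c(0, 10), mld = c(80, 100),
                          pbar = c(100 / 80, 110 / 100), pint = c(100, 110))
  rt <- rateTable(netRateOfChange(dv))
  expect_equal(rt$branch, "inventory")
  expect_equal(rt$r, (2 / 10) * 10 / 210, tolerance = 1e-12)
  expect_equal(rt$dt, 10)
  # stationary mixed layer uses the inventory branch
  dv <- makeDerivedSeries(c(0, 10), mld = c(100, 100),
                          pbar = c(10, 11), pint = c(1000, 1100))
  expect_equal(rateTable(netRateOfChange(dv))$branch, "inventory")
})

test_that("dilution and detrainment yield exactly r = 0", {
  # deepening that conserves inventory while concentration halves
  dv <- makeDerivedSeries(c(0, 8), mld = c(50, 100),
                          pbar = c(20, 10), pint = c(1000, 1000))
  expect_equal(rateTable(netRateOfChange(dv))$r, 0)
  # shoaling that conserves concentration while inventory halves
  dv <- makeDerivedSeries(c(0, 8), mld = c(100, 50),
                          pbar = c(10, 10), pint = c(1000, 500))
  expect_equal(rateTable(netRateOfChange(dv))$r, 0)
})

test_that("concentration branch equals (2/dt) tanh(k dt / 2) for exponential growth", {
  for (k in c(0.002, 0.01, 0.05)) {
    for (dt in c(5, 10, 20)) {
      p1 <- 10
      p2 <- 10 * exp(k * dt)
      dv <- makeDerivedSeries(c(0, dt), mld = c(100, 90),
                              pbar = c(p1, p2), pint = c(1000, 900 * p2 / 10))
      r <- rateTable(netRateOfChange(dv))$r
      expect_equal(r, (2 / dt) * tanh(k * dt / 2), tolerance = 1e-12)
      if (k * dt <= 0.2) expect_lt(abs(r / k - 1), 0.005)
    }
  }
})

test_that("long gaps are skipped and every retained pair has one branch", {
  dv <- makeDerivedSeries(c(0, 10, 45, 52), mld = c(100, 90, 95, 80),
                          pbar = c(10, 11, 12, 13),
                          pint = c(1000, 990, 1140, 1040))
  rs <- netRateOfChange(dv, max_gap = 20)
  expect_equal(nrow(rateTable(rs)), 2L)   # the 35-day gap pair is dropped
  expect_equal(nrow(rs@skipped), 1L)
  expect_true(all(rateTable(rs)$branch %in% c("concentration", "inventory")))
})

test_that("two-stage smoothing preserves constants and interior linearity", {
  t <- seq(0, 100, by = 2)
  expect_equal(smoothSeries(t, rep(4, length(t)), 10, 5), rep(4, length(t)))
  y <- 2 + 0.5 * t
  sm <- smoothSeries(t, y, 10, 5)
  interior <- 10:40
  expect_equal(sm[interior], y[interior], tolerance = 1e-9)
  # an isolated outlier is attenuated by roughly the window count
  y2 <- rep(1, 201)
  y2[101] <- 101
  sm2 <- smoothSeries(seq_len(201), y2, window_days = 0, window_points = 99)
  expect_lt(sm2[101], 1 + 100 / 45)
  expect_equal(smoothSeries(numeric(), numeric()), numeric())
})

test_that("weekly climatology reproduces constants and attenuates a sinusoid predictably", {
  doy <- rep(1:365, 3)
  expect_equal(unique(weeklyClimatology(doy, rep(7.7, length(doy)))$daily), 7.7)
  # annual sinusoid: binning (7-day) and circular smoothing (9 bins)
  # attenuate the amplitude by Dirichlet-kernel factors, phase unchanged
  x <- sin(2 * pi * (doy - 80) / 365)
  cl <- weeklyClimatology(doy, x)
  d7 <- sin(7 * pi / 365) / (7 * sin(pi / 365))
  d9 <- sin(9 * 7 * pi / 365) / (9 * sin(7 * pi / 365))
  basis <- cbind(sin(2 * pi * ((1:365) - 80) / 365),
                 cos(2 * pi * ((1:365) - 80) / 365))
  fit <- stats::lm.fit(basis, cl$daily)
  amp <- sqrt(sum(fit$coefficients^2))
  expect_equal(amp, d7 * d9, tolerance = 0.01)
  phase_shift <- atan2(fit$coefficients[2], fit$coefficients[1]) * 365 / (2 * pi)
  expect_lt(abs(phase_shift), 1.5)
})

test_that("sparse seasonal coverage warns and empty input errors", {
  expect_warning(weeklyClimatology(rep(1:120, 2), rnorm(240)), "low coverage")
  expect_error(weeklyClimatology(numeric(), numeric()), "empty")
})

test_that("weekly-to-daily interpolation passes through bin centers", {
  w <- rep(5, 52)
  expect_equal(interpolateWeeklyToDaily(w), rep(5, 365))
  set.seed(3)
  w <- rnorm(52)
  daily <- interpolateWeeklyToDaily(w)
  expect_equal(daily[weeklyBinCenters()[1:51]], w[1:51], tolerance = 1e-12)
  # midpoint of two adjacent weekly values 10 and 17 is 13.5
  w2 <- rep(0, 52)
  w2[10] <- 10
  w2[11] <- 17
  daily2 <- interpolateWeeklyToDaily(w2)
  # bin centers are 7 days apart; the value midway between them is the mean
  mid <- mean(daily2[weeklyBinCenters()[10] + 3:4])
  expect_equal(mid, 13.5)
  expect_error(interpolateWeeklyToDaily(c(w[-1], NA)), "empty bins")
})

test_that("circular temporal derivative is exact for constants and sinusoids", {
  expect_equal(temporalDerivative(rep(2, 365)), rep(0, 365))
  d <- 1:365
  x <- sin(2 * pi * d / 365)
  deriv <- temporalDerivative(x)
  expect_equal(deriv, (2 * pi / 365) * cos(2 * pi * d / 365), tolerance = 1e-3)
  expect_lt(abs(sum(deriv)), 1e-12)
})
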