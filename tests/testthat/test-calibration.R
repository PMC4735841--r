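test_that("histogramming conserves counts and reproduces bin edges", {
  s <- histogram_energies(c(100, 100, 200), 50, c(0, 300))
  expect_equal(sum(s$counts), 3)
  expect_equal(s$counts[s$bin_center == 125], 2)
  expect_equal(attr(s, "bin_edges"), seq(0, 300, by = 50))
  # values outside range are dropped and counted
  expect_message(s2 <- histogram_energies(c(10, 500), 50, c(100, 300)),
                 "dropped")
  expect_equal(sum(s2$counts) + attr(s2, "n_dropped"), 2)
  # empty input is a valid empty spectrum
  s3 <- histogram_energies(numeric(), 10, c(0, 100))
  expect_equal(sum(s3$counts), 0)
  # bit-exact edge reproducibility
  s4 <- histogram_energies(runif(10, 0, 300), 50, c(0, 300))
  expect_identical(attr(s4, "bin_edges"), attr(s, "bin_edges"))
})

test_that("photopeak fitting recovers generator parameters", {
  set.seed(61)
  # 6.4% FWHM at 511 keV: sigma = 0.064 * 511 / 2.3548
  sigma <- 0.064 * 511 / (2 * sqrt(2 * log(2)))
  e <- rnorm(1e5, 511, sigma)
  spec <- histogram_energies(e, 2, c(400, 620))
  fit <- fit_photopeak(spec, c(450, 570))
  expect_equal(fit$centroid, 511, tolerance = 0.5 / 511)
  expect_equal(fit$fwhm_percent, 6.4, tolerance = 0.2 / 6.4)
  # symmetric peak: centroid at the symmetry point
  expect_lt(abs(fit$centroid - mean(e)), 0.2)
  # invariance under uniform count scaling
  spec10 <- spec
  spec10$counts <- spec10$counts * 10L
  fit10 <- fit_photopeak(spec10, c(450, 570))
  expect_equal(fit10$centroid, fit$centroid, tolerance = 1e-6)
  expect_equal(fit10$fwhm_percent, fit$fwhm_percent, tolerance = 1e-6)
  # tidy interface
  td <- tidy(fit)
  expect_equal(td$centroid, fit$centroid)
})

test_that("degenerate photopeak windows are rejected", {
  s <- histogram_energies(rep(100, 3), 10, c(0, 1000))
  expect_error(fit_photopeak(s, c(500, 600)), "non-empty bins")
  flat <- histogram_energies(runif(2000, 0, 1000), 10, c(0, 1000))
  # flat spectrum: either a fit error or amplitude consistent with noise
  res <- tryCatch(fit_photopeak(flat, c(400, 600)), error = function(e) e)
  if (!inherits(res, "error")) {
    expect_lt(res$amplitude, 5 * sqrt(mean(flat$counts)))
  } else {
    succeed()
  }
})

test_that("linear calibration matches the hand-solved two-point line", {
  cal <- build_calibration(data.frame(adc = c(100, 250),
                                      kev = c(511, 1275)))
  expect_equal(cal$slope, (1275 - 511) / 150, tolerance = 1e-12)
  expect_equal(cal$intercept, 511 - cal$slope * 100, tolerance = 1e-12)
  expect_equal(cal$slope, 5.09333, tolerance = 1e-5)
  expect_equal(cal$intercept, 1.66667, tolerance = 1e-4)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_error(build_calibration(data.frame(adc = 100, kev = 511)),
               "2 distinct")
  # collinear points give r^2 = 1
  cal3 <- build_calibration(data.frame(adc = c(100, 200, 300),
                                       kev = c(500, 1000, 1500)))
  expect_equal(cal3$r_squared, 1, tolerance = 1e-12)
})

test_that("calibration round-trips energies through the ADC scale", {
  cal <- build_calibration(data.frame(adc = c(90, 130, 230, 260),
                                      kev = c(450, 662, 1173, 1332)))
  kev <- c(100, 511, 1275, 1900)
  expect_equal(apply_calibration(cal, invert_calibration(cal, kev)), kev,
               tolerance = 1e-9)
})

test_that("temperature model: linear gain, symmetric around the reference,
          invertible", {
  m <- temperature_model()
  expect_equal(gain_factor(m, 25.5), 1)
  expect_equal(gain_factor(m, 26.5), 0.95)
  expect_equal(gain_factor(m, 24.5), 1.05)
  expect_error(gain_factor(m, 50), "validity")
  # correction composed with its inverse is the identity
  e <- c(100, 511, 1275)
  g <- gain_factor(m, 30)
  expect_equal((e * g) / g, e, tolerance = 1e-12)
})

test_that("temperature slope recovery from gains", {
  m <- temperature_model()
  temps <- 20:30
  g <- gain_factor(m, temps)
  fit <- fit_temperature_slope(data.frame(temperature_c = temps, gain = g))
  expect_equal(fit$slope_per_degc, -0.05, tolerance = 1e-9)
  # 1% multiplicative noise: slope recovered within 0.005
  set.seed(71)
  gn <- g * (1 + rnorm(11, 0, 0.01))
  fitn <- fit_temperature_slope(data.frame(temperature_c = temps,
                                           gain = gn))
  expect_equal(fitn$slope_per_degc, -0.05, tolerance = 0.005 / 0.05)
  # constant gains: zero slope
  fit0 <- fit_temperature_slope(data.frame(temperature_c = temps,
                                           gain = rep(1, 11)))
  expect_equal(fit0$slope_per_degc, 0, tolerance = 1e-12)
  expect_error(fit_temperature_slope(data.frame(temperature_c = c(20, 20),
                                                gain = c(1, 1))))
})

test_that("channel equalization flattens the response", {
  uni <- matrix(5, 8, 8)
  expect_equal(equalize_channels(uni), matrix(1, 8, 8))
  # one channel at twice the grand mean of the rest
  m <- matrix(1, 8, 8); m[3, 4] <- 2
  f <- equalize_channels(m)
  gm <- mean(m)
  expect_equal(f[3, 4], gm / 2, tolerance = 1e-12)
  corrected <- f * m
  expect_equal(uniformity(corrected), 0, tolerance = 1e-12)
  dead <- m; dead[1, 1] <- 0
  expect_error(equalize_channels(dead), "dead")
})

test_that("spectrum files round-trip", {
  set.seed(3)
  s <- histogram_energies(rnorm(1000, 511, 10), 2, c(400, 600))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(s, path)
  back <- read_spectrum(path)
  expect_equal(back$counts, s$counts)
  expect_equal(back$bin_center, s$bin_center)
})
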