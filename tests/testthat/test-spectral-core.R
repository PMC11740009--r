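# Analytic building blocks: offset grid construction, the Rex and Reff
# lineshapes, the analytic peak width, the Lorentzian peak and the AREX
# metric.  Frozen expected values were computed by direct scalar evaluation
# of the formulas before the implementation existed.

test_that("offset grid unions fine and coarse sub-grids correctly", {
  g <- offset_grid()
  expect_length(g, 89)
  expect_true(all(diff(g) > 0))
  expect_true(all(seq(-10, 10, by = 1.25) %in% as.numeric(g)))

  expect_equal(as.numeric(offset_grid(1, 1, c(-1, 1), c(-1, 1))), c(-1, 0, 1))

  # independent enumeration of both sub-grids and their union
  expected <- sort(unique(c(seq(-2, 2, 0.5), seq(-10, 10, 2))))
  g2 <- offset_grid(0.5, 2, c(-2, 2), c(-10, 10))
  expect_length(g2, 17)
  expect_equal(as.numeric(g2), expected)

  expect_error(offset_grid(0.3, 1.25, c(-5, 5), c(-10, 10)), "divide")
  expect_error(offset_grid(0.125, 1.25, c(-5, 11), c(-10, 10)), "contained")
})

test_that("unit conversions use the proton Larmor frequency", {
  expect_equal(ppm_to_rads(1, 4.7), 2 * pi * 42.5764 * 4.7, tolerance = 1e-12)
  expect_equal(rads_to_ppm(ppm_to_rads(-3.5)), -3.5, tolerance = 1e-12)
  expect_equal(saturation(1)$omega1, 267.5, tolerance = 1e-3)
})

test_that("Rex lineshape matches its closed form and peaks at the pool shift", {
  p <- pool("NOE16", fs = 0.002, ksw = 20, r2s = 30, delta_ppm = -1.6)
  sat <- saturation(1)
  d <- ppm_to_rads(-1.6)

  expect_equal(rex(p, saturation(0, t_sat = 5), d), 0)
  # value at the center, from scalar evaluation: fs ksw w1^2/(w1^2+(R2s+ksw)ksw)
  expect_equal(rex(p, sat, d), 0.0394488, tolerance = 1e-5)
  w1 <- sat$omega1
  expect_equal(rex(p, sat, d), p$fs * p$ksw * w1^2 / (w1^2 + (p$r2s + p$ksw) * p$ksw),
               tolerance = 1e-12)

  # maximum over a dense offset sweep occurs at the pool shift
  for (i in 1:20) {
    set.seed(i)
    pr <- pool("x", runif(1, 1e-4, 0.01), runif(1, 5, 200), runif(1, 5, 200),
               runif(1, -4, 4))
    dw <- seq(-15000, 15000, length.out = 4001)
    vals <- rex(pr, sat, dw)
    expect_lt(abs(dw[which.max(vals)] - ppm_to_rads(pr$delta_ppm)),
              diff(dw[1:2]) + 1e-9)
  }
})

test_that("numeric FWHM of the Rex curve matches the analytic width within 1%", {
  sat_levels <- c(0, 150, 300, 600)
  set.seed(99)
  for (i in 1:100) {
    p <- pool("x", 0.002, runif(1, 5, 200), runif(1, 5, 200), 0)
    sat <- saturation(0)
    sat$omega1 <- sample(sat_levels, 1) + runif(1, 0, 50)
    w_true <- peak_width(p, sat)
    dw <- seq(-4 * w_true, 4 * w_true, length.out = 8001)
    vals <- rex(p, sat, dw)
    half <- max(vals) / 2
    above <- range(which(vals >= half))
    # linear interpolation at both crossings
    xl <- approx(vals[c(above[1] - 1, above[1])], dw[c(above[1] - 1, above[1])],
                 xout = half)$y
    xr <- approx(vals[c(above[2], above[2] + 1)], dw[c(above[2], above[2] + 1)],
                 xout = half)$y
    expect_equal(xr - xl, w_true, tolerance = 0.01)
  }
})

test_that("Reff interpolates between R1obs and R2w with tilt-angle weights", {
  w <- water_params(r1obs = 0.6, r2w = 25)
  sat <- saturation(1)
  expect_equal(reff(w, sat, ppm_to_rads(-1.6)), 1.023976, tolerance = 1e-5)
  expect_equal(reff(w, sat, 1e9), 0.6, tolerance = 1e-3)
  expect_equal(reff(w, sat, 0), 25)
  dw <- seq(-13000, 13000, length.out = 500)
  vals <- reff(w, sat, dw)
  expect_true(all(vals >= 0.6 - 1e-12 & vals <= 25 + 1e-12))
  expect_error(reff(w, saturation(0), 0), "undefined")
})

test_that("analytic width formula behaves in limits and units", {
  p <- pool("NOE16", 0.002, 20, 30, -1.6)
  expect_equal(peak_width(p, saturation(0)), 2 * (30 + 20))
  expect_equal(peak_width(p, saturation(1)), 851.8, tolerance = 1e-3)
  expect_equal(peak_width(p, saturation(1), unit = "ppm"), 0.6775, tolerance = 1e-3)
  expect_gt(peak_width(p, saturation(2)), peak_width(p, saturation(1)))
  p0 <- p; p0$ksw <- 0
  expect_error(peak_width(p0, saturation(1)), "ksw")
})

test_that("Lorentzian peak has the right center, half-maximum and symmetry", {
  expect_equal(lorentz_peak(0.05, 1, -1.6, -1.6), 0.05)
  expect_equal(lorentz_peak(0.05, 1, -1.6, -1.6 + 0.5), 0.025)
  expect_equal(lorentz_peak(0.05, 1, -1.6, -2.6), 0.01)
  x <- seq(0.1, 3, by = 0.3)
  expect_equal(lorentz_peak(0.2, 1.3, 0.5, 0.5 + x),
               lorentz_peak(0.2, 1.3, 0.5, 0.5 - x))
})

test_that("AREX metric is an inverse difference scaled by R1obs and (1+fm)", {
  expect_equal(arex(0.5, 0.5, 1, mt_correction = FALSE), 0)
  expect_equal(arex(0.5, 0.6, 1, mt_correction = FALSE), 1 / 3, tolerance = 1e-12)
  expect_equal(arex(0.5, 0.6, 0.5, mt_correction = FALSE),
               arex(0.5, 0.6, 1, mt_correction = FALSE) / 2)
  expect_equal(arex(0.5, 0.6, 1, fm = 0.1, mt_correction = TRUE), (1 / 3) * 1.1)
  expect_error(arex(0, 0.5, 1), "positive")
})
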