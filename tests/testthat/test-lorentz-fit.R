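# Six-pool Lorentzian decomposition: parameter recovery, Slab/Sref algebra,
# AREX spectra, B0 correction and NOE(-1.6) extraction.

test_that("noiseless six-Lorentzian spectra are recovered within 2% (A) / 5% (W)", {
  g <- fx_grid()
  for (seed in 1:50) {
    pars <- random_six_pool_valid(seed, g)
    z <- lorentz_z(pars, as.numeric(g))
    zs <- zspectrum(as.numeric(g), pmin(z, 1.05), r1obs = 0.6, fm = 0.07)
    fit <- fit_multipool(zs, restarts = 8)
    expect_true(fit$converged)
    ord <- match(pars$name, fit$pools$name)
    expect_lt(max(abs(fit$pools$A[ord] - pars$A) / pars$A), 0.02)
    expect_lt(max(abs(fit$pools$W[ord] - pars$W) / pars$W), 0.05)
  }
})

test_that("s_ref minus s_lab is exactly the excluded pool's Lorentzian", {
  pars <- random_six_pool(7)
  g <- fx_grid()
  zs <- zspectrum(as.numeric(g), pmin(pmax(lorentz_z(pars, as.numeric(g)), 0.01), 1.05),
                  r1obs = 0.6, fm = 0.07)
  fit <- fit_multipool(zs)
  x <- as.numeric(g)
  for (nm in fit$pools$name) {
    p <- fit$pools[fit$pools$name == nm, ]
    expect_equal(s_ref(fit, nm, x) - s_lab(fit, x),
                 lorentz_peak(max(p$A, 0), p$W, p$delta_ppm, x),
                 tolerance = 1e-12)
  }
  expect_error(s_ref(fit, "nope"), "unknown pool")
})

test_that("a flat spectrum drives the narrow solute amplitudes to zero", {
  g <- fx_grid()
  zs <- zspectrum(as.numeric(g), rep(1, length(g)), r1obs = 0.6, fm = 0)
  fit <- fit_multipool(zs)
  # the water amplitude cannot reach zero (its lower bound is 0.4), so a
  # perfectly flat spectrum is outside the model; the solute lines must
  # still (near-)collapse
  solutes <- fit$pools[fit$pools$name != "water", ]
  expect_true(all(solutes$A < 0.02))
  expect_true(all(solutes$A[solutes$name %in% c("NOE16", "NOE35",
                                                "amine_guan", "MT")] < 1e-3))
})

test_that("fitted model misfit stays at the noise level", {
  zs <- add_noise(fx_brain(), snr = 200, seed = 8)
  fit <- fit_multipool(zs)
  expect_lt(fit$residual, 0.0075)
})

test_that("B0 estimation recovers injected shifts and is near-idempotent", {
  zs <- fx_brain()
  zc <- b0_correct(zs)
  expect_lt(abs(attr(zc, "b0_shift_est_ppm")), 0.01)

  m <- fx_model(); m$b0_shift_ppm <- 0.05
  z_shift <- simulate_zspectrum(m, fx_sat(), fx_grid())
  zc1 <- b0_correct(z_shift)
  expect_lt(abs(attr(zc1, "b0_shift_est_ppm") - 0.05), 0.01)
  zc2 <- b0_correct(zc1)
  expect_lt(abs(attr(zc2, "b0_shift_est_ppm")), 0.006)
})

test_that("AREX spectra are peaked at the pool and zero for an absent pool", {
  pars <- random_six_pool(12)
  pars$A[pars$name == "amide"] <- 0
  g <- fx_grid()
  zs <- zspectrum(as.numeric(g), pmin(pmax(lorentz_z(pars, as.numeric(g)), 0.01), 1.05),
                  r1obs = 0.6, fm = 0.07)
  fit <- fit_multipool(zs)
  sp <- arex_spectrum(fit, "amide")
  expect_lt(max(abs(sp$arex)), 0.01)

  noe <- arex_spectrum(fit, "NOE16")
  d <- fit$pools$delta_ppm[fit$pools$name == "NOE16"]
  W <- fit$pools$W[fit$pools$name == "NOE16"]
  at <- function(x) noe$arex[which.min(abs(noe$offset_ppm - x))]
  expect_gt(at(d), at(d - 2 * W))
  expect_gt(at(d), at(d + 2 * W))

  # hand-evaluated center value
  zl <- s_lab(fit, d); zr <- s_ref(fit, "NOE16", d)
  expect_equal(at(d), 0.6 * (1 / zl - 1 / zr) * 1.07, tolerance = 0.02)
})

test_that("MT rate transform is L/(1-L) scaled by R1obs and monotone", {
  fit <- fit_multipool(fx_brain())
  p <- fit$pools[fit$pools$name == "MT", ]
  x0 <- p$delta_ppm
  L <- lorentz_peak(p$A, p$W, p$delta_ppm, x0)
  got <- mt_rex(fit, r1obs = 1, offsets_ppm = x0)
  expect_equal(got$rex_mt, L / (1 - L), tolerance = 1e-12)
  # scalar identity at L = 0.5
  expect_equal(1 * 0.5 / (1 - 0.5), 1)
})

test_that("amine/guan AREX uses the measured spectrum as label", {
  zs <- fx_brain()
  zc <- b0_correct(zs)
  fit <- fit_multipool(zc)
  # when the measured z equals the fitted s_lab, both AREX routes agree
  z_fake <- zspec_fake <- zc
  z_model <- pmin(pmax(s_lab(fit, zc$offset_ppm), 0.01), 1.0499)
  zspec_fake <- zspectrum(zc$offset_ppm, z_model, r1obs = attr(zc, "r1obs"),
                          fm = attr(zc, "fm"))
  # compare away from the water resonance, where the inverse metric lives
  keep <- abs(zspec_fake$offset_ppm) >= 0.5
  zsub <- zspectrum(zspec_fake$offset_ppm[keep], zspec_fake$z[keep],
                    r1obs = attr(zc, "r1obs"), fm = attr(zc, "fm"))
  ag1 <- amine_guan_rex(fit, zsub)
  ag2 <- arex_spectrum(fit, "amine_guan",
                       offsets_ppm = zspec_fake$offset_ppm[keep])
  expect_lt(max(abs(ag1$arex - ag2$arex)), 1e-6)

  # lowering the measured z raises the AREX value everywhere
  z_low <- zspectrum(zsub$offset_ppm, pmax(zsub$z - 0.01, 0.005),
                     r1obs = attr(zc, "r1obs"), fm = attr(zc, "fm"))
  ag3 <- amine_guan_rex(fit, z_low)
  expect_true(all(ag3$arex > ag1$arex))

  # on the brain-like simulation the component is concentrated on the CEST
  # side: larger through the amine/guan band than in the far downfield wing
  zc_sub <- zspectrum(zc$offset_ppm[keep], zc$z[keep],
                      r1obs = attr(zc, "r1obs"), fm = attr(zc, "fm"))
  ag <- amine_guan_rex(fit, zc_sub)
  inband <- ag$offset_ppm >= 1.5 & ag$offset_ppm <= 3.5
  wing <- ag$offset_ppm >= 8
  expect_gt(mean(ag$arex[inband]), mean(ag$arex[wing]))
})

test_that("NOE(-1.6) extraction recovers exact windowed Lorentzians", {
  dense <- seq(-2.5, -0.5, by = 0.01)
  tbl <- tibble::tibble(offset_ppm = dense,
                        arex = lorentz_peak(0.05, 0.8, -1.6, dense))
  est <- extract_noe16(tbl)
  expect_equal(est$A, 0.05, tolerance = 0.01)
  expect_equal(est$W, 0.8, tolerance = 0.01)
  expect_false(est$censored)
  expect_equal(est$peak(-1.6), est$A)

  # off-center peak: amplitude is the windowed max, regenerated peak sits at -1.6
  tbl2 <- tibble::tibble(offset_ppm = dense,
                         arex = lorentz_peak(0.05, 0.8, -1.4, dense))
  est2 <- extract_noe16(tbl2)
  expect_equal(est2$A, 0.05, tolerance = 0.01)
  expect_equal(est2$peak(-1.6), est2$A)

  # two-bump spectrum: windowed max equals brute-force maximum
  bump <- lorentz_peak(0.03, 0.5, -1.8, dense) + lorentz_peak(0.02, 0.3, -1.2, dense)
  est3 <- extract_noe16(tibble::tibble(offset_ppm = dense, arex = bump))
  sel <- dense >= -2 & dense <= -1
  expect_equal(est3$A, max(bump[sel]))

  # flat spectrum: width censored at the window
  est4 <- extract_noe16(tibble::tibble(offset_ppm = dense, arex = rep(1, length(dense))))
  expect_true(est4$censored)
  expect_equal(est4$W, 1)
})

test_that("noisy NOE(-1.6) amplitude recovery degrades gracefully", {
  pars <- random_six_pool(3)
  g <- fx_grid()
  z_clean <- pmin(pmax(lorentz_z(pars, as.numeric(g)), 0.01), 1.05)
  A_true <- pars$A[pars$name == "NOE16"]
  errs <- vapply(1:25, function(s) {
    zs <- add_noise(zspectrum(as.numeric(g), z_clean, r1obs = 0.6, fm = 0.07),
                    snr = 200, seed = 100 + s)
    fit <- fit_multipool(zs)
    abs(fit$pools$A[fit$pools$name == "NOE16"] - A_true) / A_true
  }, numeric(1))
  expect_lt(median(errs), 0.3)
})

test_that("per-voxel fitting of a uniform phantom gives a constant map", {
  ph <- make_phantom(n_side = 2, tumor_fs_factor = 1)
  fits <- fit_map(ph, b0 = FALSE)
  expect_equal(nrow(fits), 4)
  expect_true(all(fits$converged))
  expect_lt(diff(range(fits$A)), 1e-6)
})
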