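# Component extraction, inverse-summation reconstruction with B0 injection,
# and the partially synthetic training-data sampler.

test_that("components of a water+MT-only spectrum carry no NOE(-3.5) signal", {
  m <- tissue_model(
    water = list(r1w = 1 / 1.7, r2w = 20),
    pools = pool("MT", fs = 0.07, ksw = 25, r2s = 1e5, delta_ppm = -2.5))
  zs <- simulate_zspectrum(m, fx_sat(), fx_grid())
  comp <- extract_components(b0_correct(zs))
  away <- abs(comp$offset_ppm + 3.5) > 2  # outside the broad water/MT overlap
  expect_lt(max(comp$rex_noe35[comp$offset_ppm < -2.5 & comp$offset_ppm > -4.5]),
            0.02)
  expect_true(all(comp$rex_noe35 >= 0))
  expect_true(all(comp$rex_mt >= 0))
})

test_that("narrow components decay in the far wing, unlike the MT component", {
  comp <- fx_components()
  at10 <- comp[which.min(abs(comp$offset_ppm - 10)), ]
  expect_lt(at10$rex_noe35, 0.1 * max(comp$rex_noe35))
  expect_gt(at10$rex_mt, 0.3 * max(comp$rex_mt))
})

test_that("fit -> extract -> reconstruct reproduces the simulated spectrum", {
  m <- fx_model()
  zs <- fx_brain()
  comp <- fx_components()
  rec <- reconstruct_zspectrum(
    comp, model_noe16 <- m$pools[m$pools$name == "NOE16", ],
    water_params(m$r1obs, m$water$r2w),
    grid = fx_grid(), include_amide = TRUE)
  expect_lt(max(abs(rec$z - zs$z)), 0.02)
})

test_that("reconstruction limits and monotonicity in the scaling factors", {
  comp <- fx_components()
  m <- fx_model()
  p16 <- pool("NOE16", 2e-3, 20, 30, -1.6)
  w <- water_params(0.6, 20)
  rec <- reconstruct_zspectrum(comp, p16, w, grid = fx_grid())
  # far off-resonance the signal approaches full relaxation recovery
  expect_gt(rec$z[which.min(abs(rec$offset_ppm - 10))], 0.85)

  rec2 <- reconstruct_zspectrum(comp, p16, w,
                                r = list(r_noe35 = 2, r_amine_guan = 1, r_mt = 1),
                                grid = fx_grid())
  i35 <- which.min(abs(rec$offset_ppm + 3.5))
  expect_lt(rec2$z[i35], rec$z[i35])
  expect_error(reconstruct_zspectrum(comp, p16, w,
                                     r = list(r_noe35 = -1, r_amine_guan = 1,
                                              r_mt = 1), grid = fx_grid()))
})

test_that("B0 shift injection is equivalent to resampling the unshifted curve", {
  comp <- fx_components()
  p16 <- pool("NOE16", 2e-3, 20, 30, -1.6)
  w <- water_params(0.6, 20)
  g <- fx_grid()
  base <- reconstruct_zspectrum(comp, p16, w, grid = g)
  for (delta in c(-0.1, 0.05, 0.1)) {
    shifted <- reconstruct_zspectrum(comp, p16, w, b0_shift_ppm = delta, grid = g)
    # un-shift by cubic re-interpolation and compare away from the steep
    # direct-saturation dip (interpolation there is limited by the sampling,
    # not by the shift injection) and off the grid edges
    f <- splinefun(shifted$offset_ppm, shifted$z, method = "natural")
    interior <- abs(as.numeric(g)) <= 9.5 & abs(as.numeric(g)) >= 1
    expect_lt(max(abs(f(as.numeric(g)[interior] - delta) - base$z[interior])),
              0.005)
  }
})

test_that("sampled datasets draw uniformly and carry analytic targets", {
  comp <- fx_components()
  ds <- sample_partial_synth(comp, 600, seed = 5)
  expect_s3_class(ds, "cest_dataset")
  expect_equal(nrow(ds), 600)
  sat <- fx_sat()
  for (i in c(1, 100, 599)) {
    p <- ds$params[[i]]
    p16 <- pool("NOE16", p$fs, p$ksw, p$r2s, -1.6)
    expect_equal(ds$A[i], rex(p16, sat, ppm_to_rads(-1.6)), tolerance = 1e-12)
    expect_equal(ds$W[i], peak_width(p16, sat, unit = "ppm"), tolerance = 1e-12)
  }
  fs_draws <- purrr::map_dbl(ds$params, "fs")
  ks <- suppressWarnings(ks.test(fs_draws, "punif", 5e-4, 5e-3))
  expect_gt(ks$p.value, 0.01)

  # degenerate ranges give a deterministic sample
  rng1 <- purrr::map(synth_default_ranges(), ~rep(mean(.x), 2))
  one <- sample_partial_synth(comp, 1, ranges = rng1, seed = 1)
  two <- sample_partial_synth(comp, 1, ranges = rng1, seed = 99)
  expect_equal(one$z[[1]], two$z[[1]], tolerance = 1e-12)
})

test_that("analytic width target increases with the solute transverse rate", {
  sat <- fx_sat()
  r2s <- seq(10, 100, by = 10)
  w <- vapply(r2s, function(r) {
    peak_width(pool("NOE16", 2e-3, 30, r, -1.6), sat, unit = "ppm")
  }, numeric(1))
  expect_true(all(diff(w) > 0))
})

test_that("generation is fast enough for large training sets", {
  comp <- fx_components()
  t0 <- proc.time()
  invisible(sample_partial_synth(comp, 2500, seed = 2))
  cpu <- (proc.time() - t0)[["user.self"]]
  expect_lt(cpu, 15)  # 10^4 samples within a minute
})
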