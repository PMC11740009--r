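# Bloch-McConnell generator assembly, Z-spectrum propagation, dataset
# generation, parameter perturbation and noise injection.

two_pool_model <- function(fs = 2e-3, ksw = 20, r2s = 30, delta = -1.6,
                           r1w = 1 / 1.7, r2w = 20) {
  tissue_model(water = list(r1w = r1w, r2w = r2w),
               pools = pool("NOE16", fs, ksw, r2s, delta))
}

test_that("generator has conservative exchange and stable eigenvalues", {
  sat <- fx_sat()
  # water-only, no saturation: Mz decouples from Mx/My
  m0 <- tissue_model(water = list(r1w = 0.6, r2w = 20),
                     pools = pool("x", 1e-12, 20, 30, -1.6))
  gen <- bm_generator(m0, saturation(0, t_sat = 5), 0)
  expect_equal(gen$G[3, 1], 0)
  expect_equal(gen$G[3, 2], 0)

  set.seed(5)
  for (i in 1:50) {
    m <- two_pool_model(runif(1, 1e-4, 0.02), runif(1, 5, 500),
                        runif(1, 5, 200), runif(1, -4, 4),
                        runif(1, 0.3, 1.2), runif(1, 5, 30))
    gen <- bm_generator(m, sat, runif(1, -12000, 12000))
    # exchange conservation: for the z-components, water loss rate equals the
    # solute gain rate (columns of the exchange sub-block sum to zero once
    # relaxation is removed)
    kws <- m$pools$ksw * m$pools$fs
    expect_equal(gen$G[6, 3], kws)          # water z -> solute z
    expect_equal(gen$G[3, 6], m$pools$ksw)  # solute z -> water z
    ev <- eigen(gen$G, only.values = TRUE)$values
    expect_true(all(Re(ev) <= 1e-10))
  }
})

test_that("Z-spectrum limits: no saturation and full on-resonance saturation", {
  g <- fx_grid()
  m <- two_pool_model()
  z0 <- simulate_zspectrum(m, saturation(0, t_sat = 5), g)
  expect_true(all(abs(z0$z - 1) < 1e-6))

  mw <- tissue_model(water = list(r1w = 1, r2w = 20),
                     pools = pool("x", 1e-12, 20, 30, 3))
  zsat <- simulate_zspectrum(mw, saturation(5, t_sat = 20),
                             offset_grid(1, 1, c(-1, 1), c(-1, 1)))
  expect_lt(zsat$z[zsat$offset_ppm == 0], 1e-3)
})

test_that("two-pool simulation matches the analytic Rex at the pool center", {
  g <- fx_grid(); sat <- fx_sat()
  set.seed(11)
  for (i in 1:5) {
    fs <- runif(1, 5e-4, 0.01); ksw <- runif(1, 10, 100); r2s <- runif(1, 10, 80)
    m <- two_pool_model(fs, ksw, r2s)
    ref <- two_pool_model(1e-12, ksw, r2s)
    z <- simulate_zspectrum(m, sat, g)
    zr <- simulate_zspectrum(ref, sat, g)
    i16 <- which.min(abs(z$offset_ppm + 1.6))
    rex_sim <- m$water$r1w * (1 / z$z[i16] - 1 / zr$z[i16])
    rex_true <- rex(m$pools, sat, ppm_to_rads(z$offset_ppm[i16]))
    expect_equal(rex_sim, rex_true, tolerance = 0.05)
  }
})

test_that("spectrum is mirror-symmetric under reflection of pool offsets", {
  g <- fx_grid(); sat <- fx_sat()
  m <- two_pool_model(delta = -2)
  m_flip <- two_pool_model(delta = 2)
  z <- simulate_zspectrum(m, sat, g)
  zf <- simulate_zspectrum(m_flip, sat, g)
  expect_equal(z$z, rev(zf$z), tolerance = 1e-8)
})

test_that("raising a solute's pool size never raises z at its center", {
  g <- fx_grid(); sat <- fx_sat()
  base <- simulate_zspectrum(two_pool_model(fs = 1e-3), sat, g)
  up <- simulate_zspectrum(two_pool_model(fs = 4e-3), sat, g)
  i16 <- which.min(abs(as.numeric(g) + 1.6))
  expect_lt(up$z[i16], base$z[i16])
})

test_that("matrix-exponential and RK4 fine-step propagation agree to 1e-4", {
  # dt must resolve the fastest precession (~12.6 krad/s at -10 ppm);
  # 0.1 ms keeps RK4 stable over the whole grid
  sub_grid <- offset_grid(5, 5, c(-5, 5), c(-10, 10))
  set.seed(21)
  for (i in 1:3) {
    m <- two_pool_model(runif(1, 1e-3, 8e-3), runif(1, 10, 80),
                        runif(1, 10, 80), runif(1, -3.5, -1))
    z1 <- simulate_zspectrum(m, fx_sat(), sub_grid, method = "expm")
    z2 <- simulate_zspectrum(m, fx_sat(), sub_grid, method = "rk4", dt = 1e-4)
    expect_lt(max(abs(z1$z - z2$z)), 1e-4)
  }
})

test_that("parameter perturbation leaves NOE(-1.6) untouched and is unbiased", {
  m <- fx_model()
  expect_equal(perturb_parameters(m, spread = 0)$pools, m$pools)

  set.seed(3)
  i16 <- match("NOE16", m$pools$name)
  draws <- replicate(700, {
    pm <- perturb_parameters(m, spread = 0.3)
    expect_equal(pm$pools$fs[i16], m$pools$fs[i16])
    c(pm$pools$fs[-i16] / m$pools$fs[-i16],
      pm$pools$ksw[-i16] / m$pools$ksw[-i16],
      pm$pools$r2s[-i16] / m$pools$r2s[-i16])
  })
  expect_true(all(draws >= 0.7 & draws <= 1.3))
  expect_equal(mean(draws), 1.0, tolerance = 0.01)
  # the uniform variant fills the interior of the interval
  set.seed(4)
  u <- replicate(50, perturb_parameters(m, 0.3,
                                        multipliers = "uniform")$water$r1w)
  expect_gt(length(unique(round(u, 6))), 40)
  # deterministic under a fixed seed
  expect_equal(perturb_parameters(m, 0.3, seed = 9)$pools,
               perturb_parameters(m, 0.3, seed = 9)$pools)
})

test_that("noise injection has sd 1/snr, is seeded, and vanishes at high snr", {
  z <- fx_brain()
  n1 <- add_noise(z, snr = 200, seed = 4)
  n2 <- add_noise(z, snr = 200, seed = 4)
  expect_identical(n1$z, n2$z)
  expect_false(identical(add_noise(z, 200, seed = 5)$z, n1$z))
  resid <- replicate(200, add_noise(z, 200, seed = NULL)$z - z$z)
  expect_equal(sd(resid), 0.005, tolerance = 0.03)
  hi <- add_noise(z, snr = 1e9, seed = 1)
  expect_equal(hi$z, z$z, tolerance = 1e-6)
})

test_that("tissue-mimicking design enumerates the full factorial", {
  expect_equal(nrow(tissue_mimicking_design()), 177147)  # 3^11
  varied <- tm_varied_parameters()
  small <- tissue_mimicking_design(varied[c(4, 5), ])
  expect_equal(nrow(small), 9)
  expect_error(tissue_mimicking_design(max_size = 1000), "max_size")
})

test_that("simulated datasets carry analytic ground truth", {
  varied <- tm_varied_parameters()
  design <- tissue_mimicking_design(varied[c(4, 5, 8), ])
  ds <- simulate_tissue_mimicking(design, 6, seed = 31)
  expect_s3_class(ds, "cest_dataset")
  expect_equal(nrow(ds), 6)
  sat <- fx_sat()
  for (i in seq_len(nrow(ds))) {
    row <- design[design$combo_id == ds$combo_id[i], ]
    p <- pool("NOE16", row[["pool:NOE16:fs"]], row[["pool:NOE16:ksw"]], 30, -1.6)
    expect_equal(ds$A[i], rex(p, sat, ppm_to_rads(-1.6)), tolerance = 1e-10)
    expect_equal(ds$W[i], peak_width(p, sat, unit = "ppm"), tolerance = 1e-10)
  }
  # fully simulated training set: targets recompute from recorded params
  ts <- simulate_training_set(5, seed = 17)
  expect_equal(nrow(ts), 5)
  expect_true(all(ts$A > 0 & ts$W > 0))
})
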