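# Shared six-pool Lorentzian fixture generators.

# synthesize a Z-spectrum from known Lorentzian parameters; draws stay close
# to the canonical pool positions/widths so the six lines remain mutually
# identifiable (arbitrary draws across the full fit boxes are not - e.g. an
# MT line centered on the NOE(-1.6) position has no unique decomposition)
random_six_pool <- function(seed) {
  set.seed(seed)
  r <- function(lo, hi) runif(1, lo, hi)
  tibble::tibble(
    name = c("water", "amide", "amine_guan", "NOE16", "NOE35", "MT"),
    A = c(r(0.6, 0.95), r(0.01, 0.1), r(0.01, 0.15), r(0.005, 0.08),
          r(0.02, 0.2), r(0.05, 0.3)),
    W = c(r(1.2, 3), r(0.8, 2.5), r(2, 5), r(0.4, 1.5), r(2, 5), r(15, 50)),
    delta_ppm = c(r(-0.05, 0.05), 3.5 + r(-0.1, 0.1), 2.2 + r(-0.3, 0.3),
                  -1.6 + r(-0.15, 0.15), -3.5 + r(-0.25, 0.25),
                  -2.5 + r(-0.5, 0.5))
  )
}

lorentz_z <- function(pars, x) {
  1 - Reduce(`+`, purrr::pmap(pars, function(name, A, W, delta_ppm) {
    lorentz_peak(A, W, delta_ppm, x)
  }))
}

# draw until the implied spectrum is physical (z stays well above zero)
random_six_pool_valid <- function(seed, grid) {
  for (k in 0:40) {
    pars <- random_six_pool(seed + 1000L * k)
    if (min(lorentz_z(pars, as.numeric(grid))) > 0.02) return(pars)
  }
  stop("no valid draw found")
}
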