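# Multi-pool Bloch-McConnell simulation: tissue models, coupled-ODE assembly,
# continuous-wave Z-spectrum propagation (matrix exponential in src/), the
# tissue-mimicking factorial design, and random parameter perturbation.

#' Multi-pool tissue model
#'
#' Bundles water relaxation, a table of solute pools (including the semi-solid
#' MT pool, modelled as an ordinary exchanging pool with a very short T2s),
#' and a static-field (B0) shift. `r1obs` defaults to the water `r1w`; in the
#' simulator the observed and intrinsic water R1 are treated as equal.
#'
#' @param water List with `r1w` and `r2w` (1/s).
#' @param pools Tibble of pools as produced by [pool()]; the MT pool must be
#'   named `"MT"` for its size ratio to be reported as `fm`.
#' @param b0_shift_ppm Static-field offset of the whole spectrum (ppm).
#' @param r1obs Observed water longitudinal rate (1/s); default `water$r1w`.
#' @param field_T Static field in tesla.
#' @return An object of class `"tissue_model"`.
#' @export
tissue_model <- function(water, pools, b0_shift_ppm = 0,
                         r1obs = water$r1w, field_T = 4.7) {
  stopifnot(water$r1w > 0, water$r2w > 0, nrow(pools) >= 0)
  structure(
    list(water = water, pools = pools, b0_shift_ppm = b0_shift_ppm,
         r1obs = r1obs, field_T = field_T),
    class = "tissue_model"
  )
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> %d pools + water, R1w = %.3g, R2w = %.3g, B0 shift = %g ppm\n",
              nrow(x$pools), x$water$r1w, x$water$r2w, x$b0_shift_ppm))
  print(x$pools)
  invisible(x)
}

model_fm <- function(model) {
  i <- match("MT", model$pools$name)
  if (is.na(i)) 0 else model$pools$fs[i]
}

model_pool <- function(model, name) {
  i <- match(name, model$pools$name)
  if (is.na(i)) abort(sprintf("no pool named '%s' in the model.", name))
  model$pools[i, ]
}

#' Default brain-like seven-pool tissue model
#'
#' Literature-typical rat-brain parameters at 4.7 T: amide (+3.5 ppm), amine
#' (+3 ppm), guanidine (+2 ppm), NOE(-1.6), NOE(-3.5), semi-solid MT
#' (T2s = 10 us), and water with T1w = 1.7 s, T2w = 50 ms.
#'
#' @param field_T Static field (tesla).
#' @return A [tissue_model()].
#' @export
default_tissue_model <- function(field_T = 4.7) {
  pools <- dplyr::bind_rows(
    pool("amide", fs = 7.2e-4, ksw = 30,   r2s = 30,  delta_ppm = 3.5),
    pool("amine", fs = 2e-3,   ksw = 3000, r2s = 100, delta_ppm = 3.0),
    pool("guan",  fs = 1e-3,   ksw = 500,  r2s = 50,  delta_ppm = 2.0),
    pool("NOE16", fs = 2e-3,   ksw = 20,   r2s = 30,  delta_ppm = -1.6),
    pool("NOE35", fs = 1e-2,   ksw = 20,   r2s = 30,  delta_ppm = -3.5),
    pool("MT",    fs = 0.07,   ksw = 25,   r2s = 1e5, delta_ppm = -2.5)
  )
  tissue_model(water = list(r1w = 1 / 1.7, r2w = 1 / 0.05), pools = pools,
               field_T = field_T)
}

# Assemble the offset-independent part of the Bloch-McConnell generator.
# State layout: (Mx, My, Mz) per pool, water first.  Exchange uses the
# water-normalized detailed-balance convention: solute->water rate ksw,
# water->solute rate ksw*fs.
bm_base <- function(model, sat) {
  np <- nrow(model$pools)
  n <- 3 * (np + 1)
  G <- matrix(0, n, n)
  b <- numeric(n)
  w1 <- sat$omega1
  ix <- function(j) 3 * (j - 1) + 1   # pool j: x, y, z = ix, ix+1, ix+2
  kws <- model$pools$ksw * model$pools$fs
  # water block
  xw <- ix(1)
  G[xw, xw] <- -(model$water$r2w + sum(kws))
  G[xw + 1, xw + 1] <- -(model$water$r2w + sum(kws))
  G[xw + 2, xw + 2] <- -(model$water$r1w + sum(kws))
  G[xw + 1, xw + 2] <- w1
  G[xw + 2, xw + 1] <- -w1
  b[xw + 2] <- model$water$r1w * 1
  for (j in seq_len(np)) {
    p <- model$pools[j, ]
    xs <- ix(j + 1)
    G[xs, xs] <- -(p$r2s + p$ksw)
    G[xs + 1, xs + 1] <- -(p$r2s + p$ksw)
    G[xs + 2, xs + 2] <- -(p$r1s + p$ksw)
    G[xs + 1, xs + 2] <- w1
    G[xs + 2, xs + 1] <- -w1
    b[xs + 2] <- p$r1s * p$fs
    for (c in 0:2) {
      G[xw + c, xs + c] <- G[xw + c, xs + c] + p$ksw
      G[xs + c, xw + c] <- G[xs + c, xw + c] + kws[j]
    }
  }
  M0 <- numeric(n)
  M0[xw + 2] <- 1
  M0[ix(seq_len(np) + 1) + 2] <- model$pools$fs
  list(G = G, b = b,
       x_idx = ix(seq_len(np + 1)), y_idx = ix(seq_len(np + 1)) + 1,
       delta_rads = ppm_to_rads(c(0, model$pools$delta_ppm), model$field_T),
       M0 = M0, water_z = xw + 2)
}

#' Assemble the Bloch-McConnell generator at one offset
#'
#' Returns the linear system `dM/dt = G M + b` for the model under CW
#' saturation at offset `dw` (rad/s, including any B0 shift the caller wants).
#' Exposed mainly for inspection and testing; [simulate_zspectrum()] drives
#' the compiled propagator directly.
#'
#' @param model A [tissue_model()].
#' @param sat A [saturation()].
#' @param dw Offset in rad/s.
#' @return List with square matrix `G`, constant vector `b`, equilibrium
#'   magnetization `M0` and the index `water_z` of the water Mz component.
#' @export
bm_generator <- function(model, sat, dw) {
  base <- bm_base(model, sat)
  G <- base$G
  for (j in seq_along(base$x_idx)) {
    xi <- base$delta_rads[j] - dw
    G[base$x_idx[j], base$y_idx[j]] <- G[base$x_idx[j], base$y_idx[j]] + xi
    G[base$y_idx[j], base$x_idx[j]] <- G[base$y_idx[j], base$x_idx[j]] - xi
  }
  list(G = G, b = base$b, M0 = base$M0, water_z = base$water_z)
}

#' Simulate a Z-spectrum by Bloch-McConnell propagation
#'
#' Evolves the coupled magnetization from thermal equilibrium under CW
#' saturation for `t_sat` at every grid offset (exact matrix-exponential
#' propagation) and reads out the water Mz normalized by its equilibrium
#' value. The model's B0 shift is applied by substituting
#' `dw -> dw + dw_shift` so the spectrum appears shifted on the nominal grid.
#'
#' @param model A [tissue_model()].
#' @param sat A [saturation()].
#' @param grid An [offset_grid()] (ppm).
#' @param method `"expm"` (exact propagator) or `"rk4"` (fine-step
#'   integration, cross-check only).
#' @param dt RK4 step in seconds.
#' @return A [zspectrum()] with `r1obs`/`fm` taken from the model.
#' @export
simulate_zspectrum <- function(model, sat, grid = offset_grid(),
                               method = c("expm", "rk4"), dt = 1e-3) {
  method <- match.arg(method)
  base <- bm_base(model, sat)
  dw <- ppm_to_rads(as.numeric(grid) + model$b0_shift_ppm, model$field_T)
  fun <- if (method == "expm") cw_zspectrum_cpp else
    function(...) cw_zspectrum_rk4_cpp(..., dt = dt)
  z <- fun(base$G, base$b, base$x_idx - 1L, base$y_idx - 1L,
           base$delta_rads, dw, sat$t_sat, base$M0,
           as.integer(base$water_z - 1L))
  zspectrum(as.numeric(grid), pmin(pmax(z, 1e-4), 1.0499),
            r1obs = model$r1obs, fm = model_fm(model),
            field_T = model$field_T,
            meta = list(source = "simulated", b0_shift_ppm = model$b0_shift_ppm))
}

#' Analytic ground-truth NOE(-1.6) amplitude and width of a model
#'
#' Amplitude is the Rex lineshape evaluated at the pool center (no B0 shift);
#' width is the analytic FWHM, converted to ppm.
#'
#' @param model A [tissue_model()] containing a pool named `"NOE16"`.
#' @param sat A [saturation()].
#' @return Named list `A` (1/s) and `W` (ppm).
#' @export
noe16_ground_truth <- function(model, sat) {
  p <- model_pool(model, "NOE16")
  list(A = rex(p, sat, ppm_to_rads(p$delta_ppm, model$field_T), model$field_T),
       W = peak_width(p, sat, unit = "ppm", field_T = model$field_T))
}

#' Randomly perturb tissue parameters
#'
#' Multiplies every selected parameter by an independent `1 +/- spread`
#' multiplier. By default all parameters unrelated to the NOE(-1.6) pool are
#' perturbed (pool fs/ksw/r2s of the other pools plus water r1w/r2w); the
#' NOE(-1.6) pool is left untouched so its ground truth is preserved.
#'
#' With `multipliers = "binary"` (default) each draw is either `1 - spread`
#' or `1 + spread` with equal probability, so a perturbed model is always
#' systematically different from the template - this emulates the inherent
#' mismatch between a literature simulation model and real tissue.
#' `"uniform"` draws from `[1 - spread, 1 + spread]` instead.
#'
#' @param model A [tissue_model()].
#' @param spread Multiplier half-width, in `[0, 1)`.
#' @param which `"non_noe16"` (default) or `"all"`.
#' @param multipliers `"binary"` or `"uniform"`.
#' @param seed Optional integer seed.
#' @return A perturbed [tissue_model()].
#' @export
perturb_parameters <- function(model, spread = 0.3, which = c("non_noe16", "all"),
                               multipliers = c("binary", "uniform"),
                               seed = NULL) {
  which <- match.arg(which)
  multipliers <- match.arg(multipliers)
  stopifnot(spread >= 0, spread < 1)
  draw <- function(n) {
    if (multipliers == "binary") 1 + spread * sample(c(-1, 1), n, replace = TRUE)
    else runif(n, 1 - spread, 1 + spread)
  }
  run <- function() {
    sel <- if (which == "all") rep(TRUE, nrow(model$pools)) else
      model$pools$name != "NOE16"
    for (col in c("fs", "ksw", "r2s")) {
      model$pools[[col]][sel] <- model$pools[[col]][sel] * draw(sum(sel))
    }
    model$water$r1w <- model$water$r1w * draw(1)
    model$water$r2w <- model$water$r2w * draw(1)
    model$r1obs <- model$water$r1w
    model
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# ---- tissue-mimicking factorial design ----

#' Varied-parameter table of the tissue-mimicking design
#'
#' Eleven parameters at three levels each (multiplicative `x0.5/x1/x1.5`
#' around the default model, except the B0 shift which takes -0.05/0/0.05
#' ppm), giving the full 3^11 = 177147 factorial.
#'
#' @return Tibble with columns `param` (path understood by
#'   [tissue_mimicking_design()]) and `levels` (list of length-3 numerics).
#' @export
tm_varied_parameters <- function() {
  mult <- c(0.5, 1, 1.5)
  m <- default_tissue_model()
  lv <- function(x) list(x * mult)
  tibble::tibble(
    param = c("pool:amide:fs", "pool:amine:fs", "pool:guan:fs",
              "pool:NOE16:fs", "pool:NOE16:ksw", "pool:NOE16:r2s",
              "pool:NOE35:fs", "pool:MT:fs",
              "water:r1w", "water:r2w", "b0_shift_ppm"),
    levels = c(lv(7.2e-4), lv(2e-3), lv(1e-3),
               lv(2e-3), lv(20), lv(30),
               lv(1e-2), lv(0.07),
               lv(m$water$r1w), lv(m$water$r2w), list(c(-0.05, 0, 0.05)))
  )
}

#' Full-factorial tissue-mimicking design
#'
#' @param varied Tibble as from [tm_varied_parameters()]; any subset of rows
#'   gives a scaled-down design.
#' @param max_size Refuse to enumerate designs larger than this without the
#'   caller raising the cap.
#' @return Tibble with one column per varied parameter plus `combo_id`.
#' @export
tissue_mimicking_design <- function(varied = tm_varied_parameters(),
                                    max_size = 2e6) {
  sizes <- lengths(varied$levels)
  if (prod(sizes) > max_size) {
    abort(sprintf("factorial of size %g exceeds max_size = %g.",
                  prod(sizes), max_size))
  }
  g <- expand.grid(setNames(varied$levels, varied$param),
                   KEEP.OUT.ATTRS = FALSE)
  out <- tibble::as_tibble(g)
  out$combo_id <- seq_len(nrow(out))
  out
}

# apply one design row (named parameter paths) to a model
apply_design_row <- function(model, row) {
  for (nm in setdiff(names(row), "combo_id")) {
    val <- row[[nm]]
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (parts[1] == "pool") {
      i <- match(parts[2], model$pools$name)
      model$pools[[parts[3]]][i] <- val
    } else if (parts[1] == "water") {
      model$water[[parts[2]]] <- val
    } else if (nm == "b0_shift_ppm") {
      model$b0_shift_ppm <- val
    } else {
      abort(sprintf("unknown parameter path '%s'.", nm))
    }
  }
  model$r1obs <- model$water$r1w
  model
}

#' Simulate a tissue-mimicking dataset with analytic ground truth
#'
#' Draws `n_select` rows from a factorial design (with replacement when
#' `n_select` exceeds the design size), simulates each by Bloch-McConnell
#' propagation, and attaches the analytic NOE(-1.6) ground truth (computed
#' without the B0 shift).
#'
#' @param design Tibble from [tissue_mimicking_design()].
#' @param n_select Number of spectra to simulate.
#' @param seed Integer seed for the selection.
#' @param model Template [tissue_model()].
#' @param sat A [saturation()].
#' @param grid An [offset_grid()].
#' @param snr Optional SNR; when given, each spectrum gets independent noise.
#' @return A `cest_dataset` tibble: columns `sample_id`, `combo_id`, `z`
#'   (list of numeric vectors), `r1obs`, `fm`, `A`, `W`.
#' @export
simulate_tissue_mimicking <- function(design, n_select, seed = 1,
                                      model = default_tissue_model(),
                                      sat = saturation(), grid = offset_grid(),
                                      snr = NULL) {
  pick <- with_seed(seed, sample.int(nrow(design), n_select,
                                     replace = n_select > nrow(design)))
  rows <- design[pick, , drop = FALSE]
  sims <- purrr::pmap(rows, function(...) {
    row <- list(...)
    m <- apply_design_row(model, row)
    zs <- simulate_zspectrum(m, sat, grid)
    gt <- noe16_ground_truth(m, sat)
    list(z = zs$z, r1obs = r1obs(zs), fm = fm_ratio(zs), A = gt$A, W = gt$W)
  })
  out <- tibble::tibble(
    sample_id = seq_len(nrow(rows)),
    combo_id = rows$combo_id,
    z = purrr::map(sims, "z"),
    r1obs = purrr::map_dbl(sims, "r1obs"),
    fm = purrr::map_dbl(sims, "fm"),
    A = purrr::map_dbl(sims, "A"),
    W = purrr::map_dbl(sims, "W")
  )
  if (!is.null(snr)) {
    out$z <- with_seed(seed + 1L, purrr::map(out$z, function(z) {
      pmin(pmax(z + rnorm(length(z), sd = 1 / snr), 1e-4), 1.0499)
    }))
  }
  new_cest_dataset(out, grid = grid, sat = sat, source = "tissue_mimicking",
                   seed = seed, snr = snr)
}

#' Fully simulated training dataset
#'
#' Emulates the "fully simulated" training regime: NOE(-1.6) and water
#' parameters are drawn from the same ranges as the partially synthetic
#' generator, every parameter unrelated to NOE(-1.6) receives an independent
#' `1 +/- spread` multiplier per spectrum, and a random B0 shift is applied.
#' Ground truth comes from the analytic formulas without the B0 shift.
#'
#' @param n Number of spectra.
#' @param ranges Parameter ranges, see [synth_default_ranges()].
#' @param model Template [tissue_model()].
#' @param sat,grid Acquisition settings.
#' @param spread Multiplier half-width for non-NOE(-1.6) parameters.
#' @param multipliers Multiplier scheme, see [perturb_parameters()].
#' @param seed Integer seed.
#' @return A `cest_dataset` (clean spectra; add noise downstream).
#' @export
simulate_training_set <- function(n, ranges = synth_default_ranges(),
                                  model = default_tissue_model(),
                                  sat = saturation(), grid = offset_grid(),
                                  spread = 0.3,
                                  multipliers = c("binary", "uniform"),
                                  seed = 1) {
  multipliers <- match.arg(multipliers)
  with_seed(seed, {
    draws <- draw_synth_params(n, ranges)
    sims <- purrr::pmap(draws, function(fs, ksw, r2s, r1obs, r2w, r_noe35,
                                        r_amine_guan, r_mt, b0_shift_ppm) {
      m <- perturb_parameters(model, spread = spread, multipliers = multipliers)
      i <- match("NOE16", m$pools$name)
      m$pools$fs[i] <- fs; m$pools$ksw[i] <- ksw; m$pools$r2s[i] <- r2s
      m$water$r1w <- r1obs; m$water$r2w <- r2w
      m$r1obs <- r1obs
      m$b0_shift_ppm <- b0_shift_ppm
      zs <- simulate_zspectrum(m, sat, grid)
      gt <- noe16_ground_truth(m, sat)
      list(z = zs$z, r1obs = r1obs, fm = model_fm(m), A = gt$A, W = gt$W)
    })
    out <- tibble::tibble(
      sample_id = seq_len(n),
      z = purrr::map(sims, "z"),
      r1obs = purrr::map_dbl(sims, "r1obs"),
      fm = purrr::map_dbl(sims, "fm"),
      A = purrr::map_dbl(sims, "A"),
      W = purrr::map_dbl(sims, "W")
    )
    new_cest_dataset(out, grid = grid, sat = sat, source = "fully_simulated",
                     seed = seed)
  })
}

# ---- dataset container ----

new_cest_dataset <- function(tbl, grid, sat, source, seed = NULL, snr = NULL) {
  structure(tbl, class = c("cest_dataset", class(tbl)),
            grid = grid, sat = sat,
            provenance = list(source = source, seed = seed, snr = snr))
}

#' @export
print.cest_dataset <- function(x, ...) {
  p <- attr(x, "provenance")
  cat(sprintf("<cest_dataset> %d spectra x %d offsets (%s)\n",
              nrow(x), length(attr(x, "grid")), p$source))
  NextMethod()
}

dataset_grid <- function(x) attr(x, "grid")
dataset_sat <- function(x) attr(x, "sat")

#' Add noise to every spectrum of a dataset
#'
#' @param dataset A `cest_dataset`.
#' @param snr Signal-to-noise ratio (noise sd = 1/snr on the normalized z).
#' @param seed Integer seed; one stream across the whole dataset.
#' @return The dataset with noisy `z`.
#' @export
dataset_add_noise <- function(dataset, snr, seed = 1) {
  dataset$z <- with_seed(seed, purrr::map(dataset$z, function(z) {
    pmin(pmax(z + rnorm(length(z), sd = 1 / snr), 1e-4), 1.0499)
  }))
  prov <- attr(dataset, "provenance")
  prov$snr <- snr
  attr(dataset, "provenance") <- prov
  dataset
}

# pull one row of a dataset out as a zspectrum object
dataset_zspectrum <- function(dataset, i) {
  zspectrum(as.numeric(dataset_grid(dataset)), dataset$z[[i]],
            r1obs = dataset$r1obs[i], fm = dataset$fm[i],
            field_T = grid_field(dataset_grid(dataset)),
            meta = list(sample_id = dataset$sample_id[i]))
}
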