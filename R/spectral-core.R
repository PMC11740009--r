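# Analytic building blocks shared by every other module: the exchange-dependent
# relaxation lineshape Rex, the effective water relaxation Reff, the Lorentzian
# peak, the AREX metric, peak-width formula, and the acquisition offset grid.
# All spectral math is done in rad/s; ppm appears only at I/O boundaries.

#' Proton gyromagnetic ratio over 2*pi (MHz/T)
#'
#' Standard proton constant used for every ppm <-> rad/s conversion.
#' At 4.7 T one ppm corresponds to `2*pi*42.5764*4.7` = 1257.3 rad/s.
#' @export
GAMMA_MHZ_PER_T <- 42.5764

#' Convert chemical-shift offsets between ppm and rad/s
#'
#' @param x Numeric vector of offsets.
#' @param field_T Static field strength in tesla.
#' @return Numeric vector, converted linearly via the proton Larmor frequency
#'   `42.5764 * field_T` MHz.
#' @examples
#' ppm_to_rads(1, 4.7)    # ~1257.3 rad/s
#' @export
ppm_to_rads <- function(x, field_T = 4.7) {
  2 * pi * GAMMA_MHZ_PER_T * field_T * x
}

#' @rdname ppm_to_rads
#' @export
rads_to_ppm <- function(x, field_T = 4.7) {
  x / (2 * pi * GAMMA_MHZ_PER_T * field_T)
}

#' Continuous-wave saturation parameters
#'
#' @param b1_uT Saturation amplitude in microtesla. The angular amplitude is
#'   `omega1 = 2*pi*42.5764*b1_uT` rad/s (267.5 rad/s per uT).
#' @param t_sat Saturation duration in seconds.
#' @param t_rec Recovery duration in seconds (recorded; the steady-state
#'   simulator does not use it).
#' @return An object of class `"saturation"`.
#' @examples
#' saturation(b1_uT = 1, t_sat = 5)
#' @export
saturation <- function(b1_uT = 1, t_sat = 5, t_rec = 2) {
  stopifnot(b1_uT >= 0, t_sat > 0)
  structure(
    list(b1_uT = b1_uT, omega1 = 2 * pi * GAMMA_MHZ_PER_T * b1_uT,
         t_sat = t_sat, t_rec = t_rec),
    class = "saturation"
  )
}

#' @export
print.saturation <- function(x, ...) {
  cat(sprintf("<saturation> B1 = %g uT (omega1 = %.1f rad/s), t_sat = %g s\n",
              x$b1_uT, x$omega1, x$t_sat))
  invisible(x)
}

#' Solute pool parameters
#'
#' One row per pool: pool size ratio `fs` (relative to water), exchange or
#' dipolar-coupling rate `ksw` (1/s), solute transverse relaxation rate `r2s`
#' (1/s), chemical shift `delta_ppm` relative to water, and solute
#' longitudinal rate `r1s` (1/s).
#'
#' @param name Pool label, e.g. `"NOE16"`.
#' @param fs Pool size ratio (>= 0).
#' @param ksw Exchange/coupling rate in 1/s (> 0).
#' @param r2s Solute transverse relaxation rate in 1/s (> 0).
#' @param delta_ppm Chemical-shift offset from water in ppm.
#' @param r1s Solute longitudinal relaxation rate in 1/s.
#' @return A one-row tibble.
#' @examples
#' pool("NOE16", fs = 2e-3, ksw = 20, r2s = 30, delta_ppm = -1.6)
#' @export
pool <- function(name, fs, ksw, r2s, delta_ppm, r1s = 1) {
  stopifnot(fs >= 0, ksw > 0, r2s > 0)
  tibble::tibble(name = name, fs = fs, ksw = ksw, r2s = r2s,
                 delta_ppm = delta_ppm, r1s = r1s)
}

#' Water relaxation parameters
#'
#' @param r1obs Observed water longitudinal relaxation rate in 1/s.
#' @param r2w Water transverse relaxation rate in 1/s.
#' @return An object of class `"water_params"`.
#' @export
water_params <- function(r1obs, r2w) {
  stopifnot(r1obs > 0, r2w > 0)
  structure(list(r1obs = r1obs, r2w = r2w), class = "water_params")
}

#' Build the CEST acquisition offset grid
#'
#' The acquisition samples saturation offsets finely around water and coarsely
#' in the wings; the grid is the sorted union of the two regular sub-grids.
#' The default arguments give the 89-point grid used throughout: 0.125 ppm
#' steps on \[-5, 5\] ppm and 1.25 ppm steps on \[-10, 10\] ppm.
#'
#' @param fine_step_ppm,coarse_step_ppm Step sizes in ppm.
#' @param fine_range,full_range Length-2 numeric ranges in ppm; `fine_range`
#'   must lie within `full_range` and each step must divide its range evenly.
#' @param field_T Static field in tesla (kept as an attribute for unit
#'   conversions).
#' @return Numeric vector of offsets (ppm), strictly increasing, of class
#'   `"offset_grid"` with attributes `field_T` and `larmor_MHz`.
#' @examples
#' g <- offset_grid()
#' length(g)  # 89
#' @export
offset_grid <- function(fine_step_ppm = 0.125, coarse_step_ppm = 1.25,
                        fine_range = c(-5, 5), full_range = c(-10, 10),
                        field_T = 4.7) {
  stopifnot(length(fine_range) == 2, length(full_range) == 2)
  fine_range <- sort(fine_range); full_range <- sort(full_range)
  if (fine_range[1] < full_range[1] || fine_range[2] > full_range[2]) {
    abort("`fine_range` must be contained in `full_range`.")
  }
  check_divisible <- function(rng, step) {
    n <- diff(rng) / step
    if (abs(n - round(n)) > 1e-9) {
      abort(sprintf("step %g does not divide range [%g, %g] evenly.",
                    step, rng[1], rng[2]))
    }
    round(n)
  }
  nf <- check_divisible(fine_range, fine_step_ppm)
  nc <- check_divisible(full_range, coarse_step_ppm)
  fine <- fine_range[1] + fine_step_ppm * (0:nf)
  coarse <- full_range[1] + coarse_step_ppm * (0:nc)
  offs <- sort(unique(round(c(fine, coarse), 9)))
  structure(offs, class = "offset_grid",
            field_T = field_T, larmor_MHz = GAMMA_MHZ_PER_T * field_T)
}

#' @export
print.offset_grid <- function(x, ...) {
  cat(sprintf("<offset_grid> %d offsets, %g to %g ppm at %g T\n",
              length(x), min(x), max(x), attr(x, "field_T")))
  invisible(x)
}

grid_field <- function(grid) {
  f <- attr(grid, "field_T")
  if (is.null(f)) 4.7 else f
}

#' Exchange-dependent relaxation lineshape Rex
#'
#' The rotating-frame relaxation contribution of one solute pool under CW
#' saturation:
#' \deqn{R_{ex}(\Delta\omega) = \frac{f_s k_{sw} \omega_1^2}{
#'   \omega_1^2 + (R_{2s}+k_{sw})k_{sw} +
#'   (\Delta\omega-\Delta)^2 k_{sw}/(R_{2s}+k_{sw})}}
#' with all rates in 1/s and offsets in rad/s. The curve is a Lorentzian in
#' `dw` peaking at the pool's chemical shift.
#'
#' @param pool One-row pool tibble (see [pool()]).
#' @param sat A [saturation()] object.
#' @param dw Saturation offset(s) in rad/s.
#' @param field_T Field used to convert the pool's `delta_ppm` to rad/s.
#' @return Rex in 1/s, same length as `dw`.
#' @examples
#' p <- pool("NOE16", 2e-3, 20, 30, -1.6)
#' rex(p, saturation(1), ppm_to_rads(-1.6))  # peak value, ~0.0394 1/s
#' @export
rex <- function(pool, sat, dw, field_T = 4.7) {
  w1 <- sat$omega1
  delta <- ppm_to_rads(pool$delta_ppm, field_T)
  denom <- w1^2 + (pool$r2s + pool$ksw) * pool$ksw +
    (dw - delta)^2 * pool$ksw / (pool$r2s + pool$ksw)
  pool$fs * pool$ksw * w1^2 / denom
}

#' Effective water relaxation rate under saturation
#'
#' Weighted average of the longitudinal and transverse water rates with the
#' rotating-frame tilt weights:
#' \deqn{R_{eff} = R_{1obs}\frac{\Delta\omega^2}{\omega_1^2+\Delta\omega^2}
#'   + R_{2w}\frac{\omega_1^2}{\omega_1^2+\Delta\omega^2}.}
#' Always lies between `r1obs` and `r2w`.
#'
#' @param water A [water_params()] object.
#' @param sat A [saturation()] object.
#' @param dw Offset(s) in rad/s.
#' @return Reff in 1/s.
#' @export
reff <- function(water, sat, dw) {
  w1 <- sat$omega1
  if (w1 == 0 && any(dw == 0)) {
    abort("Reff is undefined at dw = 0 with zero saturation amplitude.")
  }
  w_r1 <- dw^2 / (w1^2 + dw^2)
  water$r1obs * w_r1 + water$r2w * (1 - w_r1)
}

#' Analytic full width at half maximum of the Rex lineshape
#'
#' \deqn{W \approx 2\sqrt{\omega_1^2 (R_{2s}+k_{sw})/k_{sw} + (R_{2s}+k_{sw})^2}}
#' in rad/s; increases monotonically with both `omega1` and `r2s`.
#'
#' @inheritParams rex
#' @param unit `"rads"` (default) or `"ppm"`.
#' @return Width in the requested unit.
#' @examples
#' peak_width(pool("NOE16", 2e-3, 20, 30, -1.6), saturation(1), unit = "ppm")
#' @export
peak_width <- function(pool, sat, unit = c("rads", "ppm"), field_T = 4.7) {
  unit <- match.arg(unit)
  if (pool$ksw <= 0) abort("peak width undefined for ksw <= 0.")
  rk <- pool$r2s + pool$ksw
  w <- 2 * sqrt(sat$omega1^2 * rk / pool$ksw + rk^2)
  if (unit == "ppm") rads_to_ppm(w, field_T) else w
}

#' Lorentzian peak value
#'
#' Evaluates `A / (1 + (dw - delta)^2 / (0.5 W)^2)`: amplitude `A` at the
#' center and `A/2` at `delta +/- W/2`. `dw`, `delta` and `W` must share one
#' unit (ppm or rad/s).
#'
#' @param A Amplitude.
#' @param W Full width at half maximum.
#' @param delta Peak center.
#' @param dw Evaluation offset(s).
#' @return Numeric vector of peak values.
#' @export
lorentz_peak <- function(A, W, delta, dw) {
  stopifnot(A >= 0, W > 0)
  A / (1 + (dw - delta)^2 / (0.5 * W)^2)
}

#' Apparent exchange-dependent relaxation (AREX)
#'
#' Inverse-difference quantification `R1obs * (1/Z_lab - 1/Z_ref)`, optionally
#' scaled by `(1 + fm)` to account for the semi-solid pool diluting the water
#' signal. Returns a rate in 1/s.
#'
#' @param z_lab,z_ref Label and reference normalized signals in (0, 1.05].
#' @param r1obs Observed water longitudinal rate (1/s).
#' @param fm Semi-solid pool size ratio, used when `mt_correction = TRUE`.
#' @param mt_correction Apply the `(1 + fm)` factor (default `TRUE`).
#' @return AREX in 1/s, same length as the inputs.
#' @examples
#' arex(0.5, 0.6, r1obs = 1, mt_correction = FALSE)  # 1/3
#' @export
arex <- function(z_lab, z_ref, r1obs, fm = 0, mt_correction = TRUE) {
  if (any(z_lab <= 0) || any(z_ref <= 0)) {
    abort("AREX requires strictly positive z values.")
  }
  out <- r1obs * (1 / z_lab - 1 / z_ref)
  if (mt_correction) out <- out * (1 + fm)
  out
}
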