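# The Z-spectrum container: a tibble (offset_ppm, z) subclass carrying the
# per-voxel scalars R1obs and fm plus provenance metadata as attributes.

#' Construct a Z-spectrum
#'
#' A Z-spectrum is the normalized water signal S/S0 sampled over saturation
#' offsets. Stored as a tibble with columns `offset_ppm` and `z` (sorted by
#' offset) and attributes `r1obs` (1/s), `fm` (semi-solid pool size ratio),
#' `field_T` and a free-form `meta` list.
#'
#' @param offset_ppm Offsets in ppm.
#' @param z Normalized signal values in (0, 1.05].
#' @param r1obs Observed water longitudinal rate (1/s).
#' @param fm Semi-solid MT pool size ratio.
#' @param field_T Static field (tesla).
#' @param meta Named list of provenance tags (source, seed, ...).
#' @return A tibble of class `"zspectrum"`.
#' @export
zspectrum <- function(offset_ppm, z, r1obs, fm, field_T = 4.7, meta = list()) {
  stopifnot(length(offset_ppm) == length(z), r1obs > 0, fm >= 0)
  if (any(!is.finite(z)) || any(z <= 0) || any(z > 1.05)) {
    abort("z values must be finite and in (0, 1.05].")
  }
  ord <- order(offset_ppm)
  out <- tibble::tibble(offset_ppm = offset_ppm[ord], z = z[ord])
  if (any(diff(out$offset_ppm) <= 0)) abort("offsets must be distinct.")
  structure(out, class = c("zspectrum", class(out)),
            r1obs = r1obs, fm = fm, field_T = field_T, meta = meta)
}

#' Z-spectrum scalar accessors
#' @param x A `zspectrum`.
#' @return `r1obs()` the observed water R1 (1/s); `fm_ratio()` the semi-solid
#'   pool size ratio.
#' @export
r1obs <- function(x) attr(x, "r1obs")

#' @rdname r1obs
#' @export
fm_ratio <- function(x) attr(x, "fm")

# rebuild a zspectrum like `x` but with new z values (and optional new meta)
zspec_update <- function(x, z, meta = attr(x, "meta")) {
  zspectrum(x$offset_ppm, z, r1obs = r1obs(x), fm = fm_ratio(x),
            field_T = attr(x, "field_T"), meta = meta)
}

#' @export
print.zspectrum <- function(x, ...) {
  cat(sprintf("<zspectrum> %d offsets [%g, %g] ppm, R1obs = %.3g 1/s, fm = %.3g\n",
              nrow(x), min(x$offset_ppm), max(x$offset_ppm),
              r1obs(x), fm_ratio(x)))
  NextMethod()
}

#' Add measurement noise to a Z-spectrum
#'
#' Adds zero-mean Gaussian noise with standard deviation `1/snr` to the
#' normalized signal, the usual thermal-noise model after S0 normalization
#' (SNR 200 corresponds to a noise sigma of 0.005). Deterministic under a
#' fixed seed.
#'
#' @param zspec A [zspectrum()].
#' @param snr Signal-to-noise ratio of the normalized signal (> 0).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A new `zspectrum`; z is clamped to (1e-4, 1.05) so downstream
#'   inverse metrics stay defined.
#' @export
add_noise <- function(zspec, snr, seed = NULL) {
  stopifnot(snr > 0)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  z <- zspec$z + rnorm(nrow(zspec), sd = 1 / snr)
  z <- pmin(pmax(z, 1e-4), 1.0499)
  zspec_update(zspec, z,
               meta = utils::modifyList(attr(zspec, "meta"),
                                        list(snr = snr, noise_seed = seed)))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# run code under a temporary seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Plot a Z-spectrum
#'
#' @param object A `zspectrum`.
#' @param ... Unused.
#' @return A ggplot with the conventional reversed offset axis.
#' @method autoplot zspectrum
#' @export
autoplot.zspectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$offset_ppm, y = .data$z)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "offset (ppm)", y = "S/S0") +
    ggplot2::theme_minimal()
}
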