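# Tissue-mimicking validation harness: emulates the five training-data
# regimes, trains the matching regressors, computes per-sample losses against
# the analytic ground truth, compares with the Lorentzian fit across SNR
# levels, and builds phantom maps.

REGIME_NAMES <- c("partial_synth", "measured", "measured_augmented",
                  "fully_simulated", "simulated_plus_measured")

assert_no_leakage <- function(pool, test_combo_ids) {
  if (!is.null(test_combo_ids) && "combo_id" %in% names(pool) &&
      any(pool$combo_id %in% test_combo_ids)) {
    abort("training pool overlaps the test set (leakage).")
  }
  invisible(TRUE)
}

#' Build the training dataset of one evaluation regime
#'
#' Emulates how each kind of training data would be produced in practice,
#' using a pool of tissue-mimicking spectra disjoint from the test set:
#' \describe{
#'   \item{partial_synth}{Lorentzian-fit one or more pool spectra and
#'     generate `n_synth` partially synthetic samples with analytic targets
#'     from their components (averaged, or round-robinned per sample).}
#'   \item{measured}{`n_measured` pool spectra with Lorentzian-fit targets.}
#'   \item{measured_augmented}{the measured set enlarged by pairwise
#'     averaging, targets refit on the averages.}
#'   \item{fully_simulated}{`n_synth` Bloch-McConnell spectra with every
#'     non-NOE(-1.6) parameter perturbed by an independent 1 +/- 0.3
#'     multiplier; analytic targets.}
#'   \item{simulated_plus_measured}{both of the above, for training followed
#'     by fine-tuning.}
#' }
#'
#' @param name Regime name, one of `REGIME_NAMES`.
#' @param pool `cest_dataset` of tissue-mimicking spectra (training side).
#' @param test_combo_ids Design combo ids of the test set; overlap raises a
#'   leakage error.
#' @param seed Integer seed.
#' @param n_synth Synthetic-sample count for the synthetic regimes.
#' @param n_measured Measured-sample count.
#' @param n_components Pool spectra fitted for the component extraction.
#' @param average_components Average the fitted component records into one
#'   (as in a single-ROI emulation); otherwise the sampler round-robins over
#'   the separate records, diversifying the training backgrounds the way
#'   components from multiple ROIs/voxels would.
#' @param ranges,model,sat,grid,spread Forwarded to the generators.
#' @return A `cest_dataset`, or for `simulated_plus_measured` a list with
#'   elements `simulated` and `measured`.
#' @export
emulate_regime <- function(name, pool, test_combo_ids = NULL, seed = 1,
                           n_synth = 10000,
                           n_measured = min(nrow(pool), 1000),
                           n_components = 1, average_components = FALSE,
                           ranges = synth_default_ranges(),
                           model = default_tissue_model(),
                           sat = dataset_sat(pool), grid = dataset_grid(pool),
                           spread = 0.3) {
  name <- match.arg(name, REGIME_NAMES)
  assert_no_leakage(pool, test_combo_ids)
  measured_set <- function() {
    idx <- with_seed(seed, sample.int(nrow(pool), n_measured))
    sub <- pool[idx, , drop = FALSE]
    fits <- fit_map(sub, b0 = TRUE)
    sub$A <- fits$A
    sub$W <- fits$W
    out <- sub[!is.na(sub$A), , drop = FALSE]
    prov <- attr(out, "provenance"); prov$source <- "measured"
    attr(out, "provenance") <- prov
    out
  }
  switch(name,
    partial_synth = {
      idx <- with_seed(seed + 1L, sample.int(nrow(pool), n_components))
      comps <- purrr::map(idx, function(i) {
        zs <- b0_correct(dataset_zspectrum(pool, i))
        extract_components(zs)
      })
      comp <- if (isTRUE(average_components))
        list(synthcest::average_components(comps)) else comps
      sample_partial_synth(comp, n_synth, ranges = ranges, sat = sat,
                           grid = grid, seed = seed)
    },
    measured = measured_set(),
    measured_augmented = augment_pairwise(measured_set()),
    fully_simulated = simulate_training_set(
      n_synth, ranges = ranges, model = model, sat = sat, grid = grid,
      spread = spread, seed = seed),
    simulated_plus_measured = list(
      simulated = simulate_training_set(
        n_synth, ranges = ranges, model = model, sat = sat, grid = grid,
        spread = spread, seed = seed),
      measured = measured_set())
  )
}

#' Average several measured-component records
#'
#' @param comps List of `measured_components` on one grid.
#' @return A single `measured_components` with element-wise mean spectra and
#'   mean `r1obs`/`fm`.
#' @export
average_components <- function(comps) {
  if (inherits(comps, "measured_components")) return(comps)
  stopifnot(length(comps) >= 1)
  out <- comps[[1]]
  for (col in intersect(c("rex_noe35", "rex_amine_guan", "rex_mt",
                          "rex_amide"), names(out))) {
    out[[col]] <- rowMeans(vapply(comps, function(c) c[[col]],
                                  numeric(nrow(out))))
  }
  attr(out, "r1obs") <- mean(purrr::map_dbl(comps, ~attr(.x, "r1obs")))
  attr(out, "fm") <- mean(purrr::map_dbl(comps, ~attr(.x, "fm")))
  out
}

#' Train the regressor appropriate to a regime
#'
#' Synthetic regimes (partially synthetic, fully simulated) use the full
#' curriculum; measured regimes train once without curriculum since no clean
#' version of measured data exists; the combined regime trains on the
#' simulated set and fine-tunes on the measured set.
#'
#' @param regime Regime name.
#' @param data Output of [emulate_regime()] for that regime.
#' @param target `"A"` or `"W"`.
#' @param config A [regressor_config()].
#' @param curriculum A [curriculum_config()] for the synthetic regimes.
#' @param fine_tune_epochs Fine-tuning epochs for the combined regime.
#' @param seed Integer seed.
#' @return A `noe_regressor`.
#' @export
train_regime <- function(regime, data, target = "A",
                         config = regressor_config(),
                         curriculum = curriculum_config(),
                         fine_tune_epochs = 1000, seed = 1) {
  regime <- match.arg(regime, REGIME_NAMES)
  if (regime %in% c("partial_synth", "fully_simulated")) {
    train_noe_regressor(data, target, config, curriculum, seed = seed)
  } else if (regime %in% c("measured", "measured_augmented")) {
    train_noe_regressor(data, target, config,
                        curriculum_config(n_iterations = 1), seed = seed)
  } else {
    base <- train_noe_regressor(data$simulated, target, config, curriculum,
                                seed = seed)
    fine_tune(base, data$measured, epochs = fine_tune_epochs, seed = seed + 1L)
  }
}

#' Evaluate predictors against analytic ground truth
#'
#' Adds noise at the given SNR to the clean test set (one seed, so every
#' method sees identical noisy inputs), predicts the NOE(-1.6) amplitude with
#' each model, optionally runs the Lorentzian-fit baseline, and returns
#' per-sample absolute-amplitude losses.
#'
#' @param models Named list of `noe_regressor` models (target `"A"`).
#' @param test Clean `cest_dataset` with ground-truth column `A`.
#' @param snr Test-noise SNR (`Inf` for no noise).
#' @param seed Noise seed.
#' @param lorentzian Include the six-pool Lorentzian-fit baseline.
#' @param specs Fit specs for the baseline.
#' @return Tibble `sample_id`, `method`, `loss`, `snr` of class
#'   `"loss_table"`.
#' @export
evaluate_methods <- function(models, test, snr = 75, seed = 1,
                             lorentzian = TRUE,
                             specs = default_pool_specs()) {
  noisy <- if (is.finite(snr)) dataset_add_noise(test, snr, seed) else test
  out <- purrr::imap_dfr(models, function(m, nm) {
    stopifnot(inherits(m, "noe_regressor"))
    pred <- predict(m, noisy)
    tibble::tibble(sample_id = test$sample_id, method = nm,
                   loss = abs(pred - test$A), snr = snr)
  })
  if (lorentzian) {
    fits <- fit_map(noisy, specs = specs, b0 = TRUE)
    out <- dplyr::bind_rows(out, tibble::tibble(
      sample_id = test$sample_id, method = "lorentzian",
      loss = abs(fits$A - test$A), snr = snr))
  }
  structure(out, class = c("loss_table", class(out)))
}

#' Summarise a loss table by method
#'
#' @param losses A [evaluate_methods()] result.
#' @return Tibble `method`, `snr`, `n`, `mean_loss`, `median_loss`, `sd_loss`.
#' @export
summarise_losses <- function(losses) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(losses), .data$method, .data$snr),
    n = dplyr::n(),
    mean_loss = mean(.data$loss, na.rm = TRUE),
    median_loss = median(.data$loss, na.rm = TRUE),
    sd_loss = sd(.data$loss, na.rm = TRUE),
    .groups = "drop"
  )
}

#' @method autoplot loss_table
#' @export
autoplot.loss_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$method, y = .data$loss,
                               fill = .data$method)) +
    ggplot2::geom_violin(trim = TRUE, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "|A_pred - A_truth| (1/s)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Loss of each method across SNR levels with paired noise
#'
#' Reuses one fixed test set and one noise seed for every level, so the
#' noise realizations at different SNRs are the same standard draws scaled
#' by 1/SNR (paired across levels) and all methods at a level see identical
#' noisy inputs.
#'
#' @inheritParams evaluate_methods
#' @param snr_levels Decreasing SNR levels.
#' @return Tibble from [summarise_losses()], one block per level.
#' @export
snr_sweep <- function(models, test, snr_levels = c(200, 100, 75, 50),
                      seed = 1, lorentzian = TRUE,
                      specs = default_pool_specs()) {
  purrr::map_dfr(snr_levels, function(level) {
    summarise_losses(evaluate_methods(models, test, snr = level,
                                      seed = seed, lorentzian = lorentzian,
                                      specs = specs))
  })
}

#' Two-region synthetic phantom
#'
#' An `n_side x n_side` voxel grid split into a "normal" left part and a
#' "tumor" right part in which the NOE(-1.6) pool size ratio is reduced,
#' mirroring the lower NOE(-1.6) amplitude reported in tumors.
#'
#' @param n_side Phantom side length in voxels.
#' @param tumor_fs_factor Multiplier (< 1) on the tumor NOE(-1.6) fs.
#' @param model Template [tissue_model()].
#' @param sat,grid Acquisition settings.
#' @param snr Optional per-voxel noise.
#' @param seed Noise seed.
#' @return A `cest_dataset` with extra columns `row`, `col`, `region`.
#' @export
make_phantom <- function(n_side = 3, tumor_fs_factor = 0.6,
                         model = default_tissue_model(),
                         sat = saturation(), grid = offset_grid(),
                         snr = NULL, seed = 1) {
  vox <- tidyr::expand_grid(row = seq_len(n_side), col = seq_len(n_side))
  vox$region <- ifelse(vox$col > n_side / 2, "tumor", "normal")
  sims <- purrr::map(vox$region, function(reg) {
    m <- model
    if (reg == "tumor") {
      i <- match("NOE16", m$pools$name)
      m$pools$fs[i] <- m$pools$fs[i] * tumor_fs_factor
    }
    zs <- simulate_zspectrum(m, sat, grid)
    gt <- noe16_ground_truth(m, sat)
    list(z = zs$z, r1obs = m$r1obs, fm = model_fm(m), A = gt$A, W = gt$W)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(sample_id = seq_len(nrow(vox))), vox,
    tibble::tibble(z = purrr::map(sims, "z"),
                   r1obs = purrr::map_dbl(sims, "r1obs"),
                   fm = purrr::map_dbl(sims, "fm"),
                   A = purrr::map_dbl(sims, "A"),
                   W = purrr::map_dbl(sims, "W")))
  out <- new_cest_dataset(out, grid = grid, sat = sat, source = "phantom",
                          seed = seed, snr = snr)
  if (!is.null(snr)) out <- dataset_add_noise(out, snr, seed)
  out
}

#' Predict an amplitude map over a phantom
#'
#' @param model A `noe_regressor` for the amplitude.
#' @param phantom A [make_phantom()] dataset.
#' @return List: `map` tibble (`row`, `col`, `region`, `A_pred`),
#'   `regions` per-region mean/sd, and `contrast` (tumor mean minus normal
#'   mean).
#' @export
phantom_map <- function(model, phantom) {
  pred <- predict(model, phantom)
  map <- dplyr::mutate(
    tibble::as_tibble(phantom)[, c("row", "col", "region")], A_pred = pred)
  regions <- dplyr::summarise(dplyr::group_by(map, .data$region),
                              mean_A = mean(.data$A_pred),
                              sd_A = sd(.data$A_pred), .groups = "drop")
  contrast <- regions$mean_A[regions$region == "tumor"] -
    regions$mean_A[regions$region == "normal"]
  list(map = map, regions = regions, contrast = contrast)
}
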