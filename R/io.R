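# Readers and writers: Z-spectra as CSV with a JSON sidecar for the scalar
# metadata, datasets as a directory of plain-text tables, trained regressors
# as JSON, and the seeded fixture generator.

#' Read Z-spectra from CSV
#'
#' Expects columns `offset_ppm`, `z` and optionally `voxel_id` (one spectrum
#' per voxel). Scalars `r1obs` and `fm` come from a JSON sidecar (either
#' top-level scalars or per-voxel lists keyed by voxel id); rows are sorted
#' by offset on load.
#'
#' @param path CSV/TSV file.
#' @param sidecar JSON file; default `<path without extension>.json`.
#' @param field_T Static field (tesla).
#' @return A [zspectrum()] or a named list of them when `voxel_id` exists.
#' @export
read_zspectra <- function(path, sidecar = NULL, field_T = 4.7) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("offset_ppm", "z")
  if (!all(need %in% names(df))) {
    abort(sprintf("missing column(s): %s",
                  paste(setdiff(need, names(df)), collapse = ", ")))
  }
  if (is.null(sidecar)) sidecar <- paste0(sub("\\.[ct]sv$", "", path), ".json")
  if (!file.exists(sidecar)) abort(sprintf("missing sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  one <- function(sub, r1, fm) {
    zspectrum(sub$offset_ppm, sub$z, r1obs = r1, fm = fm, field_T = field_T,
              meta = list(source = "file", path = path))
  }
  if ("voxel_id" %in% names(df)) {
    ids <- unique(df$voxel_id)
    out <- lapply(ids, function(id) {
      sub <- df[df$voxel_id == id, ]
      r1 <- if (length(meta$r1obs) > 1) meta$r1obs[[as.character(id)]] else meta$r1obs
      fm <- if (length(meta$fm) > 1) meta$fm[[as.character(id)]] else meta$fm
      one(sub, r1, fm)
    })
    names(out) <- ids
    out
  } else {
    one(df, meta$r1obs, meta$fm)
  }
}

#' Write a Z-spectrum to CSV plus JSON sidecar
#'
#' @param zspec A [zspectrum()].
#' @param path Output CSV path; the sidecar goes to `<path>.json` (extension
#'   replaced).
#' @return `path`, invisibly.
#' @export
write_zspectra <- function(zspec, path) {
  utils::write.csv(tibble::as_tibble(zspec)[, c("offset_ppm", "z")], path,
                   row.names = FALSE)
  jsonlite::write_json(
    list(r1obs = r1obs(zspec), fm = fm_ratio(zspec),
         field_T = attr(zspec, "field_T"), meta = attr(zspec, "meta")),
    paste0(sub("\\.[ct]sv$", "", path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a dataset as a directory of plain-text tables
#'
#' Layout: `offsets.csv` (one ppm per line), `samples.csv` (per-sample
#' scalars and targets), `z.csv` (samples x offsets matrix) and
#' `provenance.json` (source, seeds, saturation settings).
#'
#' @param dataset A `cest_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly (`write_dataset`); the dataset (`read_dataset`).
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- dataset_grid(dataset)
  sat <- dataset_sat(dataset)
  utils::write.csv(data.frame(offset_ppm = as.numeric(grid)),
                   file.path(dir, "offsets.csv"), row.names = FALSE)
  scalars <- tibble::as_tibble(dataset)[, intersect(
    c("sample_id", "combo_id", "r1obs", "fm", "A", "W", "row", "col", "region"),
    names(dataset))]
  utils::write.csv(scalars, file.path(dir, "samples.csv"), row.names = FALSE)
  Z <- do.call(rbind, dataset$z)
  utils::write.csv(as.data.frame(Z), file.path(dir, "z.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    c(attr(dataset, "provenance"),
      list(field_T = grid_field(grid), b1_uT = sat$b1_uT, t_sat = sat$t_sat,
           n_samples = nrow(dataset))),
    file.path(dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  offs <- utils::read.csv(file.path(dir, "offsets.csv"))$offset_ppm
  scalars <- tibble::as_tibble(utils::read.csv(file.path(dir, "samples.csv")))
  Z <- as.matrix(utils::read.csv(file.path(dir, "z.csv")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  grid <- structure(offs, class = "offset_grid", field_T = prov$field_T,
                    larmor_MHz = GAMMA_MHZ_PER_T * prov$field_T)
  scalars$z <- lapply(seq_len(nrow(Z)), function(i) unname(Z[i, ]))
  new_cest_dataset(scalars[, union(c("sample_id", "z"),
                                   names(scalars))],
                   grid = grid,
                   sat = saturation(prov$b1_uT, prov$t_sat),
                   source = prov$source, seed = prov$seed, snr = prov$snr)
}

#' Save / load a trained regressor as JSON
#'
#' Weights, offset mask, normalization constants and the training
#' configuration are stored in one JSON file; predictions after a round-trip
#' are bit-identical up to the decimal serialization.
#'
#' @param model A `noe_regressor`.
#' @param path Output `.json` path.
#' @return `path` invisibly; `load_regressor` returns the model.
#' @export
save_regressor <- function(model, path) {
  payload <- list(
    target = model$target, mask = model$mask, mask_ppm = model$mask_ppm,
    norm = model$norm, seed = model$seed,
    config = unclass(model$config), curriculum = unclass(model$curriculum),
    weights = model$weights
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_regressor
#' @export
load_regressor <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- p$weights
  for (nm in c("W1", "W2", "W3", "D1", "D2", "D3")) w[[nm]] <- as.matrix(w[[nm]])
  w$L <- as.integer(w$L); w$K <- as.integer(w$K)
  structure(
    list(weights = w, target = p$target, mask = as.logical(p$mask),
         mask_ppm = p$mask_ppm, norm = p$norm,
         config = do.call(regressor_config,
                          p$config[setdiff(names(p$config), "dense_sizes")]),
         curriculum = do.call(curriculum_config, p$curriculum),
         seed = p$seed, history = list()),
    class = "noe_regressor"
  )
}

#' Generate the bundled demonstration fixtures
#'
#' Builds, from one seed: a brain-like seven-pool spectrum, a two-pool
#' (water + NOE(-1.6)) analytic-check spectrum, a 3x3 two-region phantom,
#' and a 200-sample partially synthetic mini training set, all with ground
#' truth. Optionally writes them under `dir` through the package writers.
#'
#' @param seed Integer seed.
#' @param dir Optional output directory.
#' @return Named list `brain`, `two_pool`, `phantom`, `mini_train`.
#' @export
make_fixtures <- function(seed = 1, dir = NULL) {
  sat <- saturation()
  grid <- offset_grid()
  model <- default_tissue_model()
  brain <- simulate_zspectrum(model, sat, grid)
  two_model <- tissue_model(
    water = model$water,
    pools = pool("NOE16", fs = 2e-3, ksw = 20, r2s = 30, delta_ppm = -1.6))
  two_pool <- simulate_zspectrum(two_model, sat, grid)
  phantom <- make_phantom(n_side = 3, snr = 200, seed = seed)
  comp <- extract_components(b0_correct(brain))
  mini_train <- sample_partial_synth(comp, 200, seed = seed)
  out <- list(brain = brain, two_pool = two_pool, phantom = phantom,
              mini_train = mini_train)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_zspectra(brain, file.path(dir, "brain.csv"))
    write_zspectra(two_pool, file.path(dir, "two_pool.csv"))
    write_dataset(phantom, file.path(dir, "phantom"))
    write_dataset(mini_train, file.path(dir, "mini_train"))
  }
  out
}
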