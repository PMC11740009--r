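# The 1D-convolutional regressors for the NOE(-1.6) amplitude and width:
# R1obs/Z input construction, index-range train/validation split, curriculum
# denoising training, pairwise-averaging augmentation, fine-tuning and
# prediction.  The network itself (ELU conv stack + dropout + dense 256/128,
# Adam on MSE) lives in src/cnn.cpp.

#' Offset mask for the regressor input
#'
#' The input uses offsets in \[-10, -0.8\] and \[5, 10\] ppm: the NOE side plus
#' the far downfield wing, excluding the region near water where R1obs/Z is
#' dominated by direct saturation (and singular at 0 ppm). On the default
#' 89-point grid this selects 43 offsets.
#'
#' @param grid An [offset_grid()] (or numeric ppm vector).
#' @param ranges List of length-2 ppm intervals to keep.
#' @return Logical vector over the grid.
#' @export
input_mask <- function(grid, ranges = list(c(-10, -0.8), c(5, 10))) {
  x <- as.numeric(grid)
  Reduce(`|`, lapply(ranges, function(r) x >= r[1] & x <= r[2]))
}

#' Build the R1obs/Z input matrix
#'
#' The AREX logic suggests dividing the observed longitudinal rate by the
#' Z-spectrum: `R1obs/Z` has rate units and removes the per-voxel R1obs
#' scaling from the learning problem.
#'
#' @param dataset A `cest_dataset` (or a single [zspectrum()]).
#' @param mask Logical offset mask, see [input_mask()]; defaults to the
#'   object's own offsets.
#' @return Numeric matrix, one row per sample, `sum(mask)` columns.
#' @export
build_input <- function(dataset, mask = NULL) {
  if (is.null(mask)) {
    offs <- if (inherits(dataset, "zspectrum")) dataset$offset_ppm
            else as.numeric(dataset_grid(dataset))
    mask <- input_mask(offs)
  }
  if (inherits(dataset, "zspectrum")) {
    z <- dataset$z
    if (any(z <= 0)) abort("z must be positive to form R1obs/Z.")
    return(matrix(r1obs(dataset) / z[mask], nrow = 1))
  }
  X <- t(vapply(seq_len(nrow(dataset)), function(i) {
    z <- dataset$z[[i]]
    if (any(z <= 0)) abort("z must be positive to form R1obs/Z.")
    dataset$r1obs[i] / z[mask]
  }, numeric(sum(mask))))
  X
}

#' Index-range train/validation split
#'
#' Validation data is taken from two non-contiguous index ranges of the
#' generation-ordered dataset - \[5%, 10%) and \[70%, 80%) (zero-based,
#' floor-rounded) - so both middle-level and side-level parameter regions are
#' represented; the complement is the training set.
#'
#' @param dataset A `cest_dataset`, ordered by generation index.
#' @param fractions Numeric `c(lo1, hi1, lo2, hi2)` range fractions.
#' @return List with `train` and `val` datasets (attributes preserved).
#' @export
split_train_val <- function(dataset, fractions = c(0.05, 0.10, 0.70, 0.80)) {
  n <- nrow(dataset)
  rng <- function(lo, hi) {
    a <- floor(lo * n); b <- floor(hi * n)
    if (b > a) seq(a + 1, b) else integer(0)  # 1-based
  }
  val_idx <- c(rng(fractions[1], fractions[2]), rng(fractions[3], fractions[4]))
  if (!length(val_idx)) abort("dataset too small for a nonempty validation split.")
  list(train = dataset[-val_idx, , drop = FALSE],
       val = dataset[val_idx, , drop = FALSE])
}

#' Regressor architecture and optimization settings
#'
#' Three 1D conv layers with decreasing filter counts (ELU, stride 1, same
#' padding), dropout after the conv stack, dense layers of exactly 256 and
#' 128 units, linear scalar output; Adam on mean-squared error.
#'
#' @param conv_filters Strictly decreasing filter counts (length 3); the
#'   default (32, 16, 8) is proportionate to the 43-point input.
#' @param kernel_size Convolution kernel width (odd).
#' @param dropout_rate Dropout probability after the conv stack.
#' @param learning_rate,batch_size Adam settings.
#' @param epochs_first Epochs of the first curriculum iteration.
#' @param epochs_later Epochs of each subsequent iteration.
#' @return List of class `"regressor_config"`.
#' @export
regressor_config <- function(conv_filters = c(32, 16, 8), kernel_size = 3,
                             dropout_rate = 0.2, learning_rate = 1e-3,
                             batch_size = 32, epochs_first = 1000,
                             epochs_later = 100) {
  stopifnot(length(conv_filters) == 3, all(diff(conv_filters) < 0),
            kernel_size %% 2 == 1)
  structure(list(conv_filters = conv_filters, kernel_size = kernel_size,
                 dropout_rate = dropout_rate, dense_sizes = c(256, 128),
                 learning_rate = learning_rate, batch_size = batch_size,
                 epochs_first = epochs_first, epochs_later = epochs_later),
            class = "regressor_config")
}

#' Curriculum-learning schedule
#'
#' Training is repeated `n_iterations` times: the first pass uses the clean
#' inputs, and each later pass regenerates the inputs from the original clean
#' spectra with fresh Gaussian noise (sd `noise_sd`) so the network learns to
#' denoise. `schedule = "cumulative"` instead grows the noise sd linearly
#' with the iteration number.
#'
#' @param n_iterations Total passes (1 = plain training, no denoising).
#' @param noise_sd Noise standard deviation added to z.
#' @param schedule `"fresh"` or `"cumulative"`.
#' @return List of class `"curriculum_config"`.
#' @export
curriculum_config <- function(n_iterations = 4, noise_sd = 0.005,
                              schedule = c("fresh", "cumulative")) {
  stopifnot(n_iterations >= 1)
  structure(list(n_iterations = n_iterations, noise_sd = noise_sd,
                 schedule = match.arg(schedule)),
            class = "curriculum_config")
}

# He-normal initialization of all weight tensors; uses the R RNG
cnn_init <- function(L, config, seed) {
  f <- config$conv_filters
  K <- config$kernel_size
  d <- config$dense_sizes
  with_seed(seed, {
    he <- function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
    list(L = as.integer(L), K = as.integer(K),
         W1 = he(K * 1, f[1]), b1 = rep(0, f[1]),
         W2 = he(K * f[1], f[2]), b2 = rep(0, f[2]),
         W3 = he(K * f[2], f[3]), b3 = rep(0, f[3]),
         D1 = he(L * f[3], d[1]), d1 = rep(0, d[1]),
         D2 = he(d[1], d[2]), d2 = rep(0, d[2]),
         D3 = he(d[2], 1), d3 = 0)
  })
}

# rebuild the input matrix from clean z vectors plus fresh noise
noisy_input <- function(dataset, mask, noise_sd, seed) {
  with_seed(seed, {
    X <- t(vapply(seq_len(nrow(dataset)), function(i) {
      z <- dataset$z[[i]] + rnorm(length(dataset$z[[i]]), sd = noise_sd)
      z <- pmin(pmax(z, 1e-4), 1.0499)
      dataset$r1obs[i] / z[mask]
    }, numeric(sum(mask))))
    X
  })
}

#' Train a NOE(-1.6) regressor with curriculum denoising
#'
#' Trains one scalar regressor (amplitude `A` in 1/s or width `W` in ppm;
#' the two targets are separate models). Inputs and target are z-scored with
#' training-set statistics stored in the model. The first curriculum
#' iteration trains on clean inputs for `epochs_first` epochs; subsequent
#' iterations continue from the current weights for `epochs_later` epochs on
#' inputs rebuilt from the clean spectra with fresh Gaussian noise. Training
#' is deterministic for a fixed seed in single-threaded execution.
#'
#' @param dataset A `cest_dataset` with clean `z` and target columns `A`, `W`.
#' @param target `"A"` or `"W"`.
#' @param config A [regressor_config()].
#' @param curriculum A [curriculum_config()]; pass
#'   `curriculum_config(n_iterations = 1)` to disable denoising (as for
#'   measured data, which has no clean version).
#' @param seed Integer seed for initialization, shuffling, dropout and noise.
#' @param mask Offset mask (defaults to [input_mask()] of the dataset grid).
#' @return Object of class `"noe_regressor"`.
#' @export
train_noe_regressor <- function(dataset, target = c("A", "W"),
                                config = regressor_config(),
                                curriculum = curriculum_config(),
                                seed = 1,
                                mask = input_mask(dataset_grid(dataset))) {
  target <- match.arg(target)
  split <- split_train_val(dataset)
  y_raw <- split$train[[target]]
  X_clean <- build_input(split$train, mask)
  norm <- list(x_mean = colMeans(X_clean), x_sd = pmax(apply(X_clean, 2, sd), 1e-12),
               y_mean = mean(y_raw), y_sd = max(sd(y_raw), 1e-12))
  scale_x <- function(X) sweep(sweep(X, 2, norm$x_mean), 2, norm$x_sd, "/")
  y <- (y_raw - norm$y_mean) / norm$y_sd

  weights <- cnn_init(ncol(X_clean), config, seed)
  history <- list()
  for (it in seq_len(curriculum$n_iterations)) {
    if (it == 1) {
      X <- X_clean
    } else {
      sd_it <- if (curriculum$schedule == "fresh") curriculum$noise_sd
               else curriculum$noise_sd * (it - 1)
      X <- noisy_input(split$train, mask, sd_it, seed + 1000L * it)
    }
    epochs <- if (it == 1) config$epochs_first else config$epochs_later
    res <- cnn_train_cpp(weights, scale_x(X), y, epochs,
                         config$batch_size, config$learning_rate,
                         config$dropout_rate, seed + it)
    weights <- res$weights
    val_pred <- cnn_predict_cpp(weights, scale_x(build_input(split$val, mask)))
    val_loss <- mean((val_pred * norm$y_sd + norm$y_mean - split$val[[target]])^2)
    history[[it]] <- list(train_loss = res$loss, val_loss = val_loss)
  }
  structure(
    list(weights = weights, target = target, mask = mask,
         mask_ppm = as.numeric(dataset_grid(dataset))[mask],
         norm = norm, config = config, curriculum = curriculum,
         seed = seed, history = history),
    class = "noe_regressor"
  )
}

#' @export
print.noe_regressor <- function(x, ...) {
  cat(sprintf("<noe_regressor> target %s, %d inputs, %d curriculum iteration(s), val MSE %.3g\n",
              x$target, sum(x$mask), length(x$history),
              x$history[[length(x$history)]]$val_loss))
  invisible(x)
}

#' Predict NOE(-1.6) amplitude or width
#'
#' @param object A [train_noe_regressor()] model.
#' @param newdata A `cest_dataset`, a [zspectrum()], or a pre-built input
#'   matrix with `sum(mask)` columns.
#' @param ... Unused.
#' @return Numeric vector of predictions on the target's original scale
#'   (1/s for `A`, ppm for `W`).
#' @export
predict.noe_regressor <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else build_input(newdata, object$mask)
  if (ncol(X) != sum(object$mask)) {
    abort(sprintf("input has %d features; the model expects %d.",
                  ncol(X), sum(object$mask)))
  }
  Xs <- sweep(sweep(X, 2, object$norm$x_mean), 2, object$norm$x_sd, "/")
  as.numeric(cnn_predict_cpp(object$weights, Xs)) * object$norm$y_sd +
    object$norm$y_mean
}

#' Regenerate NOE(-1.6) spectra from predicted amplitude and width
#'
#' @param A,W Predicted amplitude (1/s) and width (ppm), recycled together.
#' @param offsets_ppm Evaluation offsets.
#' @return Tibble `sample`, `offset_ppm`, `value`: the Lorentzian
#'   `A/(1+(dw+1.6)^2/(0.5W)^2)` centered at -1.6 ppm.
#' @export
predict_noe16_spectrum <- function(A, W, offsets_ppm = seq(-3, 0, by = 0.02)) {
  purrr::map_dfr(seq_along(A), function(i) {
    tibble::tibble(sample = i, offset_ppm = offsets_ppm,
                   value = lorentz_peak(A[i], W[i], -1.6, offsets_ppm))
  })
}

#' Training-history summary of a regressor
#' @param x A `noe_regressor`.
#' @param ... Unused.
#' @return Tibble with one row per curriculum iteration.
#' @method tidy noe_regressor
#' @export
tidy.noe_regressor <- function(x, ...) {
  purrr::map_dfr(seq_along(x$history), function(i) {
    h <- x$history[[i]]
    tibble::tibble(iteration = i, epochs = length(h$train_loss),
                   final_train_mse = h$train_loss[length(h$train_loss)],
                   val_mse = h$val_loss)
  })
}

#' @method glance noe_regressor
#' @export
glance.noe_regressor <- function(x, ...) {
  tibble::tibble(target = x$target, n_inputs = sum(x$mask),
                 iterations = length(x$history),
                 val_mse = x$history[[length(x$history)]]$val_loss)
}

#' Number of pairwise-averaged samples
#'
#' Averaging every unordered pair of `n` spectra yields `n(n-1)/2` samples
#' (about a 700-fold increase for n = 1525).
#'
#' @param n Number of input spectra.
#' @return `choose(n, 2)`.
#' @export
augment_pair_count <- function(n) choose(n, 2)

#' Pairwise-averaging augmentation of measured spectra
#'
#' Averages every unordered pair of spectra (z, R1obs and fm are averaged)
#' and recomputes the training targets by Lorentzian-fitting the averaged
#' spectra, as no analytic ground truth exists for measured data.
#'
#' @param dataset A `cest_dataset` (typically "measured" spectra).
#' @param refit_targets Recompute `A`/`W` by [fit_noe16()] on each averaged
#'   spectrum (default); otherwise pair-average the existing targets.
#' @param specs Fit specs for refitting.
#' @return A `cest_dataset` of `choose(n, 2)` samples.
#' @export
augment_pairwise <- function(dataset, refit_targets = TRUE,
                             specs = default_pool_specs()) {
  n <- nrow(dataset)
  pairs <- utils::combn(n, 2)
  grid <- dataset_grid(dataset)
  out <- tibble::tibble(
    sample_id = seq_len(ncol(pairs)),
    z = purrr::map(seq_len(ncol(pairs)), function(k) {
      (dataset$z[[pairs[1, k]]] + dataset$z[[pairs[2, k]]]) / 2
    }),
    r1obs = (dataset$r1obs[pairs[1, ]] + dataset$r1obs[pairs[2, ]]) / 2,
    fm = (dataset$fm[pairs[1, ]] + dataset$fm[pairs[2, ]]) / 2
  )
  if (refit_targets) {
    ests <- purrr::map(seq_len(nrow(out)), function(i) {
      zs <- zspectrum(as.numeric(grid), out$z[[i]], out$r1obs[i], out$fm[i],
                      field_T = grid_field(grid))
      est <- fit_noe16(zs, specs)
      list(A = est$A, W = est$W)
    })
    out$A <- purrr::map_dbl(ests, "A")
    out$W <- purrr::map_dbl(ests, "W")
  } else {
    out$A <- (dataset$A[pairs[1, ]] + dataset$A[pairs[2, ]]) / 2
    out$W <- (dataset$W[pairs[1, ]] + dataset$W[pairs[2, ]]) / 2
  }
  new_cest_dataset(out, grid = grid, sat = dataset_sat(dataset),
                   source = "measured_augmented")
}

#' Fine-tune a trained regressor on another dataset
#'
#' Continues Adam optimization from the existing weights for `epochs` epochs
#' on the new dataset (typically measured data after training on fully
#' simulated data). The new inputs are scaled with the model's stored
#' normalization, so the offset mask must match.
#'
#' @param model A `noe_regressor`.
#' @param dataset A `cest_dataset` with the model's target column.
#' @param epochs Number of additional epochs.
#' @param seed Integer seed.
#' @return The updated `noe_regressor`.
#' @export
fine_tune <- function(model, dataset, epochs = 1000, seed = model$seed + 1L) {
  if (epochs == 0) return(model)
  X <- build_input(dataset, model$mask)
  if (ncol(X) != sum(model$mask)) abort("offset mask mismatch.")
  Xs <- sweep(sweep(X, 2, model$norm$x_mean), 2, model$norm$x_sd, "/")
  y <- (dataset[[model$target]] - model$norm$y_mean) / model$norm$y_sd
  res <- cnn_train_cpp(model$weights, Xs, y, epochs, model$config$batch_size,
                       model$config$learning_rate, model$config$dropout_rate,
                       seed)
  model$weights <- res$weights
  model$history <- c(model$history,
                     list(list(train_loss = res$loss, val_loss = NA_real_,
                               fine_tuned = TRUE)))
  model
}
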