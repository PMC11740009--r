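# Shared fixtures, built once per test run and cached.  Everything is
# generated in code from fixed seeds; nothing is read from disk.

fixture_cache <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (!exists(name, envir = fixture_cache)) {
    assign(name, build, envir = fixture_cache)
  }
  get(name, envir = fixture_cache)
}

fx_grid <- function() fx("grid", offset_grid())
fx_sat <- function() fx("sat", saturation())
fx_model <- function() fx("model", default_tissue_model())

# brain-like seven-pool simulated spectrum
fx_brain <- function() fx("brain", simulate_zspectrum(fx_model(), fx_sat(), fx_grid()))

# measured components extracted from the brain spectrum
fx_components <- function() {
  fx("components", extract_components(b0_correct(fx_brain())))
}

# small partially synthetic dataset
fx_mini_synth <- function() {
  fx("mini_synth", sample_partial_synth(fx_components(), 300, seed = 421))
}

# a quickly trained amplitude regressor (kept tiny; used where the tests only
# need a working model, not an accurate one)
fx_tiny_model <- function() {
  fx("tiny_model", train_noe_regressor(
    fx_mini_synth(), "A",
    regressor_config(conv_filters = c(8, 6, 4), epochs_first = 60,
                     epochs_later = 20),
    curriculum_config(n_iterations = 2), seed = 7))
}

# independent R implementation of the network forward pass (oracle for the
# compiled version)
ref_cnn_forward <- function(w, X) {
  elu <- function(x) ifelse(x > 0, x, exp(x) - 1)
  K <- w$K; L <- w$L
  conv <- function(A, W, b) {
    Cin <- ncol(A); half <- K %/% 2
    out <- matrix(0, L, ncol(W))
    for (p in seq_len(L)) {
      xcat <- numeric(0)
      for (k in seq_len(K)) {
        q <- p + (k - 1 - half)
        xcat <- c(xcat, if (q >= 1 && q <= L) A[q, ] else rep(0, Cin))
      }
      out[p, ] <- xcat %*% W + b
    }
    elu(out)
  }
  vapply(seq_len(nrow(X)), function(i) {
    A1 <- conv(matrix(X[i, ], ncol = 1), w$W1, w$b1)
    A2 <- conv(A1, w$W2, w$b2)
    A3 <- conv(A2, w$W3, w$b3)
    fl <- as.numeric(t(A3))
    H1 <- elu(fl %*% w$D1 + w$d1)
    H2 <- elu(H1 %*% w$D2 + w$d2)
    as.numeric(H2 %*% w$D3 + w$d3)
  }, numeric(1))
}
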