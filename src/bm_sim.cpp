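// Bloch-McConnell propagation under continuous-wave saturation.
// The coupled ODE dM/dt = G M + b is time-invariant per offset, so the
// saturation period is propagated exactly with one matrix exponential of the
// augmented system [[G, b], [0, 0]].  An RK4 fine-step integrator is kept as
// an independent cross-check of the propagator.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Insert the offset-dependent precession terms into a copy of the base matrix.
// xi_j = delta_j - dw couples the x/y components of pool j.
static mat offset_matrix(const mat &G0, const uvec &x_idx, const uvec &y_idx,
                         const vec &delta_rads, double dw) {
  mat G = G0;
  for (uword j = 0; j < x_idx.n_elem; ++j) {
    double xi = delta_rads(j) - dw;
    G(x_idx(j), y_idx(j)) += xi;
    G(y_idx(j), x_idx(j)) -= xi;
  }
  return G;
}

// [[Rcpp::export]]
arma::vec cw_zspectrum_cpp(const arma::mat &G0, const arma::vec &b,
                           const arma::uvec &x_idx, const arma::uvec &y_idx,
                           const arma::vec &delta_rads,
                           const arma::vec &offsets_rads, double t_sat,
                           const arma::vec &M0, arma::uword water_z_idx) {
  const uword n = G0.n_rows;
  vec z(offsets_rads.n_elem);
  mat A(n + 1, n + 1, fill::zeros);
  vec Maug(n + 1);
  Maug.head(n) = M0;
  Maug(n) = 1.0;
  for (uword i = 0; i < offsets_rads.n_elem; ++i) {
    mat G = offset_matrix(G0, x_idx, y_idx, delta_rads, offsets_rads(i));
    A.zeros();
    A.submat(0, 0, n - 1, n - 1) = G * t_sat;
    A.submat(0, n, n - 1, n) = b * t_sat;
    mat P;
    bool ok = expmat(P, A);
    if (!ok) Rcpp::stop("matrix-exponential propagation failed at offset index %d",
                        (int)(i + 1));
    vec Mt = P * Maug;
    z(i) = Mt(water_z_idx);
  }
  return z;
}

// [[Rcpp::export]]
arma::vec cw_zspectrum_rk4_cpp(const arma::mat &G0, const arma::vec &b,
                               const arma::uvec &x_idx, const arma::uvec &y_idx,
                               const arma::vec &delta_rads,
                               const arma::vec &offsets_rads, double t_sat,
                               const arma::vec &M0, arma::uword water_z_idx,
                               double dt) {
  vec z(offsets_rads.n_elem);
  for (uword i = 0; i < offsets_rads.n_elem; ++i) {
    mat G = offset_matrix(G0, x_idx, y_idx, delta_rads, offsets_rads(i));
    vec M = M0;
    double t = 0.0;
    while (t < t_sat - 1e-12) {
      double h = std::min(dt, t_sat - t);
      vec k1 = G * M + b;
      vec k2 = G * (M + 0.5 * h * k1) + b;
      vec k3 = G * (M + 0.5 * h * k2) + b;
      vec k4 = G * (M + h * k3) + b;
      M += (h / 6.0) * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
      t += h;
    }
    z(i) = M(water_z_idx);
  }
  return z;
}
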