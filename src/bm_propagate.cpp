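// Bloch-McConnell propagation through a pulsed, shaped saturation train.
//
// The coupled magnetization of N proton pools (pool 0 = free water; solute
// pools exchange with water only, star topology) is written as an affine
// linear system dX/dt = A X with X = (Mx1, My1, Mz1, ..., MxN, MyN, MzN, 1).
// For piecewise-constant RF amplitude the exact solution on each segment is
// the matrix exponential expm(A * dt); a shaped pulse is a sequence of such
// segments, an interpulse gap is a segment with B1 = 0.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Assemble the (3N+1)-dimensional affine BM generator.
// pools: N x 5 matrix, columns R1 [1/s], R2 [1/s], M0 (water = 1),
//        k [Hz, solute->water], delta [ppm]; row 0 must be water.
// offset_ppm: saturation frequency; b1_uT: RF amplitude of the segment.
// f0: Hz per ppm (field strength x gyromagnetic ratio);
// gamma: Hz per uT for the RF amplitude.
static arma::mat bm_generator(const arma::mat& pools, double offset_ppm,
                              double b1_uT, double f0, double gamma) {
  const arma::uword n = pools.n_rows;
  const arma::uword dim = 3 * n + 1;
  arma::mat A(dim, dim, arma::fill::zeros);
  const double w1 = 2.0 * M_PI * gamma * b1_uT;
  const double m0w = pools(0, 2);

  for (arma::uword i = 0; i < n; ++i) {
    const double r1 = pools(i, 0), r2 = pools(i, 1), m0 = pools(i, 2);
    const double dw = 2.0 * M_PI * f0 * (pools(i, 4) - offset_ppm);
    const arma::uword x = 3 * i, y = 3 * i + 1, z = 3 * i + 2;

    A(x, x) -= r2;  A(x, y) += dw;
    A(y, x) -= dw;  A(y, y) -= r2;  A(y, z) += w1;
    A(z, y) -= w1;  A(z, z) -= r1;  A(z, dim - 1) += r1 * m0;

    if (i > 0) {
      const double kb = pools(i, 3);            // solute -> water
      const double kf = kb * m0 / m0w;          // water -> solute (detailed balance)
      for (arma::uword c = 0; c < 3; ++c) {
        const arma::uword si = 3 * i + c, wi = c;
        A(si, si) -= kb;  A(si, wi) += kf;
        A(wi, wi) -= kf;  A(wi, si) += kb;
      }
    }
  }
  return A;
}

// Propagate the full train at each offset and return Z = Mz_water / M0_water.
// seg_amp: RF amplitude (uT) of each piecewise-constant segment of ONE pulse;
// seg_dur: matching durations (s); gap_s: interpulse delay; np: pulse count;
// spoil: zero transverse components at the start of each gap.
// [[Rcpp::export]]
NumericVector bm_z_train(const arma::mat& pools, const arma::vec& offsets_ppm,
                         const arma::vec& seg_amp, const arma::vec& seg_dur,
                         double gap_s, int np, bool spoil,
                         double f0, double gamma) {
  const arma::uword n = pools.n_rows;
  const arma::uword dim = 3 * n + 1;
  const double m0w = pools(0, 2);

  arma::vec x0(dim, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) x0(3 * i + 2) = pools(i, 2);
  x0(dim - 1) = 1.0;

  NumericVector z(offsets_ppm.n_elem);
  for (arma::uword o = 0; o < offsets_ppm.n_elem; ++o) {
    const double w = offsets_ppm(o);

    // one-pulse propagator
    arma::mat P = arma::eye(dim, dim);
    for (arma::uword s = 0; s < seg_amp.n_elem; ++s) {
      arma::mat E = arma::expmat(bm_generator(pools, w, seg_amp(s), f0, gamma) *
                                 seg_dur(s));
      P = E * P;
    }
    arma::mat G;
    const bool has_gap = (np > 1 && gap_s > 0.0);
    if (has_gap)
      G = arma::expmat(bm_generator(pools, w, 0.0, f0, gamma) * gap_s);

    arma::vec x = x0;
    for (int k = 0; k < np; ++k) {
      x = P * x;
      if (k < np - 1) {
        if (spoil)
          for (arma::uword i = 0; i < n; ++i) { x(3 * i) = 0.0; x(3 * i + 1) = 0.0; }
        if (has_gap) x = G * x;
      }
    }
    z[o] = x(2) / m0w;
  }
  return z;
}
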