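// Numerical kernels: SLR transforms, spin-domain simulation, minimum-phase
// spectral factorization, polynomial roots, and the VERSE forward-backward
// traversal. Conventions: polynomials are coefficient vectors ascending in
// z^{-1}; frequency responses are evaluated as B(w) = sum_j b_j e^{-i w j},
// so values on the m-point DFT grid equal the forward FFT of the zero-padded
// coefficient vector. RF samples are complex rotation angles in radians
// (phi * e^{i theta}); callers convert to/from microtesla.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using arma::cx_double;
using arma::cx_vec;
using arma::vec;

// Forward SLR: accumulate hard-pulse Cayley-Klein polynomials.
// rfang: complex rotation angle per sample. Returns A, B of length n.
// [[Rcpp::export]]
Rcpp::List slr_forward_cpp(const arma::cx_vec& rfang) {
  const arma::uword n = rfang.n_elem;
  cx_vec A(n, arma::fill::zeros), B(n, arma::fill::zeros);
  cx_vec At(n, arma::fill::zeros), Bt(n, arma::fill::zeros);
  A(0) = 1.0;
  for (arma::uword j = 0; j < n; ++j) {
    const double phi = std::abs(rfang(j));
    const double th = std::arg(rfang(j));
    const double C = std::cos(phi / 2.0);
    const cx_double S = cx_double(0.0, 1.0) *
      std::polar(std::sin(phi / 2.0), th);
    // z^{-1} B then rotate
    At.zeros(); Bt.zeros();
    // shifted B: zB[k] = B[k-1]
    for (arma::uword k = 0; k < n; ++k) {
      cx_double zb = (k == 0) ? cx_double(0, 0) : B(k - 1);
      At(k) = C * A(k) - std::conj(S) * zb;
      Bt(k) = S * A(k) + C * zb;
    }
    A = At; B = Bt;
  }
  return Rcpp::List::create(Rcpp::Named("A") = A, Rcpp::Named("B") = B);
}

// Inverse SLR: recover complex rotation angles from (A, B).
// [[Rcpp::export]]
arma::cx_vec slr_inverse_cpp(arma::cx_vec A, arma::cx_vec B) {
  const arma::uword n = B.n_elem;
  if (A.n_elem != n) Rcpp::stop("A and B must have equal length");
  cx_vec rf(n, arma::fill::zeros);
  for (arma::uword j = n; j-- > 0;) {
    const cx_double a0 = A(0), b0 = B(0);
    const double phi = 2.0 * std::atan2(std::abs(b0), std::abs(a0));
    double th = 0.0;
    if (std::abs(b0) > 0 && std::abs(a0) > 0)
      th = std::arg(b0 / a0) - M_PI / 2.0;
    else if (std::abs(b0) > 0)
      th = std::arg(b0) - M_PI / 2.0;
    rf(j) = std::polar(phi, th);
    const double C = std::cos(phi / 2.0);
    const cx_double S = cx_double(0.0, 1.0) *
      std::polar(std::sin(phi / 2.0), th);
    // undo the rotation: A_prev = C A + conj(S) B ; zB_prev = C B - S A
    cx_vec Ap(j + 1, arma::fill::zeros), Bp(j + 1, arma::fill::zeros);
    for (arma::uword k = 0; k <= j; ++k) {
      Ap(k) = C * A(k) + std::conj(S) * B(k);
      Bp(k) = C * B(k) - S * A(k);
    }
    // B_prev = zB_prev shifted left (drop ~zero constant term);
    // A_prev loses its highest-order (zero) coefficient.
    if (j > 0) {
      A = Ap.subvec(0, j - 1);
      B = Bp.subvec(1, j);
    }
  }
  return rf;
}

// Minimum-phase spectral factorization by the complex cepstrum.
// mag: desired magnitude samples on the m-point DFT grid (length m).
// Returns the first ntaps coefficients of the minimum-phase sequence whose
// magnitude response approximates mag.
// [[Rcpp::export]]
arma::cx_vec mag2mp_cpp(const arma::vec& mag, const int ntaps) {
  const arma::uword m = mag.n_elem;
  vec lm = arma::log(arma::clamp(mag, 1e-12, arma::datum::inf));
  cx_vec c = arma::ifft(arma::conv_to<cx_vec>::from(lm));
  // fold the cepstrum onto the causal side
  cx_vec ch(m, arma::fill::zeros);
  ch(0) = c(0);
  const arma::uword half = m / 2;
  for (arma::uword j = 1; j < half; ++j) ch(j) = 2.0 * c(j);
  if (m % 2 == 0) ch(half) = c(half);
  cx_vec H = arma::exp(arma::fft(ch));
  cx_vec h = arma::ifft(H);
  return h.subvec(0, ntaps - 1);
}

// Build an RF pulse (complex rotation angles) from a beta polynomial.
// b must be scaled so that max |B| < 1 on the unit circle. m: DFT grid size.
// [[Rcpp::export]]
arma::cx_vec beta_to_rf_cpp(const arma::cx_vec& b, const int m) {
  const arma::uword n = b.n_elem;
  cx_vec bp(m, arma::fill::zeros);
  bp.subvec(0, n - 1) = b;
  cx_vec Bg = arma::fft(bp);
  vec mag2 = 1.0 - arma::square(arma::abs(Bg));
  mag2 = arma::clamp(mag2, 1e-10, 1.0);
  cx_vec a = mag2mp_cpp(arma::sqrt(mag2), n);
  return slr_inverse_cpp(a, b);
}

// Spin-domain hard-pulse simulation.
// rfang: complex rotation angles (radians) per sample.
// gphase: per-sample precession phase per mm (gamma * g_j * dt), radians/mm.
// z: positions (mm). offphase: constant per-sample off-resonance phase (rad).
// Order per sample: RF rotation, then free precession over the dwell.
// Returns 2 x nz complex matrix: row 0 = alpha, row 1 = beta.
// [[Rcpp::export]]
arma::cx_mat spin_sim_cpp(const arma::cx_vec& rfang, const arma::vec& gphase,
                          const arma::vec& z, const double offphase) {
  const arma::uword n = rfang.n_elem, nz = z.n_elem;
  if (gphase.n_elem != n) Rcpp::stop("rf and gradient grids differ");
  arma::cx_mat out(2, nz);
  // precompute RF rotation entries
  vec Cj(n); cx_vec Sj(n);
  for (arma::uword j = 0; j < n; ++j) {
    const double phi = std::abs(rfang(j));
    Cj(j) = std::cos(phi / 2.0);
    Sj(j) = cx_double(0.0, 1.0) *
      std::polar(std::sin(phi / 2.0), std::arg(rfang(j)));
  }
  for (arma::uword iz = 0; iz < nz; ++iz) {
    cx_double al(1.0, 0.0), be(0.0, 0.0);
    const double zz = z(iz);
    for (arma::uword j = 0; j < n; ++j) {
      // RF rotation
      const cx_double aln = Cj(j) * al - std::conj(Sj(j)) * be;
      const cx_double ben = Sj(j) * al + Cj(j) * be;
      // free precession: phase accrued at position z over one dwell
      const double psi = gphase(j) * zz + offphase;
      const cx_double e = std::polar(1.0, -psi / 2.0);
      al = aln * e;
      be = ben * std::conj(e);
    }
    out(0, iz) = al;
    out(1, iz) = be;
  }
  return out;
}

// Polynomial roots via companion-matrix eigenvalues (coefficients ascending).
// [[Rcpp::export]]
arma::cx_vec poly_roots_cpp(const arma::cx_vec& coef) {
  cx_vec p = arma::flipud(coef);
  cx_vec r;
  if (!arma::roots(r, p)) Rcpp::stop("companion eigenvalue root finding failed");
  return r;
}

// Time-optimal traversal along a monotone excitation k-trajectory.
// cap: per-position gradient cap (mT/m) on a uniform arc grid of spacing
// ds (rad/mm); smax in mT/m/ms; gam = gamma in rad/(mm ms (mT/m)).
// Forward-backward slew-limited integration of d(g^2)/ds <= 2 smax / gam.
// Returns g (mT/m) and cumulative time t (ms) at each arc position.
// [[Rcpp::export]]
Rcpp::List verse_fb_cpp(const arma::vec& cap, const double ds,
                        const double smax, const double gam) {
  const arma::uword n = cap.n_elem;
  vec g2 = arma::square(cap);
  const double step = 2.0 * smax * ds / gam;
  for (arma::uword i = 1; i < n; ++i)
    g2(i) = std::min(g2(i), g2(i - 1) + step);
  for (arma::uword i = n - 1; i-- > 0;)
    g2(i) = std::min(g2(i), g2(i + 1) + step);
  vec g = arma::sqrt(g2);
  vec t(n, arma::fill::zeros);
  for (arma::uword i = 1; i < n; ++i) {
    // trapezoidal quadrature of dt = ds / (gam * g)
    t(i) = t(i - 1) + ds * 0.5 * (1.0 / (gam * g(i - 1)) + 1.0 / (gam * g(i)));
  }
  return Rcpp::List::create(Rcpp::Named("g") = g, Rcpp::Named("t") = t);
}
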