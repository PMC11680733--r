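// Voxelwise fat-water-R2* fitting engine: variable-projection grid search
// over (field offset, R2*) followed by Levenberg-Marquardt refinement of
// the full parameter set. The model per echo time t is
//   m(t) = (W + C * fat(t)) * exp(-r2s * t) * exp(-i * 2*pi * phi * t)
// with complex water/fat amplitudes W, C, fat(t) the spectral modulation of
// the multi-peak fat model, t in seconds, r2s in 1/s and phi in Hz.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const std::complex<double> I_C(0.0, 1.0);

// One Levenberg-Marquardt pass on (Re W, Im W, Re C, Im C, r2s, phi).
static void lm_refine(const cx_vec& s, const vec& t, const cx_vec& fatmod,
                      std::complex<double>& W, std::complex<double>& C,
                      double& r2s, double& phi,
                      double r2s_min, double r2s_max,
                      double phi_min, double phi_max,
                      int max_iter, double tol,
                      double& cost, bool& conv, int& iters) {
  const uword ne = s.n_elem;
  auto model = [&](std::complex<double> Wv, std::complex<double> Cv,
                   double r2, double ph, cx_vec& m) {
    for (uword i = 0; i < ne; ++i) {
      std::complex<double> E =
        std::exp(-r2 * t(i)) * std::exp(-I_C * (2.0 * M_PI * ph * t(i)));
      m(i) = (Wv + Cv * fatmod(i)) * E;
    }
  };
  cx_vec m(ne), r(ne);
  model(W, C, r2s, phi, m);
  r = s - m;
  cost = std::real(cdot(r, r));
  double mu = 1e-3;
  double last_improve = std::numeric_limits<double>::infinity();
  conv = false;
  iters = 0;
  cx_mat J(ne, 6);
  for (int it = 0; it < max_iter; ++it) {
    ++iters;
    for (uword i = 0; i < ne; ++i) {
      std::complex<double> E =
        std::exp(-r2s * t(i)) * std::exp(-I_C * (2.0 * M_PI * phi * t(i)));
      J(i, 0) = E;
      J(i, 1) = I_C * E;
      J(i, 2) = fatmod(i) * E;
      J(i, 3) = I_C * fatmod(i) * E;
      J(i, 4) = -t(i) * m(i);
      J(i, 5) = -I_C * (2.0 * M_PI * t(i)) * m(i);
    }
    mat A = real(J.t() * J);           // normal equations over stacked Re/Im
    vec g = real(J.t() * r);
    bool stepped = false;
    for (int tries = 0; tries < 10; ++tries) {
      mat Ad = A;
      Ad.diag() += mu * A.diag() + 1e-14;
      vec delta;
      if (!solve(delta, Ad, g, solve_opts::fast)) { mu *= 10; continue; }
      std::complex<double> Wn = W + std::complex<double>(delta(0), delta(1));
      std::complex<double> Cn = C + std::complex<double>(delta(2), delta(3));
      double r2n = std::min(std::max(r2s + delta(4), r2s_min), r2s_max);
      double phn = std::min(std::max(phi + delta(5), phi_min), phi_max);
      cx_vec mn(ne);
      model(Wn, Cn, r2n, phn, mn);
      cx_vec rn = s - mn;
      double cn = std::real(cdot(rn, rn));
      if (cn <= cost) {
        const double dc = cost - cn;
        W = Wn; C = Cn; r2s = r2n; phi = phn; m = mn; r = rn;
        const bool done = dc <= tol * std::max(cost, 1e-30);
        last_improve = dc;
        cost = cn;
        mu = std::max(mu / 3.0, 1e-12);
        stepped = true;
        if (done) { conv = true; return; }
        break;
      }
      mu *= 5.0;
    }
    if (!stepped) { conv = true; return; }    // stuck in a flat minimum
  }
  // iteration budget exhausted: still call it converged if the last
  // accepted step barely moved the cost (slow tail of LM descent)
  conv = last_improve <= 1e-6 * std::max(cost, 1e-30);
}

// Solve the 2x2 variable-projection amplitudes at (r2s, phi) and return
// the refined candidate.
static void refine_from(const cx_vec& s, const vec& t, const cx_vec& fatmod,
                        double r2s0, double phi0,
                        double r2s_min, double r2s_max,
                        double phi_min, double phi_max,
                        int max_iter, double tol,
                        std::complex<double>& W, std::complex<double>& C,
                        double& r2s, double& phi,
                        double& cost, bool& conv, int& iters) {
  const uword ne = s.n_elem;
  cx_vec b1(ne), b2(ne);
  for (uword i = 0; i < ne; ++i) {
    b1(i) = std::exp(-r2s0 * t(i)) *
            std::exp(-I_C * (2.0 * M_PI * phi0 * t(i)));
    b2(i) = fatmod(i) * b1(i);
  }
  cx_mat G2(2, 2);
  G2(0, 0) = cdot(b1, b1); G2(0, 1) = cdot(b1, b2);
  G2(1, 0) = cdot(b2, b1); G2(1, 1) = cdot(b2, b2);
  cx_vec rhs(2);
  rhs(0) = cdot(b1, s); rhs(1) = cdot(b2, s);
  cx_vec coef;
  if (!solve(coef, G2, rhs)) coef = cx_vec(2, fill::zeros);
  W = coef(0); C = coef(1);
  r2s = std::min(std::max(r2s0, r2s_min), r2s_max);
  phi = std::min(std::max(phi0, phi_min), phi_max);
  lm_refine(s, t, fatmod, W, C, r2s, phi, r2s_min, r2s_max,
            phi_min, phi_max, max_iter, tol, cost, conv, iters);
}

// Fit every column of S (ne x N). The (phi, r2s) grid search uses
// projection onto the orthonormalized two-column basis of each node; the
// winning node is refined by Levenberg-Marquardt, and the fat-water
// exchange ambiguity is resolved by also refining the mirrored candidates
// with the field offset shifted by +/- the dominant fat frequency
// (`dphi_swap`, Hz) and keeping the lowest-residual solution.
// [[Rcpp::export]]
Rcpp::List fit_dixon_cpp(const arma::cx_mat& S, const arma::vec& t,
                         const arma::cx_vec& fatmod,
                         const arma::vec& phi_grid, const arma::vec& r2s_grid,
                         double r2s_min, double r2s_max,
                         double dphi_swap = 0.0,
                         double phi_min = -1e9, double phi_max = 1e9,
                         int max_iter = 100, double tol = 1e-9,
                         int block = 2048) {
  const uword ne = S.n_rows, N = S.n_cols;
  const uword K = phi_grid.n_elem * r2s_grid.n_elem;
  cx_mat Q1(ne, K), Q2(ne, K), B1(ne, K), B2(ne, K);
  vec node_phi(K), node_r2s(K);
  uword k = 0;
  for (uword a = 0; a < r2s_grid.n_elem; ++a) {
    for (uword b = 0; b < phi_grid.n_elem; ++b, ++k) {
      const double r2 = r2s_grid(a), ph = phi_grid(b);
      cx_vec b1(ne), b2(ne);
      for (uword i = 0; i < ne; ++i) {
        b1(i) = std::exp(-r2 * t(i)) *
                std::exp(-I_C * (2.0 * M_PI * ph * t(i)));
        b2(i) = fatmod(i) * b1(i);
      }
      B1.col(k) = b1; B2.col(k) = b2;
      cx_vec q1 = b1 / norm(b1);
      cx_vec q2 = b2 - q1 * cdot(q1, b2);
      const double n2 = norm(q2);
      q2 = (n2 > 1e-12) ? cx_vec(q2 / n2) : cx_vec(ne, fill::zeros);
      Q1.col(k) = q1; Q2.col(k) = q2;
      node_phi(k) = ph; node_r2s(k) = r2;
    }
  }

  vec out_wr(N), out_wi(N), out_cr(N), out_ci(N), out_r2s(N), out_phi(N),
      out_res(N);
  ivec out_iter(N), out_conv(N);

  for (uword lo = 0; lo < N; lo += (uword)block) {
    const uword hi = std::min(N, lo + (uword)block);
    cx_mat Sb = S.cols(lo, hi - 1);
    mat energy = square(abs(Q1.t() * Sb)) + square(abs(Q2.t() * Sb));
    for (uword c = 0; c < Sb.n_cols; ++c) {
      const uword v = lo + c;
      cx_vec s = Sb.col(c);
      const double snorm2 = std::real(cdot(s, s));
      if (snorm2 <= 0) {
        out_wr(v) = out_wi(v) = out_cr(v) = out_ci(v) = 0.0;
        out_r2s(v) = 0.0; out_phi(v) = 0.0; out_res(v) = 0.0;
        out_iter(v) = 0; out_conv(v) = 0;
        continue;
      }
      const uword kb = energy.col(c).index_max();
      std::complex<double> W, C;
      double r2, ph, cost;
      bool conv; int iters;
      refine_from(s, t, fatmod, node_r2s(kb), node_phi(kb),
                  r2s_min, r2s_max, phi_min, phi_max, max_iter, tol,
                  W, C, r2, ph, cost, conv, iters);
      if (dphi_swap != 0.0) {
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          std::complex<double> Wa, Ca;
          double r2a, pha, costa;
          bool conva; int itersa;
          refine_from(s, t, fatmod, r2, ph + sgn * dphi_swap,
                      r2s_min, r2s_max, phi_min, phi_max, max_iter, tol,
                      Wa, Ca, r2a, pha, costa, conva, itersa);
          if (costa < cost) {
            W = Wa; C = Ca; r2 = r2a; ph = pha;
            cost = costa; conv = conva; iters += itersa;
          }
        }
      }
      out_wr(v) = W.real(); out_wi(v) = W.imag();
      out_cr(v) = C.real(); out_ci(v) = C.imag();
      out_r2s(v) = r2; out_phi(v) = ph;
      out_res(v) = std::sqrt(std::max(cost, 0.0));
      out_iter(v) = iters; out_conv(v) = conv ? 1 : 0;
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("wr") = out_wr, Rcpp::Named("wi") = out_wi,
    Rcpp::Named("cr") = out_cr, Rcpp::Named("ci") = out_ci,
    Rcpp::Named("r2s") = out_r2s, Rcpp::Named("phi") = out_phi,
    Rcpp::Named("residual") = out_res, Rcpp::Named("iterations") = out_iter,
    Rcpp::Named("converged") = out_conv);
}
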