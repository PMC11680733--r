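// Per-patch hot loops for the two locally low-rank denoisers. The R level
// owns patch bookkeeping (extract_patches); these cores receive the
// voxel-by-column source matrix plus the patch index matrix and return the
// average-aggregated result. Pure-R reference implementations of the same
// per-patch math (sure_svt, mp_noise_fit, optimal_shrink) are tested for
// agreement with these loops.
#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
#define FCONE
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// SURE for singular-value soft thresholding at threshold `lambda`;
// `complex_data` selects the divergence constants (the identity
// div(f=id) = #real coordinates fixes them: diagonal weight 2|m-n|+1 and
// cross factor 4 for complex, |m-n| and 2 for real).
static double sure_risk(const vec& d, double m, double n, double sigma,
                        double lambda, bool complex_data) {
  const double mm = std::max(m, n), nn = std::min(m, n);
  const double diagw  = complex_data ? 2.0 * (mm - nn) + 1.0 : (mm - nn);
  const double crossf = complex_data ? 4.0 : 2.0;
  const double ncoord = complex_data ? 2.0 * mm * nn : mm * nn;
  double resid = 0.0, div = 0.0;
  const uword k = d.n_elem;
  for (uword i = 0; i < k; ++i) {
    const double di = d(i);
    const double lo = std::min(di, lambda);
    resid += lo * lo;
    if (di > lambda) {
      div += 1.0;
      if (di > 0) div += diagw * (di - lambda) / di;
      double cross = 0.0;
      for (uword j = 0; j < k; ++j) {
        if (j == i) continue;
        double dif = di * di - d(j) * d(j);
        if (std::abs(dif) < 1e-300) dif = (dif < 0) ? -1e-300 : 1e-300;
        cross += di * (di - lambda) / dif;
      }
      div += crossf * cross;
    }
  }
  return -ncoord * sigma * sigma + resid + 2.0 * sigma * sigma * div;
}

// Minimizing threshold over candidates {0, d_i}.
static double sure_threshold(const vec& d, double m, double n, double sigma) {
  double best_l = 0.0;
  double best_r = sure_risk(d, m, n, sigma, 0.0, true);
  for (uword i = 0; i < d.n_elem; ++i) {
    double r = sure_risk(d, m, n, sigma, d(i), true);
    if (r < best_r) { best_r = r; best_l = d(i); }
  }
  return best_l;
}

// RLLR: complex [p x ne] patches, noise from smallest singular value vs the
// calibrated pure-noise median, SURE-optimal soft thresholding.
// [[Rcpp::export]]
Rcpp::List rllr_core_cpp(const arma::cx_mat& V, const Rcpp::IntegerMatrix idx,
                         double lambda_m, double sigma_s,
                         const Rcpp::Nullable<Rcpp::LogicalVector> process =
                           R_NilValue) {
  const uword p = idx.nrow(), npatch = idx.ncol();
  const uword nvox = V.n_rows, ne = V.n_cols;
  Rcpp::LogicalVector proc = process.isNotNull()
    ? Rcpp::LogicalVector(process)
    : Rcpp::LogicalVector(npatch, true);
  if ((uword)proc.size() != npatch) Rcpp::stop("`process` length mismatch");
  cx_mat out(nvox, ne, fill::zeros);
  vec cnt(nvox, fill::zeros), sig_acc(nvox, fill::zeros);
  vec sigma_patch(npatch, fill::zeros);

  cx_mat M(p, ne), U, W, Md;
  vec s;
  for (uword k = 0; k < npatch; ++k) {
    if (!proc[k]) continue;
    for (uword c = 0; c < ne; ++c)
      for (uword r = 0; r < p; ++r)
        M(r, c) = V(idx(r, k), c);
    if (!svd_econ(U, s, W, M)) Rcpp::stop("SVD failed in RLLR core");
    const double smin = s(s.n_elem - 1);
    const double sigma_hat = smin / lambda_m * sigma_s;
    sigma_patch(k) = sigma_hat;
    double lam = (sigma_hat > 0) ? sure_threshold(s, (double)p, (double)ne,
                                                  sigma_hat) : 0.0;
    vec snew = s - lam;
    snew.transform([](double v) { return v > 0 ? v : 0.0; });
    Md = U * diagmat(snew) * W.t();
    for (uword r = 0; r < p; ++r) {
      const uword v = idx(r, k);
      out.row(v) += Md.row(r);
      cnt(v) += 1.0;
      sig_acc(v) += sigma_hat;
    }
  }
  for (uword v = 0; v < nvox; ++v) {
    if (cnt(v) > 0) {
      out.row(v) /= cnt(v);
      sig_acc(v) /= cnt(v);
    } else {
      out.row(v) = V.row(v);
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("count") = cnt,
                            Rcpp::Named("sigma_map") = sig_acc,
                            Rcpp::Named("sigma_patch") = sigma_patch);
}

// Marchenko-Pastur noise fit on the eigenvalues (descending) of
// (1/qm) X X^T: trim top eigenvalues until the remainder's spread fits the
// MP bulk width for the trimmed aspect ratio, with a Tracy-Widom-scale
// finite-size allowance 1.5 * pm^(-2/3) on the width.
static void mp_fit(const vec& ev_desc, uword pm, uword qm,
                   double& sigma2, int& rank_hat) {
  const double slack = 1.0 + 1.5 * std::pow((double)pm, -2.0 / 3.0);
  rank_hat = (int)pm - 1;
  sigma2 = ev_desc(pm - 1);
  for (uword r = 0; r + 2 <= pm; ++r) {
    double s2 = 0.0;
    for (uword i = r; i < pm; ++i) s2 += ev_desc(i);
    s2 /= (double)(pm - r);
    const double gam = (double)(pm - r) / (double)qm;
    if ((ev_desc(r) - ev_desc(pm - 1)) <= 4.0 * std::sqrt(gam) * s2 * slack) {
      rank_hat = (int)r;
      sigma2 = s2;
      break;
    }
  }
  if (sigma2 < 0) sigma2 = 0;
}

// All eigenvalues (ascending) of the symmetric pm x pm matrix G via
// LAPACK dsyevr; G is passed by value-copy in `a` and destroyed.
static void eigvals_syevr(std::vector<double>& a, int n, double* w,
                          std::vector<double>& work,
                          std::vector<int>& iwork) {
  int m, info, lwork = (int)work.size(), liwork = (int)iwork.size();
  double vl = 0, vu = 0, abstol = 0;
  int il = 1, iu = n, isuppz_dummy[2];
  F77_CALL(dsyevr)("N", "A", "U", &n, a.data(), &n, &vl, &vu, &il, &iu,
                   &abstol, &m, w, (double*)NULL, &n, isuppz_dummy,
                   work.data(), &lwork, iwork.data(), &liwork,
                   &info FCONE FCONE FCONE);
  if (info != 0) Rcpp::stop("dsyevr (values) failed");
}

// Top `k` eigenpairs (ascending among themselves) of G.
static void eigtop_syevr(std::vector<double>& a, int n, int k, double* w,
                         double* z, std::vector<double>& work,
                         std::vector<int>& iwork,
                         std::vector<int>& isuppz) {
  int m, info, lwork = (int)work.size(), liwork = (int)iwork.size();
  double vl = 0, vu = 0, abstol = 0;
  int il = n - k + 1, iu = n;
  F77_CALL(dsyevr)("V", "I", "U", &n, a.data(), &n, &vl, &vu, &il, &iu,
                   &abstol, &m, w, z, &n, isuppz.data(),
                   work.data(), &lwork, iwork.data(), &liwork,
                   &info FCONE FCONE FCONE);
  if (info != 0 || m < k) Rcpp::stop("dsyevr (vectors) failed");
}

// RMT: real [p x 2*ne*nc] patches, MP noise estimation, optimal Frobenius
// shrinkage, reconstruction through the top eigenvectors of the small
// Gram matrix. `process` (optional) marks the patches to denoise; voxels
// covered by no processed patch pass through unchanged.
// [[Rcpp::export]]
Rcpp::List rmt_core_cpp(const arma::mat& V, const Rcpp::IntegerMatrix idx,
                        const Rcpp::Nullable<Rcpp::LogicalVector> process =
                          R_NilValue) {
  const uword p = idx.nrow(), npatch = idx.ncol();
  const uword nvox = V.n_rows, q = V.n_cols;
  const bool flip = p > q;             // orient so pm <= qm
  const int pm = (int)std::min(p, q);
  const uword qm = std::max(p, q);
  const double beta = (double)pm / (double)qm;
  const double edge_u = 1.0 + std::sqrt(beta);
  Rcpp::LogicalVector proc = process.isNotNull()
    ? Rcpp::LogicalVector(process)
    : Rcpp::LogicalVector(npatch, true);
  if ((uword)proc.size() != npatch) Rcpp::stop("`process` length mismatch");

  mat out(nvox, q, fill::zeros);
  vec cnt(nvox, fill::zeros), sig_acc(nvox, fill::zeros),
      rank_acc(nvox, fill::zeros);
  vec sigma_patch(npatch, fill::zeros);
  ivec rank_patch(npatch, fill::zeros);

  mat X(p, q);
  std::vector<double> G((size_t)pm * pm), A((size_t)pm * pm),
      w((size_t)pm), wtop((size_t)pm), Z((size_t)pm * pm);
  // workspace query
  std::vector<double> work(1);
  std::vector<int> iwork(1), isuppz(2 * (size_t)pm);
  {
    int n = pm, m, info, lwork = -1, liwork = -1, il = 1, iu = pm,
        isz[2];
    double vl = 0, vu = 0, abstol = 0, wk;
    int iwk;
    F77_CALL(dsyevr)("V", "A", "U", &n, A.data(), &n, &vl, &vu, &il, &iu,
                     &abstol, &m, w.data(), Z.data(), &n, isz,
                     &wk, &lwork, &iwk, &liwork, &info FCONE FCONE FCONE);
    work.resize((size_t)std::max(wk, 26.0 * pm));
    iwork.resize((size_t)std::max(iwk, 10 * pm));
  }
  const double inv_qm = 1.0 / (double)qm;
  const int qm_i = (int)qm;

  for (uword k = 0; k < npatch; ++k) {
    if (!proc[k]) continue;
    for (uword c = 0; c < q; ++c)
      for (uword r = 0; r < p; ++r)
        X(r, c) = V(idx(r, k), c);
    // Gram of the oriented matrix: G = Xo Xo^T / qm (pm x pm, upper)
    {
      const double zero = 0.0;
      int n = pm;
      F77_CALL(dsyrk)("U", flip ? "T" : "N", &n, &qm_i, &inv_qm,
                      X.memptr(), flip ? &qm_i : &n, &zero, G.data(),
                      &n FCONE FCONE);
    }
    A = G;
    eigvals_syevr(A, pm, w.data(), work, iwork);
    vec ev_desc(pm);
    for (int i = 0; i < pm; ++i) ev_desc(i) = w[(size_t)(pm - 1 - i)];
    double sigma2; int rank_hat;
    mp_fit(ev_desc, (uword)pm, qm, sigma2, rank_hat);
    const double sigma = std::sqrt(std::max(sigma2, 0.0));
    sigma_patch(k) = sigma;
    rank_patch(k) = rank_hat;

    // shrink: data singular values s_i = sqrt(ev * qm); components above
    // the bulk edge sigma*sqrt(qm)*(1+sqrt(beta)) survive.
    mat Xd;
    bool copy_input = false;
    if (sigma > 0) {
      const double scale = sigma * std::sqrt((double)qm);
      int nkeep = 0;
      vec wshr(pm, fill::zeros);              // eta_i / s_i, descending order
      for (int i = 0; i < pm; ++i) {
        const double s_i = std::sqrt(std::max(ev_desc(i), 0.0) * (double)qm);
        const double x = s_i / scale;
        if (x > edge_u) {
          const double t2 = (x * x - beta - 1.0);
          const double eta = std::sqrt(std::max(t2 * t2 - 4.0 * beta, 0.0)) / x;
          wshr(i) = (s_i > 0) ? (eta * scale) / s_i : 0.0;
          ++nkeep;
        } else break;                         // rest are inside the bulk
      }
      if (nkeep > 0) {
        A = G;
        eigtop_syevr(A, pm, nkeep, wtop.data(), Z.data(), work, iwork,
                     isuppz);
        mat Ur(Z.data(), pm, nkeep, false, true); // ascending within block
        mat Xo = flip ? X.t() : X;
        mat B = Ur.t() * Xo;                  // nkeep x qm
        for (int i = 0; i < nkeep; ++i) B.row(i) *= wshr(nkeep - 1 - i);
        mat Xdo = Ur * B;
        Xd = flip ? Xdo.t() : Xdo;
      } else {
        Xd.zeros(p, q);
      }
    } else {
      copy_input = true;                      // no measurable noise
    }
    for (uword r = 0; r < p; ++r) {
      const uword v = idx(r, k);
      if (copy_input) out.row(v) += V.row(v);
      else out.row(v) += Xd.row(r);
      cnt(v) += 1.0;
      sig_acc(v) += sigma;
      rank_acc(v) += (double)rank_hat;
    }
  }
  for (uword v = 0; v < nvox; ++v) {
    if (cnt(v) > 0) {
      out.row(v) /= cnt(v);
      sig_acc(v) /= cnt(v);
      rank_acc(v) /= cnt(v);
    } else {
      out.row(v) = V.row(v);
    }
  }
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("count") = cnt,
                            Rcpp::Named("sigma_map") = sig_acc,
                            Rcpp::Named("rank_map") = rank_acc,
                            Rcpp::Named("sigma_patch") = sigma_patch,
                            Rcpp::Named("rank_patch") = rank_patch);
}
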