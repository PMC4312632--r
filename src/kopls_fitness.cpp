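// Fast path for the GA fitness: balanced prediction error of a
// kernel-OPLS classifier restricted to a feature mask. Mirrors the R
// implementation (kopls_fit + predict + balanced_error) exactly; the test
// suite asserts agreement between the two paths.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// median pairwise Euclidean distance (upper triangle of the squared-
// distance matrix); matches stats::median(stats::dist(x))
static double median_distance(const mat& d2) {
  const uword n = d2.n_rows;
  std::vector<double> v;
  v.reserve(n * (n - 1) / 2);
  for (uword j = 0; j < n; ++j)
    for (uword i = j + 1; i < n; ++i) v.push_back(std::sqrt(d2(i, j)));
  if (v.empty()) return 1.0;
  const size_t h = v.size() / 2;
  std::nth_element(v.begin(), v.begin() + h, v.end());
  double m = v[h];
  if (v.size() % 2 == 0) {
    double lo = *std::max_element(v.begin(), v.begin() + h);
    m = 0.5 * (m + lo);
  }
  return (std::isfinite(m) && m > 0) ? m : 1.0;
}

// squared distances: -2 a b' + ||a||^2 + ||b||^2, clamped at zero
static mat sq_dists(const mat& a, const mat& b, const vec& sa, const vec& sb) {
  mat d2 = a * b.t();
  d2 *= -2.0;
  d2.each_col() += sa;
  d2.each_row() += sb.t();
  d2.clamp(0.0, datum::inf);
  return d2;
}

// in-place K -= u v' (rank-one update without a temporary)
static inline void sub_outer(mat& k, const vec& u, const vec& v) {
  const uword nr = k.n_rows, nc = k.n_cols;
  double* kp = k.memptr();
  const double* up = u.memptr();
  for (uword j = 0; j < nc; ++j) {
    const double vj = v(j);
    double* col = kp + j * nr;
    for (uword i = 0; i < nr; ++i) col[i] -= up[i] * vj;
  }
}

// in-place symmetric K -= to b' + b to' - xv to to'
static inline void sub_sym_update(mat& k, const vec& to, const vec& b,
                                  double xv) {
  const uword n = k.n_rows;
  double* kp = k.memptr();
  const double* tp = to.memptr();
  const double* bp = b.memptr();
  for (uword j = 0; j < n; ++j) {
    const double tj = tp[j], bj = bp[j];
    double* col = kp + j * n;
    for (uword i = 0; i < n; ++i)
      col[i] -= tp[i] * bj + bp[i] * tj - xv * tp[i] * tj;
  }
}

// core fit + predict on centred kernels; returns pooled confusion counts
// (tp, fn, tn, fp) via the out parameters
static void kopls_fit_predict_counts(const mat& kc, const vec& yc,
                                     double ym, const mat& ktec,
                                     const vec& yte, int ao,
                                     uword& tpos, uword& fneg, uword& tneg,
                                     uword& fpos, bool& ok) {
  ok = false;
  const double s = as_scalar(yc.t() * (kc * yc));
  if (!std::isfinite(s) || s <= 0) return;
  const vec u = yc / std::sqrt(s);
  mat ki1 = kc, kii;
  mat kte1 = ktec, ktei;
  bool copied = false;
  for (int i = 0; i < ao; ++i) {
    if (!copied) { kii = kc; ktei = ktec; copied = true; }
    const vec t = ki1 * u;
    const double tt = dot(t, t);
    vec to = kii * t / tt - t;
    const double ton = norm(to);
    if (!(ton > 1e-12)) break;
    to /= ton;
    const vec a = ki1.t() * to;
    const vec b = kii * to;
    const double xv = dot(to, b);
    const vec tte = kte1 * u;
    const vec tote = (ktei * t / tt - tte) / ton;
    sub_outer(ki1, to, a);
    sub_sym_update(kii, to, b, xv);
    sub_outer(kte1, tote, a);
    sub_outer(ktei, tote, b);
    const vec mto = ktei * to;
    sub_outer(ktei, mto, to);
  }
  const vec tp = ki1 * u;
  const double c = dot(yc, tp) / dot(tp, tp);
  const vec yhat = c * (kte1 * u) + ym;
  for (uword i = 0; i < yte.n_elem; ++i) {
    const bool pred1 = yhat(i) >= 0.5;
    if (yte(i) == 1) {
      if (pred1) ++tpos; else ++fneg;
    } else {
      if (pred1) ++fpos; else ++tneg;
    }
  }
  ok = true;
}

// Pooled k-fold cross-validated balanced error of the masked kernel-OPLS
// classifier. fold_ids are 1-based fold labels of the training rows; the
// masked kernel matrix is computed once and sliced per fold.
// [[Rcpp::export(name = ".kopls_cv_mask_error_cpp")]]
double kopls_cv_mask_error_cpp(const arma::mat& x, const arma::vec& y,
                               const arma::ivec& fold_ids,
                               const arma::uvec& mask_idx, double sigma,
                               int ao) {
  if (mask_idx.n_elem == 0) return 1.0;
  const mat xa = x.cols(mask_idx);
  const uword n = xa.n_rows;
  const vec sa = sum(square(xa), 1);
  mat k = sq_dists(xa, xa, sa, sa);
  k.diag().zeros();
  double sg = sigma;
  if (!(sg > 0)) sg = median_distance(k);
  const double inv = 1.0 / (2.0 * sg * sg);
  {
    double* kp = k.memptr();
    for (uword j = 0; j < n; ++j) {
      kp[j * n + j] = 1.0;
      for (uword i = j + 1; i < n; ++i) {
        const double e = std::exp(-kp[j * n + i] * inv);
        kp[j * n + i] = e;
        kp[i * n + j] = e;
      }
    }
  }
  const int n_folds = fold_ids.max();
  uword tpos = 0, fneg = 0, tneg = 0, fpos = 0;
  for (int f = 1; f <= n_folds; ++f) {
    const uvec tr = find(fold_ids != f);
    const uvec te = find(fold_ids == f);
    if (tr.n_elem == 0 || te.n_elem == 0) continue;
    mat ktr = k.submat(tr, tr);
    mat kte = k.submat(te, tr);
    const vec ytr_f = y.elem(tr);
    const vec yte_f = y.elem(te);
    // centre with the fold-training statistics
    rowvec cm = mean(ktr, 0);
    const double grand = mean(cm);
    ktr.each_row() -= cm;
    ktr.each_col() -= vec(mean(ktr, 1));
    vec rte = mean(kte, 1);
    kte.each_row() -= cm;
    kte.each_col() -= (rte - grand);
    const double ym = mean(ytr_f);
    const vec yc = ytr_f - ym;
    if (norm(yc) == 0) return 1.0;
    bool ok = false;
    kopls_fit_predict_counts(ktr, yc, ym, kte, yte_f, ao,
                             tpos, fneg, tneg, fpos, ok);
    if (!ok) return 1.0;
  }
  if (tpos + fneg == 0 || tneg + fpos == 0) return 1.0;
  const double sens = double(tpos) / double(tpos + fneg);
  const double spec = double(tneg) / double(tneg + fpos);
  return 1.0 - 0.5 * (sens + spec);
}

// [[Rcpp::export(name = ".kopls_mask_error_cpp")]]
double kopls_mask_error_cpp(const arma::mat& xtr, const arma::vec& ytr,
                            const arma::mat& xte, const arma::vec& yte,
                            const arma::uvec& mask_idx, double sigma,
                            int ao) {
  if (mask_idx.n_elem == 0) return 1.0;
  const mat xa = xtr.cols(mask_idx);
  const mat xb = xte.cols(mask_idx);
  const uword n = xa.n_rows, nt = xb.n_rows;
  const vec sa = sum(square(xa), 1);
  const vec sb = sum(square(xb), 1);

  mat k = sq_dists(xa, xa, sa, sa); // squared distances, then kernel in place
  k.diag().zeros();
  double sg = sigma;
  if (!(sg > 0)) sg = median_distance(k);
  const double inv = 1.0 / (2.0 * sg * sg);
  { // exp over one triangle, mirrored
    double* kp = k.memptr();
    for (uword j = 0; j < n; ++j) {
      kp[j * n + j] = 1.0;
      for (uword i = j + 1; i < n; ++i) {
        const double e = std::exp(-kp[j * n + i] * inv);
        kp[j * n + i] = e;
        kp[i * n + j] = e;
      }
    }
  }
  mat kte = sq_dists(xb, xa, sb, sa);
  kte.transform([inv](double d) { return std::exp(-d * inv); });

  // double-center the training kernel; center the cross kernel with the
  // training statistics (K - 1c' - r1' + grand, done in two sweeps)
  rowvec cm = mean(k, 0);
  const double grand = mean(cm);
  k.each_row() -= cm;
  k.each_col() -= vec(mean(k, 1));
  vec rte = mean(kte, 1);
  kte.each_row() -= cm;
  kte.each_col() -= (rte - grand);

  const double ym = mean(ytr);
  vec yc = ytr - ym;
  if (norm(yc) == 0) return 1.0;
  const double s = as_scalar(yc.t() * (k * yc));
  if (!std::isfinite(s) || s <= 0) return 1.0;
  const vec u = yc / std::sqrt(s);

  mat ki1 = k, kii;
  mat kte1 = kte, ktei;
  bool deflated = false; // kii/ktei copied lazily, only when ao > 0
  for (int i = 0; i < ao; ++i) {
    if (!deflated) {
      kii = k;
      ktei = kte;
      deflated = true;
    }
    const vec t = ki1 * u;
    const double tt = dot(t, t);
    vec to = kii * t / tt - t;
    const double ton = norm(to);
    if (!(ton > 1e-12)) break;
    to /= ton;
    const vec a = ki1.t() * to;
    const vec b = kii * to;
    const double xv = dot(to, b);
    const vec tte = kte1 * u;
    const vec tote = (ktei * t / tt - tte) / ton;
    sub_outer(ki1, to, a);
    sub_sym_update(kii, to, b, xv);
    sub_outer(kte1, tote, a);
    sub_outer(ktei, tote, b);       // M = ktei - tote b'
    const vec mto = ktei * to;      // then M - (M to) to'
    sub_outer(ktei, mto, to);
  }
  const vec tp = ki1 * u;
  const double c = dot(yc, tp) / dot(tp, tp);
  const vec yhat = c * (kte1 * u) + ym;

  uword tpos = 0, fneg = 0, tneg = 0, fpos = 0;
  for (uword i = 0; i < nt; ++i) {
    const bool pred1 = yhat(i) >= 0.5;
    if (yte(i) == 1) {
      if (pred1) ++tpos; else ++fneg;
    } else {
      if (pred1) ++fpos; else ++tneg;
    }
  }
  if (tpos + fneg == 0 || tneg + fpos == 0) return 1.0;
  const double sens = double(tpos) / double(tpos + fneg);
  const double spec = double(tneg) / double(tneg + fpos);
  return 1.0 - 0.5 * (sens + spec);
}
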