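// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Kabsch rotation for pre-centered 3-column matrices (sign-corrected SVD,
// reflections excluded).
static arma::mat33 kabsch_rot(const arma::mat &a, const arma::mat &b) {
  arma::mat u, v;
  arma::vec s;
  arma::svd(u, s, v, a.t() * b);
  double d = arma::det(v * u.t()) < 0 ? -1.0 : 1.0;
  arma::mat33 dd = arma::eye(3, 3);
  dd(2, 2) = d;
  return v * dd * u.t();
}

// Superpose every frame of a T x N x 3 coordinate cube onto ref
// (length(mask) x 3) using the atoms in mask (0-based).
// [[Rcpp::export]]
arma::cube align_frames_cpp(const arma::cube &coords,
                            const arma::uvec &mask, const arma::mat &ref) {
  const arma::uword nt = coords.n_rows, n = coords.n_cols;
  arma::cube out(nt, n, 3);
  arma::rowvec ct = arma::mean(ref, 0);
  arma::mat refc = ref.each_row() - ct;
  arma::mat fr(n, 3), sub(mask.n_elem, 3);
  for (arma::uword t = 0; t < nt; ++t) {
    for (arma::uword d = 0; d < 3; ++d)
      for (arma::uword i = 0; i < n; ++i) fr(i, d) = coords(t, i, d);
    sub = fr.rows(mask);
    arma::rowvec cm = arma::mean(sub, 0);
    arma::mat33 r = kabsch_rot(sub.each_row() - cm, refc);
    arma::mat moved = (fr.each_row() - cm) * r.t();
    moved.each_row() += ct;
    for (arma::uword d = 0; d < 3; ++d)
      for (arma::uword i = 0; i < n; ++i) out(t, i, d) = moved(i, d);
  }
  return out;
}

// Fitted RMSD of every frame against ref on mask atoms, straight from the
// singular values of the cross-covariance.
// [[Rcpp::export]]
arma::vec frame_rmsd_cpp(const arma::cube &coords, const arma::uvec &mask,
                         const arma::mat &ref) {
  const arma::uword nt = coords.n_rows, n = coords.n_cols,
                    m = mask.n_elem;
  arma::vec out(nt);
  arma::rowvec ct = arma::mean(ref, 0);
  arma::mat refc = ref.each_row() - ct;
  const double q2 = arma::accu(refc % refc);
  arma::mat sub(m, 3);
  for (arma::uword t = 0; t < nt; ++t) {
    for (arma::uword d = 0; d < 3; ++d)
      for (arma::uword i = 0; i < m; ++i) sub(i, d) = coords(t, mask(i), d);
    arma::rowvec cm = arma::mean(sub, 0);
    sub.each_row() -= cm;
    arma::mat u, v;
    arma::vec s;
    arma::svd(u, s, v, sub.t() * refc);
    double d = arma::det(v * u.t()) < 0 ? -1.0 : 1.0;
    double tr = s(0) + s(1) + d * s(2);
    double val = (arma::accu(sub % sub) + q2 - 2.0 * tr) / (double)m;
    out(t) = std::sqrt(std::max(val, 0.0));
  }
  return out;
}
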