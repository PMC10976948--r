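// Numerical core shared by the wavelength selectors and PLS-DA:
//  - SIMPLS partial least squares (multi-response) with coefficients for
//    every component count in one pass,
//  - fold-based cross-validated RMSE for a univariate PLS regression,
//  - successive-projections chains computed from the Gram matrix, and the
//    incremental Gram-Schmidt least-squares evaluation of a chain.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// SIMPLS (de Jong 1993) on column-centred X and Y. Returns the coefficient
// cube B[, , a] such that Yhat = (X - xmean) * B[, , a] + ymean for a
// components.
static arma::cube simpls_core(const arma::mat& Xc, const arma::mat& Yc,
                              int ncomp) {
  const arma::uword p = Xc.n_cols, m = Yc.n_cols;
  arma::mat S = Xc.t() * Yc;              // p x m cross-product
  arma::mat R(p, ncomp, arma::fill::zeros);
  arma::mat Q(m, ncomp, arma::fill::zeros);
  arma::mat V(p, ncomp, arma::fill::zeros);
  arma::cube B(p, m, ncomp, arma::fill::zeros);
  for (int a = 0; a < ncomp; ++a) {
    arma::vec r;
    if (m == 1) {
      r = S.col(0);
    } else {
      arma::mat U_, V_;
      arma::vec s_;
      arma::svd_econ(U_, s_, V_, S);
      r = U_.col(0);
    }
    arma::vec t = Xc * r;
    double tn = arma::norm(t);
    if (tn < 1e-12) { // rank exhausted: keep earlier coefficients
      for (int b = a; b < ncomp; ++b) B.slice(b) = B.slice(a > 0 ? a - 1 : 0);
      break;
    }
    t /= tn; r /= tn;
    arma::vec pl = Xc.t() * t;
    arma::vec q = Yc.t() * t;
    arma::vec v = pl;
    if (a > 0) {
      arma::mat Va = V.cols(0, a - 1);
      v -= Va * (Va.t() * pl);
    }
    v /= arma::norm(v);
    S -= v * (v.t() * S);
    R.col(a) = r; Q.col(a) = q; V.col(a) = v;
    B.slice(a) = R.cols(0, a) * Q.cols(0, a).t();
  }
  return B;
}

// [[Rcpp::export]]
List simpls_fit_cpp(const arma::mat& X, const arma::mat& Y, int ncomp) {
  arma::rowvec xm = arma::mean(X, 0);
  arma::rowvec ym = arma::mean(Y, 0);
  arma::mat Xc = X.each_row() - xm;
  arma::mat Yc = Y.each_row() - ym;
  ncomp = std::min<int>(ncomp, std::min(X.n_cols, X.n_rows - 1));
  if (ncomp < 1) ncomp = 1;
  arma::cube B = simpls_core(Xc, Yc, ncomp);
  return List::create(_["coef"] = B, _["xmean"] = xm, _["ymean"] = ym,
                      _["ncomp"] = ncomp);
}

// [[Rcpp::export]]
arma::mat simpls_predict_cpp(const arma::mat& Xnew, const arma::cube& B,
                             const arma::rowvec& xmean,
                             const arma::rowvec& ymean, int a) {
  arma::mat Xc = Xnew.each_row() - xmean;
  arma::mat Yh = Xc * B.slice(a - 1);
  Yh.each_row() += ymean;
  return Yh;
}

// Cross-validated RMSE of univariate PLS for component counts 1..ncomp.
// foldid is 1-based; centring is redone inside each training fold.
// [[Rcpp::export]]
arma::vec pls1_cv_rmse_cpp(const arma::mat& X, const arma::vec& y,
                           int ncomp, const arma::ivec& foldid) {
  const int K = foldid.max();
  const arma::uword n = X.n_rows;
  ncomp = std::max(1, ncomp);
  arma::vec sse(ncomp, arma::fill::zeros);
  int used = ncomp;
  for (int k = 1; k <= K; ++k) {
    arma::uvec te = arma::find(foldid == k);
    arma::uvec tr = arma::find(foldid != k);
    arma::mat Xtr = X.rows(tr), Xte = X.rows(te);
    arma::vec ytr = y.elem(tr);
    arma::rowvec xm = arma::mean(Xtr, 0);
    double ym = arma::mean(ytr);
    arma::mat Xc = Xtr.each_row() - xm;
    arma::mat Yc(ytr - ym);
    int nc = std::min<int>(ncomp, std::min(Xtr.n_cols, Xtr.n_rows - 1));
    if (nc < used) used = nc;
    arma::cube B = simpls_core(Xc, Yc, nc);
    arma::mat Xtec = Xte.each_row() - xm;
    for (int a = 0; a < nc; ++a) {
      arma::vec res = Xtec * B.slice(a).col(0) + ym - y.elem(te);
      sse(a) += arma::dot(res, res);
    }
  }
  arma::vec out = arma::sqrt(sse.head(used) / static_cast<double>(n));
  return out;
}

// Successive-projections chain for one start, driven entirely by the Gram
// matrix G = Xc' Xc. Selected columns are orthogonalised implicitly; the
// residual squared norm of every candidate is tracked and the largest one
// is picked next (ties -> lowest index). Returns 0-based indices; the chain
// stops early when every residual drops below tol (collinearity exhausted).
static arma::uvec spa_chain_one(const arma::mat& G, arma::uword start,
                                arma::uword kmax, double tol) {
  const arma::uword p = G.n_cols;
  arma::vec res2 = G.diag();
  std::vector<arma::uword> sel;
  std::vector<arma::vec> acoef;  // coords of orthonormal q_i over sel cols
  arma::uvec chosen(p, arma::fill::zeros);
  arma::uword j = start;
  for (arma::uword step = 0; step < kmax; ++step) {
    if (step > 0) {
      double best = -1.0; arma::uword bidx = p;
      for (arma::uword c = 0; c < p; ++c) {
        if (!chosen(c) && res2(c) > best + 1e-15) { best = res2(c); bidx = c; }
      }
      if (bidx == p || best < tol) break;
      j = bidx;
    } else if (res2(j) < tol) {
      break;
    }
    double r = std::sqrt(std::max(res2(j), 0.0));
    if (r < std::sqrt(tol)) break;
    // coordinates of the new orthonormal direction over selected columns
    arma::uword k = sel.size();
    arma::vec a(k + 1, arma::fill::zeros);
    a(k) = 1.0;
    // c_i(j) = q_i . x_j  for i < k, recomputed from stored coords
    for (arma::uword i = 0; i < k; ++i) {
      double cij = 0.0;
      for (arma::uword t = 0; t <= i; ++t) cij += acoef[i](t) * G(sel[t], j);
      for (arma::uword t = 0; t <= i; ++t) a(t) -= cij * acoef[i](t);
    }
    a /= r;
    sel.push_back(j); chosen(j) = 1;
    acoef.push_back(a);
    // update residual norms: res2 -= (q_k . x_c)^2 for every candidate
    arma::vec c(p, arma::fill::zeros);
    for (arma::uword t = 0; t < sel.size(); ++t) c += a(t) * G.row(sel[t]).t();
    res2 -= arma::square(c);
    res2.elem(arma::find(res2 < 0)).zeros();
  }
  return arma::uvec(sel);
}

// [[Rcpp::export]]
List spa_chains_cpp(const arma::mat& X, int kmax, double tol_rel) {
  arma::mat Xc = X.each_row() - arma::mean(X, 0);
  arma::mat G = Xc.t() * Xc;
  double tol = tol_rel * G.diag().max();
  const arma::uword p = X.n_cols;
  List chains(p);
  for (arma::uword s = 0; s < p; ++s) {
    arma::uvec ch = spa_chain_one(G, s, std::min<arma::uword>(kmax, p), tol);
    chains[s] = IntegerVector(ch.begin(), ch.end()); // 0-based
  }
  return chains;
}

// Validation RMSE of ordinary least squares on the first k chain columns,
// for every k = 1..len(chain), via incremental Gram-Schmidt. chain is
// 0-based. Centring uses training means only.
// [[Rcpp::export]]
arma::vec spa_eval_chain_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                             const arma::mat& Xval, const arma::vec& yval,
                             const arma::ivec& chain) {
  const arma::uword kmax = chain.n_elem;
  const arma::uword n = Xtr.n_rows, nv = Xval.n_rows;
  arma::rowvec xm = arma::mean(Xtr, 0);
  double ym = arma::mean(ytr);
  arma::mat Q(n, kmax, arma::fill::zeros);
  arma::mat Z(nv, kmax, arma::fill::zeros);
  arma::vec yhat(nv, arma::fill::zeros);
  arma::vec out(kmax); out.fill(arma::datum::nan);
  arma::vec yc = ytr - ym;
  for (arma::uword k = 0; k < kmax; ++k) {
    arma::uword j = chain(k);
    arma::vec v = Xtr.col(j) - xm(j);
    arma::vec z = Xval.col(j) - xm(j);
    if (k > 0) {
      arma::vec coef = Q.cols(0, k - 1).t() * (Xtr.col(j) - xm(j));
      v -= Q.cols(0, k - 1) * coef;
      z -= Z.cols(0, k - 1) * coef;
    }
    double nrm = arma::norm(v);
    if (nrm < 1e-10) { // rank deficient from here on: freeze last RMSE
      for (arma::uword kk = k; kk < kmax; ++kk) out(kk) = out(k > 0 ? k - 1 : 0);
      break;
    }
    v /= nrm; z /= nrm;
    Q.col(k) = v; Z.col(k) = z;
    double beta = arma::dot(v, yc);
    yhat += beta * z;
    arma::vec res = yhat + ym - yval;
    out(k) = std::sqrt(arma::dot(res, res) / static_cast<double>(nv));
  }
  return out;
}
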