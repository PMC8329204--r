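#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Per-pixel principal matrix logarithm of a field of 4x4 Mueller matrices.
//
// M16: 16 x N matrix, each column one pixel's 4x4 matrix in column-major
// order.  Returns the realified logarithm, the discarded imaginary
// magnitude, and a per-pixel status code:
//   0  ok
//   2  branch failure: eigenvalue with zero modulus or on the closed
//      negative real axis (principal log undefined), or eig_gen failed
//   3  defective matrix: eigenvector basis numerically singular
//   4  discarded imaginary part exceeded tol_imag
// (code 1, non-positive M00, is assigned upstream in R before pixels
// reach this routine)
// [[Rcpp::export]]
List cpp_field_logm(const arma::mat& M16, const double tol_imag) {
  if (M16.n_rows != 16)
    stop("internal: expected 16 rows (4x4 per pixel)");
  const arma::uword n = M16.n_cols;
  arma::mat L16(16, n, arma::fill::zeros);
  arma::vec resid(n, arma::fill::zeros);
  IntegerVector code(n, 0);

  for (arma::uword j = 0; j < n; ++j) {
    const arma::mat A = arma::reshape(M16.col(j), 4, 4);
    if (!A.is_finite()) { code[j] = 2; continue; }

    arma::cx_vec ev;
    arma::cx_mat V;
    if (!arma::eig_gen(ev, V, A)) { code[j] = 2; continue; }

    bool branch_bad = false;
    for (int k = 0; k < 4; ++k) {
      const std::complex<double> e = ev(k);
      if (std::abs(e) == 0.0 ||
          (e.imag() == 0.0 && e.real() < 0.0)) { branch_bad = true; break; }
    }
    if (branch_bad) { code[j] = 2; continue; }

    arma::cx_mat Vi;
    if (!arma::inv(Vi, V)) { code[j] = 3; continue; }

    const arma::cx_mat Lc = V * arma::diagmat(arma::log(ev)) * Vi;
    const double r = arma::abs(arma::imag(Lc)).max();
    resid(j) = r;
    L16.col(j) = arma::vectorise(arma::real(Lc));
    if (!(r <= tol_imag)) code[j] = 4;
  }

  return List::create(_["L"] = L16,
                      _["imag_residual"] = resid,
                      _["code"] = code);
}

// Per-pixel matrix exponential (Pade/scaling-and-squaring via Armadillo).
// G16: 16 x N generator field, same layout as cpp_field_logm.
// [[Rcpp::export]]
arma::mat cpp_field_expm(const arma::mat& G16) {
  if (G16.n_rows != 16)
    stop("internal: expected 16 rows (4x4 per pixel)");
  const arma::uword n = G16.n_cols;
  arma::mat E16(16, n);
  for (arma::uword j = 0; j < n; ++j) {
    const arma::mat A = arma::reshape(G16.col(j), 4, 4);
    arma::mat E;
    if (!arma::expmat(E, A))
      stop("matrix exponential failed at pixel %d", (int)(j + 1));
    E16.col(j) = arma::vectorise(E);
  }
  return E16;
}
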