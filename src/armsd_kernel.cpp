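// Symmetry-aware ARMSD kernel: minimum over graph automorphisms of the
// heavy-atom RMSD after optimal proper-rotation (Kabsch) superposition.
// The 3x3 SVD route matches the R reference implementation; the kernel
// only exists because ensemble labelling evaluates it millions of times.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double kabsch_rmsd(const mat& A, const mat& B) {
  mat Ac = A.each_row() - mean(A, 0);
  mat Bc = B.each_row() - mean(B, 0);
  mat H = Ac.t() * Bc;
  mat U, V;
  vec s;
  svd(U, s, V, H);
  double d = det(V * U.t());
  mat D = eye(3, 3);
  D(2, 2) = (d < 0) ? -1.0 : 1.0;
  mat R = V * D * U.t();
  mat diff = Ac * R.t() - Bc;
  return std::sqrt(accu(square(diff)) / A.n_rows);
}

// [[Rcpp::export(name = ".cb_armsd_pair_cpp")]]
double cb_armsd_pair(const arma::mat& A, const arma::mat& B,
                     Rcpp::List autos) {
  double best = datum::inf;
  for (int k = 0; k < autos.size(); ++k) {
    uvec sigma = Rcpp::as<uvec>(autos[k]) - 1;
    double r = kabsch_rmsd(A, B.rows(sigma));
    if (r < best) best = r;
    if (best < 1e-9) break;
  }
  return best;
}

// [[Rcpp::export(name = ".cb_armsd_min_cpp")]]
arma::vec cb_armsd_min(Rcpp::List confs, Rcpp::List refs, Rcpp::List autos) {
  const int nc = confs.size();
  const int nr = refs.size();
  std::vector<mat> B(nr);
  for (int j = 0; j < nr; ++j) B[j] = Rcpp::as<mat>(refs[j]);
  std::vector<uvec> sig(autos.size());
  for (int k = 0; k < autos.size(); ++k)
    sig[k] = Rcpp::as<uvec>(autos[k]) - 1;
  vec out(nc);
  for (int i = 0; i < nc; ++i) {
    mat A = Rcpp::as<mat>(confs[i]);
    double best = datum::inf;
    for (int j = 0; j < nr && best >= 1e-9; ++j) {
      for (size_t k = 0; k < sig.size(); ++k) {
        double r = kabsch_rmsd(A, B[j].rows(sig[k]));
        if (r < best) best = r;
        if (best < 1e-9) break;
      }
    }
    out(i) = best;
  }
  return out;
}
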