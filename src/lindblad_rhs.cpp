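#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lindblad right-hand side on the {ground sink + single excitation} space.
//
// rho_vec : (N+1)^2 complex state, column-major.
// B       : H - (i/2) A, with H the (N+1)x(N+1) Hermitian Hamiltonian
//           (zero ground row/column) and A = sum_j L_j^dag L_j the decay
//           matrix embedded in the excited block.  The commutator and
//           anticommutator of the master equation combine exactly into
//           -i (B rho - rho B^dag), evaluated with two matrix products.
// A       : used for the gain term.  Every jump operator maps an excited
//           superposition onto the sink, L_j = sqrt(g_j) |0><v_j|, so
//           sum_j L_j rho L_j^dag = tr(A rho) |0><0|.
// [[Rcpp::export]]
arma::cx_vec lindblad_rhs_cpp(const arma::cx_vec& rho_vec,
                              const arma::cx_mat& B,
                              const arma::cx_mat& A) {
  const uword d = B.n_rows;
  cx_mat rho = reshape(rho_vec, d, d);
  cx_mat drho = cx_double(0.0, -1.0) * (B * rho - rho * B.t());
  drho(0, 0) += accu(A % rho.st());
  return vectorise(drho);
}
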