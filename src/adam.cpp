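#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update over a list of parameter tensors.
//
// Mutates params, m and v directly (single pass per tensor through raw
// pointers, no R-level temporaries); the caller owns these objects
// exclusively during training. alpha and eps_t carry the bias
// corrections already folded in:
// alpha = lr * sqrt(1 - beta2^t) / (1 - beta1^t),
// eps_t = eps * sqrt(1 - beta2^t).
// [[Rcpp::export]]
void adam_update_inplace(List params, List grads, List m, List v,
                         double alpha, double eps_t,
                         double beta1, double beta2) {
  CharacterVector gn = grads.names();
  CharacterVector pn = params.names();
  IntegerVector idx = match(gn, pn);   // 1-based positions in params
  for (int i = 0; i < grads.size(); ++i) {
    int k = idx[i];
    if (k == NA_INTEGER)
      stop("adam_update_inplace: gradient name not found in params");
    SEXP gs = VECTOR_ELT(grads, i);
    SEXP ps = VECTOR_ELT(params, k - 1);
    SEXP ms = VECTOR_ELT(m, k - 1);
    SEXP vs = VECTOR_ELT(v, k - 1);
    R_xlen_t n = XLENGTH(gs);
    if (XLENGTH(ps) != n || XLENGTH(ms) != n || XLENGTH(vs) != n)
      stop("adam_update_inplace: size mismatch");
    const double *g = REAL(gs);
    double *p = REAL(ps);
    double *mi = REAL(ms);
    double *vi = REAL(vs);
    for (R_xlen_t j = 0; j < n; ++j) {
      double gj = g[j];
      double mj = beta1 * mi[j] + (1.0 - beta1) * gj;
      double vj = beta2 * vi[j] + (1.0 - beta2) * gj * gj;
      mi[j] = mj;
      vi[j] = vj;
      p[j] -= alpha * mj / (std::sqrt(vj) + eps_t);
    }
  }
}
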