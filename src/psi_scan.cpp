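#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Expected posterior entropy (bits) after one hypothetical trial at each
// candidate stimulus. `mass` is the current joint posterior flattened
// column-major over the (alpha, beta) grid; `left` holds p("left" | alpha,
// beta, s) for every grid cell and stimulus, cell index fastest. For a
// candidate stimulus s the entropy of the renormalised branch posterior is
// H = log2(S) - T/S with S = sum(m * l) and T = sum(m * l * log2(m * l)),
// and the two branches are weighted by their predictive probabilities S and
// 1 - S (which sum to one because the posterior is normalised).
// [[Rcpp::export(name = ".psi_entropy_scan")]]
NumericVector psi_entropy_scan(NumericVector mass, NumericVector left,
                               int n_stim) {
  const R_xlen_t ncell = mass.size();
  if (left.size() != ncell * (R_xlen_t)n_stim)
    stop("likelihood table does not match the posterior grid");
  NumericVector out(n_stim);
  const double inv_log2 = 1.0 / std::log(2.0);
  for (int s = 0; s < n_stim; ++s) {
    const double *l = &left[(R_xlen_t)s * ncell];
    double sl = 0.0, tl = 0.0, sr = 0.0, tr = 0.0;
    for (R_xlen_t i = 0; i < ncell; ++i) {
      const double m = mass[i];
      if (m <= 0.0) continue;
      const double ul = m * l[i];
      const double ur = m - ul;
      if (ul > 0.0) { sl += ul; tl += ul * std::log(ul) * inv_log2; }
      if (ur > 0.0) { sr += ur; tr += ur * std::log(ur) * inv_log2; }
    }
    double eh = 0.0;
    if (sl > 0.0) eh += sl * (std::log(sl) * inv_log2 - tl / sl);
    if (sr > 0.0) eh += sr * (std::log(sr) * inv_log2 - tr / sr);
    out[s] = eh;
  }
  return out;
}
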