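#include <Rcpp.h>
using namespace Rcpp;

// In-place update helpers for the phantom generator: the volume and label
// arrays are large (tens of millions of voxels) and owned privately by the
// generator, so mutating them by reference avoids a full copy per painted
// object.  Linear indices are passed as doubles (1-based).

// [[Rcpp::export]]
void blend_at_cpp(NumericVector v, const NumericVector& lin,
                  const NumericVector& frac, const double value) {
  const int n = lin.size();
  for (int i = 0; i < n; ++i) {
    const R_xlen_t j = (R_xlen_t)lin[i] - 1;
    v[j] = v[j] * (1.0 - frac[i]) + value * frac[i];
  }
}

// [[Rcpp::export]]
void set_label_at_cpp(IntegerVector lab, const NumericVector& lin,
                      const int value) {
  const int n = lin.size();
  for (int i = 0; i < n; ++i) lab[(R_xlen_t)lin[i] - 1] = value;
}

// [[Rcpp::export]]
bool any_label_at_cpp(const IntegerVector& lab, const NumericVector& lin) {
  const int n = lin.size();
  for (int i = 0; i < n; ++i)
    if (lab[(R_xlen_t)lin[i] - 1] != 0) return true;
  return false;
}
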