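// Length-weighted mean of a step profile over many query regions.
//
// Profile intervals (0-based half-open) must be sorted and non-overlapping
// within a chromosome; queries may fall partially or wholly outside coverage.
// A query whose covered fraction is below `min_cov` yields NA (the missing
// marker); imputation is a policy applied upstream.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector region_means_cpp(NumericVector qstart, NumericVector qend,
                               NumericVector pstart, NumericVector pend,
                               NumericVector pval, double min_cov) {
  const int nq = qstart.size(), np = pstart.size();
  NumericVector out(nq);
  std::vector<double> pend_v(pend.begin(), pend.end());
  for (int i = 0; i < nq; ++i) {
    const double qs = qstart[i], qe = qend[i];
    const double width = qe - qs;
    if (width <= 0) { out[i] = NA_REAL; continue; }
    // first profile interval whose end exceeds the query start
    int k = static_cast<int>(
        std::upper_bound(pend_v.begin(), pend_v.end(), qs) - pend_v.begin());
    double covered = 0.0, wsum = 0.0;
    for (; k < np && pstart[k] < qe; ++k) {
      const double ov = std::min(qe, pend[k]) - std::max(qs, pstart[k]);
      if (ov > 0) {
        covered += ov;
        wsum += ov * pval[k];
      }
    }
    out[i] = (covered / width >= min_cov && covered > 0) ? wsum / covered
                                                         : NA_REAL;
  }
  return out;
}
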