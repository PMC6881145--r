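#include <Rcpp.h>
using namespace Rcpp;

// Scan for dV/dt threshold crossings (central differences) followed within
// `w` samples by a rise of at least `min_rise` mV; returns threshold and
// peak sample indices (1-based). Mirrors the documented detection rule.
// [[Rcpp::export]]
IntegerMatrix detect_crossings_cpp(NumericVector v, double dt,
                                   double dvdt_thresh, double min_rise,
                                   int w) {
  const int n = v.size();
  std::vector<int> thr, pk;
  if (n >= 3) {
    const double lim = dvdt_thresh * 2.0 * dt;
    bool prev_above = false; // dvdt undefined at the first sample
    int last_peak = 0;       // 1-based
    for (int i = 2; i <= n - 1; ++i) {
      bool above = (v[i] - v[i - 2]) >= lim; // dvdt at sample i (1-based)
      if (above && !prev_above && i > last_peak) {
        int seg_end = std::min(n, i + w);
        int j = i;
        double best = v[i - 1];
        for (int k = i; k < seg_end; ++k) { // 0-based k covers samples i..seg_end
          if (v[k] > best) { best = v[k]; j = k + 1; }
        }
        if (best - v[i - 1] >= min_rise) {
          thr.push_back(i);
          pk.push_back(j);
          last_peak = j;
        }
      }
      prev_above = above;
    }
  }
  IntegerMatrix out(thr.size(), 2);
  for (size_t r = 0; r < thr.size(); ++r) {
    out(r, 0) = thr[r];
    out(r, 1) = pk[r];
  }
  return out;
}
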