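#include <Rcpp.h>
using namespace Rcpp;

// Index of the maximum of x over each half-open window [starts[i], ends[i])
// (1-based, end exclusive). First index wins on ties. Returns 1-based indices
// into x; NA when the window is empty.
// [[Rcpp::export]]
IntegerVector window_argmax(NumericVector x, IntegerVector starts,
                            IntegerVector ends, bool find_max) {
  const int k = starts.size();
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) {
    int s = starts[i] - 1, e = ends[i] - 1; // e exclusive, 0-based
    if (s < 0 || e > x.size() || s >= e) {
      out[i] = NA_INTEGER;
      continue;
    }
    int best = s;
    for (int j = s + 1; j < e; ++j) {
      if (find_max ? (x[j] > x[best]) : (x[j] < x[best])) best = j;
    }
    out[i] = best + 1;
  }
  return out;
}

// Maximum of x over each half-open window [starts[i], ends[i]); NaN for
// empty windows.
// [[Rcpp::export]]
NumericVector window_max(NumericVector x, IntegerVector starts,
                         IntegerVector ends) {
  const int k = starts.size();
  NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    int s = starts[i] - 1, e = ends[i] - 1;
    if (s < 0 || e > x.size() || s >= e) {
      out[i] = NA_REAL;
      continue;
    }
    double best = x[s];
    for (int j = s + 1; j < e; ++j)
      if (x[j] > best) best = x[j];
    out[i] = best;
  }
  return out;
}
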