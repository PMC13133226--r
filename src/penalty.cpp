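#include <Rcpp.h>
using namespace Rcpp;

// Range-extension misfit of one section against a composite order.
//
// Events of taxa observed in the section, taken in composite order, must be
// placed on the section's level grid at non-decreasing heights.  A first
// appearance may only be placed at or below its observed height (range
// extended downward), a last appearance at or above (extended upward).  The
// cost of a placement is the summed |placed - observed| height; the DP below
// minimises it in O(events x levels) with a running prefix minimum.

static inline double place_cost(double obs, bool fad, double h) {
  if (fad) {
    if (h > obs) return R_PosInf;
    return obs - h;
  } else {
    if (h < obs) return R_PosInf;
    return h - obs;
  }
}

//' @noRd
// [[Rcpp::export]]
double cpp_section_penalty(NumericVector obs, LogicalVector isfad,
                           NumericVector grid) {
  const int m = obs.size(), L = grid.size();
  if (m == 0) return 0.0;
  std::vector<double> prev(L), cur(L);
  for (int l = 0; l < L; ++l) prev[l] = place_cost(obs[0], isfad[0], grid[l]);
  for (int i = 1; i < m; ++i) {
    double run = R_PosInf;
    for (int l = 0; l < L; ++l) {
      if (prev[l] < run) run = prev[l];
      double c = place_cost(obs[i], isfad[i], grid[l]);
      cur[l] = (run == R_PosInf || c == R_PosInf) ? R_PosInf : run + c;
    }
    std::swap(prev, cur);
  }
  double best = R_PosInf;
  for (int l = 0; l < L; ++l) if (prev[l] < best) best = prev[l];
  if (best == R_PosInf) return -1.0;  // no monotone placement exists
  return best;
}

// Placement witness: optimal placed heights, ties broken toward the smaller
// placed height (both in the prefix argmin and in the final level choice).
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_section_placement(NumericVector obs, LogicalVector isfad,
                                    NumericVector grid) {
  const int m = obs.size(), L = grid.size();
  NumericVector placed(m);
  if (m == 0) return placed;
  NumericMatrix C(m, L);
  IntegerMatrix argprev(m, L);
  for (int l = 0; l < L; ++l) C(0, l) = place_cost(obs[0], isfad[0], grid[l]);
  for (int i = 1; i < m; ++i) {
    double run = R_PosInf;
    int arg = -1;
    for (int l = 0; l < L; ++l) {
      if (C(i - 1, l) < run) { run = C(i - 1, l); arg = l; }
      double c = place_cost(obs[i], isfad[i], grid[l]);
      C(i, l) = (run == R_PosInf || c == R_PosInf) ? R_PosInf : run + c;
      argprev(i, l) = arg;
    }
  }
  double best = R_PosInf;
  int lbest = -1;
  for (int l = 0; l < L; ++l)
    if (C(m - 1, l) < best) { best = C(m - 1, l); lbest = l; }
  if (lbest < 0) { placed.fill(NA_REAL); return placed; }
  for (int i = m - 1; i >= 0; --i) {
    placed[i] = grid[lbest];
    if (i > 0) lbest = argprev(i, lbest);
  }
  return placed;
}
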