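#include <Rcpp.h>
using namespace Rcpp;

// Two-row dynamic-programming Levenshtein distance (unit-cost
// substitution / insertion / deletion). Exact integer arithmetic, so
// downstream similarity thresholds are reproducible across platforms.
static int lev_core(const char* a, int la, const char* b, int lb,
                    std::vector<int>& prev, std::vector<int>& cur) {
  if (la == 0) return lb;
  if (lb == 0) return la;
  prev.resize(lb + 1);
  cur.resize(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i;
    for (int j = 1; j <= lb; ++j) {
      int sub = prev[j - 1] + (a[i - 1] != b[j - 1] ? 1 : 0);
      int del = prev[j] + 1;
      int ins = cur[j - 1] + 1;
      int best = sub < del ? sub : del;
      cur[j] = best < ins ? best : ins;
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export]]
IntegerVector cpp_lev_dist(CharacterVector a, CharacterVector b) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("'a' and 'b' must have the same length");
  IntegerVector out(n);
  std::vector<int> prev, cur;
  for (R_xlen_t k = 0; k < n; ++k) {
    if (a[k] == NA_STRING || b[k] == NA_STRING) {
      out[k] = NA_INTEGER;
      continue;
    }
    const char* sa = CHAR(a[k]);
    const char* sb = CHAR(b[k]);
    out[k] = lev_core(sa, (int)LENGTH(a[k]), sb, (int)LENGTH(b[k]), prev, cur);
  }
  return out;
}

// Condensed upper triangle of all pairwise L-sim scores, in the same
// order as stats::dist: for 1-based i < j the pair sits at
// n*(i-1) - i*(i-1)/2 + (j-i).
// [[Rcpp::export]]
NumericVector cpp_lsim_condensed(CharacterVector s) {
  R_xlen_t n = s.size();
  R_xlen_t npair = n * (n - 1) / 2;
  NumericVector out(npair);
  std::vector<int> prev, cur;
  R_xlen_t k = 0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    const char* si = CHAR(s[i]);
    int li = (int)LENGTH(s[i]);
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const char* sj = CHAR(s[j]);
      int lj = (int)LENGTH(s[j]);
      int m = li > lj ? li : lj;
      if (m == 0) {
        out[k++] = NA_REAL;  // both empty: undefined
      } else {
        int d = lev_core(si, li, sj, lj, prev, cur);
        out[k++] = 1.0 - (double)d / (double)m;
      }
    }
  }
  return out;
}

// L-sim of every string in 'a' against every string in 'b' (rows = a).
// [[Rcpp::export]]
NumericMatrix cpp_lsim_cross(CharacterVector a, CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size();
  NumericMatrix out(na, nb);
  std::vector<int> prev, cur;
  for (R_xlen_t i = 0; i < na; ++i) {
    const char* sa = CHAR(a[i]);
    int la = (int)LENGTH(a[i]);
    for (R_xlen_t j = 0; j < nb; ++j) {
      const char* sb = CHAR(b[j]);
      int lb = (int)LENGTH(b[j]);
      int m = la > lb ? la : lb;
      if (m == 0) {
        out(i, j) = NA_REAL;
      } else {
        int d = lev_core(sa, la, sb, lb, prev, cur);
        out(i, j) = 1.0 - (double)d / (double)m;
      }
    }
  }
  return out;
}
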