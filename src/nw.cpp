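#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Needleman-Wunsch global alignment under unit costs (match 0, mismatch 1,
// indel 1).  The distance reported is (mismatch columns + gap columns) /
// alignment length for the optimal alignment recovered by a deterministic
// traceback (diagonal preferred over up over left on ties), so results are
// identical across platforms.

namespace {

struct AlnStats {
  int edits;      // mismatch + gap columns
  int length;     // alignment columns
  std::string a;  // aligned a (with '-')
  std::string b;  // aligned b
};

AlnStats nw_align(const std::string &a, const std::string &b,
                  bool keep_strings) {
  const int n = a.size(), m = b.size();
  // cost matrix, row-major (n+1) x (m+1)
  std::vector<int> C((n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) C[j] = j;
  for (int i = 1; i <= n; ++i) {
    C[i * (m + 1)] = i;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int diag = C[(i - 1) * (m + 1) + (j - 1)] + (ai == b[j - 1] ? 0 : 1);
      int up = C[(i - 1) * (m + 1) + j] + 1;
      int left = C[i * (m + 1) + (j - 1)] + 1;
      int best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      C[i * (m + 1) + j] = best;
    }
  }
  // deterministic traceback
  AlnStats st;
  st.edits = 0;
  st.length = 0;
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int cur = C[i * (m + 1) + j];
    if (i > 0 && j > 0 &&
        cur == C[(i - 1) * (m + 1) + (j - 1)] + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      if (a[i - 1] != b[j - 1]) ++st.edits;
      if (keep_strings) { ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); }
      --i; --j;
    } else if (i > 0 && cur == C[(i - 1) * (m + 1) + j] + 1) {
      ++st.edits;
      if (keep_strings) { ra.push_back(a[i - 1]); rb.push_back('-'); }
      --i;
    } else {
      ++st.edits;
      if (keep_strings) { ra.push_back('-'); rb.push_back(b[j - 1]); }
      --j;
    }
    ++st.length;
  }
  if (keep_strings) {
    st.a.assign(ra.rbegin(), ra.rend());
    st.b.assign(rb.rbegin(), rb.rend());
  }
  return st;
}

double dist_from_stats(const std::string &a, const std::string &b,
                       bool terminal_gaps) {
  AlnStats st = nw_align(a, b, !terminal_gaps);
  if (st.length == 0) return 0.0;
  if (terminal_gaps) return (double)st.edits / (double)st.length;
  // exclude leading/trailing gap columns from numerator and denominator
  int lo = 0, hi = st.length - 1;
  while (lo <= hi && (st.a[lo] == '-' || st.b[lo] == '-')) ++lo;
  while (hi >= lo && (st.a[hi] == '-' || st.b[hi] == '-')) --hi;
  if (hi < lo) return 0.0;
  int edits = 0;
  for (int k = lo; k <= hi; ++k)
    if (st.a[k] != st.b[k] || st.a[k] == '-') ++edits;
  return (double)edits / (double)(hi - lo + 1);
}

}  // namespace

// The distance is defined on the unordered pair: the pair is oriented
// canonically (lexicographically) before the deterministic traceback so
// that d(a,b) == d(b,a) holds exactly.

// [[Rcpp::export]]
double nw_distance_cpp(std::string a, std::string b, bool terminal_gaps) {
  if (a == b) return 0.0;
  if (b < a) std::swap(a, b);
  return dist_from_stats(a, b, terminal_gaps);
}

// [[Rcpp::export]]
NumericVector nw_distance_matrix_cpp(CharacterVector seqs,
                                     bool terminal_gaps) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  NumericVector d((double)n * (n - 1) / 2);
  int k = 0;
  for (int j = 0; j < n - 1; ++j)
    for (int i = j + 1; i < n; ++i, ++k) {
      if (s[i] == s[j]) { d[k] = 0.0; continue; }
      const bool swap = s[i] < s[j];
      d[k] = dist_from_stats(swap ? s[i] : s[j], swap ? s[j] : s[i],
                             terminal_gaps);
    }
  return d;
}

// [[Rcpp::export]]
CharacterVector nw_align_cpp(std::string a, std::string b) {
  AlnStats st = nw_align(a, b, true);
  return CharacterVector::create(st.a, st.b);
}
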