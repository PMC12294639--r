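#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Optimal string alignment (restricted Damerau-Levenshtein) distance:
// unit-cost substitution, insertion, deletion, and adjacent transposition,
// with the restriction that no substring is edited more than once.
static int osa_distance(const std::string &a, const std::string &b) {
  const int n = a.size(), m = b.size();
  if (n == 0) return m;
  if (m == 0) return n;

  std::vector<int> d0(m + 1), d1(m + 1), d2(m + 1);
  for (int j = 0; j <= m; ++j) d1[j] = j;

  for (int i = 1; i <= n; ++i) {
    d2[0] = i;
    for (int j = 1; j <= m; ++j) {
      const int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int best = std::min(std::min(d2[j - 1] + 1, d1[j] + 1), d1[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        best = std::min(best, d0[j - 2] + 1);
      d2[j] = best;
    }
    std::swap(d0, d1);
    std::swap(d1, d2);
  }
  return d1[m];
}

// [[Rcpp::export(name = ".dl_distance_cpp")]]
IntegerVector dl_distance_cpp(CharacterVector a, CharacterVector b) {
  const R_xlen_t na = a.size(), nb = b.size();
  const R_xlen_t n = std::max(na, nb);
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    String sa = a[i % na], sb = b[i % nb];
    if (sa == NA_STRING || sb == NA_STRING) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = osa_distance(std::string(sa.get_cstring()),
                            std::string(sb.get_cstring()));
    }
  }
  return out;
}

// Cross-product distance matrix: rows = tokens, cols = reference words.
// [[Rcpp::export(name = ".dl_cross_cpp")]]
IntegerMatrix dl_cross_cpp(CharacterVector tokens, CharacterVector words) {
  const R_xlen_t nt = tokens.size(), nw = words.size();
  std::vector<std::string> toks(nt), ws(nw);
  for (R_xlen_t i = 0; i < nt; ++i) toks[i] = std::string(tokens[i]);
  for (R_xlen_t j = 0; j < nw; ++j) ws[j] = std::string(words[j]);
  IntegerMatrix out(nt, nw);
  for (R_xlen_t i = 0; i < nt; ++i)
    for (R_xlen_t j = 0; j < nw; ++j)
      out(i, j) = osa_distance(toks[i], ws[j]);
  return out;
}
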