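// Hamming-neighbourhood barcode correction against a whitelist hash.
//
// A query is assigned to a whitelist barcode iff exactly one member lies
// within Hamming distance <= 2; zero or several candidates yield NA
// (ambiguity is a discard, never a repair). The distance-<=2 neighbourhood
// of a 30-mer holds 1 + 90 + C(30,2)*9 = 4006 distinct sequences, each an
// exact hash lookup. When the whitelist's minimum pairwise distance is >= 3
// an exact match provably excludes any second member within distance 2, so
// the caller may enable an exact-match shortcut.

#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export]]
IntegerVector match_barcodes_cpp(CharacterVector queries,
                                 CharacterVector whitelist,
                                 bool exact_shortcut) {
  std::unordered_map<std::string, int> wl;
  wl.reserve(whitelist.size() * 2);
  for (int i = 0; i < whitelist.size(); ++i) {
    wl.emplace(std::string(whitelist[i]), i + 1);  // 1-based
  }
  const size_t L = whitelist.size() > 0 ? std::string(whitelist[0]).size() : 0;

  IntegerVector out(queries.size(), NA_INTEGER);
  std::vector<int> cand;
  std::string q;
  for (int qi = 0; qi < queries.size(); ++qi) {
    if (queries[qi] == NA_STRING) continue;
    q = std::string(queries[qi]);
    if (q.size() != L) continue;

    auto hit0 = wl.find(q);
    if (hit0 != wl.end() && exact_shortcut) {
      out[qi] = hit0->second;
      continue;
    }
    cand.clear();
    if (hit0 != wl.end()) cand.push_back(hit0->second);

    // all 1-substitution neighbours
    for (size_t i = 0; i < L && cand.size() < 2; ++i) {
      const char orig_i = q[i];
      for (int b = 0; b < 4; ++b) {
        if (BASES[b] == orig_i) continue;
        q[i] = BASES[b];
        auto it = wl.find(q);
        if (it != wl.end()) {
          cand.push_back(it->second);
          if (cand.size() >= 2) break;
        }
      }
      q[i] = orig_i;
    }
    // all 2-substitution neighbours (i < j, both bases changed)
    for (size_t i = 0; i + 1 < L && cand.size() < 2; ++i) {
      const char orig_i = q[i];
      for (int bi = 0; bi < 4 && cand.size() < 2; ++bi) {
        if (BASES[bi] == orig_i) continue;
        q[i] = BASES[bi];
        for (size_t j = i + 1; j < L && cand.size() < 2; ++j) {
          const char orig_j = q[j];
          for (int bj = 0; bj < 4; ++bj) {
            if (BASES[bj] == orig_j) continue;
            q[j] = BASES[bj];
            auto it = wl.find(q);
            if (it != wl.end()) {
              cand.push_back(it->second);
              if (cand.size() >= 2) break;
            }
          }
          q[j] = orig_j;
        }
      }
      q[i] = orig_i;
    }
    if (cand.size() == 1) out[qi] = cand[0];
  }
  return out;
}

// Exact minimum pairwise Hamming distance over a set of equal-length strings.
// [[Rcpp::export]]
double min_pairwise_hamming_cpp(CharacterVector x) {
  const int n = x.size();
  if (n < 2) return R_PosInf;
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = std::string(x[i]);
  const size_t L = s[0].size();
  size_t best = L + 1;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      size_t d = 0;
      for (size_t k = 0; k < L && d < best; ++k) {
        if (s[i][k] != s[j][k]) ++d;
      }
      if (d < best) {
        best = d;
        if (best == 0) return 0;
      }
    }
  }
  return static_cast<double>(best);
}

// Hamming distance between two equal-length strings (vectorised over pairs).
// [[Rcpp::export]]
IntegerVector hamming_distance_cpp(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string sa(a[i]), sb(b[i]);
    if (sa.size() != sb.size()) { out[i] = NA_INTEGER; continue; }
    int d = 0;
    for (size_t k = 0; k < sa.size(); ++k) if (sa[k] != sb[k]) ++d;
    out[i] = d;
  }
  return out;
}
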