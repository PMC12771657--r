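#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encoding; -1 for anything not A/C/G/T (treated as a hard break).
static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static bool motifPrimitive(const char* s, int u) {
  for (int d = 1; d < u; ++d) {
    if (u % d != 0) continue;
    bool periodic = true;
    for (int i = d; i < u; ++i) {
      if (s[i] != s[i - d]) { periodic = false; break; }
    }
    if (periodic) return false;
  }
  return true;
}

// Maximal perfect tandem repeats of unit length 1..6 (MISA-style SSRs).
// thresholds: integer vector of length 6, minimum repeat count per unit length.
// Returns 0-based starts; end = start + unit_len * repeats.
// [[Rcpp::export(name = ".cpp_find_ssrs")]]
DataFrame cpp_find_ssrs(std::string seq, IntegerVector thresholds) {
  int n = (int) seq.size();
  std::vector<int> starts, unit_lens, repcounts;
  std::vector<std::string> motifs;
  for (int u = 1; u <= 6; ++u) {
    int thr = thresholds[u - 1];
    int i = 0;
    while (i + u < n) {
      char a = seq[i];
      if (baseCode(a) < 0 || seq[i] != seq[i + u]) { ++i; continue; }
      // run of positions j with seq[j] == seq[j+u], all unambiguous
      int j = i;
      while (j + u < n && baseCode(seq[j]) >= 0 && baseCode(seq[j + u]) >= 0 &&
             seq[j] == seq[j + u]) ++j;
      int runlen = (j - i) + u;        // total tandem tract length
      int reps = runlen / u;
      if (reps >= thr && motifPrimitive(seq.c_str() + i, u)) {
        starts.push_back(i);
        unit_lens.push_back(u);
        repcounts.push_back(reps);
        motifs.push_back(seq.substr(i, u));
      }
      i = j + 1;
    }
  }
  return DataFrame::create(
    Named("start") = starts,
    Named("unit_len") = unit_lens,
    Named("repeats") = repcounts,
    Named("motif") = motifs,
    Named("stringsAsFactors") = false);
}

// All maximal exact matches (MEMs) of length >= min_len between strings a and
// b, enumerated by left-maximal seed extension with packed k-mers
// (k = min(min_len, 31)).  When same_string is true (a and b identical),
// the trivial diagonal i == j is skipped.
// Returns 0-based start positions in a and b plus the match length.
// [[Rcpp::export(name = ".cpp_find_mems")]]
DataFrame cpp_find_mems(std::string a, std::string b, int min_len,
                        bool same_string = false) {
  int na = (int) a.size(), nb = (int) b.size();
  int k = min_len < 31 ? min_len : 31;
  if (k < 1) stop("min_len must be >= 1");
  std::vector<int> ia, ib, lens;
  if (na < k || nb < k) {
    return DataFrame::create(Named("i") = ia, Named("j") = ib,
                             Named("len") = lens);
  }
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_multimap<uint64_t, int> index;
  index.reserve((size_t) na * 2);
  {
    uint64_t h = 0; int valid = 0;
    for (int i = 0; i < na; ++i) {
      int c = baseCode(a[i]);
      if (c < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) c) & mask;
      if (++valid >= k) index.emplace(h, i - k + 1);
    }
  }
  uint64_t h = 0; int valid = 0;
  for (int p = 0; p < nb; ++p) {
    int c = baseCode(b[p]);
    if (c < 0) { valid = 0; h = 0; continue; }
    h = ((h << 2) | (uint64_t) c) & mask;
    if (++valid < k) continue;
    int j = p - k + 1;
    auto range = index.equal_range(h);
    for (auto it = range.first; it != range.second; ++it) {
      int i = it->second;
      if (same_string && i == j) continue;
      // left-maximality: each MEM is reported from its leftmost seed only
      if (i > 0 && j > 0 && a[i - 1] == b[j - 1] &&
          baseCode(a[i - 1]) >= 0) continue;
      int l = k;
      while (i + l < na && j + l < nb && a[i + l] == b[j + l] &&
             baseCode(a[i + l]) >= 0) ++l;
      if (l >= min_len) {
        ia.push_back(i); ib.push_back(j); lens.push_back(l);
      }
    }
  }
  return DataFrame::create(Named("i") = ia, Named("j") = ib,
                           Named("len") = lens);
}
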