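#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>
using namespace Rcpp;

// Hamming distance between two L-mers with early exit once > m.
static inline bool within_mismatches(const char *a, const char *b, int L, int m) {
  int d = 0;
  for (int k = 0; k < L; ++k) {
    if (a[k] != b[k]) {
      if (++d > m) return false;
    }
  }
  return true;
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

// Multi-mapping counts for every L-mer start position across all contigs.
// count[i] = 1 (self) + number of other start positions whose L-mer lies
// within Hamming distance m. L-mers containing N match nothing (count 1,
// flagged). With both_strands, reverse-complement L-mers at other positions
// (and the position itself) also count as matches.
// [[Rcpp::export(name = ".mapp_counts_cpp")]]
List mapp_counts_cpp(CharacterVector contigs, int L, int m, bool both_strands) {
  int nc = contigs.size();
  std::vector<std::string> seq(nc), rcs(nc);
  std::vector<int> npos(nc);
  for (int c = 0; c < nc; ++c) {
    seq[c] = as<std::string>(contigs[c]);
    if ((int)seq[c].size() < L)
      stop("read length L exceeds contig length");
    npos[c] = (int)seq[c].size() - L + 1;
    if (both_strands) {
      const std::string &s = seq[c];
      rcs[c].resize(s.size());
      for (size_t k = 0; k < s.size(); ++k)
        rcs[c][s.size() - 1 - k] = comp_base(s[k]);
    }
  }
  // flatten start positions
  std::vector<const char *> ptr;          // forward L-mer at each start
  std::vector<const char *> rptr;         // rev-comp L-mer at the same start
  std::vector<bool> hasN;
  std::vector<int> contig_of;
  for (int c = 0; c < nc; ++c) {
    const std::string &s = seq[c];
    for (int i = 0; i < npos[c]; ++i) {
      ptr.push_back(s.c_str() + i);
      if (both_strands) {
        // rev-comp of s[i, i+L) starts at mirrored offset in rcs
        rptr.push_back(rcs[c].c_str() + ((int)s.size() - L - i));
      }
      bool n = false;
      for (int k = 0; k < L; ++k)
        if (s[i + k] != 'A' && s[i + k] != 'C' && s[i + k] != 'G' && s[i + k] != 'T') { n = true; break; }
      hasN.push_back(n);
      contig_of.push_back(c);
    }
  }
  int P = (int)ptr.size();
  std::vector<int> cnt(P, 1);
  for (int i = 0; i < P; ++i) {
    if (hasN[i]) continue;
    for (int j = i + 1; j < P; ++j) {
      if (hasN[j]) continue;
      if (within_mismatches(ptr[i], ptr[j], L, m)) { ++cnt[i]; ++cnt[j]; }
    }
    if (both_strands) {
      for (int j = i; j < P; ++j) {
        if (hasN[j]) continue;
        if (within_mismatches(ptr[i], rptr[j], L, m)) {
          ++cnt[i];
          if (j != i) ++cnt[j];
        }
      }
    }
  }
  // split back per contig
  List counts(nc), flags(nc);
  int off = 0;
  for (int c = 0; c < nc; ++c) {
    IntegerVector v(npos[c]);
    LogicalVector f(npos[c]);
    for (int i = 0; i < npos[c]; ++i) {
      v[i] = cnt[off + i];
      f[i] = hasN[off + i];
    }
    counts[c] = v;
    flags[c] = f;
    off += npos[c];
  }
  counts.attr("names") = contigs.attr("names");
  flags.attr("names") = contigs.attr("names");
  return List::create(_["counts"] = counts, _["flagged"] = flags);
}

// Base-pair score of a simplified nearest-neighbour-free energy model:
// each pair contributes independently (GC 3, AU 2, GU 1), hairpin loops
// must hold >= 3 unpaired bases. Maximising total pair score stands in
// for minimum-free-energy folding.
static inline int pair_score(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Nussinov-style dynamic program with deterministic traceback.
// Returns 1-based partner index per position, 0 = unpaired.
// [[Rcpp::export(name = ".fold_pairs_cpp")]]
IntegerVector fold_pairs_cpp(std::string s) {
  int n = (int)s.size();
  IntegerVector partner(n);
  if (n < 5) return partner;
  const int MINLOOP = 3;
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = MINLOOP + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i][j - 1]; // j unpaired
      for (int k = i; k <= j - MINLOOP - 1; ++k) {
        int ps = pair_score(s[k], s[j]);
        if (ps == 0) continue;
        int v = (k > i ? M[i][k - 1] : 0) + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0) + ps;
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // iterative traceback; prefer "j unpaired", then smallest k
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < MINLOOP + 1) continue;
    if (M[i][j] == M[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - MINLOOP - 1; ++k) {
      int ps = pair_score(s[k], s[j]);
      if (ps == 0) continue;
      int v = (k > i ? M[i][k - 1] : 0) + (k + 1 <= j - 1 ? M[k + 1][j - 1] : 0) + ps;
      if (v == M[i][j]) {
        partner[k] = j + 1;
        partner[j] = k + 1;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
  return partner;
}
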