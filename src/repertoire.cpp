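#include <Rcpp.h>
#include <functional>
#include <map>
#include <set>
#include <string>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline bool comparable_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T' ||
         c == 'a' || c == 'c' || c == 'g' || c == 't';
}

static inline char upcase(char c) {
  return (c >= 'a' && c <= 'z') ? c - 32 : c;
}

// Count mismatches between each aligned sequence and its germline over the
// IGHV region (gapped positions 1..v_region_end). Positions where either
// string carries a gap or ambiguous character are excluded from both the
// mismatch count and the comparable length.
// [[Rcpp::export]]
IntegerMatrix cpp_ighv_mismatch(CharacterVector seq, CharacterVector germ,
                                int v_region_end) {
  int n = seq.size();
  if (germ.size() != n) stop("seq and germ must have equal length");
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    if (seq[i] == NA_STRING || germ[i] == NA_STRING) {
      out(i, 0) = NA_INTEGER; out(i, 1) = NA_INTEGER; continue;
    }
    const char *s = CHAR(seq[i]);
    const char *g = CHAR(germ[i]);
    int ls = LENGTH(seq[i]);
    int lg = LENGTH(germ[i]);
    int lim = ls < lg ? ls : lg;
    if (v_region_end < lim) lim = v_region_end;
    int mism = 0, comp = 0;
    for (int j = 0; j < lim; ++j) {
      if (!comparable_base(s[j]) || !comparable_base(g[j])) continue;
      ++comp;
      if (upcase(s[j]) != upcase(g[j])) ++mism;
    }
    out(i, 0) = mism;
    out(i, 1) = comp;
  }
  colnames(out) = CharacterVector::create("mutations", "comparable_length");
  return out;
}

// Single-linkage clusters of equal-length strings at normalized Hamming
// distance <= threshold, via union-find over the threshold graph (the
// single-linkage cut equals the transitive closure of <=-threshold edges).
// Returns dense 1-based labels in order of first member appearance.
// [[Rcpp::export]]
IntegerVector cpp_cluster_junctions(CharacterVector x, double threshold) {
  int n = x.size();
  IntegerVector parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  if (n > 1) {
    int len = LENGTH(x[0]);
    for (int i = 1; i < n; ++i)
      if (LENGTH(x[i]) != len) stop("junctions must have equal length");
    int maxd = (int)std::floor(threshold * len + 1e-9);
    for (int i = 0; i < n - 1; ++i) {
      const char *a = CHAR(x[i]);
      for (int j = i + 1; j < n; ++j) {
        int ri = find(i), rj = find(j);
        if (ri == rj) continue;
        const char *b = CHAR(x[j]);
        int d = 0;
        for (int k = 0; k < len && d <= maxd; ++k)
          if (a[k] != b[k]) ++d;
        if (d <= maxd) parent[ri] = rj;
      }
    }
  }
  IntegerVector lab(n);
  std::map<int, int> relabel;
  int nxt = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel[r] = ++nxt; lab[i] = nxt; }
    else lab[i] = it->second;
  }
  return lab;
}

// Normalized Hamming distance matrix for equal-length strings.
// [[Rcpp::export]]
NumericMatrix cpp_hamming_matrix(CharacterVector x) {
  int n = x.size();
  NumericMatrix out(n, n);
  if (n == 0) return out;
  int len = LENGTH(x[0]);
  for (int i = 1; i < n; ++i)
    if (LENGTH(x[i]) != len) stop("strings must have equal length");
  for (int i = 0; i < n - 1; ++i) {
    const char *a = CHAR(x[i]);
    for (int j = i + 1; j < n; ++j) {
      const char *b = CHAR(x[j]);
      int d = 0;
      for (int k = 0; k < len; ++k) if (a[k] != b[k]) ++d;
      out(i, j) = out(j, i) = (double)d / len;
    }
  }
  return out;
}

// Draw k distinct positions in [0, len) using R's RNG.
static void sample_positions(int len, int k, std::vector<int> &out) {
  out.clear();
  while ((int)out.size() < k) {
    int p = (int)(unif_rand() * len);
    if (p >= len) p = len - 1;
    bool seen = false;
    for (int q : out) if (q == p) { seen = true; break; }
    if (!seen) out.push_back(p);
  }
}

static inline char random_other_base(char orig) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  int oi = 0;
  for (int i = 0; i < 4; ++i) if (bases[i] == orig) { oi = i; break; }
  int off = 1 + (int)(unif_rand() * 3);
  if (off > 3) off = 3;
  return bases[(oi + off) % 4];
}

// Random nucleotide sequences of a common length.
// [[Rcpp::export]]
CharacterVector cpp_random_seqs(int n, int len) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector out(n);
  std::string s(len, 'A');
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < len; ++j) {
      int b = (int)(unif_rand() * 4);
      if (b > 3) b = 3;
      s[j] = bases[b];
    }
    out[i] = s;
  }
  return out;
}

// Member junctions: the first member of every lineage keeps the ancestor
// junction; later members mutate 1..floor(threshold*len) random positions,
// kept distinct within the lineage so no two clonotypes share a sequence.
// [[Rcpp::export]]
CharacterVector cpp_junction_variants(CharacterVector anc, IntegerVector lineage_of,
                                      double threshold) {
  int n = lineage_of.size();
  CharacterVector out(n);
  std::vector<int> pos;
  std::map<int, std::set<std::string> > used;
  for (int i = 0; i < n; ++i) {
    int lin = lineage_of[i] - 1;
    std::string a = as<std::string>(anc[lin]);
    int len = a.size();
    auto &seen = used[lin];
    if (seen.empty()) {       // lineage founder keeps the ancestor junction
      seen.insert(a);
      out[i] = a;
      continue;
    }
    int rmax = (int)std::floor(threshold * len + 1e-9);
    if (rmax < 1) rmax = 1;
    std::string v;
    for (int attempt = 0; attempt < 100; ++attempt) {
      v = a;
      int k = 1 + (int)(unif_rand() * rmax);
      if (k > rmax) k = rmax;
      sample_positions(len, k, pos);
      for (int p : pos) v[p] = random_other_base(v[p]);
      if (seen.find(v) == seen.end()) break;
    }
    seen.insert(v);
    out[i] = v;
  }
  return out;
}

// Per-member IGHV sequences: copy the allele germline and plant the given
// number of substitutions at distinct random positions.
// [[Rcpp::export]]
CharacterVector cpp_build_v_sequences(CharacterVector germ_pool, IntegerVector allele_of,
                                      IntegerVector mut_count) {
  int n = allele_of.size();
  if (mut_count.size() != n) stop("allele_of and mut_count must have equal length");
  CharacterVector out(n);
  std::vector<int> pos;
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(germ_pool[allele_of[i] - 1]);
    int len = s.size();
    int k = mut_count[i];
    if (k > len) k = len;
    if (k > 0) {
      sample_positions(len, k, pos);
      for (int p : pos) s[p] = random_other_base(s[p]);
    }
    out[i] = s;
  }
  return out;
}
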