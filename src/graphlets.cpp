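// Small-digraph canonical forms, automorphisms, graphlet dictionary
// enumeration, and the exhaustive ESU induced-subgraph census.
//
// A digraph on n <= 6 nodes (no self-loops) is packed into an integer mask
// with the ordered pair (i,j), i != j, stored at bit p = i*(n-1) + (j<i ? j : j-1).
// The canonical form of a graphlet is the numerically smallest mask over all
// n! node permutations; two digraphs are isomorphic iff their canonical masks
// are equal.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline int pairBit(int i, int j, int n) {
  return i * (n - 1) + (j < i ? j : j - 1);
}

static uint32_t permuteMask(uint32_t mask, const int* perm, int n) {
  uint32_t out = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (mask & (1u << pairBit(i, j, n)))
        out |= 1u << pairBit(perm[i], perm[j], n);
    }
  }
  return out;
}

static bool weaklyConnectedMask(uint32_t mask, int n) {
  if (n <= 1) return true;
  int parent[8];
  for (int i = 0; i < n; ++i) parent[i] = i;
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      if (mask & (1u << pairBit(i, j, n))) {
        int a = find(i), b = find(j);
        if (a != b) parent[a] = b;
      }
    }
  int r = find(0);
  for (int i = 1; i < n; ++i) if (find(i) != r) return false;
  return true;
}

struct CanonResult { uint32_t mask; std::vector<int> perm; int aut; };

static CanonResult canonicalMask(uint32_t mask, int n) {
  std::vector<int> perm(n), best(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  uint32_t bestMask = mask; // identity permutation included in scan below
  best = perm;
  int aut = 0;
  do {
    uint32_t m = permuteMask(mask, perm.data(), n);
    if (m == mask) ++aut;
    if (m < bestMask) { bestMask = m; best = perm; }
  } while (std::next_permutation(perm.begin(), perm.end()));
  CanonResult res; res.mask = bestMask; res.perm = best; res.aut = aut;
  return res;
}

// [[Rcpp::export(name = ".canonical_mask_cpp")]]
List canonical_mask_cpp(int n, int mask) {
  if (n < 1 || n > 6) stop("graphlet size must be between 1 and 6");
  CanonResult res = canonicalMask((uint32_t)mask, n);
  return List::create(_["mask"] = (int)res.mask,
                      _["perm"] = IntegerVector(res.perm.begin(), res.perm.end()),
                      _["aut"] = res.aut);
}

// [[Rcpp::export(name = ".weakly_connected_mask_cpp")]]
bool weakly_connected_mask_cpp(int n, int mask) {
  if (n < 1) stop("empty node set");
  return weaklyConnectedMask((uint32_t)mask, n);
}

// Enumerate all isomorphism classes of weakly connected digraphs on n nodes.
// Ascending scan over all masks: the first unseen mask of a class is its
// canonical (minimal) representative; its whole orbit is then marked seen.
// [[Rcpp::export(name = ".enumerate_graphlets_cpp")]]
List enumerate_graphlets_cpp(int n) {
  if (n < 2 || n > 5) stop("dictionary enumeration supports 2 <= n <= 5");
  const int L = n * (n - 1);
  const uint32_t total = 1u << L;
  std::vector<bool> seen(total, false);
  std::vector<int> masks, auts;
  std::vector<int> perm(n);
  for (uint32_t mask = 1; mask < total; ++mask) {
    if (seen[mask]) continue;
    for (int i = 0; i < n; ++i) perm[i] = i;
    int aut = 0;
    do {
      uint32_t m = permuteMask(mask, perm.data(), n);
      seen[m] = true;
      if (m == mask) ++aut;
    } while (std::next_permutation(perm.begin(), perm.end()));
    if (weaklyConnectedMask(mask, n)) {
      masks.push_back((int)mask);
      auts.push_back(aut);
    }
  }
  return List::create(_["mask"] = IntegerVector(masks.begin(), masks.end()),
                      _["aut"] = IntegerVector(auts.begin(), auts.end()));
}

// ---------------------------------------------------------------------------
// ESU census
// ---------------------------------------------------------------------------

namespace {

struct EsuState {
  int k;
  const std::vector<std::vector<int>>* nbr;   // undirected neighbor lists (sorted)
  const std::vector<std::vector<uint64_t>>* outRow;
  std::vector<int> sub;
  std::vector<char> inSub;
  std::vector<int> nbhdStamp;
  std::vector<std::vector<int>> extBuf, addedBuf; // per-depth scratch
  int root;
  const std::vector<int>* maskToGamma; // induced mask -> gamma index or -1
  std::vector<long long>* counts;
  std::vector<std::vector<int>>* occ;
  bool keepSubsets;
  long long totalEnumerated;
};

static inline bool hasEdge(const std::vector<std::vector<uint64_t>>& rows, int i, int j) {
  return (rows[i][j >> 6] >> (j & 63)) & 1ull;
}

static void recordSubset(EsuState& st) {
  const int k = st.k;
  int nodes[6];
  for (int i = 0; i < k; ++i) nodes[i] = st.sub[i];
  std::sort(nodes, nodes + k);
  uint32_t mask = 0;
  for (int a = 0; a < k; ++a)
    for (int b = 0; b < k; ++b) {
      if (a == b) continue;
      if (hasEdge(*st.outRow, nodes[a], nodes[b]))
        mask |= 1u << pairBit(a, b, k);
    }
  st.totalEnumerated++;
  int g = (*st.maskToGamma)[mask];
  if (g < 0) return;
  (*st.counts)[g]++;
  if (st.keepSubsets) {
    std::vector<int>& v = (*st.occ)[g];
    v.insert(v.end(), nodes, nodes + k);
  }
}

// per-depth scratch buffers avoid one allocation per recursion node; the
// child call drains its extension buffer, so the exclusive neighbors added
// by w are snapshotted separately for unmarking on backtrack
static void esuExtend(EsuState& st, std::vector<int>& ext, int depth, int stamp) {
  if ((int)st.sub.size() == st.k) { recordSubset(st); return; }
  while (!ext.empty()) {
    int w = ext.back();
    ext.pop_back();
    std::vector<int>& ext2 = st.extBuf[depth];
    std::vector<int>& added = st.addedBuf[depth];
    ext2.assign(ext.begin(), ext.end());
    added.clear();
    for (int u : (*st.nbr)[w]) {
      if (u <= st.root) continue;
      if (st.inSub[u]) continue;
      if (st.nbhdStamp[u] == stamp) continue;
      st.nbhdStamp[u] = stamp;
      ext2.push_back(u);
      added.push_back(u);
    }
    st.sub.push_back(w);
    st.inSub[w] = 1;
    esuExtend(st, ext2, depth + 1, stamp);
    st.inSub[w] = 0;
    st.sub.pop_back();
    for (int u : st.addedBuf[depth]) st.nbhdStamp[u] = 0;
  }
}

// classification table for size k: orbit fill, marking every labeled mask of a
// weakly connected class with its dictionary index (or -1 when absent)
static std::vector<int> buildMaskTable(int k, const std::vector<std::pair<uint32_t,int>>& canonOfSize) {
  const int L = k * (k - 1);
  std::vector<int> table(1u << L, -1);
  std::vector<bool> seen(1u << L, false);
  std::vector<int> perm(k);
  for (uint32_t mask = 1; mask < (1u << L); ++mask) {
    if (seen[mask]) continue;
    int g = -1;
    if (weaklyConnectedMask(mask, k)) {
      for (const auto& pr : canonOfSize)
        if (pr.first == mask) { g = pr.second; break; }
    }
    for (int i = 0; i < k; ++i) perm[i] = i;
    do {
      uint32_t m = permuteMask(mask, perm.data(), k);
      if (!seen[m]) { seen[m] = true; table[m] = g; }
    } while (std::next_permutation(perm.begin(), perm.end()));
  }
  return table;
}

} // namespace

// gamma_n / gamma_mask give the dictionary (canonical masks per size).
// Returns per-gamma counts and, if keep_subsets, the node subsets
// (flattened, 0-based, each sorted ascending).
// [[Rcpp::export(name = ".esu_census_cpp")]]
List esu_census_cpp(int N, IntegerMatrix edges, IntegerVector sizes,
                    IntegerVector gamma_n, IntegerVector gamma_mask,
                    bool keep_subsets) {
  int G = gamma_n.size();
  int W = (N + 63) >> 6;
  std::vector<std::vector<uint64_t>> outRow(N, std::vector<uint64_t>(W, 0));
  std::vector<std::vector<int>> nbr(N);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    if (i < 0 || j < 0 || i >= N || j >= N) stop("edge endpoint out of range");
    if (i == j) stop("self-loop in edge list");
    outRow[i][j >> 6] |= 1ull << (j & 63);
    nbr[i].push_back(j);
    nbr[j].push_back(i);
  }
  for (int i = 0; i < N; ++i) {
    std::sort(nbr[i].begin(), nbr[i].end());
    nbr[i].erase(std::unique(nbr[i].begin(), nbr[i].end()), nbr[i].end());
  }

  std::vector<long long> counts(G, 0);
  std::vector<std::vector<int>> occ(G);
  long long totalEnumerated = 0;

  for (int si = 0; si < sizes.size(); ++si) {
    int k = sizes[si];
    if (k < 2 || k > 5) stop("census sizes must be between 2 and 5");
    std::vector<std::pair<uint32_t,int>> canonOfSize;
    for (int g = 0; g < G; ++g)
      if (gamma_n[g] == k) canonOfSize.push_back({(uint32_t)gamma_mask[g], g});
    std::vector<int> maskToGamma = buildMaskTable(k, canonOfSize);

    EsuState st;
    st.k = k; st.nbr = &nbr; st.outRow = &outRow;
    st.inSub.assign(N, 0);
    st.nbhdStamp.assign(N, 0);
    st.extBuf.assign(k + 1, {});
    st.addedBuf.assign(k + 1, {});
    st.maskToGamma = &maskToGamma;
    st.counts = &counts;
    st.occ = &occ;
    st.keepSubsets = keep_subsets;
    st.totalEnumerated = 0;

    int stamp = 0;
    for (int v = 0; v < N; ++v) {
      ++stamp;
      st.root = v;
      st.sub.clear();
      st.sub.push_back(v);
      st.inSub[v] = 1;
      std::vector<int> ext;
      for (int u : nbr[v]) if (u > v) { ext.push_back(u); st.nbhdStamp[u] = stamp; }
      esuExtend(st, ext, 0, stamp);
      for (int u : nbr[v]) if (u > v) st.nbhdStamp[u] = 0;
      st.inSub[v] = 0;
    }
    totalEnumerated += st.totalEnumerated;
  }

  List occOut(G);
  if (keep_subsets) {
    for (int g = 0; g < G; ++g) {
      occOut[g] = IntegerVector(occ[g].begin(), occ[g].end());
      occ[g].clear(); occ[g].shrink_to_fit();
    }
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["subsets"] = occOut,
                      _["total_enumerated"] = (double)totalEnumerated);
}
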