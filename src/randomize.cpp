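// Microcanonical null-model samplers: uniform resampling (ER, RER) and
// Markov-chain edge swaps (CM, RCM) that exactly preserve the constrained
// features of each family while keeping the graph simple and loop-free.

#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <random>
#include <cstdint>
using namespace Rcpp;

static inline int64_t okey(int i, int j, int N) { return (int64_t)i * N + j; }
static inline int64_t ukey(int i, int j, int N) {
  return i < j ? (int64_t)i * N + j : (int64_t)j * N + i;
}

// [[Rcpp::export(name = ".er_resample_cpp")]]
IntegerMatrix er_resample_cpp(int N, int E, int seed) {
  if ((double)E > (double)N * (N - 1)) stop("too many edges for simple digraph");
  std::mt19937 gen((uint32_t)seed);
  std::unordered_set<int64_t> used;
  IntegerMatrix out(E, 2);
  int placed = 0;
  while (placed < E) {
    int i = (int)(gen() % (uint32_t)N);
    int j = (int)(gen() % (uint32_t)N);
    if (i == j) continue;
    int64_t k = okey(i, j, N);
    if (used.count(k)) continue;
    used.insert(k);
    out(placed, 0) = i;
    out(placed, 1) = j;
    placed++;
  }
  return out;
}

// [[Rcpp::export(name = ".rer_resample_cpp")]]
IntegerMatrix rer_resample_cpp(int N, int Em, int Ed, int seed) {
  double pairs = (double)N * (N - 1) / 2.0;
  if ((double)Em + Ed > pairs) stop("too many edges for simple digraph");
  std::mt19937 gen((uint32_t)seed);
  std::unordered_set<int64_t> usedPair;
  IntegerMatrix out(2 * Em + Ed, 2);
  int row = 0, placed = 0;
  while (placed < Em) {
    int i = (int)(gen() % (uint32_t)N);
    int j = (int)(gen() % (uint32_t)N);
    if (i == j) continue;
    int64_t k = ukey(i, j, N);
    if (usedPair.count(k)) continue;
    usedPair.insert(k);
    out(row, 0) = i; out(row, 1) = j; row++;
    out(row, 0) = j; out(row, 1) = i; row++;
    placed++;
  }
  placed = 0;
  while (placed < Ed) {
    int i = (int)(gen() % (uint32_t)N);
    int j = (int)(gen() % (uint32_t)N);
    if (i == j) continue;
    int64_t k = ukey(i, j, N);
    if (usedPair.count(k)) continue;
    usedPair.insert(k);
    out(row, 0) = i; out(row, 1) = j; row++;
    placed++;
  }
  return out;
}

// Degree-preserving directed double-edge swaps, run as a lazy Markov chain:
// each step proposes a swap with probability 1/2 and otherwise stays put.
// The lazy half-step makes the chain aperiodic (plain double-edge swaps can
// be periodic on small ensembles, e.g. a directed 4-cycle alternates between
// the Hamiltonian-cycle and dyad-pair classes at every accepted move).
// [[Rcpp::export(name = ".cm_swap_cpp")]]
List cm_swap_cpp(int N, IntegerMatrix edges, double n_steps, int seed) {
  std::mt19937 gen((uint32_t)seed);
  long long E = edges.nrow();
  std::vector<int> src(E), dst(E);
  std::unordered_set<int64_t> eset;
  for (long long e = 0; e < E; ++e) {
    src[e] = edges(e, 0); dst[e] = edges(e, 1);
    eset.insert(okey(src[e], dst[e], N));
  }
  double accepted = 0;
  for (double step = 0; step < n_steps && E >= 2; ++step) {
    if (gen() & 1u) continue; // lazy half-step
    long long e1 = (long long)(gen() % (uint64_t)E);
    long long e2 = (long long)(gen() % (uint64_t)E);
    if (e1 == e2) continue;
    int a = src[e1], b = dst[e1], c = src[e2], d = dst[e2];
    if (a == d || c == b) continue;
    if (eset.count(okey(a, d, N)) || eset.count(okey(c, b, N))) continue;
    eset.erase(okey(a, b, N));
    eset.erase(okey(c, d, N));
    eset.insert(okey(a, d, N));
    eset.insert(okey(c, b, N));
    dst[e1] = d; dst[e2] = b;
    accepted++;
  }
  IntegerMatrix out(E, 2);
  for (long long e = 0; e < E; ++e) { out(e, 0) = src[e]; out(e, 1) = dst[e]; }
  return List::create(_["edges"] = out, _["accepted"] = accepted);
}

// Reciprocal-degree-preserving swaps: undirected double-edge swaps within the
// reciprocated subgraph and directed swaps within the non-reciprocated one,
// rejecting moves that place two edges on the same node pair. Lazy chain as
// in cm_swap_cpp.
// [[Rcpp::export(name = ".rcm_swap_cpp")]]
List rcm_swap_cpp(int N, IntegerMatrix edges, double n_steps, int seed) {
  std::mt19937 gen((uint32_t)seed);
  std::unordered_set<int64_t> eset;
  for (int e = 0; e < edges.nrow(); ++e)
    eset.insert(okey(edges(e, 0), edges(e, 1), N));
  std::vector<std::pair<int,int>> sym;  // i < j, reciprocated pairs
  std::vector<std::pair<int,int>> asym; // directed single edges
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    if (eset.count(okey(j, i, N))) {
      if (i < j) sym.push_back({i, j});
    } else {
      asym.push_back({i, j});
    }
  }
  // pair occupancy: 0 free, 1 reciprocated, 2 single
  std::unordered_map<int64_t, char> pst;
  for (auto& p : sym) pst[ukey(p.first, p.second, N)] = 1;
  for (auto& p : asym) pst[ukey(p.first, p.second, N)] = 2;

  auto occupied = [&](int i, int j) {
    auto it = pst.find(ukey(i, j, N));
    return it != pst.end() && it->second != 0;
  };

  long long nSym = sym.size(), nAsym = asym.size();
  double accepted = 0;
  for (double step = 0; step < n_steps && (nSym >= 2 || nAsym >= 2); ++step) {
    if (gen() & 1u) continue; // lazy half-step
    bool doSym;
    if (nSym >= 2 && nAsym >= 2) doSym = (gen() & 1u);
    else doSym = (nSym >= 2);
    if (doSym) {
      long long e1 = (long long)(gen() % (uint64_t)nSym);
      long long e2 = (long long)(gen() % (uint64_t)nSym);
      if (e1 == e2) continue;
      int a = sym[e1].first, b = sym[e1].second;
      int c = sym[e2].first, d = sym[e2].second;
      if (gen() & 1u) std::swap(c, d);
      // proposed pairs {a,c}, {b,d}
      if (a == c || b == d) continue;
      if (occupied(a, c) || occupied(b, d)) continue;
      if (ukey(a, c, N) == ukey(b, d, N)) continue;
      pst[ukey(a, b, N)] = 0; pst[ukey(c, d, N)] = 0;
      pst[ukey(a, c, N)] = 1; pst[ukey(b, d, N)] = 1;
      sym[e1] = {std::min(a, c), std::max(a, c)};
      sym[e2] = {std::min(b, d), std::max(b, d)};
      accepted++;
    } else {
      long long e1 = (long long)(gen() % (uint64_t)nAsym);
      long long e2 = (long long)(gen() % (uint64_t)nAsym);
      if (e1 == e2) continue;
      int a = asym[e1].first, b = asym[e1].second;
      int c = asym[e2].first, d = asym[e2].second;
      if (a == d || c == b) continue;
      if (occupied(a, d) || occupied(c, b)) continue;
      if (ukey(a, d, N) == ukey(c, b, N)) continue;
      pst[ukey(a, b, N)] = 0; pst[ukey(c, d, N)] = 0;
      pst[ukey(a, d, N)] = 2; pst[ukey(c, b, N)] = 2;
      asym[e1] = {a, d}; asym[e2] = {c, b};
      accepted++;
    }
  }
  IntegerMatrix out(2 * nSym + nAsym, 2);
  int row = 0;
  for (auto& p : sym) {
    out(row, 0) = p.first; out(row, 1) = p.second; row++;
    out(row, 0) = p.second; out(row, 1) = p.first; row++;
  }
  for (auto& p : asym) { out(row, 0) = p.first; out(row, 1) = p.second; row++; }
  return List::create(_["edges"] = out, _["accepted"] = accepted);
}
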