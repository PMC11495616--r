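// Stochastic greedy motif-set search.
//
// Maintains the reduction state (multigraph H, supernodes, motif multiset)
// together with running sufficient statistics for the four microcanonical
// base codes, so the codelength gain of a candidate contraction is evaluated
// incrementally in O(boundary size). The R layer provides a naive
// full-recomputation reference against which these incremental gains are
// validated (trajectory replay and per-candidate logs).
//
// Families: 0 = ER, 1 = CM, 2 = RER, 3 = RCM (multigraph base codes).

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <algorithm>
#include <random>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const double LN2C = 0.6931471805599453;

// lgamma lookup tables for the small integer / half-integer arguments that
// dominate the incremental codelength updates
static const int LFCAP = 1 << 14;
static std::vector<double> lfTab;      // lfTab[n] = log2(n!)
static std::vector<double> lgHalfTab;  // lgHalfTab[c] = lgamma(0.5 + c)
static void ensureTables() {
  if (!lfTab.empty()) return;
  lfTab.resize(LFCAP);
  lgHalfTab.resize(LFCAP);
  for (int n = 0; n < LFCAP; ++n) {
    lfTab[n] = std::lgamma(n + 1.0) / LN2C;
    lgHalfTab[n] = std::lgamma(0.5 + n);
  }
}

static inline double lf(double n) {            // log2(n!)
  int i = (int)n;
  if (i >= 0 && i < LFCAP && (double)i == n) return lfTab[i];
  return std::lgamma(n + 1.0) / LN2C;
}
static inline double lgammaHalfPlus(long long c) { // lgamma(0.5 + c)
  if (c >= 0 && c < LFCAP) return lgHalfTab[c];
  return std::lgamma(0.5 + (double)c);
}
static inline double log2choose(double n, double r) {
  if (r <= 0 || r >= n) return 0.0;
  return lf(n) - lf(r) - lf(n - r);
}
static inline double LNint(double n) {          // universal integer code, n >= 1
  return std::log2(n * (n + 1.0));
}
static inline double LNg(double n) {            // zero-guarded variant
  double m = n < 1 ? 1.0 : n;
  return std::log2(m * (m + 1.0));
}

struct Hist {
  std::vector<long long> c;
  void add(int v, long long d) {
    if (v >= (int)c.size()) c.resize(v + 1, 0);
    c[v] += d;
  }
};

// L_seq over the value multiset of the alive nodes, held as a histogram
static double seqCodeLength(const Hist& h, long long n) {
  if (n <= 0) return 0.0;
  int lo = -1, hi = -1;
  for (int v = 0; v < (int)h.c.size(); ++v)
    if (h.c[v] > 0) { if (lo < 0) lo = v; hi = v; }
  if (lo < 0) return 0.0;
  int K = hi - lo + 1;
  double best = (double)n * std::log2((double)K) + LNg(hi) + LNg(lo);
  {
    // lambda = 1: lgamma(1 + c) = log(c!)
    double L = (-std::lgamma((double)K) + std::lgamma((double)n + K)) / LN2C;
    for (int v = lo; v <= hi; ++v) L -= lf((double)h.c[v]);
    if (L < best) best = L;
  }
  {
    const double lgHalf = 0.5723649429247001; // lgamma(1/2)
    double Lam = 0.5 * K;
    double L = -std::lgamma(Lam) + std::lgamma((double)n + Lam);
    for (int v = lo; v <= hi; ++v) L -= lgammaHalfPlus(h.c[v]) - lgHalf;
    L /= LN2C;
    if (L < best) best = L;
  }
  return best + std::log2(3.0) + LNint((double)n);
}

namespace {

struct Engine {
  int NG;
  int family;
  double gammaTotal;
  std::vector<int> gN;
  std::vector<double> gOrient;

  int maxNodes, nextId;
  std::vector<char> alive, isSuper;
  std::vector<int> superSize, superGamma;
  std::vector<double> superRew;
  std::vector<std::unordered_map<int,int>> outAdj, inAdj; // inAdj[i][l] = A_{l i}
  std::vector<int> kout, kin, kapm, kapp, kapmi;

  long long Nh, E, Em, Ed;
  double SlogA, SlogSym, SlogAsym, SlfK, SlfKappa, sumRew, sumOrient;
  Hist hkout, hkin, hkapm, hkapp, hkapmi;

  std::vector<long long> mcount;
  long long sS, sA, mmax;
  double SlfM;

  double Lcur;

  std::vector<char> inSub;
  std::vector<int> nbrPos;
  struct Rec {
    int l;
    int newOut, newIn;
    int oldSym, oldAsymFromL, oldAsymToL;
    double oldRewL;
  };
  std::vector<Rec> recs;

  void init(int N, const IntegerMatrix& edges, int famIn, double gammaTotalIn,
            const IntegerVector& gn, const NumericVector& gorient) {
    ensureTables();
    NG = N; family = famIn; gammaTotal = gammaTotalIn;
    gN.assign(gn.begin(), gn.end());
    gOrient.assign(gorient.begin(), gorient.end());
    maxNodes = N + N / 2 + 2;
    nextId = N;
    alive.assign(maxNodes, 0); isSuper.assign(maxNodes, 0);
    superSize.assign(maxNodes, 1); superGamma.assign(maxNodes, -1);
    superRew.assign(maxNodes, 0.0);
    outAdj.assign(maxNodes, {}); inAdj.assign(maxNodes, {});
    kout.assign(maxNodes, 0); kin.assign(maxNodes, 0);
    kapm.assign(maxNodes, 0); kapp.assign(maxNodes, 0); kapmi.assign(maxNodes, 0);
    for (int i = 0; i < N; ++i) alive[i] = 1;
    for (int e = 0; e < edges.nrow(); ++e) {
      int i = edges(e, 0), j = edges(e, 1);
      outAdj[i][j] = 1;
      inAdj[j][i] = 1;
      kout[i]++; kin[j]++;
    }
    Nh = N; E = edges.nrow(); Em = 0; Ed = 0;
    SlogA = SlogSym = SlogAsym = 0.0;
    SlfK = SlfKappa = sumRew = sumOrient = 0.0;
    for (int i = 0; i < N; ++i) {
      int km = 0;
      for (auto& pr : outAdj[i]) {
        int j = pr.first;
        auto it = outAdj[j].find(i);
        if (it != outAdj[j].end()) { km += 1; if (i < j) Em += 1; }
      }
      kapm[i] = km;
      kapp[i] = kout[i] - km;
      kapmi[i] = kin[i] - km;
      Ed += kapp[i];
      SlfK += lf(kout[i]) + lf(kin[i]);
      SlfKappa += lf(kapm[i]) + lf(kapp[i]) + lf(kapmi[i]);
      hkout.add(kout[i], 1); hkin.add(kin[i], 1);
      hkapm.add(kapm[i], 1); hkapp.add(kapp[i], 1); hkapmi.add(kapmi[i], 1);
    }
    mcount.assign(gN.size(), 0);
    sS = sA = 0; mmax = 0; SlfM = 0.0;
    inSub.assign(maxNodes, 0);
    nbrPos.assign(maxNodes, -1);
    Lcur = totalL();
  }

  double baseL(long long NhV, long long EV, long long EmV, long long EdV,
               double SlogAV, double SlogSymV, double SlogAsymV,
               double SlfKV, double SlfKappaV) const {
    double S = 0.0, Lphi = 0.0;
    double P2 = (double)NhV * ((double)NhV - 1.0);
    switch (family) {
    case 0:
      S = (EV > 0 ? (double)EV * std::log2(P2) : 0.0) - lf((double)EV) + SlogAV;
      Lphi = LNg((double)NhV) + LNg((double)EV);
      break;
    case 1:
      S = lf((double)EV) - SlfKV + SlogAV;
      Lphi = seqCodeLength(hkout, NhV) + seqCodeLength(hkin, NhV);
      break;
    case 2:
      S = ((EmV + EdV) > 0 ? (double)(EmV + EdV) * std::log2(P2) : 0.0)
        - ((double)EmV + lf((double)EmV)) - lf((double)EdV) + SlogSymV + SlogAsymV;
      Lphi = LNg((double)NhV) + LNg((double)EmV) + LNg((double)EdV);
      break;
    case 3:
      S = (lf(2.0 * EmV) - (double)EmV - lf((double)EmV)) + lf((double)EdV)
        - SlfKappaV + SlogSymV + SlogAsymV;
      Lphi = seqCodeLength(hkapm, NhV) + seqCodeLength(hkapp, NhV) + seqCodeLength(hkapmi, NhV);
      break;
    }
    return S + Lphi;
  }

  double motifSetL(long long sAv, long long mmaxv, long long sSv) const {
    if (sSv == 0) return 0.0;
    return (double)sAv * std::log2(gammaTotal) + LNint(gammaTotal)
         + (double)sAv * std::log2((double)mmaxv) + LNint((double)mmaxv);
  }
  double labelsL(long long NhV, long long sSv, double SlfMv) const {
    if (sSv == 0) return 0.0;
    return log2choose((double)NhV, (double)sSv) + (lf((double)sSv) - SlfMv);
  }

  double totalL() const {
    return motifSetL(sA, mmax, sS)
         + baseL(Nh, E, Em, Ed, SlogA, SlogSym, SlogAsym, SlfK, SlfKappa)
         + labelsL(Nh, sS, SlfM)
         + (lf((double)NG) - lf((double)Nh)) + sumOrient + sumRew;
  }

  // Evaluate (apply = false) or perform (apply = true) the contraction of the
  // k-node subset `sub`, classified as graphlet g. Returns L(before) - L(after).
  double evalContraction(const int* sub, int k, int g, bool apply) {
    for (int a = 0; a < k; ++a) inSub[sub[a]] = 1;

    recs.clear();
    int intAdj[5][5] = {{0}};
    long long eInt = 0;
    double dSlogA = 0, dSlogSym = 0, dSlogAsym = 0, dSlfK = 0, dSlfKappa = 0;
    long long dEm = 0, dEd = 0;

    auto addPair = [&](int i, int l, int aout, int ain) {
      (void)i;
      int pos = nbrPos[l];
      if (pos < 0 || pos >= (int)recs.size() || recs[pos].l != l) {
        nbrPos[l] = (int)recs.size();
        recs.push_back({l, 0, 0, 0, 0, 0, 0.0});
        pos = nbrPos[l];
      }
      Rec& r = recs[pos];
      int sym = std::min(aout, ain);
      r.newOut += aout;
      r.newIn += ain;
      r.oldSym += sym;
      r.oldAsymToL += aout - sym;   // A^asym_{i,l}
      r.oldAsymFromL += ain - sym;  // A^asym_{l,i}
      if (isSuper[l]) {
        int nl = superSize[l];
        r.oldRewL += log2choose((double)nl, ain) + log2choose((double)nl, aout);
      }
      dSlogA -= lf(aout) + lf(ain);
      dSlogSym -= lf(sym);
      dSlogAsym -= lf(aout - sym) + lf(ain - sym);
    };

    for (int a = 0; a < k; ++a) {
      int i = sub[a];
      for (auto& pr : outAdj[i]) {
        int l = pr.first, aout = pr.second;
        if (inSub[l]) {
          int b = 0; while (sub[b] != l) ++b;
          intAdj[a][b] = aout;
          eInt += aout;
          continue;
        }
        auto it = inAdj[i].find(l);
        int ain = (it == inAdj[i].end()) ? 0 : it->second;
        addPair(i, l, aout, ain);
      }
      for (auto& pr : inAdj[i]) {
        int l = pr.first, ain = pr.second;
        if (inSub[l]) continue;
        if (outAdj[i].count(l)) continue; // handled above
        addPair(i, l, 0, ain);
      }
    }

    for (int a = 0; a < k; ++a)
      for (int b = a + 1; b < k; ++b) {
        int s = std::min(intAdj[a][b], intAdj[b][a]);
        dEm -= s;
        dEd -= (intAdj[a][b] - s) + (intAdj[b][a] - s);
      }

    struct Move { Hist* h; int v; int d; };
    std::vector<Move> moves;
    const bool needK = (family == 1);
    const bool needKap = (family == 3);

    int skout = 0, skin = 0, skapm = 0, skapp = 0, skapmi = 0;
    double newRew = 0.0, dRewOthers = 0.0;
    for (auto& r : recs) {
      dEm -= r.oldSym;
      dEd -= r.oldAsymFromL + r.oldAsymToL;
      int newSym = std::min(r.newOut, r.newIn);
      int newAsymOut = r.newOut - newSym; // A^asym_{s,l}
      int newAsymIn = r.newIn - newSym;   // A^asym_{l,s}
      dEm += newSym;
      dEd += newAsymOut + newAsymIn;
      dSlogSym += lf(newSym);
      dSlogAsym += lf(newAsymOut) + lf(newAsymIn);
      dSlogA += lf(r.newOut) + lf(r.newIn);
      skout += r.newOut; skin += r.newIn;
      skapm += newSym; skapp += newAsymOut; skapmi += newAsymIn;
      int dkm = newSym - r.oldSym;
      int dkp = newAsymIn - r.oldAsymFromL;  // kappa+_l counts A^asym_{l,*}
      int dkmi = newAsymOut - r.oldAsymToL;  // kappa-_l counts A^asym_{*,l}
      if (dkm || dkp || dkmi) {
        int l = r.l;
        dSlfKappa += lf(kapm[l] + dkm) - lf(kapm[l])
                   + lf(kapp[l] + dkp) - lf(kapp[l])
                   + lf(kapmi[l] + dkmi) - lf(kapmi[l]);
        if (needKap) {
          if (dkm)  { moves.push_back({&hkapm,  kapm[l], -1});  moves.push_back({&hkapm,  kapm[l] + dkm, 1}); }
          if (dkp)  { moves.push_back({&hkapp,  kapp[l], -1});  moves.push_back({&hkapp,  kapp[l] + dkp, 1}); }
          if (dkmi) { moves.push_back({&hkapmi, kapmi[l], -1}); moves.push_back({&hkapmi, kapmi[l] + dkmi, 1}); }
        }
      }
      if (isSuper[r.l]) {
        int nl = superSize[r.l];
        newRew += log2choose((double)k * nl, r.newOut);
        dRewOthers += log2choose((double)nl * k, r.newIn) - r.oldRewL;
      } else {
        newRew += log2choose((double)k, r.newOut) + log2choose((double)k, r.newIn);
      }
    }

    for (int a = 0; a < k; ++a) {
      int i = sub[a];
      dSlfK -= lf(kout[i]) + lf(kin[i]);
      dSlfKappa -= lf(kapm[i]) + lf(kapp[i]) + lf(kapmi[i]);
      if (needK) {
        moves.push_back({&hkout, kout[i], -1});
        moves.push_back({&hkin, kin[i], -1});
      }
      if (needKap) {
        moves.push_back({&hkapm, kapm[i], -1});
        moves.push_back({&hkapp, kapp[i], -1});
        moves.push_back({&hkapmi, kapmi[i], -1});
      }
    }

    dSlfK += lf(skout) + lf(skin);
    dSlfKappa += lf(skapm) + lf(skapp) + lf(skapmi);
    if (needK) {
      moves.push_back({&hkout, skout, 1});
      moves.push_back({&hkin, skin, 1});
    }
    if (needKap) {
      moves.push_back({&hkapm, skapm, 1});
      moves.push_back({&hkapp, skapp, 1});
      moves.push_back({&hkapmi, skapmi, 1});
    }

    long long Nh2 = Nh - (k - 1);
    long long E2 = E - eInt;
    long long Em2 = Em + dEm, Ed2 = Ed + dEd;
    long long m2 = mcount[g] + 1;
    long long sS2 = sS + 1;
    long long sA2 = sA + (mcount[g] == 0 ? 1 : 0);
    long long mmax2 = std::max(mmax, m2);
    double SlfM2 = SlfM + lf((double)m2) - lf((double)mcount[g]);
    double sumRew2 = sumRew + newRew + dRewOthers;
    double sumOrient2 = sumOrient + gOrient[g];

    for (auto& mv : moves) mv.h->add(mv.v, mv.d);
    double Lafter = motifSetL(sA2, mmax2, sS2)
      + baseL(Nh2, E2, Em2, Ed2, SlogA + dSlogA, SlogSym + dSlogSym,
              SlogAsym + dSlogAsym, SlfK + dSlfK, SlfKappa + dSlfKappa)
      + labelsL(Nh2, sS2, SlfM2)
      + (lf((double)NG) - lf((double)Nh2)) + sumOrient2 + sumRew2;

    if (!apply) {
      for (auto& mv : moves) mv.h->add(mv.v, -mv.d);
      for (int a = 0; a < k; ++a) inSub[sub[a]] = 0;
      return Lcur - Lafter;
    }

    int id = nextId++;
    if (id >= maxNodes) stop("supernode id overflow");
    for (int a = 0; a < k; ++a) {
      int i = sub[a];
      for (auto& pr : outAdj[i]) if (!inSub[pr.first]) inAdj[pr.first].erase(i);
      for (auto& pr : inAdj[i])  if (!inSub[pr.first]) outAdj[pr.first].erase(i);
      alive[i] = 0;
      outAdj[i].clear(); inAdj[i].clear();
      kout[i] = kin[i] = kapm[i] = kapp[i] = kapmi[i] = 0;
    }
    alive[id] = 1; isSuper[id] = 1;
    superSize[id] = k; superGamma[id] = g; superRew[id] = newRew;
    kout[id] = skout; kin[id] = skin;
    kapm[id] = skapm; kapp[id] = skapp; kapmi[id] = skapmi;
    for (auto& r : recs) {
      if (r.newOut > 0) { outAdj[id][r.l] = r.newOut; inAdj[r.l][id] = r.newOut; }
      if (r.newIn > 0)  { inAdj[id][r.l] = r.newIn;  outAdj[r.l][id] = r.newIn; }
      int newSym = std::min(r.newOut, r.newIn);
      kapm[r.l] += newSym - r.oldSym;
      kapp[r.l] += (r.newIn - newSym) - r.oldAsymFromL;
      kapmi[r.l] += (r.newOut - newSym) - r.oldAsymToL;
      if (isSuper[r.l]) {
        int nl = superSize[r.l];
        superRew[r.l] += log2choose((double)nl * k, r.newIn) - r.oldRewL;
      }
    }
    Nh = Nh2; E = E2; Em = Em2; Ed = Ed2;
    SlogA += dSlogA; SlogSym += dSlogSym; SlogAsym += dSlogAsym;
    SlfK += dSlfK; SlfKappa += dSlfKappa;
    sumRew = sumRew2; sumOrient = sumOrient2;
    mcount[g] = m2; sS = sS2; sA = sA2; mmax = mmax2; SlfM = SlfM2;
    double gain = Lcur - Lafter;
    Lcur = Lafter;
    for (int a = 0; a < k; ++a) inSub[sub[a]] = 0;
    return gain;
  }
};

} // namespace

// census_subsets: per graphlet, flattened sorted node subsets (0-based)
// [[Rcpp::export(name = ".greedy_run_cpp")]]
List greedy_run_cpp(int N, IntegerMatrix edges, int family, double gamma_total,
                    IntegerVector gamma_n, NumericVector gamma_orient,
                    List census_subsets, int B, int seed,
                    int log_candidates) {
  int G = gamma_n.size();
  Engine eng;
  eng.init(N, edges, family, gamma_total, gamma_n, gamma_orient);

  // census views: per graphlet, vector of surviving subset indices
  std::vector<const int*> data(G, nullptr);
  std::vector<long long> nOcc(G, 0);
  std::vector<std::vector<int>> aliveIdx(G);
  for (int g = 0; g < G; ++g) {
    IntegerVector v = census_subsets[g];
    int k = gamma_n[g];
    long long cnt = v.size() / k;
    data[g] = INTEGER(v);
    nOcc[g] = cnt;
    aliveIdx[g].resize(cnt);
    for (long long i = 0; i < cnt; ++i) aliveIdx[g][i] = (int)i;
  }
  std::vector<long long> aliveN(G);
  for (int g = 0; g < G; ++g) aliveN[g] = nOcc[g];

  std::mt19937 gen((uint32_t)seed);
  auto rnd = [&](long long m) -> long long { return (long long)(gen() % (uint64_t)m); };

  std::vector<double> trajectory;
  trajectory.push_back(eng.Lcur);
  std::vector<int> contrG;
  std::vector<double> contrGain;
  std::vector<IntegerVector> contrSubs;
  std::vector<int> candIter, candG;
  std::vector<double> candGain;
  std::vector<IntegerVector> candSubs;

  struct Cand { int g; int idx; const int* s; };
  std::vector<Cand> batch;

  int iter = 0;
  for (;;) {
    // Sample up to B non-overlapping occurrences per graphlet, without
    // replacement within the batch. Draws that overlap a supernode are
    // discarded permanently; unselected batch members return to the
    // surviving pool after the contraction, so the search only terminates
    // when no occurrence free of supernodes is left.
    batch.clear();
    for (int g = 0; g < G; ++g) {
      int k = eng.gN[g];
      int taken = 0;
      while (taken < B && aliveN[g] > 0) {
        long long r = rnd(aliveN[g]);
        int idx = aliveIdx[g][r];
        aliveIdx[g][r] = aliveIdx[g][aliveN[g] - 1];
        aliveN[g]--;
        const int* s = data[g] + (long long)idx * k;
        bool ok = true;
        for (int a = 0; a < k; ++a) if (!eng.alive[s[a]]) { ok = false; break; }
        if (ok) { batch.push_back({g, idx, s}); taken++; }
      }
    }
    if (batch.empty()) break;
    iter++;

    int bestG = -1;
    const int* bestS = nullptr;
    double bestGain = 0.0;
    for (auto& c : batch) {
      int k = eng.gN[c.g];
      double gain = eng.evalContraction(c.s, k, c.g, false);
      if ((int)candIter.size() < log_candidates) {
        candIter.push_back(iter);
        candG.push_back(c.g);
        candGain.push_back(gain);
        candSubs.push_back(IntegerVector(c.s, c.s + k));
      }
      bool better = false;
      if (bestG < 0 || gain > bestGain) better = true;
      else if (gain == bestGain) {
        if (c.g < bestG) better = true;
        else if (c.g == bestG) {
          for (int a = 0; a < k; ++a) {
            if (c.s[a] < bestS[a]) { better = true; break; }
            if (c.s[a] > bestS[a]) break;
          }
        }
      }
      if (better) { bestG = c.g; bestS = c.s; bestGain = gain; }
    }

    int k = eng.gN[bestG];
    eng.evalContraction(bestS, k, bestG, true);
    trajectory.push_back(eng.Lcur);
    contrG.push_back(bestG);
    contrGain.push_back(bestGain);
    contrSubs.push_back(IntegerVector(bestS, bestS + k));
    // return unselected batch members to the pool (the contracted one's
    // nodes are absorbed now, so it would be dropped on any later draw)
    for (auto& c : batch) {
      if (c.s == bestS) continue;
      aliveIdx[c.g][aliveN[c.g]++] = c.idx;
    }
    if (iter % 64 == 0) Rcpp::checkUserInterrupt();
  }

  int bestIter = 0;
  double bestL = trajectory[0];
  for (int t = 1; t < (int)trajectory.size(); ++t)
    if (trajectory[t] < bestL) { bestL = trajectory[t]; bestIter = t; }

  return List::create(
    _["trajectory"] = NumericVector(trajectory.begin(), trajectory.end()),
    _["contraction_graphlet"] = IntegerVector(contrG.begin(), contrG.end()),
    _["contraction_gain"] = NumericVector(contrGain.begin(), contrGain.end()),
    _["contraction_subsets"] = List(contrSubs.begin(), contrSubs.end()),
    _["best_iteration"] = bestIter,
    _["candidate_iter"] = IntegerVector(candIter.begin(), candIter.end()),
    _["candidate_graphlet"] = IntegerVector(candG.begin(), candG.end()),
    _["candidate_gain"] = NumericVector(candGain.begin(), candGain.end()),
    _["candidate_subsets"] = List(candSubs.begin(), candSubs.end()));
}
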