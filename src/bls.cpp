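// Breakout local search for the constrained maximum-weight clique over the
// compatibility graph: exactly one secondary-structure vertex per strand,
// any number of interaction vertices, weak cliques (zero base pairs)
// forbidden. Every distinct valid clique encountered anywhere in the search
// is archived as a candidate sub-optimal complex.
//
// The graph is small (tens of vertices) but the search runs hundreds of
// iterations over many restarts and instances, so the inner loop lives here.

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cstdint>
using namespace Rcpp;

namespace {

// xorshift64* -- deterministic across platforms, seeded from SolverConfig
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform integer in [0, k)
  int below(int k) { return (int)(next() % (uint64_t)k); }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct Move { int type; int v; int u; double delta; };
// type: 0 add, 1 replace, 2 remove

struct Solver {
  int n, nStrands;
  std::vector<char> adj;          // n*n
  std::vector<int> kind;          // 0 structure, 1 interaction
  std::vector<int> strandIdx;     // 0-based, -1 for interactions
  std::vector<double> w;
  std::vector<int> np;

  std::vector<char> inC;
  std::vector<int> cnt;           // members adjacent to each vertex
  std::vector<int> structOf;      // per strand, its structure vertex in C
  int sizeC;
  double weightC;
  long pairsC;
  std::vector<long> tabuUntil;
  long iter;

  std::set<std::vector<int>> seen;
  std::vector<std::vector<int>> archMembers;
  std::vector<double> archWeights;

  bool A(int i, int j) const { return adj[(size_t)i * n + j] != 0; }

  void reset() {
    inC.assign(n, 0); cnt.assign(n, 0);
    structOf.assign(nStrands, -1);
    sizeC = 0; weightC = 0.0; pairsC = 0;
  }

  void addV(int v) {
    inC[v] = 1; sizeC++; weightC += w[v]; pairsC += np[v];
    if (kind[v] == 0) structOf[strandIdx[v]] = v;
    for (int u = 0; u < n; ++u) if (A(v, u)) cnt[u]++;
  }
  void remV(int v) {
    inC[v] = 0; sizeC--; weightC -= w[v]; pairsC -= np[v];
    if (kind[v] == 0 && structOf[strandIdx[v]] == v) structOf[strandIdx[v]] = -1;
    for (int u = 0; u < n; ++u) if (A(v, u)) cnt[u]--;
  }

  void archive() {
    std::vector<int> m;
    m.reserve(sizeC);
    for (int v = 0; v < n; ++v) if (inC[v]) m.push_back(v);
    if (seen.insert(m).second) {
      archMembers.push_back(m);
      archWeights.push_back(weightC);
    }
  }

  // find the unique member not adjacent to v (valid when cnt[v] == sizeC-1)
  int missingMember(int v) const {
    for (int u = 0; u < n; ++u) if (inC[u] && !A(v, u)) return u;
    return -1;
  }

  void applyMove(const Move& mv) {
    if (mv.type == 0) { addV(mv.v); }
    else if (mv.type == 1) { remV(mv.u); addV(mv.v); tabuUntil[mv.u] = iter + /*phi*/ phi_; }
    else { remV(mv.v); tabuUntil[mv.v] = iter + phi_; }
    archive();
  }

  long phi_;

  // enumerate legal moves. improvingOnly: descent (adds/replaces with
  // delta > 0, tabu ignored). Otherwise perturbation: all non-tabu
  // add/replace/remove moves, optionally filtered by the directed-
  // perturbation acceptance rules.
  void legalMoves(std::vector<Move>& out, bool improvingOnly,
                  bool directedFilter, double alphaS, double alphaR) {
    out.clear();
    for (int v = 0; v < n; ++v) {
      if (inC[v]) continue;
      bool tabu = tabuUntil[v] > iter;
      if (cnt[v] == sizeC && kind[v] == 1) {           // add
        if (improvingOnly) { if (w[v] > 0) out.push_back({0, v, -1, w[v]}); }
        else if (!tabu) out.push_back({0, v, -1, w[v]});
      } else if (cnt[v] == sizeC - 1) {                // replace
        int u = missingMember(v);
        if (u < 0 || kind[u] != kind[v]) continue;
        double d = w[v] - w[u];
        if (pairsC - np[u] + np[v] <= 0) continue;     // weak: never offered
        if (improvingOnly) { if (d > 0) out.push_back({1, v, u, d}); }
        else if (!tabu) {
          if (directedFilter && d < 0 && weightC > 0 &&
              (weightC + d) / weightC < alphaS) continue;
          out.push_back({1, v, u, d});
        }
      }
    }
    if (!improvingOnly) {
      for (int v = 0; v < n; ++v) {
        if (!inC[v] || kind[v] != 1) continue;         // remove: interactions only
        if (pairsC - np[v] <= 0) continue;             // weak
        if (directedFilter && w[v] > (1.0 - alphaR) * weightC) continue;
        out.push_back({2, v, -1, -w[v]});
      }
    }
  }

  // pick uniformly among moves attaining the maximum delta
  int bestMove(const std::vector<Move>& mv, Rng& rng) {
    double best = -1e300; int nb = 0; int pick = -1;
    for (size_t k = 0; k < mv.size(); ++k) {
      if (mv[k].delta > best + 1e-12) { best = mv[k].delta; nb = 1; pick = (int)k; }
      else if (mv[k].delta > best - 1e-12) { nb++; if (rng.below(nb) == 0) pick = (int)k; }
    }
    return pick;
  }

  // C = one random interaction + one compatible structure per strand
  // (the empty structure guarantees feasibility)
  void initialClique(Rng& rng) {
    reset();
    std::vector<int> inter;
    for (int v = 0; v < n; ++v) if (kind[v] == 1) inter.push_back(v);
    addV(inter[rng.below((int)inter.size())]);
    for (int s = 0; s < nStrands; ++s) {
      std::vector<int> ok;
      for (int v = 0; v < n; ++v)
        if (kind[v] == 0 && strandIdx[v] == s && cnt[v] == sizeC)
          ok.push_back(v);
      addV(ok[rng.below((int)ok.size())]);
    }
    archive();
  }

  // best-improvement descent over add/replace; returns end weight
  void descend(Rng& rng) {
    std::vector<Move> mv;
    for (;;) {
      legalMoves(mv, true, false, 0, 0);
      if (mv.empty()) break;
      applyMove(mv[bestMove(mv, rng)]);
    }
  }

  // strong perturbation: force a random outside interaction in, repair
  // structures (empty fallback), drop interactions that no longer fit
  void restart(Rng& rng) {
    std::vector<int> oc;
    for (int v = 0; v < n; ++v) if (kind[v] == 1 && !inC[v]) oc.push_back(v);
    if (oc.empty()) return;
    int vNew = oc[rng.below((int)oc.size())];

    std::vector<int> oldStruct(structOf), oldInter;
    for (int v = 0; v < n; ++v) if (inC[v] && kind[v] == 1) oldInter.push_back(v);

    reset();
    addV(vNew);
    for (int s = 0; s < nStrands; ++s) {
      int keep = oldStruct[s];
      if (keep >= 0 && cnt[keep] == sizeC) { addV(keep); continue; }
      std::vector<int> ok;
      for (int v = 0; v < n; ++v)
        if (kind[v] == 0 && strandIdx[v] == s && cnt[v] == sizeC)
          ok.push_back(v);
      addV(ok[rng.below((int)ok.size())]);
    }
    for (size_t k = 0; k < oldInter.size(); ++k) {
      int v = oldInter[k];
      if (v != vNew && cnt[v] == sizeC) addV(v);
      else if (v != vNew) tabuUntil[v] = iter + phi_;
    }
    archive();
  }

  void perturb(Rng& rng, int L, long T, long& omega, double alphaS,
               double alphaR, double p0) {
    if (omega > T) { restart(rng); omega = 0; return; }
    bool directed = rng.unif() < p0;
    std::vector<Move> mv;
    for (int step = 0; step < L; ++step) {
      legalMoves(mv, false, directed, alphaS, alphaR);
      if (mv.empty()) { restart(rng); return; }
      if (directed) applyMove(mv[bestMove(mv, rng)]);
      else applyMove(mv[rng.below((int)mv.size())]);
    }
  }
};

Solver makeSolver(const LogicalMatrix& adj, const IntegerVector& kind,
                  const IntegerVector& strandIdx, const NumericVector& w,
                  const IntegerVector& np, int nStrands, long phi) {
  Solver S;
  S.n = adj.nrow();
  S.nStrands = nStrands;
  S.adj.assign((size_t)S.n * S.n, 0);
  for (int i = 0; i < S.n; ++i)
    for (int j = 0; j < S.n; ++j)
      S.adj[(size_t)i * S.n + j] = adj(i, j) ? 1 : 0;
  S.kind = std::vector<int>(kind.begin(), kind.end());
  S.strandIdx = std::vector<int>(strandIdx.begin(), strandIdx.end());
  S.w = std::vector<double>(w.begin(), w.end());
  S.np = std::vector<int>(np.begin(), np.end());
  S.tabuUntil.assign(S.n, 0);
  S.iter = 0;
  S.phi_ = phi;
  return S;
}

List archiveToList(const Solver& S) {
  int m = (int)S.archMembers.size();
  List members(m);
  NumericVector weights(m);
  for (int k = 0; k < m; ++k) {
    IntegerVector ids((int)S.archMembers[k].size());
    for (size_t t = 0; t < S.archMembers[k].size(); ++t)
      ids[t] = S.archMembers[k][t] + 1;                // 1-based for R
    members[k] = ids;
    weights[k] = S.archWeights[k];
  }
  return List::create(_["members"] = members, _["weight"] = weights);
}

} // namespace

// [[Rcpp::export(name = ".bls_run")]]
List bls_run(LogicalMatrix adj, IntegerVector kind, IntegerVector strandIdx,
             NumericVector weight, IntegerVector nPairs, int nStrands,
             int maxIterations, int restarts, double lFrac, int T,
             double alphaS, double alphaR, int phi, double p0,
             double seed) {
  Solver S = makeSolver(adj, kind, strandIdx, weight, nPairs, nStrands, phi);
  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0x1234ABCDULL);
  int L = (int)std::ceil(lFrac * S.n);
  if (L < 1) L = 1;
  for (int r = 0; r < restarts; ++r) {
    S.tabuUntil.assign(S.n, 0);
    S.iter = 0;
    S.initialClique(rng);
    double bestW = S.weightC;
    long omega = 0;
    for (int it = 0; it < maxIterations; ++it) {
      S.iter = it + 1;
      S.descend(rng);
      if (S.weightC > bestW + 1e-12) { bestW = S.weightC; omega = 0; }
      else omega++;
      S.perturb(rng, L, T, omega, alphaS, alphaR, p0);
    }
  }
  return archiveToList(S);
}

// Random walk over legal moves, exposing the incrementally maintained
// move sets after every step so they can be checked against their
// from-scratch definitions.
// [[Rcpp::export(name = ".bls_trace")]]
List bls_trace(LogicalMatrix adj, IntegerVector kind, IntegerVector strandIdx,
               NumericVector weight, IntegerVector nPairs, int nStrands,
               int nMoves, int phi, double seed) {
  Solver S = makeSolver(adj, kind, strandIdx, weight, nPairs, nStrands, phi);
  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 0x77AB10CDULL);
  S.initialClique(rng);
  List snaps(nMoves);
  std::vector<Move> mv;
  for (int step = 0; step < nMoves; ++step) {
    S.iter = step + 1;
    S.legalMoves(mv, false, false, 0, 0);
    bool didRestart = false;
    if (mv.empty() || rng.unif() < 0.1) { S.restart(rng); didRestart = true; }
    else S.applyMove(mv[rng.below((int)mv.size())]);
    // snapshot C plus incremental PA / OM / OC
    std::vector<int> C, PA, OC, omV, omU;
    for (int v = 0; v < S.n; ++v) {
      if (S.inC[v]) { C.push_back(v + 1); continue; }
      if (S.kind[v] == 1) {
        OC.push_back(v + 1);
        if (S.cnt[v] == S.sizeC) PA.push_back(v + 1);
      }
      if (S.cnt[v] == S.sizeC - 1) {
        int u = S.missingMember(v);
        if (u >= 0 && S.kind[u] == S.kind[v]) { omV.push_back(v + 1); omU.push_back(u + 1); }
      }
    }
    IntegerMatrix OM((int)omV.size(), 2);
    for (size_t t = 0; t < omV.size(); ++t) { OM(t, 0) = omV[t]; OM(t, 1) = omU[t]; }
    snaps[step] = List::create(
      _["members"] = wrap(C), _["PA"] = wrap(PA), _["OM"] = OM,
      _["OC"] = wrap(OC), _["weight"] = S.weightC,
      _["restarted"] = didRestart);
  }
  return snaps;
}
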