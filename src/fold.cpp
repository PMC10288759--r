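// Dynamic-programming secondary-structure engines.
//
// Two engines share the same scaffolding:
//   * maxpair  - Nussinov-style base-pair maximisation
//   * energy   - nearest-neighbour stacking model with a logarithmic
//                hairpin-loop penalty (interior/bulge/multi-loop closures
//                are penalty-free; see the methods vignette)
//
// Circular folding uses the doubled-sequence reduction: fill the tables
// for every window of length n on s+s, take the best cut point, and map
// traceback indices mod n.  Pairs are restricted to nested structures
// (no pseudoknots); hairpin loops must span >= minLoop unpaired bases.
//
// Tie-breaking is deterministic: tables are scanned left to right and the
// traceback prefers pairing the leftmost free base with its smallest
// admissible partner (stack > inner substructure > hairpin inside a
// closed pair).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double NEG_INF = -1e18;
static const double POS_INF = 1e18;

static inline int baseCode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
  }
  return -1;
}

// ordered pair type of (s[i], s[j]); -1 if not an allowed pair
// 0 CG, 1 GC, 2 UA, 3 AU, 4 UG, 5 GU
static inline int pairIndex(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 0 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 2 && b == 3) return 5;
  return -1;
}

struct FoldProblem {
  std::vector<int> s;   // doubled for circular mode
  int n;                // true sequence length
  int m;                // working length (n or 2n)
  int minLoop;
  bool circular;
};

// ---------------------------------------------------------------- maxpair

struct MaxPair {
  const FoldProblem &P;
  std::vector<int> N;   // m x m, 0 below diagonal
  MaxPair(const FoldProblem &p) : P(p), N((size_t)p.m * p.m, 0) {}
  int at(int i, int j) const {
    return (i > j) ? 0 : N[(size_t)i * P.m + j];
  }
  void fill() {
    int m = P.m;
    for (int len = P.minLoop + 2; len <= (P.circular ? P.n : m); ++len) {
      for (int i = 0; i + len - 1 < m; ++i) {
        int j = i + len - 1;
        int best = at(i + 1, j);
        for (int k = i + P.minLoop + 1; k <= j; ++k) {
          if (pairIndex(P.s[i], P.s[k]) < 0) continue;
          int cand = 1 + at(i + 1, k - 1) + at(k + 1, j);
          if (cand > best) best = cand;
        }
        N[(size_t)i * m + j] = best;
      }
    }
  }
  void traceback(int i, int j, std::vector<int> &pt) const {
    while (i <= j) {
      int target = at(i, j);
      if (target == 0) return;
      bool paired = false;
      for (int k = i + P.minLoop + 1; k <= j; ++k) {
        if (pairIndex(P.s[i], P.s[k]) < 0) continue;
        if (1 + at(i + 1, k - 1) + at(k + 1, j) == target) {
          pt[i % P.n] = k % P.n;
          pt[k % P.n] = i % P.n;
          traceback(i + 1, k - 1, pt);
          i = k + 1;
          paired = true;
          break;
        }
      }
      if (!paired) ++i;
    }
  }
};

// ----------------------------------------------------------------- energy

struct EnergyFold {
  const FoldProblem &P;
  const std::vector<double> &stack;  // 6 x 6, row-major [outer][inner]
  double hpA, hpB;                   // hairpin penalty hpA + hpB*log(s/minLoop)
  double closeP;                     // interior/bulge/multi-loop closure penalty
  std::vector<double> V, W;
  EnergyFold(const FoldProblem &p, const std::vector<double> &st,
             double a, double b, double cp)
      : P(p), stack(st), hpA(a), hpB(b), closeP(cp),
        V((size_t)p.m * p.m, POS_INF), W((size_t)p.m * p.m, 0.0) {}
  double hairpin(int size) const {
    return hpA + hpB * std::log((double)size / (double)P.minLoop);
  }
  double v(int i, int j) const {
    return (i > j) ? POS_INF : V[(size_t)i * P.m + j];
  }
  double w(int i, int j) const {
    return (i > j) ? 0.0 : W[(size_t)i * P.m + j];
  }
  void fill() {
    int m = P.m;
    int cap = P.circular ? P.n : m;
    for (int len = 2; len <= cap; ++len) {
      for (int i = 0; i + len - 1 < m; ++i) {
        int j = i + len - 1;
        // V: structure closed by pair (i, j)
        int po = pairIndex(P.s[i], P.s[j]);
        if (po >= 0 && j - i - 1 >= P.minLoop) {
          double best = hairpin(j - i - 1);
          int pi = pairIndex(P.s[i + 1], P.s[j - 1]);
          if (pi >= 0 && v(i + 1, j - 1) < POS_INF / 2) {
            double cand = stack[po * 6 + pi] + v(i + 1, j - 1);
            if (cand < best) best = cand;
          }
          double inner = w(i + 1, j - 1);
          if (inner < 0.0 && inner + closeP < best) best = inner + closeP;
          V[(size_t)i * m + j] = best;
        }
        // W: best over [i, j], empty structure allowed (energy 0)
        double best = w(i + 1, j);
        for (int k = i + P.minLoop + 1; k <= j; ++k) {
          double vk = v(i, k);
          if (vk >= POS_INF / 2) continue;
          double cand = vk + w(k + 1, j);
          if (cand < best) best = cand;
        }
        W[(size_t)i * m + j] = best;
      }
    }
  }
  void traceV(int i, int j, std::vector<int> &pt) const;
  void traceW(int i, int j, std::vector<int> &pt) const {
    while (i <= j) {
      double target = w(i, j);
      if (target >= 0.0) return;  // open chain is optimal here
      bool paired = false;
      for (int k = i + P.minLoop + 1; k <= j; ++k) {
        double vk = v(i, k);
        if (vk >= POS_INF / 2) continue;
        if (vk + w(k + 1, j) == target) {
          traceV(i, k, pt);
          i = k + 1;
          paired = true;
          break;
        }
      }
      if (!paired) ++i;
    }
  }
};

void EnergyFold::traceV(int i, int j, std::vector<int> &pt) const {
  pt[i % P.n] = j % P.n;
  pt[j % P.n] = i % P.n;
  double target = v(i, j);
  int po = pairIndex(P.s[i], P.s[j]);
  int pi = pairIndex(P.s[i + 1], P.s[j - 1]);
  if (pi >= 0 && v(i + 1, j - 1) < POS_INF / 2 &&
      stack[po * 6 + pi] + v(i + 1, j - 1) == target) {
    traceV(i + 1, j - 1, pt);
    return;
  }
  double inner = w(i + 1, j - 1);
  if (inner < 0.0 && inner + closeP == target) {
    traceW(i + 1, j - 1, pt);
    return;
  }
  // hairpin closure: nothing further to trace
}

// ------------------------------------------------------------------ entry

static FoldProblem makeProblem(const std::string &seq, bool circular,
                               int minLoop) {
  FoldProblem P;
  P.n = (int)seq.size();
  P.circular = circular && P.n > 1;
  P.m = P.circular ? 2 * P.n : P.n;
  P.minLoop = minLoop;
  P.s.resize(P.m);
  for (int i = 0; i < P.m; ++i) {
    int c = baseCode(seq[i % P.n]);
    if (c < 0) stop("invalid RNA alphabet");
    P.s[i] = c;
  }
  return P;
}

// [[Rcpp::export(name = ".foldMaxpairC")]]
List foldMaxpairC(std::string seq, bool circular, int minLoop) {
  FoldProblem P = makeProblem(seq, circular, minLoop);
  MaxPair dp(P);
  dp.fill();
  int bestR = 0, best = dp.at(0, P.n - 1);
  if (P.circular) {
    for (int r = 1; r < P.n; ++r)
      if (dp.at(r, r + P.n - 1) > best) { best = dp.at(r, r + P.n - 1); bestR = r; }
  }
  std::vector<int> pt(P.n, -1);
  dp.traceback(bestR, bestR + P.n - 1, pt);
  IntegerVector out(P.n);
  for (int i = 0; i < P.n; ++i) out[i] = pt[i] < 0 ? 0 : pt[i] + 1;
  return List::create(_["pairTable"] = out,
                      _["pairs"] = best,
                      _["dG"] = -(double)best,
                      _["cut"] = bestR);
}

// [[Rcpp::export(name = ".foldEnergyC")]]
List foldEnergyC(std::string seq, bool circular, int minLoop,
                 NumericMatrix stackTable, double hairpinA, double hairpinB,
                 double closePenalty) {
  if (stackTable.nrow() != 6 || stackTable.ncol() != 6)
    stop("stacking table must be 6 x 6");
  FoldProblem P = makeProblem(seq, circular, minLoop);
  std::vector<double> st(36);
  for (int a = 0; a < 6; ++a)
    for (int b = 0; b < 6; ++b)
      st[a * 6 + b] = stackTable(a, b);
  EnergyFold dp(P, st, hairpinA, hairpinB, closePenalty);
  dp.fill();
  int bestR = 0;
  double best = dp.w(0, P.n - 1);
  if (P.circular) {
    for (int r = 1; r < P.n; ++r)
      if (dp.w(r, r + P.n - 1) < best) { best = dp.w(r, r + P.n - 1); bestR = r; }
  }
  std::vector<int> pt(P.n, -1);
  dp.traceW(bestR, bestR + P.n - 1, pt);
  IntegerVector out(P.n);
  int np = 0;
  for (int i = 0; i < P.n; ++i) {
    out[i] = pt[i] < 0 ? 0 : pt[i] + 1;
    if (pt[i] >= 0) ++np;
  }
  return List::create(_["pairTable"] = out,
                      _["pairs"] = np / 2,
                      _["dG"] = best,
                      _["cut"] = bestR);
}
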