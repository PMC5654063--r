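#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Base-pair maximisation folding (Nussinov-style) with an optional stacking
// bonus, over canonical pairs {AU, GC} plus GU wobble when allowed.
//
// Score of a structure = (# pairs) + stacking_bonus * (# stacked pairs),
// where pair (i,j) is stacked if (i+1, j-1) is also paired.
//
// Two tables over intervals [i, j]:
//   M[i][j] : best score of any structure on the interval.
//   P[i][j] : best score given (i, j) is paired (-Inf if not pairable or the
//             hairpin constraint j - i - 1 >= min_hairpin fails).
// Recurrences:
//   P[i][j] = 1 + max(M[i+1][j-1], P[i+1][j-1] + bonus)
//   M[i][j] = max(M[i+1][j], max_k P[i][k] + M[k+1][j])
// Traceback is deterministic: in M, position i is paired with the smallest
// admissible partner k achieving the optimum (unpaired only if no partner
// does); inside a closed pair the stacked continuation is preferred on ties.

static const double NEG = -std::numeric_limits<double>::infinity();
static const double EPS = 1e-9;

// residues encoded 1=A, 2=C, 3=G, 4=U
static inline bool canonical(int a, int b, bool allow_gu) {
  if ((a == 1 && b == 4) || (a == 4 && b == 1)) return true;  // AU
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return true;  // GC
  if (allow_gu && ((a == 3 && b == 4) || (a == 4 && b == 3))) return true;
  return false;
}

class Folder {
public:
  Folder(const IntegerVector& code, int min_hairpin, bool allow_gu,
         double bonus)
      : s(code.begin(), code.end()), n(code.size()), h(min_hairpin),
        gu(allow_gu), w(bonus), M(n * n, 0.0), P(n * n, NEG),
      pairs(code.size(), 0) {}

  void run() {
    for (int span = h + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // P[i][j]
        if (canonical(s[i], s[j], gu)) {
          double inner = (j - i >= 2) ? m(i + 1, j - 1) : 0.0;
          double stacked = (j - i >= 2 && p(i + 1, j - 1) > NEG)
                               ? p(i + 1, j - 1) + w
                               : NEG;
          P[idx(i, j)] = 1.0 + std::max(inner, stacked);
        }
        // M[i][j]
        double best = m(i + 1, j);
        for (int k = i + h + 1; k <= j; ++k) {
          if (P[idx(i, k)] > NEG) {
            double v = P[idx(i, k)] + (k + 1 <= j ? m(k + 1, j) : 0.0);
            if (v > best) best = v;
          }
        }
        M[idx(i, j)] = best;
      }
    }
    if (n > 1) traceM(0, n - 1);
  }

  double score() const { return n > 1 ? M[idx(0, n - 1)] : 0.0; }
  IntegerVector pair_table() const {
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) out[i] = pairs[i];  // 1-based partners, 0 = unpaired
    return out;
  }

private:
  std::vector<int> s;
  int n, h;
  bool gu;
  double w;
  std::vector<double> M, P;
  std::vector<int> pairs;

  inline size_t idx(int i, int j) const { return (size_t)i * n + j; }
  inline double m(int i, int j) const { return (i > j) ? 0.0 : M[idx(i, j)]; }
  inline double p(int i, int j) const { return (i > j) ? NEG : P[idx(i, j)]; }

  void traceM(int i, int j) {
    while (i < j) {
      double target = M[idx(i, j)];
      bool paired = false;
      for (int k = i + h + 1; k <= j; ++k) {
        if (P[idx(i, k)] > NEG &&
            P[idx(i, k)] + (k + 1 <= j ? m(k + 1, j) : 0.0) >= target - EPS) {
          traceP(i, k);
          i = k + 1;  // continue on the suffix
          paired = true;
          break;
        }
      }
      if (!paired) ++i;  // i unpaired
    }
  }

  void traceP(int i, int j) {
    while (true) {
      pairs[i] = j + 1;
      pairs[j] = i + 1;
      double target = P[idx(i, j)];
      double stacked = (j - i >= 2 && p(i + 1, j - 1) > NEG)
                           ? p(i + 1, j - 1) + w
                           : NEG;
      if (stacked >= target - 1.0 - EPS && stacked > NEG) {
        ++i; --j;  // stacked pair continues the helix
      } else {
        if (j - i >= 2) traceM(i + 1, j - 1);
        return;
      }
    }
  }
};

// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(IntegerVector code, int min_hairpin, bool allow_gu,
              double stacking_bonus) {
  Folder f(code, min_hairpin, allow_gu, stacking_bonus);
  f.run();
  return List::create(_["pairs"] = f.pair_table(), _["score"] = f.score());
}
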