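#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand under a simplified
// nearest-neighbour model: stacking energies for canonical (Watson-Crick
// plus G:U) pair stacks, linear hairpin / internal-loop / multiloop
// penalties. Nested structures only, hairpin loops >= min_hairpin,
// internal loops capped at max_internal unpaired bases.
//
// The model is deliberately small enough that an independent enumerator
// can score every nested structure of a short sequence and agree exactly
// with the DP optimum.

static const double INF = 1e9;

// base codes: A=0, C=1, G=2, U/T=3, other=-1
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// pair types: AU=0, UA=1, CG=2, GC=3, GU=4, UG=5, none=-1
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 1 && b == 2) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Params {
  NumericMatrix stack;   // 6 x 6, indexed by pair types (outer, inner)
  double hairpin_a, hairpin_b;
  double internal_a, internal_b;
  double multi_a, multi_b, multi_c;
  int min_hairpin, max_internal;
};

// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq, List par) {
  int n = (int) seq.size();
  Params P;
  P.stack = as<NumericMatrix>(par["stack"]);
  P.hairpin_a = as<double>(par["hairpin_a"]);
  P.hairpin_b = as<double>(par["hairpin_b"]);
  P.internal_a = as<double>(par["internal_a"]);
  P.internal_b = as<double>(par["internal_b"]);
  P.multi_a = as<double>(par["multi_a"]);
  P.multi_b = as<double>(par["multi_b"]);
  P.multi_c = as<double>(par["multi_c"]);
  P.min_hairpin = as<int>(par["min_hairpin"]);
  P.max_internal = as<int>(par["max_internal"]);

  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = base_code(seq[i]);
    if (s[i] < 0) stop("sequence contains a non-ACGTU character");
  }

  if (n == 0) {
    return List::create(_["structure"] = "", _["mfe"] = 0.0,
                        _["pairs"] = IntegerVector(0));
  }

  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF));
  std::vector<std::vector<double> > WM(n, std::vector<double>(n, INF));

  // fill by increasing span
  for (int span = P.min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pt = pair_type(s[i], s[j]);
      if (pt >= 0 && j - i - 1 >= P.min_hairpin) {
        int u = j - i - 1;
        double best = P.hairpin_a + P.hairpin_b * (u - 3); // hairpin closure
        // stack / bulge / internal loop with inner pair (p, q)
        for (int p = i + 1; p < j; ++p) {
          int u1 = p - i - 1;
          if (u1 > P.max_internal) break;
          for (int q = j - 1; q > p; --q) {
            int u2 = j - q - 1;
            int uu = u1 + u2;
            if (uu > P.max_internal) break;
            if (V[p][q] >= INF) continue;
            double e;
            if (uu == 0) {
              int pt2 = pair_type(s[p], s[q]);
              e = P.stack(pt, pt2) + V[p][q];
            } else {
              e = P.internal_a + P.internal_b * uu + V[p][q];
            }
            if (e < best) best = e;
          }
        }
        // multiloop: at least two branches inside
        for (int k = i + 1; k < j - 1; ++k) {
          if (WM[i + 1][k] < INF && WM[k + 1][j - 1] < INF) {
            double e = P.multi_a + WM[i + 1][k] + WM[k + 1][j - 1];
            if (e < best) best = e;
          }
        }
        V[i][j] = best;
      }
      // WM over [i, j]
      double wbest = INF;
      if (j > i) {
        if (WM[i + 1][j] < INF) wbest = std::min(wbest, WM[i + 1][j] + P.multi_c);
        if (WM[i][j - 1] < INF) wbest = std::min(wbest, WM[i][j - 1] + P.multi_c);
      }
      if (V[i][j] < INF) wbest = std::min(wbest, V[i][j] + P.multi_b);
      for (int k = i; k < j; ++k) {
        if (WM[i][k] < INF && WM[k + 1][j] < INF)
          wbest = std::min(wbest, WM[i][k] + WM[k + 1][j]);
      }
      WM[i][j] = wbest;
    }
  }
  // single bases
  for (int i = 0; i < n; ++i) WM[i][i] = INF;

  // external loop
  std::vector<double> W(n + 1, 0.0); // W[k] = best energy of prefix of length k
  for (int j = 0; j < n; ++j) {
    double best = W[j]; // j unpaired
    for (int i = 0; i <= j; ++i) {
      if (V[i][j] < INF) {
        double e = W[i] + V[i][j];
        if (e < best) best = e;
      }
    }
    W[j + 1] = best;
  }

  double mfe = W[n];
  IntegerVector pairs(n, 0); // 1-based partner, 0 = unpaired
  const double EPS = 1e-9;

  if (mfe < -EPS) {
    // traceback
    std::vector<std::pair<std::pair<int,int>, int> > stack_tb;
    // state: 0 = external prefix [0, j), 1 = V(i,j), 2 = WM(i,j)
    // encode external as (j, -1)
    stack_tb.push_back(std::make_pair(std::make_pair(n, -1), 0));
    while (!stack_tb.empty()) {
      std::pair<std::pair<int,int>, int> top = stack_tb.back();
      stack_tb.pop_back();
      int state = top.second;
      if (state == 0) {
        int j = top.first.first; // prefix length
        while (j > 0) {
          if (std::fabs(W[j] - W[j - 1]) < EPS) { --j; continue; }
          bool found = false;
          for (int i = 0; i < j; ++i) {
            if (V[i][j - 1] < INF &&
                std::fabs(W[j] - (W[i] + V[i][j - 1])) < EPS) {
              stack_tb.push_back(std::make_pair(std::make_pair(i, j - 1), 1));
              j = i;
              found = true;
              break;
            }
          }
          if (!found) --j; // numerical safety
        }
      } else if (state == 1) {
        int i = top.first.first, j = top.first.second;
        pairs[i] = j + 1;
        pairs[j] = i + 1;
        int u = j - i - 1;
        double target = V[i][j];
        if (std::fabs(target - (P.hairpin_a + P.hairpin_b * (u - 3))) < EPS)
          continue;
        int pt = pair_type(s[i], s[j]);
        bool found = false;
        for (int p = i + 1; p < j && !found; ++p) {
          int u1 = p - i - 1;
          if (u1 > P.max_internal) break;
          for (int q = j - 1; q > p; --q) {
            int u2 = j - q - 1;
            int uu = u1 + u2;
            if (uu > P.max_internal) break;
            if (V[p][q] >= INF) continue;
            double e;
            if (uu == 0) {
              int pt2 = pair_type(s[p], s[q]);
              e = P.stack(pt, pt2) + V[p][q];
            } else {
              e = P.internal_a + P.internal_b * uu + V[p][q];
            }
            if (std::fabs(target - e) < EPS) {
              stack_tb.push_back(std::make_pair(std::make_pair(p, q), 1));
              found = true;
              break;
            }
          }
        }
        if (found) continue;
        for (int k = i + 1; k < j - 1; ++k) {
          if (WM[i + 1][k] < INF && WM[k + 1][j - 1] < INF &&
              std::fabs(target - (P.multi_a + WM[i + 1][k] + WM[k + 1][j - 1])) < EPS) {
            stack_tb.push_back(std::make_pair(std::make_pair(i + 1, k), 2));
            stack_tb.push_back(std::make_pair(std::make_pair(k + 1, j - 1), 2));
            break;
          }
        }
      } else {
        int i = top.first.first, j = top.first.second;
        double target = WM[i][j];
        if (target >= INF) continue;
        if (V[i][j] < INF && std::fabs(target - (V[i][j] + P.multi_b)) < EPS) {
          stack_tb.push_back(std::make_pair(std::make_pair(i, j), 1));
          continue;
        }
        if (j > i && WM[i + 1][j] < INF &&
            std::fabs(target - (WM[i + 1][j] + P.multi_c)) < EPS) {
          stack_tb.push_back(std::make_pair(std::make_pair(i + 1, j), 2));
          continue;
        }
        if (j > i && WM[i][j - 1] < INF &&
            std::fabs(target - (WM[i][j - 1] + P.multi_c)) < EPS) {
          stack_tb.push_back(std::make_pair(std::make_pair(i, j - 1), 2));
          continue;
        }
        for (int k = i; k < j; ++k) {
          if (WM[i][k] < INF && WM[k + 1][j] < INF &&
              std::fabs(target - (WM[i][k] + WM[k + 1][j])) < EPS) {
            stack_tb.push_back(std::make_pair(std::make_pair(i, k), 2));
            stack_tb.push_back(std::make_pair(std::make_pair(k + 1, j), 2));
            break;
          }
        }
      }
    }
  } else {
    mfe = 0.0;
  }

  std::string db(n, '.');
  for (int i = 0; i < n; ++i) {
    if (pairs[i] > i + 1) db[i] = '(';
    else if (pairs[i] > 0) db[i] = ')';
  }

  return List::create(_["structure"] = db, _["mfe"] = mfe, _["pairs"] = pairs);
}
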