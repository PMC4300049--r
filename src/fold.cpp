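// Zuker-style minimum-free-energy folding for DNA single strands and strand
// pairs.  The pair ("co-fold") case folds the concatenation of the two strands
// with a junction between them: loops whose unpaired region spans the junction
// carry no loop penalty and are exempt from the minimum-hairpin and loop-cap
// rules; a bimolecular initiation term is added by the R wrapper when the MFE
// structure contains an inter-strand pair.
//
// Encoding: A=0, C=1, G=2, T=3; Watson-Crick pairs only (b1 + b2 == 3).
// `cut` is the 0-based index of the first base of the second strand
// (cut == n for a single strand).  All energies are free energies at the
// evaluation temperature, precomputed by the R caller.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double INF = 1e9;
const double EPS = 1e-9;

struct Fold {
  int n, cut, cap;
  const int *s;
  const double *stackG;    // 16, index 4*x + y for 5'-xy-3' step
  const double *hairpinG;  // index by loop size, length >= n
  const double *bulgeG;    // index 1..cap
  const double *internalG; // index 2..cap
  double mlA, mlB, mlC;
  std::vector<double> V, M, WF, J, X2;
  std::vector<double> W;
  std::vector<std::pair<int,int> > pairs;

  double &v(std::vector<double> &a, int i, int j) { return a[(size_t)i * n + j]; }

  bool comp(int i, int j) const { return s[i] + s[j] == 3; }
  bool containsJ(int i, int j) const { return i < cut && j >= cut; }
  bool canPair(int i, int j) const {
    if (j <= i || !comp(i, j)) return false;
    if (containsJ(i, j)) return true;      // inter-strand pair
    return j - i - 1 >= 3;                 // min hairpin for intra pairs
  }
  // junction strictly between loop-adjacent positions p < q
  bool junctionInGap(int p, int q) const { return p < cut && q >= cut; }

  // penalty of the loop between closing pair (i,j) and interior pair (k,l),
  // junction known not to lie in either gap
  double twoLoop(int i, int j, int k, int l) const {
    int g1 = k - i - 1, g2 = j - l - 1;
    if (g1 == 0 && g2 == 0) return stackG[4 * s[i] + s[k]];
    int g = g1 + g2;
    if (g > cap) return INF;
    if (g1 == 0 || g2 == 0) return bulgeG[g];
    return internalG[g];
  }

  void run() {
    size_t nn = (size_t)n * n;
    V.assign(nn, INF); M.assign(nn, INF); WF.assign(nn, 0.0);
    J.assign(nn, INF); X2.assign(nn, INF);

    for (int len = 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        computeV(i, j);
        computeM(i, j);
        computeWF(i, j);
        if (containsJ(i, j)) { computeJ(i, j); computeX2(i, j); }
      }
    }
    W.assign(n + 1, 0.0); // W[j+1] = best for prefix 0..j
    for (int j = 0; j < n; ++j) {
      double best = W[j];
      for (int k = 0; k <= j - 1; ++k)
        if (canPair(k, j) && v(V, k, j) < INF / 2)
          best = std::min(best, W[k] + v(V, k, j));
      W[j + 1] = best;
    }
  }

  void computeV(int i, int j) {
    if (!canPair(i, j)) return;
    double best = INF;
    if (!containsJ(i, j)) {
      // hairpin
      best = hairpinG[j - i - 1];
      // stack / bulge / internal
      for (int k = i + 1; k <= j - 2 && k - i - 1 <= cap; ++k) {
        int g1 = k - i - 1;
        for (int l = j - 1; l > k && (g1 + (j - l - 1)) <= cap; --l) {
          if (!canPair(k, l) || v(V, k, l) > INF / 2) continue;
          best = std::min(best, twoLoop(i, j, k, l) + v(V, k, l));
        }
      }
      // multiloop (>= 2 branches)
      for (int k = i + 2; k <= j - 2; ++k) {
        double a = v(M, i + 1, k - 1), b = v(M, k, j - 1);
        if (a < INF / 2 && b < INF / 2)
          best = std::min(best, mlA + mlB + a + b);
      }
    } else {
      // (1) two-loop closed on an interior inter-strand pair
      for (int k = i + 1; k < cut && k - i - 1 <= cap; ++k) {
        int g1 = k - i - 1;
        for (int l = j - 1; l >= cut && (g1 + (j - l - 1)) <= cap; --l) {
          if (l <= k || !canPair(k, l) || v(V, k, l) > INF / 2) continue;
          best = std::min(best, twoLoop(i, j, k, l) + v(V, k, l));
        }
      }
      // (2) loop spans the junction: both sides are free regions
      double wl = (i + 1 <= cut - 1) ? v(WF, i + 1, cut - 1) : 0.0;
      double wr = (cut <= j - 1) ? v(WF, cut, j - 1) : 0.0;
      best = std::min(best, wl + wr);
      // (3) multiloop not containing the junction (an interior inter-strand
      //     branch covers it, plus at least one more branch)
      if (i + 1 <= j - 1 && containsJ(i + 1, j - 1)) {
        double x = v(X2, i + 1, j - 1);
        if (x < INF / 2) best = std::min(best, mlA + mlB + x);
      }
    }
    v(V, i, j) = best;
  }

  void computeM(int i, int j) {
    if (containsJ(i, j)) return; // only needed on junction-free regions
    double best = (j > i && v(M, i, j - 1) < INF / 2) ? v(M, i, j - 1) + mlC : INF;
    for (int k = i; k <= j - 1; ++k) {
      if (!canPair(k, j) || v(V, k, j) > INF / 2) continue;
      double left = 0.0;
      if (k > i) {
        left = mlC * (k - i);
        if (v(M, i, k - 1) < left) left = v(M, i, k - 1);
      }
      best = std::min(best, left + v(V, k, j) + mlB);
    }
    v(M, i, j) = best;
  }

  void computeWF(int i, int j) {
    if (containsJ(i, j)) return;
    double best = (j > i) ? v(WF, i, j - 1) : 0.0;
    for (int k = i; k <= j - 1; ++k) {
      if (!canPair(k, j) || v(V, k, j) > INF / 2) continue;
      double left = (k > i) ? v(WF, i, k - 1) : 0.0;
      best = std::min(best, left + v(V, k, j));
    }
    v(WF, i, j) = best;
  }

  void computeJ(int i, int j) {
    double best = INF;
    if (canPair(i, j) && v(V, i, j) < INF / 2) best = v(V, i, j) + mlB;
    if (containsJ(i + 1, j) && v(J, i + 1, j) < INF / 2)
      best = std::min(best, v(J, i + 1, j) + mlC);
    if (containsJ(i, j - 1) && v(J, i, j - 1) < INF / 2)
      best = std::min(best, v(J, i, j - 1) + mlC);
    v(J, i, j) = best;
  }

  void computeX2(int i, int j) {
    double best = INF;
    if (containsJ(i + 1, j) && v(X2, i + 1, j) < INF / 2)
      best = std::min(best, v(X2, i + 1, j) + mlC);
    if (containsJ(i, j - 1) && v(X2, i, j - 1) < INF / 2)
      best = std::min(best, v(X2, i, j - 1) + mlC);
    for (int k = i + 1; k <= j; ++k) {
      // left region [i, k-1], right region [k, j]
      if (!containsJ(i, k - 1) && containsJ(k, j)) {
        double l = v(M, i, k - 1);
        double r = std::min(v(J, k, j), v(X2, k, j));
        if (l < INF / 2 && r < INF / 2) best = std::min(best, l + r);
      } else if (containsJ(i, k - 1) && !containsJ(k, j)) {
        double l = std::min(v(J, i, k - 1), v(X2, i, k - 1));
        double r = v(M, k, j);
        if (l < INF / 2 && r < INF / 2) best = std::min(best, l + r);
      }
    }
    v(X2, i, j) = best;
  }

  // ---- traceback -----------------------------------------------------------

  bool close(double a, double b) const { return std::fabs(a - b) < EPS; }

  void traceV(int i, int j) {
    pairs.push_back(std::make_pair(i, j));
    double tgt = v(V, i, j);
    if (!containsJ(i, j)) {
      if (close(tgt, hairpinG[j - i - 1])) return;
      for (int k = i + 1; k <= j - 2 && k - i - 1 <= cap; ++k) {
        int g1 = k - i - 1;
        for (int l = j - 1; l > k && (g1 + (j - l - 1)) <= cap; --l) {
          if (!canPair(k, l) || v(V, k, l) > INF / 2) continue;
          if (close(tgt, twoLoop(i, j, k, l) + v(V, k, l))) { traceV(k, l); return; }
        }
      }
      for (int k = i + 2; k <= j - 2; ++k) {
        double a = v(M, i + 1, k - 1), b = v(M, k, j - 1);
        if (a < INF / 2 && b < INF / 2 && close(tgt, mlA + mlB + a + b)) {
          traceM(i + 1, k - 1); traceM(k, j - 1); return;
        }
      }
    } else {
      for (int k = i + 1; k < cut && k - i - 1 <= cap; ++k) {
        int g1 = k - i - 1;
        for (int l = j - 1; l >= cut && (g1 + (j - l - 1)) <= cap; --l) {
          if (l <= k || !canPair(k, l) || v(V, k, l) > INF / 2) continue;
          if (close(tgt, twoLoop(i, j, k, l) + v(V, k, l))) { traceV(k, l); return; }
        }
      }
      double wl = (i + 1 <= cut - 1) ? v(WF, i + 1, cut - 1) : 0.0;
      double wr = (cut <= j - 1) ? v(WF, cut, j - 1) : 0.0;
      if (close(tgt, wl + wr)) {
        if (i + 1 <= cut - 1) traceWF(i + 1, cut - 1);
        if (cut <= j - 1) traceWF(cut, j - 1);
        return;
      }
      if (i + 1 <= j - 1 && containsJ(i + 1, j - 1) && v(X2, i + 1, j - 1) < INF / 2 &&
          close(tgt, mlA + mlB + v(X2, i + 1, j - 1))) {
        traceX2(i + 1, j - 1); return;
      }
    }
    Rcpp::stop("traceback failure in V");
  }

  void traceM(int i, int j) {
    double tgt = v(M, i, j);
    if (j > i && v(M, i, j - 1) < INF / 2 && close(tgt, v(M, i, j - 1) + mlC)) {
      traceM(i, j - 1); return;
    }
    for (int k = i; k <= j - 1; ++k) {
      if (!canPair(k, j) || v(V, k, j) > INF / 2) continue;
      if (k == i) {
        if (close(tgt, v(V, k, j) + mlB)) { traceV(k, j); return; }
      } else {
        if (v(M, i, k - 1) < INF / 2 &&
            close(tgt, v(M, i, k - 1) + v(V, k, j) + mlB)) {
          traceM(i, k - 1); traceV(k, j); return;
        }
        if (close(tgt, mlC * (k - i) + v(V, k, j) + mlB)) { traceV(k, j); return; }
      }
    }
    Rcpp::stop("traceback failure in M");
  }

  void traceWF(int i, int j) {
    double tgt = v(WF, i, j);
    if (close(tgt, 0.0) && tgt >= -EPS) {
      // may still contain structure at exactly 0; prefer the empty reading
      if (tgt > -EPS) return;
    }
    if (j > i && close(tgt, v(WF, i, j - 1))) { traceWF(i, j - 1); return; }
    for (int k = i; k <= j - 1; ++k) {
      if (!canPair(k, j) || v(V, k, j) > INF / 2) continue;
      double left = (k > i) ? v(WF, i, k - 1) : 0.0;
      if (close(tgt, left + v(V, k, j))) {
        if (k > i) traceWF(i, k - 1);
        traceV(k, j); return;
      }
    }
    Rcpp::stop("traceback failure in WF");
  }

  void traceJ(int i, int j) {
    double tgt = v(J, i, j);
    if (canPair(i, j) && v(V, i, j) < INF / 2 && close(tgt, v(V, i, j) + mlB)) {
      traceV(i, j); return;
    }
    if (containsJ(i + 1, j) && v(J, i + 1, j) < INF / 2 &&
        close(tgt, v(J, i + 1, j) + mlC)) { traceJ(i + 1, j); return; }
    if (containsJ(i, j - 1) && v(J, i, j - 1) < INF / 2 &&
        close(tgt, v(J, i, j - 1) + mlC)) { traceJ(i, j - 1); return; }
    Rcpp::stop("traceback failure in J");
  }

  void traceX2(int i, int j) {
    double tgt = v(X2, i, j);
    if (containsJ(i + 1, j) && v(X2, i + 1, j) < INF / 2 &&
        close(tgt, v(X2, i + 1, j) + mlC)) { traceX2(i + 1, j); return; }
    if (containsJ(i, j - 1) && v(X2, i, j - 1) < INF / 2 &&
        close(tgt, v(X2, i, j - 1) + mlC)) { traceX2(i, j - 1); return; }
    for (int k = i + 1; k <= j; ++k) {
      if (!containsJ(i, k - 1) && containsJ(k, j)) {
        double l = v(M, i, k - 1);
        if (l > INF / 2) continue;
        if (v(J, k, j) < INF / 2 && close(tgt, l + v(J, k, j))) {
          traceM(i, k - 1); traceJ(k, j); return;
        }
        if (v(X2, k, j) < INF / 2 && close(tgt, l + v(X2, k, j))) {
          traceM(i, k - 1); traceX2(k, j); return;
        }
      } else if (containsJ(i, k - 1) && !containsJ(k, j)) {
        double r = v(M, k, j);
        if (r > INF / 2) continue;
        if (v(J, i, k - 1) < INF / 2 && close(tgt, v(J, i, k - 1) + r)) {
          traceJ(i, k - 1); traceM(k, j); return;
        }
        if (v(X2, i, k - 1) < INF / 2 && close(tgt, v(X2, i, k - 1) + r)) {
          traceX2(i, k - 1); traceM(k, j); return;
        }
      }
    }
    Rcpp::stop("traceback failure in X2");
  }

  void traceW(int j) { // prefix 0..j-1, target W[j]
    while (j > 0) {
      if (close(W[j], W[j - 1])) { --j; continue; }
      bool found = false;
      for (int k = 0; k <= j - 2; ++k) {
        if (canPair(k, j - 1) && v(V, k, j - 1) < INF / 2 &&
            close(W[j], W[k] + v(V, k, j - 1))) {
          traceV(k, j - 1); j = k; found = true; break;
        }
      }
      if (!found) Rcpp::stop("traceback failure in W");
    }
  }
};

} // namespace

// [[Rcpp::export]]
List c_fold(IntegerVector seq, int cut, NumericVector stackG,
            NumericVector hairpinG, NumericVector bulgeG,
            NumericVector internalG, double mlA, double mlB, double mlC,
            int cap) {
  int n = seq.size();
  if (n == 0) return List::create(_["dG"] = 0.0,
                                  _["pairs"] = IntegerMatrix(0, 2));
  Fold f;
  f.n = n; f.cut = cut; f.cap = cap;
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = seq[i];
    if (s[i] < 0 || s[i] > 3) stop("sequence codes must be in 0..3");
  }
  f.s = s.data();
  if ((int)hairpinG.size() < n)
    stop("hairpin table shorter than sequence length");
  f.stackG = REAL(stackG); f.hairpinG = REAL(hairpinG);
  f.bulgeG = REAL(bulgeG); f.internalG = REAL(internalG);
  f.mlA = mlA; f.mlB = mlB; f.mlC = mlC;
  f.run();
  double dG = f.W[n];
  if (dG < -EPS) f.traceW(n);
  IntegerMatrix pm(f.pairs.size(), 2);
  for (size_t k = 0; k < f.pairs.size(); ++k) {
    pm(k, 0) = f.pairs[k].first + 1;  // 1-based for R
    pm(k, 1) = f.pairs[k].second + 1;
  }
  return List::create(_["dG"] = (dG < -EPS ? dG : 0.0), _["pairs"] = pm);
}
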