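#include <Rcpp.h>
#include <vector>
#include <utility>
#include <cmath>
using namespace Rcpp;

// base encoding: A=0, C=1, G=2, T/U=3, anything else < 0
static inline double pair_score(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 1.5; // G-C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 1.0; // A-U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 0.5; // G-U wobble
  return 0.0;
}

// Maximum-weight non-crossing pairing with a minimum hairpin loop.
// Returns the proxy free energy (minus the total pair weight) and the
// 1-based pair list of one optimal structure.
// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(IntegerVector enc, int min_loop = 3) {
  int n = enc.size();
  if (n < 2) return List::create(_["energy"] = 0.0,
                                 _["pairs"] = IntegerMatrix(0, 2));
  NumericMatrix M(n, n); // zero-initialised
  for (int len = min_loop + 1; len < n; ++len) {
    for (int i = 0; i + len < n; ++i) {
      int j = i + len;
      double best = M(i, j - 1); // j unpaired
      for (int k = i; k <= j - min_loop - 1; ++k) {
        double s = pair_score(enc[k], enc[j]);
        if (s > 0.0) {
          double v = s + (k > i ? M(i, k - 1) : 0.0) + M(k + 1, j - 1);
          if (v > best) best = v;
        }
      }
      M(i, j) = best;
    }
  }
  std::vector< std::pair<int, int> > todo, pairs;
  todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (j - i <= min_loop) continue;
    if (M(i, j) == M(i, j - 1)) { todo.push_back(std::make_pair(i, j - 1)); continue; }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      double s = pair_score(enc[k], enc[j]);
      if (s > 0.0) {
        double left = (k > i ? M(i, k - 1) : 0.0);
        if (std::fabs(s + left + M(k + 1, j - 1) - M(i, j)) < 1e-9) {
          pairs.push_back(std::make_pair(k, j));
          if (k > i) todo.push_back(std::make_pair(i, k - 1));
          todo.push_back(std::make_pair(k + 1, j - 1));
          break;
        }
      }
    }
  }
  IntegerMatrix P(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    P(r, 0) = pairs[r].first + 1;
    P(r, 1) = pairs[r].second + 1;
  }
  return List::create(_["energy"] = -M(0, n - 1), _["pairs"] = P);
}

// Log-odds PWM scores at every start position (forward strand only).
// lom is L x 4 (rows = motif positions, columns = A,C,G,T).
// Windows containing non-ACGT letters score NA.
// [[Rcpp::export(name = ".pwm_scan")]]
NumericVector pwm_scan(IntegerVector enc, NumericMatrix lom) {
  int n = enc.size(), L = lom.nrow();
  if (n < L) return NumericVector(0);
  NumericVector out(n - L + 1);
  for (int s = 0; s <= n - L; ++s) {
    double tot = 0.0; bool ok = true;
    for (int p = 0; p < L; ++p) {
      int b = enc[s + p];
      if (b < 0 || b > 3) { ok = false; break; }
      tot += lom(p, b);
    }
    out[s] = ok ? tot : NA_REAL;
  }
  return out;
}

// Direct-form II transposed IIR filter with explicit initial state.
// Caller guarantees a and b share length nb with a[0] == 1, zi length nb-1.
// [[Rcpp::export(name = ".iir_filter")]]
NumericVector iir_filter(NumericVector b, NumericVector a,
                         NumericVector x, NumericVector zi) {
  int n = x.size(), nb = b.size();
  NumericVector y(n);
  std::vector<double> z(zi.begin(), zi.end());
  z.push_back(0.0); // phantom state, always zero
  for (int m = 0; m < n; ++m) {
    double xm = x[m];
    double ym = b[0] * xm + z[0];
    for (int i = 1; i < nb; ++i)
      z[i - 1] = b[i] * xm + z[i] - a[i] * ym;
    y[m] = ym;
  }
  return y;
}
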