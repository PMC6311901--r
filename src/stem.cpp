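#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Equilibrium base-pairing ("stem") probabilities under a nested-structure
// partition function with per-pair Boltzmann weights (canonical pairs
// AU/GC/GU), a minimum hairpin loop, and a maximum pairing span.  Banded
// O(N * span^2) inside/outside with adaptive per-base scaling so partition
// values stay inside double range for long transcripts.
//
// Encoding: 0=A, 1=C, 2=G, 3=T(U), 4=N (unpairable).

static inline double pair_w(int a, int b, double wAU, double wGC, double wGU) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wAU;
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return wGC;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wGU;
  return 0.0;
}

// [[Rcpp::export(name = ".stem_pair_probs_cpp")]]
NumericVector stem_pair_probs_cpp(IntegerVector s, int span, double wAU,
                                  double wGC, double wGU, int minloop) {
  const int N = s.size();
  NumericVector probs(N);
  if (N < minloop + 2) return probs;
  if (span > N - 1) span = N - 1;
  if (span < minloop + 1) return probs;

  const int W = span + 2;                 // band width (j - i in [-1, span])
  std::vector<double> Z((size_t)(N + 2) * W), Zb((size_t)(N + 2) * W);
  std::vector<double> Z1(N + 2), Z2(N + 3);
  auto at = [W](int i, int j) { return (size_t)i * W + (j - i + 1); };

  const double OVER = 1e240, UNDER = 1e-240;
  double c = 1.8;                         // per-base scale, tuned adaptively
  bool ok = false;

  for (int iter = 0; iter < 60 && !ok; ++iter) {
    ok = true;
    double bad_val = 1.0; int bad_len = 1;
    const double invc = 1.0 / c, invc2 = invc * invc;

    for (int i = 1; i <= N + 1; ++i) {    // empty intervals
      Z[at(i, i - 1)] = 1.0;
      Zb[at(i, i - 1)] = 0.0;
    }
    for (int d = 0; d <= span && ok; ++d) {
      for (int i = 1; i + d <= N; ++i) {
        int j = i + d;
        double zb = 0.0;
        if (d >= minloop + 1) {
          double w = pair_w(s[i - 1], s[j - 1], wAU, wGC, wGU);
          if (w > 0.0) zb = w * invc2 * Z[at(i + 1, j - 1)];
        }
        Zb[at(i, j)] = zb;
        double z = invc * Z[at(i + 1, j)];
        int kmax = std::min(j, i + span);
        for (int k = i + minloop + 1; k <= kmax; ++k) {
          if (Zb[at(i, k)] > 0.0) z += Zb[at(i, k)] * Z[at(k + 1, j)];
        }
        Z[at(i, j)] = z;
        if (z > OVER) { ok = false; bad_val = z; bad_len = d + 1; break; }
      }
    }
    if (ok) {                             // prefix / suffix over full length
      Z1[0] = 1.0;
      for (int j = 1; j <= N && ok; ++j) {
        double z = invc * Z1[j - 1];
        int kmin = std::max(1, j - span);
        for (int k = kmin; k <= j - minloop - 1; ++k) {
          if (Zb[at(k, j)] > 0.0) z += Z1[k - 1] * Zb[at(k, j)];
        }
        Z1[j] = z;
        if (z > OVER) { ok = false; bad_val = z; bad_len = j; }
        if (z < UNDER) { ok = false; bad_val = (z > 0 ? z : UNDER); bad_len = j; }
      }
      Z2[N + 1] = 1.0;
      for (int i = N; i >= 1 && ok; --i) {
        double z = invc * Z2[i + 1];
        int kmax = std::min(N, i + span);
        for (int k = i + minloop + 1; k <= kmax; ++k) {
          if (Zb[at(i, k)] > 0.0) z += Zb[at(i, k)] * Z2[k + 1];
        }
        Z2[i] = z;
        if (z > OVER || z < UNDER) { ok = false; bad_val = z; bad_len = N - i + 1; }
      }
    }
    if (!ok) c *= std::pow(bad_val, 1.0 / bad_len);  // re-center the scale
  }
  if (!ok) stop("stem_pair_probs: scaling failed to converge");

  const double invc2 = 1.0 / (c * c), Ztot = Z1[N];
  std::vector<double> H((size_t)(N + 2) * W, 0.0);
  auto hat = [W](int p, int j) { return (size_t)p * W + (j - p); };

  for (int d = span; d >= minloop + 1; --d) {
    for (int i = 1; i + d <= N; ++i) {
      int j = i + d;
      double zb = Zb[at(i, j)];
      if (zb <= 0.0) continue;
      double zout = Z1[i - 1] * Z2[j + 1];
      int pmin = std::max(1, j - span);
      for (int p = pmin; p <= i - 1; ++p) {
        double h = H[hat(p, j)];
        if (h > 0.0) zout += Z[at(p + 1, i - 1)] * h;
      }
      double P = zb * zout / Ztot;
      probs[i - 1] += P;
      probs[j - 1] += P;
      double G = pair_w(s[i - 1], s[j - 1], wAU, wGC, wGU) * invc2 * zout;
      if (G > 0.0) {
        for (int jp = i + 1; jp <= j - 1; ++jp) {
          H[hat(i, jp)] += G * Z[at(jp + 1, j - 1)];
        }
      }
    }
  }
  for (int i = 0; i < N; ++i) {
    if (probs[i] < 0.0) probs[i] = 0.0;
    if (probs[i] > 1.0) probs[i] = 1.0;
  }
  return probs;
}
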