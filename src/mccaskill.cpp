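#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// McCaskill inside-outside partition function over nested secondary
// structures with canonical pairs (AU/AT, GC, GU/GT), hairpin loops of at
// least `min_hairpin` unpaired bases, and a simple energy model: one energy
// per pair type plus a stacking bonus when pair (i,j) sits directly on
// (i+1,j-1).  All Boltzmann factors are passed in precomputed
// (w = exp(-E/RT)).  Partition functions are scaled per nucleotide
// (factor exp(-lambda) per base) to avoid overflow on long or very stable
// windows; probabilities are scale-invariant.

// seq: 0=A, 1=C, 2=G, 3=U/T; returns n x n matrix, upper triangle = P[i][j].

static inline double pair_weight(int a, int b, double wAU, double wGC,
                                 double wGU) {
  // unordered pair lookup
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return wAU;
  if ((a == 1 && b == 2) || (a == 2 && b == 1)) return wGC;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return wGU;
  return 0.0;
}

// One scaled inside-outside pass; returns false on numeric overflow.
static bool bpp_pass(const std::vector<int> &s, int n, double wAU, double wGC,
                     double wGU, double wStack, int min_hairpin, double lambda,
                     NumericMatrix &P) {
  const double u = std::exp(-lambda);  // per-base scale factor
  const double u2 = u * u;

  // Q(i,j): scaled partition function of interval [i,j]; empty interval = 1.
  // Stored in (n+2)^2 arrays, 1-based indices.
  const int m = n + 2;
  std::vector<double> Q((size_t)m * m, 0.0), Qb((size_t)m * m, 0.0);
  std::vector<double> Qout((size_t)m * m, 0.0), A((size_t)m * m, 0.0);
#define IX(i, j) ((size_t)(i)*m + (j))

  // empty intervals: Q(i, i-1) = 1 for i = 1..n+1
  for (int i = 1; i <= n + 1; ++i) Q[IX(i, i - 1)] = 1.0;

  for (int d = 1; d <= n; ++d) {
    for (int i = 1; i + d - 1 <= n; ++i) {
      int j = i + d - 1;
      double qb = 0.0;
      if (j - i > min_hairpin) {
        double w = pair_weight(s[i - 1], s[j - 1], wAU, wGC, wGU);
        if (w > 0.0) {
          double inner = Q[IX(i + 1, j - 1)];
          double innerb = (j - 1 >= i + 1) ? Qb[IX(i + 1, j - 1)] : 0.0;
          qb = w * u2 * ((inner - innerb) + wStack * innerb);
        }
      }
      Qb[IX(i, j)] = qb;
      // Q(i,j) = u * Q(i,j-1) + sum_k Q(i,k-1) * Qb(k,j)
      double q = u * Q[IX(i, j - 1)];
      for (int k = i; k <= j - min_hairpin - 1; ++k)
        q += Q[IX(i, k - 1)] * Qb[IX(k, j)];
      Q[IX(i, j)] = q;
      if (!std::isfinite(q)) return false;
    }
  }

  const double Qtot = Q[IX(1, n)];
  if (!std::isfinite(Qtot) || Qtot <= 0.0) return false;

  // Outside pass, decreasing span.  Qout(i,j) is the scaled exterior weight
  // for pair (i,j).  A(k,j) = sum_{l>j} Qout(k,l) * w(k,l) * u^2 * Q(j+1,l-1).
  bool ok = true;
  for (int d = n; d >= min_hairpin + 2; --d) {
    // A entries with j - k == d become computable now (need spans >= d+2)
    for (int k = 1; k + d <= n; ++k) {
      int j = k + d;
      double acc = 0.0;
      for (int l = j + 1; l <= n; ++l) {
        double qo = Qout[IX(k, l)];
        if (qo > 0.0) {
          double w = pair_weight(s[k - 1], s[l - 1], wAU, wGC, wGU);
          if (w > 0.0) acc += qo * w * u2 * Q[IX(j + 1, l - 1)];
        }
      }
      A[IX(k, j)] = acc;
    }
    for (int i = 1; i + d - 1 <= n; ++i) {
      int j = i + d - 1;
      if (Qb[IX(i, j)] <= 0.0) continue;
      double qo = Q[IX(1, i - 1)] * Q[IX(j + 1, n)];
      for (int k = 1; k <= i - 1; ++k)
        qo += Q[IX(k + 1, i - 1)] * A[IX(k, j)];
      // stacking correction for direct enclosure by (i-1, j+1)
      if (i >= 2 && j + 1 <= n) {
        double w = pair_weight(s[i - 2], s[j], wAU, wGC, wGU);
        if (w > 0.0)
          qo += (wStack - 1.0) * Qout[IX(i - 1, j + 1)] * w * u2;
      }
      Qout[IX(i, j)] = qo;
      if (!std::isfinite(qo)) ok = false;
    }
    if (!ok) return false;
  }

  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j) {
      double p = Qb[IX(i, j)] * Qout[IX(i, j)] / Qtot;
      if (!std::isfinite(p)) return false;
      P(i - 1, j - 1) = p;
    }
#undef IX
  return true;
}

// [[Rcpp::export]]
NumericMatrix mccaskill_bpp_cpp(IntegerVector seq, double wAU, double wGC,
                                double wGU, double wStack, int min_hairpin) {
  int n = seq.size();
  NumericMatrix P(n, n);
  if (n < min_hairpin + 2) return P;
  std::vector<int> s(seq.begin(), seq.end());
  // adaptive per-base scaling: raise lambda until no overflow
  double lambda = 0.0;
  const double step = 600.0 / n;
  for (int attempt = 0; attempt < 30; ++attempt) {
    std::fill(P.begin(), P.end(), 0.0);
    if (bpp_pass(s, n, wAU, wGC, wGU, wStack, min_hairpin, lambda, P))
      return P;
    lambda += step;
  }
  stop("partition function overflow: scaling failed");
  return P;  // not reached
}

// Maximum normalized structural distance between two base-pair probability
// matrices over all subintervals [a,b] with length >= min_span:
//   d(a,b) = sqrt( sum_{a<=i<j<=b} (P1[i][j]-P2[i][j])^2 ) / (b-a+1)
// Computed with interval prefix sums in O(n^2).
// [[Rcpp::export]]
double dmax_scan_cpp(NumericMatrix P1, NumericMatrix P2, int min_span) {
  int n = P1.nrow();
  if (P2.nrow() != n) stop("matrix dimension mismatch");
  if (n < min_span) return 0.0;
  // rowcum[a][b] = sum_{j=a+1..b} D[a][j]
  std::vector<double> rowcum((size_t)n * n, 0.0), T((size_t)n * n, 0.0);
  for (int a = 0; a < n; ++a) {
    double acc = 0.0;
    for (int b = a + 1; b < n; ++b) {
      double diff = P1(a, b) - P2(a, b);
      acc += diff * diff;
      rowcum[(size_t)a * n + b] = acc;
    }
  }
  double best = 0.0;
  // T[a][b] = T[a+1][b] + rowcum[a][b]
  for (int a = n - 1; a >= 0; --a) {
    for (int b = a + 1; b < n; ++b) {
      double t = rowcum[(size_t)a * n + b];
      if (a + 1 < n) t += T[(size_t)(a + 1) * n + b];
      T[(size_t)a * n + b] = t;
      int len = b - a + 1;
      if (len >= min_span) {
        double d = std::sqrt(t) / len;
        if (d > best) best = d;
      }
    }
  }
  return best;
}
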