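#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Base-pair probabilities under a uniform pair-energy model: every
// Watson-Crick or GU pair contributes Boltzmann weight q, structures are
// all non-crossing pairings with hairpin loops of at least 3 unpaired
// bases. Inside-outside recursions on the unambiguous grammar
//   S(i,j) -> S(i,j-1) | S(i,k-1) . B(k,j),   B(k,j) -> ( S(k+1,j-1) )
// give exact P(i,j) in O(n^3). long double keeps the partition function
// in range up to the length cap without rescaling.

static inline bool canpair(int a, int b) {
  // bases coded 0=A 1=C 2=G 3=U
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (lo == 0 && hi == 3) ||  // A-U
         (lo == 1 && hi == 2) ||  // C-G
         (lo == 2 && hi == 3);    // G-U
}

// [[Rcpp::export(name = ".bpp_simple_cpp")]]
NumericMatrix bpp_simple_cpp(IntegerVector codes, double q) {
  const int n = codes.size();
  NumericMatrix P(n, n);
  if (n < 2) return P;
  const long double Q = (long double)q;
  // Z(i,j), 1-based, empty intervals (j < i) have Z = 1.
  const int m = n + 2;
  std::vector<long double> Z((size_t)m * m, 0.0L), OS((size_t)m * m, 0.0L),
      PP((size_t)m * m, 0.0L);
  auto idx = [m](int i, int j) { return (size_t)i * m + j; };
  auto Zat = [&](int i, int j) -> long double {
    return (j < i) ? 1.0L : Z[idx(i, j)];
  };
  auto pairable = [&](int i, int j) {
    return (j - i >= 4) && canpair(codes[i - 1], codes[j - 1]);
  };
  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      long double z = Zat(i, j - 1);
      for (int k = i; k <= j - 4; ++k)
        if (pairable(k, j)) z += Zat(i, k - 1) * Q * Zat(k + 1, j - 1);
      Z[idx(i, j)] = z;
    }
  }
  const long double Ztot = Zat(1, n);
  OS[idx(1, n)] = 1.0L;
  for (int len = n; len >= 2; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      long double os = OS[idx(i, j)];
      if (os == 0.0L) continue;
      OS[idx(i, j - 1)] += os;
      for (int k = i; k <= j - 4; ++k) {
        if (!pairable(k, j)) continue;
        long double ob = os * Zat(i, k - 1);       // outside of B(k,j)
        long double zin = Zat(k + 1, j - 1);
        if (k - 1 >= i) OS[idx(i, k - 1)] += os * Q * zin;
        if (j - 1 >= k + 1) OS[idx(k + 1, j - 1)] += ob * Q;
        PP[idx(k, j)] += ob * Q * zin;
      }
    }
  }
  for (int i = 1; i <= n; ++i)
    for (int j = i + 1; j <= n; ++j) {
      double p = (double)(PP[idx(i, j)] / Ztot);
      if (p < 0) p = 0;
      if (p > 1) p = 1;
      P(i - 1, j - 1) = p;
      P(j - 1, i - 1) = p;
    }
  return P;
}
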