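#include <Rcpp.h>
using namespace Rcpp;

// Pattern-matching kernels for delay-embedded entropy estimators.
// Embedding matrices are Q x M with rows x~(q) = (x[q], ..., x[q+M-1]).
// All pair statistics are over ordered pairs q != q'; by symmetry each
// unordered pair is visited once and counted twice.

// Proportion of ordered pairs (q, q') with Chebyshev distance
// strictly below rhoAbs.
// [[Rcpp::export(name = ".chebMatchProportion")]]
double chebMatchProportion(NumericMatrix emb, double rhoAbs) {
  const int Q = emb.nrow(), M = emb.ncol();
  if (Q < 2) return NA_REAL;
  long long cnt = 0;
  for (int i = 0; i < Q - 1; ++i) {
    for (int j = i + 1; j < Q; ++j) {
      double d = 0.0;
      bool over = false;
      for (int m = 0; m < M; ++m) {
        double a = std::fabs(emb(i, m) - emb(j, m));
        if (a > d) d = a;
        if (d >= rhoAbs) { over = true; break; }
      }
      if (!over) ++cnt;
    }
  }
  return (2.0 * (double)cnt) / ((double)Q * (double)(Q - 1));
}

// Mean over ordered pairs of the fuzzy membership exp(-d^2 / rhoAbs),
// with d the Chebyshev distance (membership degree of a template match).
// [[Rcpp::export(name = ".fuzzyMatchMean")]]
double fuzzyMatchMean(NumericMatrix emb, double rhoAbs) {
  const int Q = emb.nrow(), M = emb.ncol();
  if (Q < 2) return NA_REAL;
  double s = 0.0;
  for (int i = 0; i < Q - 1; ++i) {
    for (int j = i + 1; j < Q; ++j) {
      double d = 0.0;
      for (int m = 0; m < M; ++m) {
        double a = std::fabs(emb(i, m) - emb(j, m));
        if (a > d) d = a;
      }
      s += std::exp(-(d * d) / rhoAbs);
    }
  }
  return (2.0 * s) / ((double)Q * (double)(Q - 1));
}

// Greedy online codebook: the first row is always admitted; row q is
// admitted iff its distance to EVERY current code row exceeds rhoAbs.
// Distance is the squared Euclidean norm when squared = true (the
// default convention), plain Euclidean otherwise. Returns 1-based row
// indices of the admitted rows, in admission order.
// [[Rcpp::export(name = ".greedyCodebookIdx")]]
IntegerVector greedyCodebookIdx(NumericMatrix emb, double rhoAbs, bool squared) {
  const int Q = emb.nrow(), M = emb.ncol();
  std::vector<int> idx;
  idx.reserve(64);
  idx.push_back(0);
  for (int q = 1; q < Q; ++q) {
    bool admit = true;
    for (size_t k = 0; k < idx.size(); ++k) {
      const int c = idx[k];
      double d2 = 0.0;
      for (int m = 0; m < M; ++m) {
        const double a = emb(q, m) - emb(c, m);
        d2 += a * a;
      }
      const double d = squared ? d2 : std::sqrt(d2);
      if (d <= rhoAbs) { admit = false; break; }
    }
    if (admit) idx.push_back(q);
  }
  IntegerVector out(idx.size());
  for (size_t k = 0; k < idx.size(); ++k) out[k] = idx[k] + 1;
  return out;
}
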