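#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Batch training of absorbance-ratio metrics.
//
// A: absorbance matrix, spectra x wavenumbers (row = one spectrum), so each
// wavenumber's values are contiguous in memory.
// isT: 1 for class T, 0 for NT, one entry per spectrum.
// pairs: m x 2 matrix of 1-based column indices (numerator, denominator).
// epsilon: denominator guard; |A(den)| < epsilon makes the ratio undefined
// and the spectrum is excluded from training for that metric.
//
// Per metric: per-class mean/sd of the defined ratios; polarity = class with
// the higher mean (ties -> T); threshold = the cut maximising balanced
// accuracy over the defined training ratios. Candidate cuts are the
// midpoints of adjacent distinct sorted ratios plus a sentinel below all of
// them (balanced accuracy 0.5), so the trained rule never scores below
// chance on its own training set. Balanced accuracy is compared in exact
// integer arithmetic; ties resolve to the lowest cut.
//
// Returns m x 10: meanT, meanNT, sdT, sdNT, nT, nNT, threshold,
// hiT (1 = class T above the cut), trainBA, trainable (0/1). A metric with
// fewer than two defined ratios in either class is untrainable (NA stats).
// [[Rcpp::export]]
NumericMatrix cpp_train_metrics(const NumericMatrix& A,
                                const IntegerVector& isT,
                                const IntegerMatrix& pairs,
                                double epsilon) {
  const int ns = A.nrow();
  const int m = pairs.nrow();
  NumericMatrix out(m, 10);
  std::vector<double> r(ns);
  std::vector<int> lab(ns);
  std::vector<int> ord(ns);

  for (int k = 0; k < m; ++k) {
    const int i = pairs(k, 0) - 1;
    const int j = pairs(k, 1) - 1;
    int n = 0, nT = 0, nN = 0;
    double sT = 0.0, sN = 0.0;
    for (int s = 0; s < ns; ++s) {
      const double den = A(s, j);
      if (std::fabs(den) >= epsilon) {
        const double v = A(s, i) / den;
        r[n] = v;
        lab[n] = isT[s];
        if (isT[s]) { ++nT; sT += v; } else { ++nN; sN += v; }
        ++n;
      }
    }
    if (nT < 2 || nN < 2) {
      for (int c = 0; c < 10; ++c) out(k, c) = NA_REAL;
      out(k, 4) = nT;
      out(k, 5) = nN;
      out(k, 9) = 0.0;
      continue;
    }
    const double mT = sT / nT;
    const double mN = sN / nN;
    double vT = 0.0, vN = 0.0;
    for (int q = 0; q < n; ++q) {
      const double d = r[q] - (lab[q] ? mT : mN);
      if (lab[q]) vT += d * d; else vN += d * d;
    }
    const double sdT = std::sqrt(vT / (nT - 1));
    const double sdN = std::sqrt(vN / (nN - 1));

    const int hiT = (mT >= mN) ? 1 : 0;
    const long long nHi = hiT ? nT : nN;
    const long long nLo = hiT ? nN : nT;
    for (int q = 0; q < n; ++q) ord[q] = q;
    std::sort(ord.begin(), ord.begin() + n,
              [&](int a, int b) { return r[a] < r[b]; });

    // Integer score: 2 * nHi * nLo * BA(t) = (nHi - cumHi) * nLo + cumLo * nHi
    long long best = nHi * nLo;            // sentinel below all ratios: BA 0.5
    double bestT = r[ord[0]] - 1.0;
    long long cumHi = 0, cumLo = 0;
    for (int q = 0; q < n - 1; ++q) {
      if ((lab[ord[q]] == 1) == (hiT == 1)) ++cumHi; else ++cumLo;
      if (r[ord[q + 1]] > r[ord[q]]) {
        const long long sc = (nHi - cumHi) * nLo + cumLo * nHi;
        if (sc > best) {
          best = sc;
          bestT = 0.5 * (r[ord[q]] + r[ord[q + 1]]);
        }
      }
    }
    out(k, 0) = mT;
    out(k, 1) = mN;
    out(k, 2) = sdT;
    out(k, 3) = sdN;
    out(k, 4) = nT;
    out(k, 5) = nN;
    out(k, 6) = bestT;
    out(k, 7) = hiT;
    out(k, 8) = static_cast<double>(best) / (2.0 * nHi * nLo);
    out(k, 9) = 1.0;
  }
  return out;
}

// Balanced accuracy of each trained rule on a test set. Undefined ratios
// (|denominator| < epsilon) count as misclassified: they appear in the class
// totals but never in the correct counts. Untrainable metrics score NA.
// [[Rcpp::export]]
NumericVector cpp_score_metrics(const NumericMatrix& A,
                                const IntegerVector& isT,
                                const IntegerMatrix& pairs,
                                const NumericVector& threshold,
                                const IntegerVector& hiT,
                                const LogicalVector& trainable,
                                double epsilon) {
  const int ns = A.nrow();
  const int m = pairs.nrow();
  int totT = 0;
  for (int s = 0; s < ns; ++s) if (isT[s]) ++totT;
  const int totN = ns - totT;
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    if (!trainable[k]) { out[k] = NA_REAL; continue; }
    const int i = pairs(k, 0) - 1;
    const int j = pairs(k, 1) - 1;
    const double t = threshold[k];
    const bool hi = hiT[k] == 1;
    int corrT = 0, corrN = 0;
    for (int s = 0; s < ns; ++s) {
      const double den = A(s, j);
      if (std::fabs(den) < epsilon) continue;
      const bool above = (A(s, i) / den) > t;
      const bool predT = hi ? above : !above;
      if (predT == (isT[s] == 1)) {
        if (isT[s]) ++corrT; else ++corrN;
      }
    }
    out[k] = 0.5 * (static_cast<double>(corrT) / totT +
                    static_cast<double>(corrN) / totN);
  }
  return out;
}
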