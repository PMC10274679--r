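// Hot-path PSM scoring kernels.  Semantics mirror the (slower) R reference
// expressions exactly: nearest-peak matching with ties to the lower m/z
// peak, hyperscore with factorials capped at 20!, and site localization
// with the 1e-6 tie rule.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double PROTON = 1.00727646688;
static const int FACT_CAP = 20;

// nearest peak within tol; returns index or -1.  peaks sorted ascending.
static inline int nearestPeak(const double *mz, int np, double x,
                              double tol) {
  const double *hi = std::lower_bound(mz, mz + np, x);
  int ih = static_cast<int>(hi - mz);
  int il = ih - 1;
  double dl = (il >= 0) ? x - mz[il] : R_PosInf;
  double dh = (ih < np) ? mz[ih] - x : R_PosInf;
  int best = (dl <= dh) ? il : ih;
  double d = std::min(dl, dh);
  return (d <= tol) ? best : -1;
}

struct MatchAcc {
  int nb = 0, ny = 0;
  double sb = 0.0, sy = 0.0;
};

static inline void accumulateSeries(const double *pkMz, const double *pkInt,
                                    int np, const double *frag, int nf,
                                    double shiftDelta, int shiftFrom,
                                    double tol, int maxZ, bool isB,
                                    MatchAcc &acc) {
  for (int z = 1; z <= maxZ; ++z) {
    for (int i = 0; i < nf; ++i) {
      double neutral = frag[i] + ((i + 1 >= shiftFrom) ? shiftDelta : 0.0);
      double x = (neutral + z * PROTON) / z;
      int hit = nearestPeak(pkMz, np, x, tol);
      if (hit >= 0) {
        if (isB) { acc.nb += 1; acc.sb += pkInt[hit]; }
        else     { acc.ny += 1; acc.sy += pkInt[hit]; }
      }
    }
  }
}

static inline double hyperscore(const MatchAcc &acc) {
  if (acc.nb + acc.ny == 0) return 0.0;
  return std::lgamma(std::min(acc.nb, FACT_CAP) + 1.0) +
         std::lgamma(std::min(acc.ny, FACT_CAP) + 1.0) +
         std::log(std::max(1.0, acc.sb)) +
         std::log(std::max(1.0, acc.sy));
}

// 1-based [first index >= lo, last index <= hi] over a sorted mass vector.
// [[Rcpp::export(name = ".massWindowCpp")]]
IntegerVector massWindowCpp(NumericVector masses, double lo, double hi) {
  int i0 = static_cast<int>(
      std::lower_bound(masses.begin(), masses.end(), lo) - masses.begin()) + 1;
  int i1 = static_cast<int>(
      std::upper_bound(masses.begin(), masses.end(), hi) - masses.begin());
  return IntegerVector::create(i0, i1);
}

// [[Rcpp::export(name = ".scoreArraysCpp")]]
NumericVector scoreArraysCpp(NumericVector peakMz, NumericVector peakInt,
                             NumericVector b, NumericVector y, double tolDa,
                             int maxZ) {
  MatchAcc acc;
  int np = peakMz.size();
  if (np > 0) {
    accumulateSeries(peakMz.begin(), peakInt.begin(), np, b.begin(),
                     b.size(), 0.0, b.size() + 2, tolDa, maxZ, true, acc);
    accumulateSeries(peakMz.begin(), peakInt.begin(), np, y.begin(),
                     y.size(), 0.0, y.size() + 2, tolDa, maxZ, false, acc);
  }
  return NumericVector::create(hyperscore(acc),
                               static_cast<double>(acc.nb + acc.ny));
}

// Localization: place `delta` at each 0-based candidate site, shifting b
// ions with index >= p+1 and y ions with index >= n-p (n = peptide length).
// [[Rcpp::export(name = ".localizeArraysCpp")]]
List localizeArraysCpp(NumericVector peakMz, NumericVector peakInt,
                       NumericVector b, NumericVector y, int n, double delta,
                       IntegerVector sites, double tolDa, int maxZ) {
  int ns = sites.size();
  NumericVector scores(ns);
  IntegerVector matched(ns);
  int np = peakMz.size();
  for (int k = 0; k < ns; ++k) {
    int p = sites[k];
    MatchAcc acc;
    if (np > 0) {
      accumulateSeries(peakMz.begin(), peakInt.begin(), np, b.begin(),
                       b.size(), delta, p + 1, tolDa, maxZ, true, acc);
      accumulateSeries(peakMz.begin(), peakInt.begin(), np, y.begin(),
                       y.size(), delta, n - p, tolDa, maxZ, false, acc);
    }
    scores[k] = hyperscore(acc);
    matched[k] = acc.nb + acc.ny;
  }
  double best = *std::max_element(scores.begin(), scores.end());
  int firstTied = -1, nTied = 0;
  for (int k = 0; k < ns; ++k) {
    if (scores[k] >= best - 1e-6) {
      if (firstTied < 0) firstTied = k;
      ++nTied;
    }
  }
  return List::create(
    _["position"] = (nTied > 1) ? NA_INTEGER : sites[firstTied],
    _["score"] = best,
    _["siteScores"] = scores,
    _["matched"] = matched[firstTied]);
}
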