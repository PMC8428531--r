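#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Template match counts for sample entropy: B = pairs within r at length m,
// A = pairs within r at length m+1, self-matches excluded (Chebyshev norm).
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int np = n - m;            // number of (m+1)-length template starts is n-m
  double A = 0.0, B = 0.0;
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) {
        B += 1.0;
        double dd = std::fabs(x[i + m] - x[j + m]);
        if (std::max(d, dd) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}

// ApEn = phi(m) - phi(m+1) with self-matches included. Both template
// lengths are counted in one pair sweep: a pair within r at length m is
// tested for the extra (m+1)-th dimension only when both windows fit.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int npm = n - m + 1;       // templates of length m
  int npm1 = n - m;          // templates of length m+1
  std::vector<int> cm(npm, 1), cm1(npm1, 1);  // self-matches
  for (int i = 0; i < npm - 1; ++i) {
    for (int j = i + 1; j < npm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
      }
      if (d <= r) {
        ++cm[i]; ++cm[j];
        if (i < npm1 && j < npm1 &&
            std::fabs(x[i + m] - x[j + m]) <= r) {
          ++cm1[i]; ++cm1[j];
        }
      }
    }
  }
  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < npm; ++i) phim += std::log((double)cm[i] / npm);
  for (int i = 0; i < npm1; ++i) phim1 += std::log((double)cm1[i] / npm1);
  return phim / npm - phim1 / npm1;
}

// Fuzzy entropy with exponential membership exp(-(d/r)^n) and
// mean-removed templates; the m and (m+1) similarity sums share one pair
// sweep. Both sums use the standard n-m template count.
// [[Rcpp::export(name = ".fuzzyen_cpp")]]
double fuzzyen_cpp(NumericVector x, int m, double r, double nexp) {
  int n = x.size();
  int np = n - m;
  std::vector<double> mum(np), mum1(np);
  for (int i = 0; i < np; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    mum[i] = s / m;
    mum1[i] = (s + x[i + m]) / (m + 1);
  }
  bool quad = std::fabs(nexp - 2.0) < 1e-12;
  double tm = 0.0, tm1 = 0.0;
  long pairs = 0;
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double dm = 0.0, dm1 = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs((x[i + k] - mum[i]) - (x[j + k] - mum[j]));
        if (a > dm) dm = a;
        double b = std::fabs((x[i + k] - mum1[i]) - (x[j + k] - mum1[j]));
        if (b > dm1) dm1 = b;
      }
      double b = std::fabs((x[i + m] - mum1[i]) - (x[j + m] - mum1[j]));
      if (b > dm1) dm1 = b;
      double zm = dm / r, zm1 = dm1 / r;
      tm += quad ? std::exp(-zm * zm) : std::exp(-std::pow(zm, nexp));
      tm1 += quad ? std::exp(-zm1 * zm1) : std::exp(-std::pow(zm1, nexp));
      ++pairs;
    }
  }
  return std::log(tm / pairs) - std::log(tm1 / pairs);
}

// Higuchi fractal dimension: slope of log mean curve length vs log(1/k).
// [[Rcpp::export(name = ".higuchi_cpp")]]
double higuchi_cpp(NumericVector x, int kmax) {
  int n = x.size();
  std::vector<double> lk(kmax), lnk(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double lsum = 0.0;
    for (int m0 = 0; m0 < k; ++m0) {
      int nm = (n - 1 - m0) / k;
      if (nm < 1) continue;
      double len = 0.0;
      for (int i = 1; i <= nm; ++i)
        len += std::fabs(x[m0 + i * k] - x[m0 + (i - 1) * k]);
      len *= (double)(n - 1) / (nm * (double)k);
      lsum += len / k;
    }
    lk[k - 1] = std::log(lsum / k);
    lnk[k - 1] = std::log(1.0 / k);
  }
  double mx = 0.0, my = 0.0;
  for (int k = 0; k < kmax; ++k) { mx += lnk[k]; my += lk[k]; }
  mx /= kmax; my /= kmax;
  double sxy = 0.0, sxx = 0.0;
  for (int k = 0; k < kmax; ++k) {
    sxy += (lnk[k] - mx) * (lk[k] - my);
    sxx += (lnk[k] - mx) * (lnk[k] - mx);
  }
  return sxy / sxx;
}
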