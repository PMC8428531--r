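#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Natural cubic spline through (t, y), evaluated at integer grid 0..n-1.
// Extrapolation beyond the first/last knot holds the end values.
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& y,
                                int n, std::vector<double>& out) {
  int m = t.size();
  out.assign(n, 0.0);
  if (m == 1) { std::fill(out.begin(), out.end(), y[0]); return; }
  if (m == 2) {
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) {
      double x = i;
      if (x <= t[0]) out[i] = y[0];
      else if (x >= t[1]) out[i] = y[1];
      else out[i] = y[0] + slope * (x - t[0]);
    }
    return;
  }
  // second derivatives M via tridiagonal solve (natural: M[0]=M[m-1]=0)
  std::vector<double> h(m - 1), alpha(m, 0.0), l(m), mu(m), z(m), M(m);
  for (int i = 0; i < m - 1; ++i) h[i] = t[i + 1] - t[i];
  for (int i = 1; i < m - 1; ++i)
    alpha[i] = 3.0 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]);
  l[0] = 1.0; mu[0] = 0.0; z[0] = 0.0;
  for (int i = 1; i < m - 1; ++i) {
    l[i] = 2.0 * (t[i + 1] - t[i - 1]) - h[i - 1] * mu[i - 1];
    mu[i] = h[i] / l[i];
    z[i] = (alpha[i] - h[i - 1] * z[i - 1]) / l[i];
  }
  M[m - 1] = 0.0;
  for (int i = m - 2; i >= 0; --i) M[i] = z[i] - mu[i] * M[i + 1];
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double x = i;
    if (x <= t[0]) { out[i] = y[0]; continue; }
    if (x >= t[m - 1]) { out[i] = y[m - 1]; continue; }
    while (seg < m - 2 && t[seg + 1] < x) ++seg;
    double hk = h[seg], a = (t[seg + 1] - x) / hk, b = (x - t[seg]) / hk;
    out[i] = a * y[seg] + b * y[seg + 1] +
      ((a * a * a - a) * M[seg] + (b * b * b - b) * M[seg + 1]) *
      (hk * hk) / 6.0;
  }
}

static void find_extrema(const std::vector<double>& x,
                         std::vector<int>& maxima,
                         std::vector<int>& minima) {
  maxima.clear(); minima.clear();
  int n = x.size();
  for (int i = 1; i < n - 1; ++i) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) maxima.push_back(i);
    else if (x[i] < x[i - 1] && x[i] <= x[i + 1]) minima.push_back(i);
  }
}

// [[Rcpp::export(name = ".emd_decompose_cpp")]]
NumericMatrix emd_decompose_cpp(NumericVector x, int max_imf = 10,
                                double sd_tol = 0.2, int max_sift = 10) {
  int n = x.size();
  std::vector<double> resid(x.begin(), x.end());
  std::vector<std::vector<double> > imfs;
  std::vector<int> maxima, minima;
  std::vector<double> upper, lower, h(n), hn(n);
  std::vector<double> tmax, ymax, tmin, ymin;

  for (int k = 0; k < max_imf; ++k) {
    find_extrema(resid, maxima, minima);
    if ((int)maxima.size() < 2 || (int)minima.size() < 2) break;
    h = resid;
    for (int s = 0; s < max_sift; ++s) {
      find_extrema(h, maxima, minima);
      if ((int)maxima.size() < 2 || (int)minima.size() < 2) break;
      // envelope knots with clamped endpoints
      tmax.clear(); ymax.clear(); tmin.clear(); ymin.clear();
      tmax.push_back(0); ymax.push_back(h[0]);
      for (size_t i = 0; i < maxima.size(); ++i) {
        tmax.push_back(maxima[i]); ymax.push_back(h[maxima[i]]);
      }
      tmax.push_back(n - 1); ymax.push_back(h[n - 1]);
      tmin.push_back(0); ymin.push_back(h[0]);
      for (size_t i = 0; i < minima.size(); ++i) {
        tmin.push_back(minima[i]); ymin.push_back(h[minima[i]]);
      }
      tmin.push_back(n - 1); ymin.push_back(h[n - 1]);
      natural_spline_eval(tmax, ymax, n, upper);
      natural_spline_eval(tmin, ymin, n, lower);
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) {
        double m = 0.5 * (upper[i] + lower[i]);
        hn[i] = h[i] - m;
        num += m * m;
        den += h[i] * h[i];
      }
      h = hn;
      if (den > 0 && num / den < sd_tol * sd_tol) break;
    }
    imfs.push_back(h);
    for (int i = 0; i < n; ++i) resid[i] -= h[i];
  }
  // rows: IMFs then residue; residue = x - sum(IMFs) exactly by construction
  NumericMatrix out(imfs.size() + 1, n);
  for (size_t k = 0; k < imfs.size(); ++k)
    for (int i = 0; i < n; ++i) out(k, i) = imfs[k][i];
  for (int i = 0; i < n; ++i) out(imfs.size(), i) = resid[i];
  return out;
}
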