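#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Type-7 (linear interpolation) quantile on a sorted buffer.
static double quantile7(const std::vector<double> &s, double p) {
  const int n = (int)s.size();
  if (n == 1) return s[0];
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  if (lo >= n - 1) return s[n - 1];
  return s[lo] + (h - lo) * (s[lo + 1] - s[lo]);
}

struct StatBlock {
  double mean, median, kurtosis, skewness, entropy, uniformity, iqr, cv, sd,
      mad;
};

// All ten first-order statistics of a sample. Histogram bins for
// entropy/uniformity are nbins equal-width bins over [lo, hi]; a degenerate
// range puts all mass in one bin (entropy 0, uniformity 1). Constant samples
// return skewness 0 and kurtosis 3 by convention; cv is 0 when the mean is 0.
static StatBlock first_order_block(std::vector<double> &v, int nbins,
                                   double lo, double hi, bool sample_var) {
  StatBlock out;
  const int n = (int)v.size();
  double sum = 0.0;
  for (double x : v) sum += x;
  const double mu = sum / n;
  double m2 = 0, m3 = 0, m4 = 0;
  for (double x : v) {
    const double d = x - mu;
    m2 += d * d;
    m3 += d * d * d;
    m4 += d * d * d * d;
  }
  m2 /= n;
  m3 /= n;
  m4 /= n;
  out.mean = mu;
  const double var = sample_var ? m2 * n / (n - 1.0) : m2;
  out.sd = std::sqrt(var);
  if (m2 > 0) {
    out.skewness = m3 / std::pow(m2, 1.5);
    out.kurtosis = m4 / (m2 * m2);
  } else {
    out.skewness = 0.0;
    out.kurtosis = 3.0;
  }
  out.cv = (mu != 0.0) ? out.sd / mu : 0.0;

  std::vector<double> s(v);
  std::sort(s.begin(), s.end());
  out.median = quantile7(s, 0.5);
  out.iqr = quantile7(s, 0.75) - quantile7(s, 0.25);
  std::vector<double> ad(n);
  for (int i = 0; i < n; ++i) ad[i] = std::fabs(s[i] - out.median);
  std::sort(ad.begin(), ad.end());
  out.mad = quantile7(ad, 0.5);

  // histogram-based entropy (bits) and uniformity (energy)
  std::vector<int> cnt(nbins, 0);
  if (hi > lo) {
    const double w = (hi - lo) / nbins;
    for (double x : v) {
      int b = (int)std::floor((x - lo) / w);
      if (b < 0) b = 0;
      if (b >= nbins) b = nbins - 1;
      cnt[b]++;
    }
  } else {
    cnt[0] = n;
  }
  double H = 0.0, U = 0.0;
  for (int b = 0; b < nbins; ++b) {
    if (cnt[b] == 0) continue;
    const double p = (double)cnt[b] / n;
    H -= p * std::log2(p);
    U += p * p;
  }
  out.entropy = H;
  out.uniformity = U;
  return out;
}

// [[Rcpp::export]]
List cpp_first_order(NumericVector values, int nbins, double lo, double hi,
                     bool sample_var) {
  std::vector<double> v(values.begin(), values.end());
  StatBlock b = first_order_block(v, nbins, lo, hi, sample_var);
  return List::create(
      _["mean"] = b.mean, _["median"] = b.median, _["kurtosis"] = b.kurtosis,
      _["skewness"] = b.skewness, _["entropy"] = b.entropy,
      _["uniformity"] = b.uniformity, _["iqr"] = b.iqr, _["cv"] = b.cv,
      _["std"] = b.sd, _["mad"] = b.mad);
}

// Sliding-window local feature maps over the gland mask. For every gland
// pixel the window (size w, odd) is intersected with the gland; the pixel is
// defined when at least min_frac of the w*w window pixels lie inside the
// gland (window pixels beyond the image border count as outside). Histogram
// bins for the entropy/uniformity maps span [lo, hi] (the gland-wide range),
// shared across windows so neighbouring windows are comparable.
// [[Rcpp::export]]
List cpp_local_maps(NumericMatrix image, LogicalMatrix gland, int window,
                    double min_frac, int nbins, double lo, double hi,
                    bool sample_var) {
  const int nr = image.nrow(), nc = image.ncol();
  const int half = window / 2;
  const int wtot = window * window;
  const char *names[10] = {"mean",    "median",     "kurtosis", "skewness",
                           "entropy", "uniformity", "iqr",      "cv",
                           "std",     "mad"};
  std::vector<NumericMatrix> maps;
  for (int k = 0; k < 10; ++k) {
    NumericMatrix m(nr, nc);
    std::fill(m.begin(), m.end(), NA_REAL);
    maps.push_back(m);
  }
  LogicalMatrix defined(nr, nc);
  std::vector<double> buf;
  buf.reserve(wtot);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      defined(i, j) = FALSE;
      if (!gland(i, j)) continue;
      buf.clear();
      for (int dj = -half; dj <= half; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= nc) continue;
        for (int di = -half; di <= half; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nr) continue;
          if (gland(ii, jj)) buf.push_back(image(ii, jj));
        }
      }
      if ((double)buf.size() < min_frac * wtot || buf.size() < 2) continue;
      StatBlock b = first_order_block(buf, nbins, lo, hi, sample_var);
      maps[0](i, j) = b.mean;
      maps[1](i, j) = b.median;
      maps[2](i, j) = b.kurtosis;
      maps[3](i, j) = b.skewness;
      maps[4](i, j) = b.entropy;
      maps[5](i, j) = b.uniformity;
      maps[6](i, j) = b.iqr;
      maps[7](i, j) = b.cv;
      maps[8](i, j) = b.sd;
      maps[9](i, j) = b.mad;
      defined(i, j) = TRUE;
    }
  }
  List out(10);
  CharacterVector nm(10);
  for (int k = 0; k < 10; ++k) {
    out[k] = maps[k];
    nm[k] = names[k];
  }
  out.attr("names") = nm;
  return List::create(_["maps"] = out, _["defined"] = defined);
}
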