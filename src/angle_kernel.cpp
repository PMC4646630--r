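#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

// Sorted sliding window over a numeric series. Centered width k (odd),
// shrunk at the ends so every position gets a median of the available
// samples; an NA inside the window makes the median NA. Replace moves the
// span between the deletion and insertion points with one memmove, which
// keeps the update well under O(k) on average.
struct SortedWindow {
  std::vector<double> w;
  int na = 0;

  void insert(double v) {
    if (NumericVector::is_na(v)) { ++na; return; }
    w.insert(std::upper_bound(w.begin(), w.end(), v), v);
  }
  void erase(double v) {
    if (NumericVector::is_na(v)) { --na; return; }
    w.erase(std::lower_bound(w.begin(), w.end(), v));
  }
  void replace(double out, double in) {
    bool out_na = NumericVector::is_na(out), in_na = NumericVector::is_na(in);
    if (out_na || in_na) {
      if (out_na) --na; else erase(out);
      if (in_na) ++na; else insert(in);
      return;
    }
    size_t p_out = std::lower_bound(w.begin(), w.end(), out) - w.begin();
    size_t p_in = std::upper_bound(w.begin(), w.end(), in) - w.begin();
    if (p_in > p_out) {
      std::move(w.begin() + p_out + 1, w.begin() + p_in, w.begin() + p_out);
      w[p_in - 1] = in;
    } else {
      std::move_backward(w.begin() + p_in, w.begin() + p_out, w.begin() + p_out + 1);
      w[p_in] = in;
    }
  }
  double median() const {
    if (na > 0 || w.empty()) return NA_REAL;
    size_t m = w.size();
    return (m % 2 == 1) ? w[m / 2] : 0.5 * (w[m / 2 - 1] + w[m / 2]);
  }
};

} // namespace

// Centered rolling median, width k (odd), shrunk at the edges.
// [[Rcpp::export]]
NumericVector roll_median_c(NumericVector x, int k) {
  int n = x.size();
  if (k < 1) stop("window width must be >= 1");
  if (k % 2 == 0) stop("window width must be odd");
  int h = (k - 1) / 2;
  NumericVector out(n);
  SortedWindow win;
  win.w.reserve(k);
  int hi = std::min(h, n - 1);
  for (int j = 0; j <= hi; ++j) win.insert(x[j]);
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      int add = i + h, drop = i - h - 1;
      if (add < n && drop >= 0) win.replace(x[drop], x[add]);
      else if (add < n) win.insert(x[add]);
      else if (drop >= 0) win.erase(x[drop]);
    }
    out[i] = win.median();
  }
  return out;
}

// Per-sample arm angle from rolling medians of the three axes, in one pass:
// angle = atan2(med(az), sqrt(med(ax)^2 + med(ay)^2)) * 180/pi. A zero
// median vector has no direction and yields NA.
// [[Rcpp::export]]
NumericVector median_angle_c(NumericVector ax, NumericVector ay, NumericVector az,
                             int k) {
  int n = ax.size();
  if (ay.size() != n || az.size() != n) stop("axes must have equal length");
  if (k < 1) stop("window width must be >= 1");
  if (k % 2 == 0) stop("window width must be odd");
  int h = (k - 1) / 2;
  NumericVector out(n);
  const double rad2deg = 180.0 / M_PI;
  SortedWindow wx, wy, wz;
  wx.w.reserve(k); wy.w.reserve(k); wz.w.reserve(k);
  int hi = std::min(h, n - 1);
  for (int j = 0; j <= hi; ++j) { wx.insert(ax[j]); wy.insert(ay[j]); wz.insert(az[j]); }
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      int add = i + h, drop = i - h - 1;
      if (add < n && drop >= 0) {
        wx.replace(ax[drop], ax[add]);
        wy.replace(ay[drop], ay[add]);
        wz.replace(az[drop], az[add]);
      } else if (add < n) {
        wx.insert(ax[add]); wy.insert(ay[add]); wz.insert(az[add]);
      } else if (drop >= 0) {
        wx.erase(ax[drop]); wy.erase(ay[drop]); wz.erase(az[drop]);
      }
    }
    double mx = wx.median(), my = wy.median(), mz = wz.median();
    if (ISNAN(mx) || ISNAN(my) || ISNAN(mz)) {
      out[i] = NA_REAL;
    } else if (mx == 0.0 && my == 0.0 && mz == 0.0) {
      out[i] = NA_REAL;
    } else {
      out[i] = std::atan2(mz, std::sqrt(mx * mx + my * my)) * rad2deg;
    }
  }
  return out;
}

// Arm angle from already-filtered per-sample accelerations.
// [[Rcpp::export]]
NumericVector angle_deg_c(NumericVector ax, NumericVector ay, NumericVector az) {
  int n = ax.size();
  if (ay.size() != n || az.size() != n) stop("axes must have equal length");
  NumericVector out(n);
  const double rad2deg = 180.0 / M_PI;
  for (int i = 0; i < n; ++i) {
    double x = ax[i], y = ay[i], z = az[i];
    if (NumericVector::is_na(x) || NumericVector::is_na(y) || NumericVector::is_na(z)) {
      out[i] = NA_REAL;
    } else if (x == 0.0 && y == 0.0 && z == 0.0) {
      out[i] = NA_REAL;
    } else {
      out[i] = std::atan2(z, std::sqrt(x * x + y * y)) * rad2deg;
    }
  }
  return out;
}

// Single-pass validity scan of the three axes: counts non-finite samples and
// tracks the largest absolute value.
// [[Rcpp::export]]
List check_axes_c(NumericVector ax, NumericVector ay, NumericVector az) {
  int n = ax.size();
  long n_bad = 0;
  double mx = 0.0;
  const NumericVector* axes[3] = {&ax, &ay, &az};
  for (int a = 0; a < 3; ++a) {
    const NumericVector& v = *axes[a];
    for (int i = 0; i < n; ++i) {
      double val = v[i];
      if (!R_finite(val)) { ++n_bad; continue; }
      double av = std::fabs(val);
      if (av > mx) mx = av;
    }
  }
  return List::create(_["n_nonfinite"] = (double)n_bad, _["max_abs"] = mx);
}
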