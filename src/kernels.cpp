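#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Biased (1/N at every lag) sample autocorrelation, mean taken over the
// whole input. Returns lags 0..max_lag.
// [[Rcpp::export]]
NumericVector acf_biased_cpp(NumericVector x, int max_lag) {
  const int n = x.size();
  double mean = 0.0;
  for (int t = 0; t < n; ++t) mean += x[t];
  mean /= n;
  double var = 0.0;
  for (int t = 0; t < n; ++t) var += (x[t] - mean) * (x[t] - mean);
  var /= n;
  NumericVector out(max_lag + 1);
  if (var <= 0.0) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  for (int m = 0; m <= max_lag; ++m) {
    double acov = 0.0;
    for (int t = 0; t < n - m; ++t)
      acov += (x[t] - mean) * (x[t + m] - mean);
    acov /= n;
    out[m] = acov / var;
  }
  return out;
}

// Interpolated crossing point between lag m-1 (value above the threshold)
// and lag m (value at or below it): log-linear when the bracketing values
// and threshold are positive (exact for exponential ACFs), linear otherwise.
static double interp_crossing(int m, double r_prev, double r_m, double thr) {
  if (r_prev <= thr) return (double)m;  // defensive; should not happen
  if (r_m > 0.0 && thr > 0.0 && r_prev > 0.0) {
    double num = std::log(r_prev) - std::log(thr);
    double den = std::log(r_prev) - std::log(r_m);
    if (den > 0.0) return (m - 1) + num / den;
  }
  double den = r_prev - r_m;
  if (den <= 0.0) return (double)m;
  return (m - 1) + (r_prev - thr) / den;
}

// First lag m >= 1 whose biased ACF is <= threshold, computed lazily
// (lag by lag with early exit). Returns the (possibly interpolated)
// crossing, or -(max_lag) when no crossing occurs within max_lag
// (censored), or 0 for a constant window.
static double first_crossing(const double* x, int n, int max_lag,
                             double threshold, bool interpolate) {
  double mean = 0.0;
  for (int t = 0; t < n; ++t) mean += x[t];
  mean /= n;
  double var = 0.0;
  for (int t = 0; t < n; ++t) var += (x[t] - mean) * (x[t] - mean);
  var /= n;
  if (var <= 0.0) return 0;
  double r_prev = 1.0;
  for (int m = 1; m <= max_lag; ++m) {
    double acov = 0.0;
    for (int t = 0; t < n - m; ++t)
      acov += (x[t] - mean) * (x[t + m] - mean);
    acov /= n;
    double r = acov / var;
    if (r <= threshold)
      return interpolate ? interp_crossing(m, r_prev, r, threshold) : (double)m;
    r_prev = r;
  }
  return (double)(-max_lag);
}

// Sliding-window ACW: for each window of `wlen` samples advancing by `step`,
// the first ACF crossing of `threshold` with max_lag = wlen - 1.
// Returns lag per window (samples), with censored and missing flags.
// [[Rcpp::export]]
List dynamic_acw_cpp(NumericVector x, int wlen, int step, double threshold,
                     bool interpolate) {
  const int n = x.size();
  const int n_win = (n - wlen) / step + 1;
  NumericVector lag(n_win);
  LogicalVector censored(n_win), missing(n_win);
  const int max_lag = wlen - 1;
  for (int w = 0; w < n_win; ++w) {
    double r = first_crossing(&x[w * step], wlen, max_lag, threshold,
                              interpolate);
    if (r == 0) {
      lag[w] = NA_REAL; missing[w] = true; censored[w] = false;
    } else if (r < 0) {
      lag[w] = -r; censored[w] = true; missing[w] = false;
    } else {
      lag[w] = r; censored[w] = false; missing[w] = false;
    }
  }
  return List::create(_["lag"] = lag, _["censored"] = censored,
                      _["missing"] = missing);
}

static inline double maxnorm_update(double acc, double a, double b) {
  double d = std::abs(a - b);
  return d > acc ? d : acc;
}

// KSG conditional mutual information I(X;Y|Z), Frenzel-Pompe digamma form,
// max-norm distances, brute-force neighbour search. With zero z columns this
// is the KSG algorithm-1 MI estimator. Rows are samples, assumed in temporal
// order when `theiler` > 0: samples closer than `theiler` rows to the query
// point are excluded from all neighbour sets (dynamic correlation exclusion,
// which removes the serial-correlation bias on autocorrelated series).
// [[Rcpp::export]]
double ksg_cmi_cpp(NumericMatrix x, NumericMatrix y, NumericMatrix z, int K,
                   int theiler) {
  const int n = x.nrow();
  const int dx = x.ncol(), dy = y.ncol(), dz = z.ncol();
  if (y.nrow() != n || (dz > 0 && z.nrow() != n))
    stop("point sets must have equal sample counts");
  if (n <= K) stop("need more samples than neighbours (n > K)");
  if (theiler < 0) theiler = 0;
  if (theiler > 0 && n - 2 * theiler <= K)
    stop("Theiler window too wide for the sample count");

  // flat column-major copies: avoids Rcpp accessor overhead in the O(n^2) loop
  const double* xp = REAL(x); const double* yp = REAL(y);
  const double* zp = dz > 0 ? REAL(z) : nullptr;
  std::vector<double> ddx(n), ddy(n), ddz(n, 0.0), joint(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < dx; ++c) {
      const double xi = xp[(size_t)c * n + i];
      const double* col = xp + (size_t)c * n;
      if (c == 0) for (int j = 0; j < n; ++j) ddx[j] = std::abs(xi - col[j]);
      else for (int j = 0; j < n; ++j) ddx[j] = maxnorm_update(ddx[j], xi, col[j]);
    }
    for (int c = 0; c < dy; ++c) {
      const double yi = yp[(size_t)c * n + i];
      const double* col = yp + (size_t)c * n;
      if (c == 0) for (int j = 0; j < n; ++j) ddy[j] = std::abs(yi - col[j]);
      else for (int j = 0; j < n; ++j) ddy[j] = maxnorm_update(ddy[j], yi, col[j]);
    }
    for (int c = 0; c < dz; ++c) {
      const double zi = zp[(size_t)c * n + i];
      const double* col = zp + (size_t)c * n;
      if (c == 0) for (int j = 0; j < n; ++j) ddz[j] = std::abs(zi - col[j]);
      else for (int j = 0; j < n; ++j) ddz[j] = maxnorm_update(ddz[j], zi, col[j]);
    }
    for (int j = 0; j < n; ++j)
      joint[j] = std::max(ddx[j], std::max(ddy[j], ddz[j]));
    const int lo = std::max(0, i - theiler), hi = std::min(n - 1, i + theiler);
    for (int j = lo; j <= hi; ++j) joint[j] = R_PosInf;  // self + Theiler band
    std::vector<double> tmp(joint);
    std::nth_element(tmp.begin(), tmp.begin() + (K - 1), tmp.end());
    const double eps = tmp[K - 1];

    if (dz == 0) {
      int nx = 0, ny = 0;
      for (int j = 0; j < n; ++j) {
        if (j >= lo && j <= hi) continue;
        if (ddx[j] < eps) ++nx;
        if (ddy[j] < eps) ++ny;
      }
      // psi(N) uses the per-point usable count under the exclusion band
      acc += R::digamma(nx + 1) + R::digamma(ny + 1)
           - R::digamma(n - (hi - lo + 1) + 1);
    } else {
      int nxz = 0, nyz = 0, nz = 0;
      for (int j = 0; j < n; ++j) {
        if (j >= lo && j <= hi) continue;
        bool inz = ddz[j] < eps;
        if (inz) {
          ++nz;
          if (ddx[j] < eps) ++nxz;
          if (ddy[j] < eps) ++nyz;
        }
      }
      acc += R::digamma(nxz + 1) + R::digamma(nyz + 1) - R::digamma(nz + 1);
    }
  }
  acc /= n;
  if (z.ncol() == 0)
    return R::digamma(K) - acc;  // psi(N_i) folded into acc per point
  return R::digamma(K) - acc;
}

// FNV-1a 32-bit hash of a token, mixed with a seed; used by the
// deterministic hashed bag-of-words embedder.
// [[Rcpp::export]]
IntegerVector hash_tokens_cpp(CharacterVector tokens, int seed) {
  const int n = tokens.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    uint32_t h = 2166136261u ^ (uint32_t)seed;
    const char* s = tokens[i];
    for (const char* p = s; *p; ++p) {
      h ^= (uint32_t)(unsigned char)(*p);
      h *= 16777619u;
    }
    out[i] = (int)(h & 0x7fffffffu);
  }
  return out;
}
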