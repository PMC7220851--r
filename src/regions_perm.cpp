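#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Box smoothing with half-width h (window 2h+1), truncated at chromosome
// ends and renormalised by the actual window size. h = 0 is the identity.
static void box_smooth_range(const double* x, int n, int h, double* out) {
  if (h <= 0) { std::copy(x, x + n, out); return; }
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h), hi = std::min(n - 1, i + h);
    out[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
  }
}

// Plateau-collapsed local extrema of one chromosome's profile. Appends the
// heights of local maxima and *internal* local minima. For any threshold t,
// the number of maximal runs {b : f(b) >= t} equals
//   #{maxima >= t} - #{internal minima >= t},
// which is what the permutation-FDR estimator counts.
static void extrema_range(const double* x, int n,
                          std::vector<double>& mx, std::vector<double>& mn) {
  std::vector<double> v;
  v.reserve(64);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && x[j + 1] == x[i]) ++j;
    v.push_back(x[i]);
    i = j + 1;
  }
  int m = (int)v.size();
  for (int k = 0; k < m; ++k) {
    bool upL = (k == 0) || (v[k] > v[k - 1]);
    bool upR = (k == m - 1) || (v[k] > v[k + 1]);
    if (upL && upR) mx.push_back(v[k]);
    else if (k > 0 && k < m - 1 && v[k] < v[k - 1] && v[k] < v[k + 1])
      mn.push_back(v[k]);
  }
}

// [[Rcpp::export]]
NumericVector box_smooth_cpp(NumericVector x, IntegerVector chrom_start,
                             IntegerVector chrom_end, int half_width) {
  NumericVector out(x.size());
  for (int c = 0; c < chrom_start.size(); ++c) {
    int s = chrom_start[c], e = chrom_end[c];
    box_smooth_range(&x[s], e - s + 1, half_width, &out[s]);
  }
  return out;
}

// [[Rcpp::export]]
List profile_extrema_cpp(NumericVector x, IntegerVector chrom_start,
                         IntegerVector chrom_end) {
  std::vector<double> mx, mn;
  for (int c = 0; c < chrom_start.size(); ++c) {
    int s = chrom_start[c], e = chrom_end[c];
    extrema_range(&x[s], e - s + 1, mx, mn);
  }
  std::sort(mx.begin(), mx.end());
  std::sort(mn.begin(), mn.end());
  return List::create(_["max"] = wrap(mx), _["min"] = wrap(mn));
}

// Permutation null for the recurrent-region caller. Rt is the rectified
// binned cohort, bins x samples (so one sample is contiguous in memory).
// Each permutation cyclically shifts every sample independently within each
// chromosome by the supplied offset, re-aggregates across samples, smooths
// at every half-width, and pools the extrema heights per scale. The offsets
// matrix (n_perm rows, n_samples * n_chrom columns, sample-major) is drawn
// in R so that all randomness flows from the caller's seed.
// [[Rcpp::export]]
List perm_null_extrema_cpp(NumericMatrix Rt, IntegerVector chrom_start,
                           IntegerVector chrom_end,
                           IntegerVector half_widths,
                           IntegerMatrix offsets) {
  const int n_bins = Rt.nrow(), n_samples = Rt.ncol();
  const int n_chrom = chrom_start.size();
  const int n_perm = offsets.nrow();
  const int n_scales = half_widths.size();
  if (offsets.ncol() != n_samples * n_chrom)
    stop("offsets must have n_samples * n_chrom columns");

  std::vector<std::vector<double> > mx(n_scales), mn(n_scales);
  std::vector<double> agg(n_bins), sm(n_bins);

  for (int p = 0; p < n_perm; ++p) {
    std::fill(agg.begin(), agg.end(), 0.0);
    for (int s = 0; s < n_samples; ++s) {
      const double* col = &Rt(0, s);
      for (int c = 0; c < n_chrom; ++c) {
        int cs = chrom_start[c], ce = chrom_end[c];
        int len = ce - cs + 1;
        int o = offsets(p, s * n_chrom + c) % len;
        // agg[cs + b] += col[cs + (b + o) mod len], split to avoid modulo
        int head = len - o;
        for (int b = 0; b < head; ++b) agg[cs + b] += col[cs + b + o];
        for (int b = head; b < len; ++b) agg[cs + b] += col[cs + b - head];
      }
    }
    for (int k = 0; k < n_scales; ++k) {
      for (int c = 0; c < n_chrom; ++c) {
        int cs = chrom_start[c], ce = chrom_end[c];
        box_smooth_range(&agg[cs], ce - cs + 1, half_widths[k], &sm[cs]);
        extrema_range(&sm[cs], ce - cs + 1, mx[k], mn[k]);
      }
    }
  }
  List out(n_scales);
  for (int k = 0; k < n_scales; ++k) {
    std::sort(mx[k].begin(), mx[k].end());
    std::sort(mn[k].begin(), mn[k].end());
    out[k] = List::create(_["max"] = wrap(mx[k]), _["min"] = wrap(mn[k]));
  }
  return out;
}
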