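#include <Rcpp.h>
using namespace Rcpp;

// Topographic peak analysis of a 1-D series, shared by the spectral
// ("frequency step") and temporal ("time step") passes.
//
// A peak is an interior strict local maximum (left neighbour lower, right
// neighbour not higher; the first sample of a plateau wins).  Prominence is
// the height above the higher of the two flanking minima, where each
// flanking minimum is the lowest value between the peak and the nearest
// strictly higher sample (or the window edge).  Widths are measured at
// height - prominence/2 with linear interpolation, clipped at the bases.

struct Peak1D {
  int idx;          // 0-based apex index
  double height;
  double prominence;
  double lo, hi;    // fractional 0-based positions of half-prominence crossings
};

static std::vector<Peak1D> analyze_peaks(const double* x, int n) {
  std::vector<Peak1D> out;
  if (n < 3) return out;
  for (int i = 1; i < n - 1; ++i) {
    if (!(x[i] > x[i - 1])) continue;
    // allow flat-topped peaks: advance over the plateau
    int j = i;
    while (j < n - 1 && x[j + 1] == x[i]) ++j;
    if (j >= n - 1 || x[j + 1] > x[i]) { i = j; continue; }
    double h = x[i];
    // left base: min until a strictly higher sample or the edge
    double lmin = h; int lbase = i;
    for (int k = i - 1; k >= 0; --k) {
      if (x[k] > h) break;
      if (x[k] < lmin) { lmin = x[k]; lbase = k; }
    }
    // right base
    double rmin = h; int rbase = i;
    for (int k = j + 1; k < n; ++k) {
      if (x[k] > h) break;
      if (x[k] < rmin) { rmin = x[k]; rbase = k; }
    }
    double prom = h - std::max(lmin, rmin);
    if (!(prom > 0)) { i = j; continue; }
    double ref = h - prom / 2.0;
    // left crossing
    double lo = (double)lbase;
    for (int k = i; k > lbase; --k) {
      if (x[k - 1] < ref) {
        lo = (k - 1) + (ref - x[k - 1]) / (x[k] - x[k - 1]);
        break;
      }
    }
    // right crossing
    double hi = (double)rbase;
    for (int k = j; k < rbase; ++k) {
      if (x[k + 1] < ref) {
        hi = k + (x[k] - ref) / (x[k] - x[k + 1]);
        break;
      }
    }
    Peak1D p; p.idx = i; p.height = h; p.prominence = prom; p.lo = lo; p.hi = hi;
    out.push_back(p);
    i = j;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame peaks_1d_cpp(NumericVector x) {
  std::vector<Peak1D> ps = analyze_peaks(REAL(x), x.size());
  int m = ps.size();
  IntegerVector idx(m); NumericVector h(m), prom(m), lo(m), hi(m);
  for (int i = 0; i < m; ++i) {
    idx[i] = ps[i].idx + 1;  // 1-based for R
    h[i] = ps[i].height; prom[i] = ps[i].prominence;
    lo[i] = ps[i].lo + 1; hi[i] = ps[i].hi + 1;
  }
  return DataFrame::create(_["idx"] = idx, _["height"] = h,
                           _["prominence"] = prom, _["lo"] = lo, _["hi"] = hi);
}

// Per-column scan of a (frequency x time) dB matrix: peaks and prominence
// bases are computed over the whole column (full spectrum), and for every
// column the largest-prominence peak whose apex row lies in [row_lo, row_hi]
// (1-based, inclusive) is reported (ties: lowest row), or zeros if none.
// [[Rcpp::export]]
List col_prominence_cpp(NumericMatrix m, int row_lo, int row_hi) {
  int nr = m.nrow(), nc = m.ncol();
  NumericVector value(nc), row_at(nc), width(nc);
  std::vector<double> col(nr);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) col[i] = m(i, j);
    std::vector<Peak1D> ps = analyze_peaks(col.data(), nr);
    double best = 0; int bi = -1;
    for (size_t k = 0; k < ps.size(); ++k) {
      if (ps[k].idx + 1 < row_lo || ps[k].idx + 1 > row_hi) continue;
      if (ps[k].prominence > best) { best = ps[k].prominence; bi = (int)k; }
    }
    if (bi >= 0) {
      value[j] = ps[bi].prominence;
      row_at[j] = ps[bi].idx + 1;
      width[j] = ps[bi].hi - ps[bi].lo;
    } else {
      value[j] = 0; row_at[j] = NA_REAL; width[j] = NA_REAL;
    }
  }
  return List::create(_["value"] = value, _["row_at"] = row_at,
                      _["width"] = width);
}
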