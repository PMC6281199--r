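#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of buf[0..n), destroys buffer order
static double med_inplace(std::vector<double> &buf, int n) {
  if (n <= 0) return NA_REAL;
  int h = n / 2;
  std::nth_element(buf.begin(), buf.begin() + h, buf.begin() + n);
  double m = buf[h];
  if (n % 2 == 0) {
    double lo = *std::max_element(buf.begin(), buf.begin() + h);
    m = 0.5 * (m + lo);
  }
  return m;
}

// Cascade of second-order (or first-order, with trailing zeros) sections,
// direct form II transposed. sos: k x 5 matrix, columns b0 b1 b2 a1 a2
// (a0 normalized to 1).
// [[Rcpp::export]]
NumericVector sos_filter_cpp(NumericMatrix sos, NumericVector x) {
  int n = x.size(), k = sos.nrow();
  NumericVector y = clone(x);
  for (int s = 0; s < k; ++s) {
    double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    double a1 = sos(s, 3), a2 = sos(s, 4);
    double z1 = 0.0, z2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double xi = y[i];
      double yi = b0 * xi + z1;
      z1 = b1 * xi - a1 * yi + z2;
      z2 = b2 * xi - a2 * yi;
      y[i] = yi;
    }
  }
  return y;
}

// Per-sample closed feedback loop: AR(2) oscillator plant driven by
// innovations plus (clipped, delayed, band-pass-filtered) feedback current.
// Returns plant output (uV) and stimulator command (V).
//
// plant:  y[t] = c1 y[t-1] + c2 y[t-2] + innov[t]
//                + drive * diff_scale * (cmd[t] - cmd[t-1])
//         (the command couples to the oscillator's velocity equation: the
//         normalized differentiator advances the drive by 90 degrees with
//         unit gain at the natural frequency, so a command in phase with
//         the recorded oscillation pumps energy into it)
// filter: biquad (b0 b1 b2 a1 a2) acting on preamp * y[t-1]
// cmd:    while stim_mask: polarity * clip(delayed filter output) where
//         ext_mask == 0 (closed-loop feedback), else the supplied external
//         command (Open sinusoid / Brain replay). Filter state runs
//         continuously so segment boundaries carry no transients.
// [[Rcpp::export]]
List closed_loop_cpp(NumericVector innov, double c1, double c2,
                     NumericVector biquad, double preamp, int delay,
                     double limit, double polarity, double drive,
                     double diff_scale, IntegerVector stim_mask,
                     NumericVector ext_cmd, IntegerVector ext_mask) {
  int n = innov.size();
  NumericVector y(n), cmd(n);
  double b0 = biquad[0], b1 = biquad[1], b2 = biquad[2];
  double a1 = biquad[3], a2 = biquad[4];
  double z1 = 0.0, z2 = 0.0;
  std::vector<double> dline(delay > 0 ? delay : 1, 0.0);
  int dpos = 0;
  double y1 = 0.0, y2 = 0.0, cprev = 0.0;
  for (int t = 0; t < n; ++t) {
    // filter sees the most recent available (previous) plant sample
    double xi = preamp * y1;
    double v = b0 * xi + z1;
    z1 = b1 * xi - a1 * v + z2;
    z2 = b2 * xi - a2 * v;
    double w;
    if (delay > 0) {
      w = dline[dpos];
      dline[dpos] = v;
      dpos = (dpos + 1) % delay;
    } else {
      w = v;
    }
    double c = 0.0;
    if (stim_mask[t]) {
      c = ext_mask[t] ? ext_cmd[t] : polarity * w;
      if (c > limit) c = limit;
      if (c < -limit) c = -limit;
    }
    cmd[t] = c;
    double yt = c1 * y1 + c2 * y2 + innov[t] +
      drive * diff_scale * (c - cprev);
    cprev = c;
    y2 = y1;
    y1 = yt;
    y[t] = yt;
  }
  return List::create(_["output"] = y, _["command"] = cmd);
}

// Row medians over a per-row closed index range [start, end] (1-based).
// [[Rcpp::export]]
NumericVector row_medians_range_cpp(NumericMatrix x, IntegerVector start,
                                    IntegerVector end) {
  int nr = x.nrow();
  NumericVector out(nr);
  std::vector<double> buf(x.ncol());
  for (int r = 0; r < nr; ++r) {
    int s = start[r] - 1, e = end[r] - 1, n = 0;
    for (int c = s; c <= e; ++c) buf[n++] = x(r, c);
    out[r] = med_inplace(buf, n);
  }
  return out;
}

// Column medians.
// [[Rcpp::export]]
NumericVector col_medians_cpp(NumericMatrix x) {
  int nc = x.ncol(), nr = x.nrow();
  NumericVector out(nc);
  std::vector<double> buf(nr);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) buf[r] = x(r, c);
    out[c] = med_inplace(buf, nr);
  }
  return out;
}

// Band-window summary recomputed per resampling draw.
//
// X: trials x cols matrix of epoch-median-normalized power, columns restricted
//    to the valid baseline and summary-window samples of each band frequency.
// colfreq: 0-based frequency index per column (nfreq frequencies).
// coltype: 0 = baseline column, 1 = summary-window column.
// draws:   ndraw x nsel matrix of 1-based trial indices (bootstrap or
//          permutation group membership).
// For each draw: per-column median across the selected trials; per frequency
// the grand median of its baseline columns; dB = 10 log10(median / baseline);
// returned value is the mean dB over all window columns (freq x time).
// [[Rcpp::export]]
NumericVector band_summary_draws_cpp(NumericMatrix X, IntegerVector colfreq,
                                     IntegerVector coltype, int nfreq,
                                     IntegerMatrix draws) {
  int ncol = X.ncol(), ndraw = draws.nrow(), nsel = draws.ncol();
  NumericVector out(ndraw);
  std::vector<double> med(ncol);
  std::vector<double> buf(std::max(nsel, ncol));
  std::vector<std::vector<double> > basecols(nfreq);
  for (int d = 0; d < ndraw; ++d) {
    for (int c = 0; c < ncol; ++c) {
      const double *colp = &X(0, c);
      for (int s = 0; s < nsel; ++s) buf[s] = colp[draws(d, s) - 1];
      med[c] = med_inplace(buf, nsel);
    }
    for (int f = 0; f < nfreq; ++f) basecols[f].clear();
    for (int c = 0; c < ncol; ++c)
      if (coltype[c] == 0) basecols[colfreq[c]].push_back(med[c]);
    std::vector<double> base(nfreq, NA_REAL);
    for (int f = 0; f < nfreq; ++f) {
      int nb = basecols[f].size();
      base[f] = med_inplace(basecols[f], nb);
    }
    double acc = 0.0;
    int nw = 0;
    for (int c = 0; c < ncol; ++c) {
      if (coltype[c] == 1) {
        acc += 10.0 * std::log10(med[c] / base[colfreq[c]]);
        ++nw;
      }
    }
    out[d] = acc / nw;
  }
  return out;
}
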