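// Sample-level DSP kernels: time-varying formant resonators for the vowel
// synthesizer, minimum-distance peak picking for the amplitude-variation
// feature, and autocorrelation-LPC formant estimation per analysis frame.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Cascade of K second-order resonators with per-sample center frequencies.
// Coefficients: C = -r^2, B = 2 r cos(theta), r = exp(-pi * bw / fs); the
// numerator gain normalizes each section to unity gain AT the resonance
// peak, so a drifting center modulates timbre rather than amplitude.
// [[Rcpp::export(name = ".resonator_cascade_cpp")]]
NumericVector resonator_cascade_cpp(NumericVector x, NumericMatrix f_hz,
                                    NumericVector bw_hz, double fs) {
  const int n = x.size();
  const int k = bw_hz.size();
  if (f_hz.nrow() != n || f_hz.ncol() != k)
    stop("formant track dimensions do not match signal/bandwidths");
  NumericVector y = clone(x);
  const double pi = 3.14159265358979323846;
  for (int j = 0; j < k; ++j) {
    const double r = std::exp(-pi * bw_hz[j] / fs);
    const double c = -r * r;
    double y1 = 0.0, y2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double th = 2.0 * pi * f_hz(i, j) / fs;
      const double b = 2.0 * r * std::cos(th);
      // |1 - B z^-1 - C z^-2| at z = e^{i th} (the resonance peak)
      const double c2 = std::cos(2.0 * th), s2 = std::sin(2.0 * th);
      const double x_re = 1.0 - b * std::cos(th) + r * r * c2;
      const double x_im = b * std::sin(th) - r * r * s2;
      const double a = std::sqrt(x_re * x_re + x_im * x_im);
      const double yi = a * y[i] + b * y1 + c * y2;
      y2 = y1;
      y1 = yi;
      y[i] = yi;
    }
  }
  return y;
}

// Direct-form-II-transposed IIR filter (single pass); a[0] must be 1.
// [[Rcpp::export(name = ".iir_filter_cpp")]]
NumericVector iir_filter_cpp(NumericVector x, NumericVector b,
                             NumericVector a) {
  const int n = x.size();
  const int nb = b.size(), na = a.size();
  const int ns = std::max(nb, na) - 1;
  std::vector<double> w(ns + 1, 0.0);
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    const double yi = b[0] * x[i] + w[0];
    for (int k = 0; k < ns; ++k) {
      const double bk = (k + 1 < nb) ? b[k + 1] : 0.0;
      const double ak = (k + 1 < na) ? a[k + 1] : 0.0;
      w[k] = bk * x[i] - ak * yi + ((k + 1 <= ns - 1) ? w[k + 1] : 0.0);
    }
    y[i] = yi;
  }
  return y;
}

// Local maxima of x honoring a minimum spacing, greedily from the tallest
// candidate down (ties broken by position). 1-based indices.
// [[Rcpp::export(name = ".peaks_min_dist_cpp")]]
IntegerVector peaks_min_dist_cpp(NumericVector x, int min_dist) {
  const int n = x.size();
  std::vector<int> cand;
  for (int i = 1; i + 1 < n; ++i)
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) cand.push_back(i);
  std::sort(cand.begin(), cand.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] > x[b];
    return a < b;
  });
  std::vector<bool> blocked(n, false);
  std::vector<int> keep;
  for (int idx : cand) {
    if (blocked[idx]) continue;
    keep.push_back(idx);
    const int lo = std::max(0, idx - min_dist);
    const int hi = std::min(n - 1, idx + min_dist);
    for (int i = lo; i <= hi; ++i) blocked[i] = true;
  }
  std::sort(keep.begin(), keep.end());
  IntegerVector out(keep.size());
  for (size_t i = 0; i < keep.size(); ++i) out[i] = keep[i] + 1;
  return out;
}

// Autocorrelation-method LPC formant estimation on a matrix of windowed,
// pre-emphasized frames (one column per frame). For each frame: Levinson-
// Durbin recursion of the given order, polynomial roots, conversion of
// upper-half-plane roots to (frequency, bandwidth), then candidate
// filtering (bandwidth < bw_max, freq in [f_lo, f_hi]); the two lowest
// surviving frequencies are F1 and F2. Returns an n_frames x 3 matrix
// (F1, F2, valid); invalid frames carry NA frequencies.
// [[Rcpp::export(name = ".lpc_formants_cpp")]]
NumericMatrix lpc_formants_cpp(NumericMatrix frames, int order, double fs,
                               double bw_max, double f_lo, double f_hi) {
  const int len = frames.nrow();
  const int nf = frames.ncol();
  const double pi = 3.14159265358979323846;
  NumericMatrix out(nf, 3);
  std::vector<double> r(order + 1), a(order + 1), a_prev(order + 1);
  std::vector<std::complex<double>> z_warm;
  for (int fidx = 0; fidx < nf; ++fidx) {
    out(fidx, 0) = NA_REAL;
    out(fidx, 1) = NA_REAL;
    out(fidx, 2) = 0.0;
    // biased autocorrelation
    for (int lag = 0; lag <= order; ++lag) {
      double s = 0.0;
      for (int i = lag; i < len; ++i) s += frames(i, fidx) * frames(i - lag, fidx);
      r[lag] = s;
    }
    if (r[0] <= 0.0 || !std::isfinite(r[0])) continue;
    // Levinson-Durbin: prediction polynomial A(z) = 1 - sum a_k z^-k
    double err = r[0];
    bool ok = true;
    std::fill(a.begin(), a.end(), 0.0);
    for (int m = 1; m <= order; ++m) {
      double acc = r[m];
      for (int k = 1; k < m; ++k) acc -= a[k] * r[m - k];
      if (err <= 0.0 || !std::isfinite(err)) { ok = false; break; }
      const double kref = acc / err;
      std::copy(a.begin(), a.end(), a_prev.begin());
      a[m] = kref;
      for (int k = 1; k < m; ++k) a[k] = a_prev[k] - kref * a_prev[m - k];
      err *= (1.0 - kref * kref);
    }
    if (!ok || err <= 0.0 || !std::isfinite(err)) continue;
    // roots of z^order - a1 z^(order-1) - ... - a_order, by Durand-Kerner
    // (cheap, LPC polynomials are well conditioned); eigenvalue fallback
    std::vector<std::complex<double>> coef(order + 1);
    coef[0] = 1.0;
    for (int k = 1; k <= order; ++k) coef[k] = -a[k];
    std::vector<std::complex<double>> z(order);
    if ((int)z_warm.size() == order) {
      z = z_warm; // consecutive frames have nearly identical poles
    } else {
      const std::complex<double> seed0(0.4, 0.9);
      std::complex<double> zp(1.0, 0.0);
      for (int k = 0; k < order; ++k) { zp *= seed0; z[k] = zp; }
    }
    bool converged = false;
    for (int it = 0; it < 80 && !converged; ++it) {
      double delta = 0.0;
      for (int k = 0; k < order; ++k) {
        std::complex<double> p(coef[0]);
        for (int j = 1; j <= order; ++j) p = p * z[k] + coef[j];
        std::complex<double> q(1.0, 0.0);
        for (int j = 0; j < order; ++j)
          if (j != k) q *= (z[k] - z[j]);
        const std::complex<double> step = p / q;
        z[k] -= step;
        delta = std::max(delta, std::abs(step));
      }
      converged = delta < 1e-7;
    }
    arma::cx_vec roots(order);
    if (converged) {
      for (int k = 0; k < order; ++k) roots[k] = z[k];
      z_warm = z;
    } else {
      z_warm.clear();
      arma::vec rc(order + 1);
      for (int k = 0; k <= order; ++k) rc[k] = coef[k].real();
      if (!arma::roots(roots, arma::conv_to<arma::cx_vec>::from(rc)))
        continue;
    }
    std::vector<double> freqs;
    for (arma::uword i = 0; i < roots.n_elem; ++i) {
      const double re = roots[i].real(), im = roots[i].imag();
      if (im <= 0.0) continue;
      const double mod = std::sqrt(re * re + im * im);
      if (mod <= 0.0 || mod >= 1.0) continue;
      const double f = std::atan2(im, re) * fs / (2.0 * pi);
      const double bw = -std::log(mod) * fs / pi;
      if (bw < bw_max && f >= f_lo && f <= f_hi) freqs.push_back(f);
    }
    if (freqs.size() < 2) continue;
    std::sort(freqs.begin(), freqs.end());
    out(fidx, 0) = freqs[0];
    out(fidx, 1) = freqs[1];
    out(fidx, 2) = 1.0;
  }
  return out;
}
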