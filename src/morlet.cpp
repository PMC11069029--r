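// Morlet wavelet time-frequency decomposition.
//
// Complex Morlet with Gaussian envelope sigma_t = n_cycles / (2*pi*f) and
// unit energy, applied by frequency-domain multiplication: the wavelet's
// spectrum is a Gaussian centred on the analysis frequency,
//   W(f') = sqrt(2) * pi^(1/4) * sqrt(sigma_t) * exp(-2 pi^2 sigma_t^2 (f'-f)^2),
// sampled on the padded FFT grid (analytic: negative frequencies zero).
// Power is |x * w|^2 on the subsampled grid t = 0, D, 2D, ...  The
// decimated samples are computed exactly by folding (aliasing) the product
// spectrum onto nfft/D bins before the inverse FFT, which only changes the
// transform length, not the values.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// epochs: trials x channels x time (numeric 3D array); decim = D >= 1 with
// nfft % D == 0.  Returns trials x channels x nfreq x ceil(n_time/D).
// [[Rcpp::export(rng = false)]]
NumericVector morlet_power_cpp(NumericVector epochs, NumericVector freqs,
                               double n_cycles, double fs, int decim,
                               int nfft) {
  IntegerVector dims = epochs.attr("dim");
  const int n_trial = dims[0], n_chan = dims[1], n_time = dims[2];
  const int n_freq = freqs.size();
  if (nfft < n_time) stop("nfft must be >= epoch length");
  if (decim < 1 || nfft % decim != 0) stop("nfft must be a multiple of decim");
  const int L = nfft / decim;
  const int n_dec = (n_time + decim - 1) / decim;
  if (n_dec > L) stop("decimated length exceeds folded transform length");

  // wavelet spectra on the padded grid (analytic: positive freqs only)
  arma::vec fgrid(nfft);
  for (int k = 0; k < nfft; ++k) {
    double f = (double)k * fs / nfft;
    if (k > nfft / 2) f -= fs;
    fgrid[k] = f;
  }
  arma::mat wspec(nfft, n_freq, arma::fill::zeros);
  for (int j = 0; j < n_freq; ++j) {
    double f0 = freqs[j];
    double st = n_cycles / (2.0 * M_PI * f0);
    double amp = std::sqrt(2.0) * std::pow(M_PI, 0.25) * std::sqrt(st);
    for (int k = 0; k < nfft; ++k) {
      if (fgrid[k] <= 0.0) continue;
      double d = fgrid[k] - f0;
      double e = -2.0 * M_PI * M_PI * st * st * d * d;
      if (e > -25.0) wspec(k, j) = amp * std::exp(e);  // else ~0: skip later
    }
  }

  NumericVector out((R_xlen_t)n_trial * n_chan * n_freq * n_dec);
  out.attr("dim") = IntegerVector::create(n_trial, n_chan, n_freq, n_dec);

  arma::cx_vec sig(nfft), folded(L);
  for (int c = 0; c < n_chan; ++c) {
    for (int t = 0; t < n_trial; ++t) {
      sig.zeros();
      for (int i = 0; i < n_time; ++i) {
        double v = epochs[t + (R_xlen_t)n_trial * (c + (R_xlen_t)n_chan * i)];
        sig[i] = arma::cx_double(v, 0.0);
      }
      arma::cx_vec spec = arma::fft(sig);
      for (int j = 0; j < n_freq; ++j) {
        folded.zeros();
        const double* w = wspec.colptr(j);
        for (int k = 0; k < nfft; ++k) {
          if (w[k] != 0.0) folded[k % L] += spec[k] * w[k];
        }
        arma::cx_vec conv = arma::ifft(folded) / (double)decim;
        for (int d = 0; d < n_dec; ++d) {
          double re = conv[d].real(), im = conv[d].imag();
          out[t + (R_xlen_t)n_trial *
                  (c + (R_xlen_t)n_chan * (j + (R_xlen_t)n_freq * d))] =
              (re * re + im * im) / fs;
        }
      }
    }
  }
  return out;
}
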