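#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Complex Morlet wavelet power, evaluated only at the requested samples.
//
// x:      time x channel signal matrix
// sfreq:  sampling rate (Hz)
// freqs:  wavelet center frequencies (Hz)
// cycles: number of cycles per frequency (sigma_t = cycles / (2*pi*f))
// keep:   1-based time indices at which power is returned
//
// Returns a cube (n_keep, n_channel, n_freq).  Each wavelet is scaled so
// that a unit-amplitude sinusoid at the bin frequency yields power ~1
// (amplitude-squared convention).  Wavelet support is +/- 3 sigma_t,
// truncated to the signal length; the signal is zero padded at the
// edges.
//
// Implementation: per channel, a lagged copy of the signal is assembled
// once (lags -hmax..hmax at every kept sample) and each frequency's
// real/imaginary wavelet pair hits the relevant lag rows as one small
// matrix product, so the cost scales with the true wavelet supports.
// [[Rcpp::export]]
arma::cube morlet_power_cpp(const arma::mat& x, double sfreq,
                            const arma::vec& freqs, const arma::vec& cycles,
                            const arma::uvec& keep) {
  const uword n = x.n_rows, nch = x.n_cols, nf = freqs.n_elem,
              nk = keep.n_elem;
  std::vector<uword> half(nf);
  uword hmax = 0;
  for (uword f = 0; f < nf; ++f) {
    double sigma = cycles(f) / (2.0 * M_PI * freqs(f));
    uword h = (uword) std::ceil(3.0 * sigma * sfreq);
    if (h > n - 1) h = n - 1;
    half[f] = h;
    if (h > hmax) hmax = h;
  }

  // wavelets as 2 x L (real; imag) blocks, amplitude normalized
  std::vector<mat> W(nf);
  for (uword f = 0; f < nf; ++f) {
    const uword h = half[f], L = 2 * h + 1;
    const double sigma = cycles(f) / (2.0 * M_PI * freqs(f));
    mat w(2, L);
    double gsum = 0.0;
    for (uword j = 0; j < L; ++j) {
      double t = ((double) j - (double) h) / sfreq;
      double g = std::exp(-t * t / (2.0 * sigma * sigma));
      gsum += g;
      w(0, j) = g * std::cos(2.0 * M_PI * freqs(f) * t);
      w(1, j) = g * std::sin(2.0 * M_PI * freqs(f) * t);
    }
    W[f] = w * (2.0 / gsum);
  }

  cube out(nk, nch, nf);
  vec px(n + 2 * hmax, fill::zeros);
  mat lag(2 * hmax + 1, nk);
  for (uword c = 0; c < nch; ++c) {
    px.subvec(hmax, hmax + n - 1) = x.col(c);
    for (uword k = 0; k < nk; ++k)
      lag.col(k) = px.subvec(keep(k) - 1, keep(k) - 1 + 2 * hmax);
    for (uword f = 0; f < nf; ++f) {
      const uword h = half[f];
      mat ri = W[f] * lag.rows(hmax - h, hmax + h);   // 2 x nk
      for (uword k = 0; k < nk; ++k)
        out(k, c, f) = ri(0, k) * ri(0, k) + ri(1, k) * ri(1, k);
    }
  }
  return out;
}
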