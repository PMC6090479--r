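#' Background EEG noise: 1/f plus white
#'
#' Gaussian background activity composed of a pink (power spectral density
#' proportional to `1/f^alpha`) component and a white component. The pink
#' component is produced by shaping the spectrum of Gaussian white noise with
#' deterministic weights `max(f, f_floor)^(-alpha/2)` and rescaling so that
#' its theoretical standard deviation equals `pink_sd` exactly; the result is
#' Gaussian because the shaping is linear. The spectral floor below
#' `f_floor` keeps very-low-frequency drift bounded, as real scalp EEG
#' spectra flatten toward 0 Hz.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param pink_sd standard deviation of the pink component (microvolts).
#' @param white_sd standard deviation of the white component (microvolts).
#' @param alpha spectral exponent of the pink component.
#' @param f_floor low-frequency shoulder (Hz) below which the pink spectrum
#'   is flat.
#' @return numeric vector of length `n` (microvolts). Total variance is
#'   `pink_sd^2 + white_sd^2`.
#' @examples
#' set.seed(1)
#' x <- generate_noise(5000, 500)
#' sd(x)
#' @export
generate_noise <- function(n, fs = 500, pink_sd = 8, white_sd = 3,
                           alpha = 1, f_floor = 0.25) {
  if (pink_sd < 0 || white_sd < 0) stop("noise SDs must be >= 0",
                                        call. = FALSE)
  out <- numeric(n)
  if (pink_sd > 0) out <- out + pink_sd * pink_noise_unit(n, fs, alpha, f_floor)
  if (white_sd > 0) out <- out + rnorm(n, 0, white_sd)
  out
}

# matrix variant: independent columns, one FFT call. The FFT length is
# padded to the next highly composite size (2^a 3^b 5^c) so the transform
# stays O(n log n) for arbitrary recording lengths; the pad is discarded.
generate_noise_matrix <- function(n, k, fs = 500, pink_sd = 8, white_sd = 3,
                                  alpha = 1, f_floor = 0.25) {
  out <- matrix(0, n, k)
  if (pink_sd > 0) {
    nn <- stats::nextn(n, c(2, 3, 5))
    w <- pink_weights(nn, fs, alpha, f_floor)
    z <- matrix(rnorm(nn * k), nn, k)
    shaped <- Re(stats::mvfft(stats::mvfft(z) * w, inverse = TRUE)) / nn
    out <- out + pink_sd * shaped[seq_len(n), , drop = FALSE] /
      pink_weight_sd(w, nn)
  }
  if (white_sd > 0) out <- out + matrix(rnorm(n * k, 0, white_sd), n, k)
  out
}

pink_weights <- function(n, fs, alpha, f_floor) {
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)               # fold to physical frequencies
  w <- pmax(f, f_floor)^(-alpha / 2)
  w[1] <- 0                          # no DC power
  w
}

# theoretical sd of Re(ifft(fft(z) * w))/n for unit white z
pink_weight_sd <- function(w, n) sqrt(sum(w^2) / n)

pink_noise_unit <- function(n, fs, alpha, f_floor) {
  nn <- stats::nextn(n, c(2, 3, 5))
  w <- pink_weights(nn, fs, alpha, f_floor)
  z <- rnorm(nn)
  shaped <- Re(stats::fft(stats::fft(z) * w, inverse = TRUE)) / nn
  shaped[seq_len(n)] / pink_weight_sd(w, nn)
}
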