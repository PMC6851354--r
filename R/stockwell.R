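#' Stockwell (S-) transform of a signal segment
#'
#' Time-frequency representation with a frequency-scaled Gaussian window:
#' at analysis frequency f the window has time-domain standard deviation
#' 1/f (equivalently sigma_f = f/(2*pi) in frequency), so resolution
#' adapts across the HFO bands. Computed voice-by-voice in the frequency
#' domain: the DFT of the signal is shifted by the voice frequency,
#' multiplied by the sampled Gaussian, and inverse transformed.
#'
#' Analysis frequencies are the DFT bins of the segment falling inside
#' `[fmin_hz, fmax_hz]`, optionally thinned to a step of about
#' `freq_step_hz` for speed.
#'
#' @param x numeric signal segment (at least 64 samples)
#' @param fs_hz sampling rate
#' @param fmin_hz,fmax_hz frequency range; `fmax_hz` must not exceed
#'   Nyquist
#' @param freq_step_hz optional approximate frequency step; `NULL` keeps
#'   every DFT bin in range
#' @return a list of class `tf_map` with elements `power` (frequencies x
#'   time, squared magnitude), `freqs_hz`, and `times_s`
#' @examples
#' x <- sin(2 * pi * 120 * seq(0, 0.5, by = 1 / 2000))
#' m <- st_transform(x, 2000, 80, 250)
#' m$freqs_hz[which.max(rowMeans(m$power))]   # ~120
#' @export
st_transform <- function(x, fs_hz, fmin_hz, fmax_hz, freq_step_hz = NULL) {
  n <- length(x)
  if (n < 64L) stop("invalid-argument: segment must have >= 64 samples")
  if (fmax_hz > fs_hz / 2) stop("invalid-argument: fmax above Nyquist")
  if (fmin_hz <= 0 || fmin_hz >= fmax_hz)
    stop("invalid-argument: need 0 < fmin < fmax")
  kmin <- max(1L, ceiling(fmin_hz * n / fs_hz))
  kmax <- min(floor(n / 2), floor(fmax_hz * n / fs_hz))
  if (kmax < kmin) stop("invalid-argument: no DFT bin inside band")
  step <- if (is.null(freq_step_hz)) 1L else
    max(1L, round(freq_step_hz * n / fs_hz))
  kvec <- seq(kmin, kmax, by = step)
  X <- stats::fft(x) / n
  m <- 0:(n - 1L)
  m_off <- ifelse(m > n / 2, m - n, m)    # signed frequency offsets
  power <- matrix(0, length(kvec), n)
  for (i in seq_along(kvec)) {
    k <- kvec[i]
    gauss <- exp(-2 * pi^2 * m_off^2 / k^2)
    shifted <- X[((m + k) %% n) + 1L]
    power[i, ] <- Mod(stats::fft(shifted * gauss, inverse = TRUE))^2
  }
  structure(list(power = power, freqs_hz = kvec * fs_hz / n,
                 times_s = m / fs_hz),
            class = "tf_map")
}

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d frequencies (%.1f-%.1f Hz) x %d samples\n",
              length(x$freqs_hz), min(x$freqs_hz), max(x$freqs_hz),
              length(x$times_s)))
  invisible(x)
}
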