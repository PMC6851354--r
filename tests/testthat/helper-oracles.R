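# Shared helpers and independent oracles for the test suite.

# Jaccard overlap of two half-open intervals
jaccard <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0))
  union <- (a1 - a0) + (b1 - b0) - inter
  inter / union
}

# segment-averaged one-sided periodogram (Welch-style, boxcar windows),
# in power per Hz, independent of any package code
welch_psd <- function(x, fs, seg_len) {
  n_seg <- floor(length(x) / seg_len)
  acc <- 0
  for (i in seq_len(n_seg)) {
    seg <- x[((i - 1) * seg_len + 1):(i * seg_len)]
    acc <- acc + Mod(fft(seg))^2 / (seg_len * fs)
  }
  psd <- 2 * acc / n_seg            # one-sided
  k <- 2:floor(seg_len / 2)         # skip DC and Nyquist
  list(freq = (k - 1) * fs / seg_len, psd = psd[k])
}

# hand-built minimal EDF writer (independent of the package writer):
# one signal, 1-s records, given physical range
write_edf_oracle <- function(path, x, fs, label, phys_max) {
  n_rec <- length(x) / fs
  stopifnot(n_rec == round(n_rec))
  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(pad("0", 8), pad("", 80), pad("", 80),
                   "01.01.00", "00.00.00", pad(512, 8), pad("", 44),
                   pad(n_rec, 8), pad(1, 8), pad(1, 4)),
            con, eos = NULL)
  writeChar(paste0(pad(label, 16), pad("", 80), pad("uV", 8),
                   pad(-phys_max, 8), pad(phys_max, 8),
                   pad(-32767, 8), pad(32767, 8), pad("", 80),
                   pad(fs, 8), pad("", 32)),
            con, eos = NULL)
  writeBin(as.integer(round(x / phys_max * 32767)), con, size = 2,
           endian = "little")
  invisible(path)
}

# direct definition-based Stockwell oracle: voice-by-voice matrix DFTs,
# no fft() anywhere
st_oracle_power <- function(x, fs, fmin, fmax) {
  n <- length(x)
  m <- 0:(n - 1)
  W <- exp(-2i * pi * outer(m, m) / n)      # DFT matrix
  X <- as.vector(W %*% x) / n
  m_off <- ifelse(m > n / 2, m - n, m)
  kvec <- seq(max(1, ceiling(fmin * n / fs)), floor(fmax * n / fs))
  P <- matrix(0, length(kvec), n)
  for (i in seq_along(kvec)) {
    k <- kvec[i]
    voice <- X[((m + k) %% n) + 1] * exp(-2 * pi^2 * m_off^2 / k^2)
    S <- as.vector(Conj(W) %*% voice)       # inverse DFT, unnormalized
    P[i, ] <- Mod(S)^2
  }
  list(power = P, freqs_hz = kvec * fs / n)
}

# small synthetic background + amplifier noise channel for detector tests
lna_channel <- function(dur_s, fs = 2000, seed = 1, density = 2.3) {
  make_background(dur_s, fs, 20, 3, seed = seed) +
    make_amplifier_noise(dur_s, fs, density, seed = seed + 5000)
}
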