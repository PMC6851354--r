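#' Specification for a synthetic EEG recording
#'
#' Collects the parameters of the synthetic scalp-EEG generator. The
#' defaults emulate an LNA-style low-noise sleep recording: a steep
#' power-law background (power ~ 1/f^3, typical of NREM sleep EEG, total
#' RMS in the tens of microvolts dominated by slow waves), white amplifier
#' noise given as an input noise density in nV/sqrt(Hz) (2.3 for the
#' low-noise amplifier; 21 for a commercial device), ripple-band
#' oscillation bursts with amplitudes drawn from the detected-population
#' distribution (mean 3.89, SD 2.41 microvolts, floored at 0.5 microvolts,
#' roughly the low-noise amplifier's detection limit), and sharp spike
#' transients that produce spurious band-passed oscillations.
#'
#' @param duration_s recording duration in seconds
#' @param fs_hz sampling rate; must exceed 1000 Hz when fast-ripple events
#'   are requested (Nyquist above 500 Hz)
#' @param channel_labels channel names; the defaults are eight bipolar
#'   derivations, four per hemisphere
#' @param background_rms_uv total RMS of the power-law background, in uV
#' @param spectral_exponent background power exponent (power ~ 1/f^exponent)
#' @param amplifier_noise_density_nv white-noise density in nV/sqrt(Hz)
#' @param event_rate_per_min HFO events per minute per channel per band
#' @param event_amp_mean_uv,event_amp_sd_uv,event_amp_min_uv normal
#'   amplitude distribution of injected HFO peaks (uV), truncated below
#' @param event_cycles_min,event_cycles_max uniform range of oscillation
#'   cycles per event
#' @param spike_rate_per_min sharp-transient rate per minute per channel
#' @param bands bands in which to inject events: subset of
#'   `c("ripple", "fast_ripple")`
#' @param seed integer random seed (mandatory for reproducibility)
#' @return a list of class `recording_spec`
#' @export
recording_spec <- function(duration_s = 1800, fs_hz = 2000,
                           channel_labels = c("C4-P4", "P4-O2", "C4-T6",
                                              "T6-O2", "C3-P3", "P3-O1",
                                              "C3-T5", "T5-O1"),
                           background_rms_uv = 20,
                           spectral_exponent = 3,
                           amplifier_noise_density_nv = 2.3,
                           event_rate_per_min = 2,
                           event_amp_mean_uv = 3.89,
                           event_amp_sd_uv = 2.41,
                           event_amp_min_uv = 0.5,
                           event_cycles_min = 6, event_cycles_max = 12,
                           spike_rate_per_min = 1,
                           bands = "ripple",
                           seed = 1L) {
  spec <- list(duration_s = duration_s, fs_hz = fs_hz,
               channel_labels = as.character(channel_labels),
               background_rms_uv = background_rms_uv,
               spectral_exponent = spectral_exponent,
               amplifier_noise_density_nv = amplifier_noise_density_nv,
               event_rate_per_min = event_rate_per_min,
               event_amp_mean_uv = event_amp_mean_uv,
               event_amp_sd_uv = event_amp_sd_uv,
               event_amp_min_uv = event_amp_min_uv,
               event_cycles_min = event_cycles_min,
               event_cycles_max = event_cycles_max,
               spike_rate_per_min = spike_rate_per_min,
               bands = match.arg(bands, c("ripple", "fast_ripple"),
                                 several.ok = TRUE),
               seed = as.integer(seed))
  if (duration_s < 0) stop("invalid-argument: duration_s must be >= 0")
  if (fs_hz <= 0) stop("invalid-argument: fs_hz must be > 0")
  if ("fast_ripple" %in% spec$bands && fs_hz < 2000)
    stop("invalid-argument: fast-ripple events need fs_hz >= 2000")
  if (event_rate_per_min < 0 || spike_rate_per_min < 0)
    stop("invalid-argument: rates must be >= 0")
  if (event_amp_mean_uv <= 0 || event_amp_min_uv <= 0)
    stop("invalid-argument: amplitudes must be > 0")
  structure(spec, class = "recording_spec")
}

#' Power-law (pink/brown) EEG background
#'
#' Synthesizes a Gaussian background whose power spectrum follows
#' 1/f^exponent, by spectral shaping of white noise (FFT filter
#' f^(-exponent/2)), then rescales to the exact requested RMS.
#'
#' @param duration_s duration in seconds (0 gives an empty signal)
#' @param fs_hz sampling rate
#' @param background_rms_uv target RMS in microvolts
#' @param spectral_exponent power-law exponent (1 = classic pink noise)
#' @param seed integer seed
#' @return numeric vector of length `round(duration_s * fs_hz)`, in uV
#' @export
make_background <- function(duration_s, fs_hz, background_rms_uv = 20,
                            spectral_exponent = 1, seed = 1L) {
  if (duration_s < 0) stop("invalid-argument: negative duration")
  if (fs_hz <= 0) stop("invalid-argument: fs_hz must be > 0")
  n <- round(duration_s * fs_hz)
  if (n == 0L) return(numeric(0))
  set.seed(seed)
  w <- stats::rnorm(n)
  wf <- stats::fft(w)
  freq <- seq(0, n - 1L) * fs_hz / n
  freq[freq > fs_hz / 2] <- fs_hz - freq[freq > fs_hz / 2]  # fold
  gain <- c(0, freq[-1L]^(-spectral_exponent / 2))          # kill DC
  x <- Re(stats::fft(wf * gain, inverse = TRUE)) / n
  x <- x - mean(x)
  rms <- sqrt(mean(x^2))
  if (rms == 0) return(x)
  x * background_rms_uv / rms
}

#' White amplifier noise at a given input noise density
#'
#' @param duration_s duration in seconds
#' @param fs_hz sampling rate
#' @param density_nv_sqrthz one-sided noise density in nV/sqrt(Hz); the
#'   resulting signal (in uV) has variance `density^2 * fs/2` in nV^2
#' @param seed integer seed; the same seed yields the same normalized
#'   draw, so two densities differ by an exact scale factor
#' @return numeric vector in microvolts
#' @export
make_amplifier_noise <- function(duration_s, fs_hz, density_nv_sqrthz,
                                 seed = 1L) {
  if (density_nv_sqrthz < 0) stop("invalid-argument: density must be >= 0")
  if (duration_s < 0) stop("invalid-argument: negative duration")
  n <- round(duration_s * fs_hz)
  if (n == 0L) return(numeric(0))
  set.seed(seed)
  sigma_uv <- density_nv_sqrthz * 1e-3 * sqrt(fs_hz / 2)
  stats::rnorm(n) * sigma_uv
}

#' Oscillatory HFO burst waveform
#'
#' A sinusoid at the centre frequency under a tapered envelope (Tukey
#' window with 25% cosine ramps by default, avoiding spectral splatter
#' from step edges), scaled so the peak absolute amplitude equals
#' `peak_amp_uv`. Duration is `n_cycles / centre_freq_hz`.
#'
#' @param centre_freq_hz oscillation frequency; must be below `fs_hz / 2`
#' @param n_cycles number of cycles (>= 1)
#' @param peak_amp_uv peak amplitude in microvolts
#' @param fs_hz sampling rate
#' @param envelope_kind `"tukey"` (25% ramps) or `"hann"`
#' @return numeric waveform in microvolts
#' @export
make_hfo_waveform <- function(centre_freq_hz, n_cycles, peak_amp_uv = 3.89,
                              fs_hz = 2000, envelope_kind = c("tukey",
                                                              "hann")) {
  envelope_kind <- match.arg(envelope_kind)
  if (centre_freq_hz <= 0 || centre_freq_hz >= fs_hz / 2)
    stop("invalid-argument: centre frequency must lie in (0, fs/2)")
  if (n_cycles < 1) stop("invalid-argument: n_cycles must be >= 1")
  n <- round(n_cycles / centre_freq_hz * fs_hz)
  t <- seq_len(n) / fs_hz
  u <- (seq_len(n) - 0.5) / n
  env <- switch(envelope_kind,
                tukey = tukey_env(u, ramp = 0.25),
                hann = 0.5 * (1 - cos(2 * pi * u)))
  x <- sin(2 * pi * centre_freq_hz * t) * env
  x * peak_amp_uv / max(abs(x))
}

tukey_env <- function(u, ramp = 0.25) {
  env <- rep(1, length(u))
  lo <- u < ramp
  hi <- u > 1 - ramp
  env[lo] <- 0.5 * (1 - cos(pi * u[lo] / ramp))
  env[hi] <- 0.5 * (1 - cos(pi * (1 - u[hi]) / ramp))
  env
}

#' Artifact transient waveform (spike or muscle burst)
#'
#' `"spike"` is a sharp biphasic transient (derivative-of-Gaussian shape)
#' whose band-passed version rings inside the HFO bands; `"muscle"` is a
#' broadband noise burst under a tapered envelope. Both scale linearly
#' with `peak_amp_uv`.
#'
#' @param kind `"spike"` or `"muscle"`
#' @param peak_amp_uv peak amplitude in microvolts
#' @param duration_ms transient duration in milliseconds
#' @param fs_hz sampling rate
#' @param seed integer seed (used by the muscle noise burst; spikes are
#'   deterministic)
#' @return numeric waveform in microvolts
#' @export
make_transient <- function(kind = c("spike", "muscle"), peak_amp_uv = 50,
                           duration_ms = 50, fs_hz = 2000, seed = 1L) {
  kind <- match.arg(kind)
  if (duration_ms <= 0) stop("invalid-argument: duration_ms must be > 0")
  n <- max(8L, round(duration_ms / 1000 * fs_hz))
  if (kind == "spike") {
    # sharp biphasic wave: fast rise, steep fall through a negative
    # undershoot, slow recovery; the kinks carry broadband energy that
    # rings inside the HFO bands after filtering
    u <- (seq_len(n) - 0.5) / n
    x <- numeric(n)
    r1 <- u < 0.15
    x[r1] <- u[r1] / 0.15
    r2 <- u >= 0.15 & u < 0.25
    x[r2] <- 1 - 1.6 * (u[r2] - 0.15) / 0.10
    r3 <- u >= 0.25
    x[r3] <- -0.6 * (1 - (u[r3] - 0.25) / 0.75)
  } else {
    set.seed(seed)
    x <- stats::rnorm(n) * tukey_env((seq_len(n) - 0.5) / n, ramp = 0.25)
  }
  x * peak_amp_uv / max(abs(x))
}

#' Generate a synthetic recording with ground truth
#'
#' Sums the power-law background, white amplifier noise, injected HFO
#' bursts and artifact transients per channel. Event and transient onsets
#' follow independent Poisson processes per channel; events never overlap
#' within a channel (bounded rejection sampling). The whole recording is
#' annotated as NREM sleep, so the full duration counts as clean time.
#'
#' @param spec a [recording_spec]
#' @param seed optional integer overriding `spec$seed`
#' @return list with elements `recording` (a [recording]) and `truth`
#'   (data frame: `channel`, `band`, `start_s`, `end_s`, `centre_freq_hz`,
#'   `peak_amp_uv`, `kind` in hfo/spike)
#' @export
make_recording <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "recording_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  n <- round(spec$duration_s * spec$fs_hz)
  nch <- length(spec$channel_labels)
  samples <- matrix(0, nch, n)
  truth <- data.frame(channel = character(0), band = character(0),
                      start_s = numeric(0), end_s = numeric(0),
                      centre_freq_hz = numeric(0), peak_amp_uv = numeric(0),
                      kind = character(0))
  band_freqs <- list(ripple = c(90, 240), fast_ripple = c(260, 450))
  for (ch in seq_len(nch)) {
    ch_seed <- (spec$seed * 1009L + ch * 7919L) %% .Machine$integer.max
    bg <- make_background(spec$duration_s, spec$fs_hz,
                          spec$background_rms_uv, spec$spectral_exponent,
                          seed = ch_seed)
    amp <- make_amplifier_noise(spec$duration_s, spec$fs_hz,
                                spec$amplifier_noise_density_nv,
                                seed = ch_seed + 1L)
    x <- bg + amp
    set.seed(ch_seed + 2L)
    placed <- iv_empty()
    for (band in spec$bands) {
      n_ev <- stats::rpois(1L, spec$event_rate_per_min *
                             spec$duration_s / 60)
      for (k in seq_len(n_ev)) {
        f0 <- stats::runif(1L, band_freqs[[band]][1L],
                           band_freqs[[band]][2L])
        cyc <- sample(spec$event_cycles_min:spec$event_cycles_max, 1L)
        amp_uv <- trunc_norm1(spec$event_amp_mean_uv, spec$event_amp_sd_uv,
                              spec$event_amp_min_uv)
        wav <- make_hfo_waveform(f0, cyc, amp_uv, spec$fs_hz)
        pl <- place_event(placed, length(wav), n, spec$fs_hz,
                          margin_s = 0.1)
        if (is.null(pl)) stop("generation-failure: could not place event ",
                              "without overlap; lower the event rate")
        idx <- pl$i0:(pl$i0 + length(wav) - 1L)
        x[idx] <- x[idx] + wav
        placed <- rbind(placed, data.frame(start_s = pl$start_s,
                                           end_s = pl$end_s))
        truth <- rbind(truth, data.frame(
          channel = spec$channel_labels[ch], band = band,
          start_s = pl$start_s, end_s = pl$end_s, centre_freq_hz = f0,
          peak_amp_uv = amp_uv, kind = "hfo"))
      }
    }
    n_sp <- stats::rpois(1L, spec$spike_rate_per_min * spec$duration_s / 60)
    for (k in seq_len(n_sp)) {
      dur_ms <- stats::runif(1L, 40, 70)
      amp_uv <- stats::runif(1L, 20, 60)
      wav <- make_transient("spike", amp_uv, dur_ms, spec$fs_hz)
      pl <- place_event(placed, length(wav), n, spec$fs_hz, margin_s = 0.1)
      if (is.null(pl)) stop("generation-failure: could not place spike")
      idx <- pl$i0:(pl$i0 + length(wav) - 1L)
      x[idx] <- x[idx] + wav
      placed <- rbind(placed, data.frame(start_s = pl$start_s,
                                         end_s = pl$end_s))
      truth <- rbind(truth, data.frame(
        channel = spec$channel_labels[ch], band = NA_character_,
        start_s = pl$start_s, end_s = pl$end_s, centre_freq_hz = NA_real_,
        peak_amp_uv = amp_uv, kind = "spike"))
    }
    samples[ch, ] <- x
  }
  ann <- data.frame(label = "sleep_nrem", start_s = 0,
                    end_s = spec$duration_s)
  rec <- recording(samples, spec$fs_hz, spec$channel_labels, ann)
  truth <- truth[order(truth$channel, truth$start_s), ]
  rownames(truth) <- NULL
  list(recording = rec, truth = truth)
}

# one draw from N(mean, sd) truncated below at lo (rejection sampling)
trunc_norm1 <- function(mean, sd, lo) {
  for (i in 1:1000) {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo) return(x)
  }
  lo
}

# uniform placement of an n_wav-sample event avoiding existing intervals
place_event <- function(placed, n_wav, n_total, fs_hz, margin_s = 0.1,
                        max_tries = 200L) {
  dur_s <- n_wav / fs_hz
  for (try in seq_len(max_tries)) {
    i0 <- sample.int(n_total - n_wav, 1L)
    start_s <- (i0 - 1L) / fs_hz
    end_s <- start_s + dur_s
    if (nrow(placed) == 0L ||
        !any(iv_overlaps(start_s - margin_s, end_s + margin_s,
                         placed$start_s, placed$end_s)))
      return(list(i0 = i0, start_s = start_s, end_s = end_s))
  }
  NULL
}

#' Specification for a synthetic clinical cohort
#'
#' Parameters of the cohort-level power-law relation between seizure
#' frequency and affected-hemisphere HFO rate,
#' `log10(rate) = log10(a) + b * log10(SF) + N(0, noise_sd_log10)`.
#' The defaults were fitted once to the packaged 19-recording clinical
#' table (a = 0.6 HFO/min at 1 seizure/month, b = 0.4, residual SD 0.28
#' decades, 6/19 seizure-free recordings mapped to 0.05 seizures/month),
#' so a 19-row draw behaves like the observed cohort.
#'
#' @param n_recordings number of recordings (>= 2)
#' @param rate_scale_a HFO/min at 1 seizure/month
#' @param rate_exponent_b power-law slope on log10-log10 axes
#' @param noise_sd_log10 lognormal scatter, in decades
#' @param seizure_freq_range range of seizure frequencies per month for
#'   recordings with active epilepsy (sampled log-uniformly)
#' @param freedom_fraction proportion of seizure-free recordings
#' @param freedom_proxy seizures/month standing in for seizure freedom
#' @param seed integer seed
#' @return a list of class `cohort_spec`
#' @export
cohort_spec <- function(n_recordings = 19, rate_scale_a = 0.6,
                        rate_exponent_b = 0.4, noise_sd_log10 = 0.28,
                        seizure_freq_range = c(0.2, 450),
                        freedom_fraction = 6 / 19, freedom_proxy = 0.05,
                        seed = 1L) {
  if (n_recordings < 2) stop("invalid-argument: n_recordings must be >= 2")
  if (freedom_proxy <= 0) stop("invalid-argument: freedom_proxy must be > 0")
  if (freedom_fraction < 0 || freedom_fraction > 1)
    stop("invalid-argument: freedom_fraction must be in [0, 1]")
  structure(list(n_recordings = n_recordings, rate_scale_a = rate_scale_a,
                 rate_exponent_b = rate_exponent_b,
                 noise_sd_log10 = noise_sd_log10,
                 seizure_freq_range = seizure_freq_range,
                 freedom_fraction = freedom_fraction,
                 freedom_proxy = freedom_proxy, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort table under the power-law severity model
#'
#' @param spec a [cohort_spec]
#' @param seed optional integer overriding `spec$seed`
#' @return data frame with columns `recording_id`,
#'   `seizure_freq_per_month`, `affected_rate`, `nonaffected_rate`,
#'   `active_flag`; seizure-free rows carry `seizure_freq_per_month =
#'   freedom_proxy` and `active_flag = FALSE`
#' @export
make_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  set.seed(spec$seed)
  n <- spec$n_recordings
  n_free <- round(spec$freedom_fraction * n)
  active <- c(rep(TRUE, n - n_free), rep(FALSE, n_free))
  lr <- log10(spec$seizure_freq_range)
  sf <- ifelse(active, 10^stats::runif(n, lr[1L], lr[2L]),
               spec$freedom_proxy)
  log_rate <- log10(spec$rate_scale_a) +
    spec$rate_exponent_b * log10(sf) +
    stats::rnorm(n, 0, spec$noise_sd_log10)
  # contralateral hemisphere: lower by ~0.6 decades on average
  log_ratio <- -0.6 + stats::rnorm(n, 0, 0.5)
  data.frame(recording_id = sprintf("R%02d", seq_len(n)),
             seizure_freq_per_month = sf,
             affected_rate = 10^log_rate,
             nonaffected_rate = 10^(log_rate + pmin(log_ratio, 0)),
             active_flag = active)
}
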