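#' HFO frequency bands
#'
#' The two canonical HFO sub-bands: ripples (80-250 Hz) and fast ripples
#' (250-500 Hz).
#'
#' @param name `"ripple"` or `"fast_ripple"`, or an existing band object
#' @return a list of class `hfo_band` with `name`, `lo_hz`, `hi_hz`
#' @export
hfo_band <- function(name) {
  if (inherits(name, "hfo_band")) return(name)
  name <- match.arg(name, c("ripple", "fast_ripple"))
  lims <- switch(name, ripple = c(80, 250), fast_ripple = c(250, 500))
  structure(list(name = name, lo_hz = lims[1L], hi_hz = lims[2L]),
            class = "hfo_band")
}

#' Detector configuration
#'
#' Tunable constants of the three-stage detector. The main text of the
#' detector lineage specifies the workflow skeleton (band-limited
#' candidate detection against a background-derived amplitude threshold
#' Th_amp, Stockwell time-frequency validation, artifact rejection); the
#' concrete stage rules and all defaults here are this package's own
#' definitions, every one of them exposed for tuning.
#'
#' @param band band name or [hfo_band]
#' @param threshold_factor Th_amp = baseline envelope mean plus this many
#'   baseline envelope SDs
#' @param min_cycles minimal number of oscillation cycles (zero crossings
#'   / 2) a candidate must span at its dominant frequency
#' @param min_gap_ms supra-threshold runs closer than this are merged
#'   before the duration test
#' @param tf_trough_ratio isolation criterion: the spectral minimum
#'   between the in-band peak and lower frequencies must fall below this
#'   fraction of the peak power
#' @param cross_channel_fraction events co-occurring on more than this
#'   fraction of channels are flagged as artifacts
#' @param baseline_entropy_quantile Stockwell column entropy quantile
#'   above which samples count as oscillation-free background
#' @param baseline_max_s at most this many seconds of evenly spaced
#'   windows per epoch enter the baseline estimate
#' @param entropy_win_s window length for the baseline entropy maps
#' @param entropy_decim entropy is evaluated every this many samples
#' @param tf_fmin_hz lower edge of the validation time-frequency map
#'   (below the band, so low-frequency power can mask non-isolated peaks)
#' @param tf_pad_s raw-signal padding around a candidate for its
#'   validation map
#' @param tf_freq_step_hz frequency step of the validation map
#' @return a list of class `detector_config`
#' @export
detector_config <- function(band = "ripple", threshold_factor = 3,
                            min_cycles = 4, min_gap_ms = 10,
                            tf_trough_ratio = 0.5,
                            cross_channel_fraction = 0.8,
                            baseline_entropy_quantile = 0.25,
                            baseline_max_s = 60, entropy_win_s = 1,
                            entropy_decim = 16, tf_fmin_hz = 40,
                            tf_pad_s = 0.25, tf_freq_step_hz = 5) {
  band <- hfo_band(band)
  stopifnot(threshold_factor > 0, min_cycles >= 1,
            cross_channel_fraction > 0, cross_channel_fraction <= 1,
            tf_trough_ratio > 0, tf_trough_ratio <= 1,
            baseline_entropy_quantile >= 0, baseline_entropy_quantile < 1)
  structure(list(band = band, threshold_factor = threshold_factor,
                 min_cycles = min_cycles, min_gap_ms = min_gap_ms,
                 tf_trough_ratio = tf_trough_ratio,
                 cross_channel_fraction = cross_channel_fraction,
                 baseline_entropy_quantile = baseline_entropy_quantile,
                 baseline_max_s = baseline_max_s,
                 entropy_win_s = entropy_win_s,
                 entropy_decim = entropy_decim, tf_fmin_hz = tf_fmin_hz,
                 tf_pad_s = tf_pad_s, tf_freq_step_hz = tf_freq_step_hz),
            class = "detector_config")
}

#' Zero-phase band-pass filter into an HFO band
#'
#' Fourth-order Butterworth applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion, flat passband and
#' steep (> 40 dB one octave out) stopband attenuation.
#'
#' @param x numeric signal
#' @param band band name or [hfo_band]
#' @param fs_hz sampling rate; must be at least twice the band's upper
#'   edge
#' @return filtered signal
#' @export
bandpass_filter <- function(x, band, fs_hz) {
  band <- hfo_band(band)
  if (fs_hz < 2 * band$hi_hz)
    stop("invalid-argument: fs_hz must be >= 2 * band upper edge")
  hi <- min(band$hi_hz, 0.495 * fs_hz)
  bt <- signal::butter(4, c(band$lo_hz, hi) / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bt, x))
}

# analytic-signal magnitude (FFT Hilbert transform)
analytic_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE)) / n
}

#' Background-adaptive amplitude threshold (Th_amp)
#'
#' Characterizes the oscillation-free background of a band-filtered
#' epoch: the Stockwell column entropy of the band's instantaneous power
#' spectrum is computed over evenly spaced windows; samples whose entropy
#' exceeds the `baseline_entropy_quantile` (i.e. with a flat, peak-free
#' spectrum) form the baseline, and
#' `Th_amp = mean + threshold_factor * SD` of the analytic-signal
#' envelope over those baseline samples. Scales linearly with the signal
#' (entropy is scale-invariant).
#'
#' @param band_signal band-filtered signal of one channel epoch (at least
#'   10 s)
#' @param fs_hz sampling rate
#' @param config a [detector_config]
#' @return threshold in microvolts (strictly positive)
#' @export
estimate_baseline_threshold <- function(band_signal, fs_hz, config) {
  n <- length(band_signal)
  if (n < 10 * fs_hz)
    stop("insufficient-data: need >= 10 s to estimate the background")
  env <- analytic_envelope(band_signal)
  win_n <- round(config$entropy_win_s * fs_hz)
  n_win <- floor(n / win_n)
  max_win <- max(1L, floor(config$baseline_max_s / config$entropy_win_s))
  wins <- unique(round(seq(1L, n_win, length.out = min(n_win, max_win))))
  band <- config$band
  ent <- env_sel <- numeric(0)
  for (w in wins) {
    i0 <- (w - 1L) * win_n + 1L
    seg <- band_signal[i0:(i0 + win_n - 1L)]
    tf <- st_transform(seg, fs_hz, band$lo_hz,
                       min(band$hi_hz, 0.499 * fs_hz),
                       freq_step_hz = 10)
    cols <- seq(1L, win_n, by = config$entropy_decim)
    p <- tf$power[, cols, drop = FALSE]
    p <- sweep(p, 2L, pmax(colSums(p), .Machine$double.xmin), `/`)
    ent <- c(ent, -colSums(p * log(pmax(p, .Machine$double.xmin))))
    env_sel <- c(env_sel, env[i0 - 1L + cols])
  }
  q <- stats::quantile(ent, config$baseline_entropy_quantile, names = FALSE)
  base <- env_sel[ent >= q]
  th <- mean(base) + config$threshold_factor * stats::sd(base)
  if (!is.finite(th) || th <= 0)
    stop("insufficient-data: degenerate baseline")
  th
}

#' Stage 1: band-limited candidate detection
#'
#' Finds maximal runs where the analytic envelope of the band-filtered
#' signal exceeds `th_amp`; runs closer than `min_gap_ms` are merged, and
#' a merged run is kept only if it spans at least `min_cycles`
#' oscillation cycles at its dominant frequency (zero-crossing count /
#' 2).
#'
#' @param band_signal band-filtered signal
#' @param fs_hz sampling rate
#' @param th_amp amplitude threshold in microvolts (> 0)
#' @param config a [detector_config]
#' @return data frame of candidate intervals: `start_s`, `end_s`
#'   (half-open, relative to the start of `band_signal`), `peak_amp_uv`
#' @export
detect_candidates <- function(band_signal, fs_hz, th_amp, config) {
  stopifnot(th_amp > 0)
  env <- analytic_envelope(band_signal)
  above <- env > th_amp
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      peak_amp_uv = numeric(0))
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  # merge runs separated by less than min_gap_ms
  gap_n <- config$min_gap_ms / 1000 * fs_hz
  if (nrow(runs) > 1L) {
    keep_i0 <- runs$i0[1L]; merged <- NULL; cur_i1 <- runs$i1[1L]
    for (i in 2L:nrow(runs)) {
      if (runs$i0[i] - cur_i1 - 1L < gap_n) {
        cur_i1 <- runs$i1[i]
      } else {
        merged <- rbind(merged, c(keep_i0, cur_i1))
        keep_i0 <- runs$i0[i]; cur_i1 <- runs$i1[i]
      }
    }
    merged <- rbind(merged, c(keep_i0, cur_i1))
    runs <- data.frame(i0 = merged[, 1L], i1 = merged[, 2L])
  }
  ok <- logical(nrow(runs))
  peak <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    seg <- band_signal[runs$i0[i]:runs$i1[i]]
    zc <- sum(diff(sign(seg)) != 0)
    ok[i] <- zc / 2 >= config$min_cycles
    peak[i] <- max(env[runs$i0[i]:runs$i1[i]])
  }
  data.frame(start_s = (runs$i0[ok] - 1L) / fs_hz,
             end_s = runs$i1[ok] / fs_hz,
             peak_amp_uv = peak[ok])
}

#' Stage 2: Stockwell time-frequency validation
#'
#' A candidate is accepted only if the time-averaged instantaneous power
#' spectrum over its interval has its in-band maximum separated from
#' lower-frequency power by a trough: the spectral minimum between the
#' map's lower edge and the peak must fall below
#' `tf_trough_ratio * peak power`. Filtered sharp transients (spikes,
#' muscle) have monotonically decaying spectra without such an isolated
#' peak and are rejected; so are bursts whose true peak lies below the
#' band edge (filter-skirt leakage).
#'
#' @param candidate one-row data frame (or list) with `start_s`, `end_s`
#'   relative to the map's time axis
#' @param tf_map a `tf_map` from [st_transform] of the raw (unfiltered)
#'   signal covering the candidate
#' @param config a [detector_config]
#' @return list with `status` (`"accepted"` or `"rejected_tf"`) and
#'   `peak_freq_hz`
#' @export
validate_time_frequency <- function(candidate, tf_map, config) {
  band <- config$band
  cols <- which(tf_map$times_s >= candidate$start_s &
                  tf_map$times_s < candidate$end_s)
  if (length(cols) == 0L)
    stop("invalid-argument: tf_map does not cover the candidate")
  s <- rowMeans(tf_map$power[, cols, drop = FALSE])
  ib <- which(tf_map$freqs_hz >= band$lo_hz & tf_map$freqs_hz <= band$hi_hz)
  if (length(ib) == 0L)
    stop("invalid-argument: tf_map does not cover the band")
  ipk <- ib[which.max(s[ib])]
  peak_freq <- tf_map$freqs_hz[ipk]
  # isolation is judged on the bandwidth-normalized spectrum (power per
  # Hz): the Gaussian voice width grows with f, so raw white/broadband
  # power rises linearly with frequency and would fake an in-band peak
  sn <- s / tf_map$freqs_hz
  jpk <- ib[which.max(sn[ib])]
  trough <- min(sn[1:jpk])
  isolated <- trough <= config$tf_trough_ratio * sn[jpk]
  # the peak must also dominate everything below the band edge: filtered
  # sharp transients and broadband (muscle) bursts carry comparable
  # power at lower frequencies, a narrowband oscillation does not
  below <- which(tf_map$freqs_hz < band$lo_hz)
  dominated <- length(below) > 0L &&
    max(sn[below]) > config$tf_trough_ratio * sn[jpk]
  # a narrowband oscillation leaves most of the band at background
  # level; a broadband burst lifts the whole band towards the peak
  diffuse <- stats::median(sn[ib]) > config$tf_trough_ratio * sn[jpk]
  list(status = if (isolated && !dominated && !diffuse) "accepted"
       else "rejected_tf",
       peak_freq_hz = peak_freq)
}

#' Stage 3: cross-channel artifact rejection
#'
#' Events that co-occur in time on more than `cross_channel_fraction` of
#' the recording's channels are physiologically implausible as focal HFO
#' and are flagged `rejected_cross_channel` (an automated surrogate for
#' part of the visual artifact review). Single-channel recordings are
#' left untouched.
#'
#' @param events HFO event data frame (columns `channel`, `start_s`,
#'   `end_s`, `status`)
#' @param n_channels total number of channels in the recording
#' @param config a [detector_config]
#' @return `events` with updated `status`
#' @export
reject_cross_channel <- function(events, n_channels, config) {
  if (nrow(events) == 0L || n_channels <= 1L) return(events)
  acc <- which(events$status == "accepted")
  for (i in acc) {
    ov <- iv_overlaps(events$start_s[i], events$end_s[i],
                      events$start_s, events$end_s)
    n_ch <- length(unique(events$channel[ov]))
    if (n_ch / n_channels > config$cross_channel_fraction)
      events$status[i] <- "rejected_cross_channel"
  }
  events
}

#' Run the full three-stage HFO detection on a recording
#'
#' Per clean NREM epoch and channel: band-pass filtering, background
#' threshold Th_amp, candidate detection, Stockwell validation on the raw
#' signal around each candidate, and finally cross-channel artifact
#' rejection across the whole recording. Deterministic for fixed input.
#'
#' @param rec a [recording] in bipolar montage with NREM/artifact
#'   annotations
#' @param band band name or [hfo_band]; overrides `config$band`
#' @param config a [detector_config]
#' @return data frame of HFO events: `event_id`, `channel`, `band`,
#'   `start_s`, `end_s` (absolute, half-open), `peak_freq_hz`,
#'   `peak_amp_uv`, `status` (`accepted`, `rejected_tf`,
#'   `rejected_cross_channel`, `rejected_review`), `review_note`
#' @export
detect_hfo <- function(rec, band = NULL, config = detector_config()) {
  stopifnot(inherits(rec, "recording"))
  if (!is.null(band)) config$band <- hfo_band(band)
  band <- config$band
  if (rec$fs_hz < 2 * band$hi_hz)
    stop("invalid-argument: sampling rate too low for the ", band$name,
         " band")
  es <- clean_epochs(rec)
  fs <- rec$fs_hz
  empty <- data.frame(event_id = integer(0), channel = character(0),
                      band = character(0), start_s = numeric(0),
                      end_s = numeric(0), peak_freq_hz = numeric(0),
                      peak_amp_uv = numeric(0), status = character(0),
                      review_note = character(0))
  if (es$clean_minutes == 0) return(empty)
  out <- list()
  for (ch in seq_along(rec$channel_labels)) {
    for (e in seq_len(nrow(es$epochs))) {
      i0 <- floor(es$epochs$start_s[e] * fs) + 1L
      i1 <- min(floor(es$epochs$end_s[e] * fs), ncol(rec$samples))
      if ((i1 - i0 + 1L) < 10 * fs) next   # too short for a baseline
      raw <- rec$samples[ch, i0:i1]
      bs <- bandpass_filter(raw, band, fs)
      th <- estimate_baseline_threshold(bs, fs, config)
      cand <- detect_candidates(bs, fs, th, config)
      if (nrow(cand) == 0L) next
      for (k in seq_len(nrow(cand))) {
        pad <- config$tf_pad_s
        j0 <- max(1L, floor((cand$start_s[k] - pad) * fs) + 1L)
        j1 <- min(length(raw), ceiling((cand$end_s[k] + pad) * fs))
        # pad to a 2-3-5-smooth length so the segment FFTs stay fast
        len <- stats::nextn(j1 - j0 + 1L, c(2L, 3L, 5L))
        if (j0 + len - 1L <= length(raw)) j1 <- j0 + len - 1L
        else if (len <= length(raw)) j0 <- j1 - len + 1L
        seg <- raw[j0:j1]
        if (length(seg) < 64L) next
        tf <- st_transform(seg, fs, config$tf_fmin_hz,
                           min(band$hi_hz + 20, 0.499 * fs),
                           freq_step_hz = config$tf_freq_step_hz)
        loc <- list(start_s = cand$start_s[k] - (j0 - 1L) / fs,
                    end_s = cand$end_s[k] - (j0 - 1L) / fs)
        v <- validate_time_frequency(loc, tf, config)
        out[[length(out) + 1L]] <- data.frame(
          channel = rec$channel_labels[ch], band = band$name,
          start_s = es$epochs$start_s[e] + cand$start_s[k],
          end_s = es$epochs$start_s[e] + cand$end_s[k],
          peak_freq_hz = v$peak_freq_hz,
          peak_amp_uv = cand$peak_amp_uv[k],
          status = v$status, review_note = "")
      }
    }
  }
  if (length(out) == 0L) return(empty)
  events <- do.call(rbind, out)
  events <- reject_cross_channel(events, length(rec$channel_labels), config)
  events <- events[order(events$channel, events$start_s), ]
  events <- cbind(event_id = seq_len(nrow(events)), events)
  rownames(events) <- NULL
  events
}

#' Apply human review decisions to detected events
#'
#' Mirrors the visual artifact-rejection step: a review file maps event
#' ids to keep/reject decisions; rejected events get status
#' `rejected_review`. Review never promotes an automatically rejected
#' event: it only rejects, it does not detect.
#'
#' @param events event data frame from [detect_hfo]
#' @param review either a path to a JSON file or a named list; each entry
#'   `list(decision = "keep"|"reject", note = "...")`, named by event id
#' @return `events` with updated `status` and `review_note`
#' @export
apply_review <- function(events, review) {
  if (is.character(review)) review <- jsonlite::read_json(review)
  for (id in names(review)) {
    i <- which(events$event_id == as.integer(id))
    if (length(i) != 1L) next
    dec <- review[[id]]$decision
    if (identical(dec, "reject") && events$status[i] == "accepted") {
      events$status[i] <- "rejected_review"
      note <- review[[id]]$note
      events$review_note[i] <- if (is.null(note)) "" else note
    }
  }
  events
}
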