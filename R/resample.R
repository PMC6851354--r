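#' Downsample a recording with anti-alias filtering
#'
#' Acquisition-rate data (e.g. 10 kHz) are reduced to the analysis rate
#' (2 kHz) by zero-phase low-pass filtering at 0.4 x the target rate
#' followed by decimation, so that the upper edge of the fast-ripple band
#' (500 Hz) is preserved without aliasing. Only integer decimation factors
#' are supported; upsampling is not (the pipeline never needs it).
#'
#' @param rec a [recording]
#' @param target_fs_hz target sampling rate; must divide `fs_hz`
#' @return a [recording] at `target_fs_hz`, annotations unchanged
#' @export
resample_to <- function(rec, target_fs_hz) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs_hz > rec$fs_hz)
    stop("invalid-argument: upsampling not supported (target ",
         target_fs_hz, " > ", rec$fs_hz, ")")
  if (target_fs_hz == rec$fs_hz) return(rec)
  q <- rec$fs_hz / target_fs_hz
  if (abs(q - round(q)) > 1e-9)
    stop("invalid-argument: decimation factor must be an integer, got ", q)
  q <- as.integer(round(q))
  # linear-phase FIR, cutoff 0.4*target_fs; filtfilt makes it zero-phase
  b <- signal::fir1(128, 0.4 * target_fs_hz / (rec$fs_hz / 2))
  idx <- seq(1L, ncol(rec$samples), by = q)
  out <- matrix(0, nrow(rec$samples), length(idx))
  for (i in seq_len(nrow(rec$samples)))
    out[i, ] <- signal::filtfilt(b, rec$samples[i, ])[idx]
  recording(out, target_fs_hz, rec$channel_labels, rec$annotations)
}
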