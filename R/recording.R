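#' Multichannel EEG/ECoG recording container
#'
#' A `recording` holds a channels-by-time matrix of samples in microvolts,
#' the sampling rate, channel labels, and annotation intervals (half-open,
#' seconds from recording start). Annotations carry a `label` column whose
#' recognized values are `"sleep_nrem"` (intervals scored as NREM sleep)
#' and `"artifact"` (intervals to be excluded from analysis); other labels
#' are kept but ignored by the pipeline.
#'
#' @param samples numeric matrix, channels x time, in microvolts. A single
#'   channel may be given as a vector.
#' @param fs_hz sampling rate in samples per second
#' @param channel_labels character vector of channel names (10-20 system
#'   labels for scalp EEG, or bipolar `"A-B"` labels)
#' @param annotations data frame with columns `label`, `start_s`, `end_s`,
#'   or `NULL` for none
#' @return an object of class `recording`
#' @examples
#' rec <- recording(matrix(rnorm(4000), 2), fs_hz = 2000,
#'                  channel_labels = c("C4", "P4"))
#' rec
#' @export
recording <- function(samples, fs_hz, channel_labels,
                      annotations = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0)
    stop("fs_hz must be a positive scalar")
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(samples))
    stop("channel_labels length (", length(channel_labels),
         ") != number of channels (", nrow(samples), ")")
  if (anyDuplicated(channel_labels))
    stop("duplicate channel labels")
  if (is.null(annotations)) {
    annotations <- data.frame(label = character(0),
                              start_s = numeric(0), end_s = numeric(0))
  }
  stopifnot(all(c("label", "start_s", "end_s") %in% names(annotations)))
  if (any(annotations$end_s <= annotations$start_s))
    stop("annotation intervals must satisfy start < end")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs_hz = fs_hz,
                 channel_labels = channel_labels,
                 annotations = annotations[, c("label", "start_s", "end_s")]),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s), %.1f s @ %g Hz, %d annotation(s)\n",
              nrow(x$samples), duration_s(x), x$fs_hz, nrow(x$annotations)))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `recording`
#' @return duration in seconds (`n_samples / fs_hz`)
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$fs_hz

# channel index by label, with a helpful error
channel_index <- function(rec, labels) {
  idx <- match(labels, rec$channel_labels)
  if (anyNA(idx))
    stop("channel-not-found: ", paste(labels[is.na(idx)], collapse = ", "))
  idx
}
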