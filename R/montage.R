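#' Build a bipolar montage
#'
#' Derives bipolar channels as the samplewise difference anode - cathode,
#' the standard derivation for suppressing common-mode activity (e.g.
#' `C4-P4` from the 10-20 electrodes `C4` and `P4`). Annotations and
#' sampling rate are carried over unchanged.
#'
#' @param rec a [recording] in referential montage
#' @param pairs montage pairs: either a two-column data frame / matrix with
#'   columns (anode, cathode), a list of length-2 character vectors, or a
#'   character vector of `"ANODE-CATHODE"` strings
#' @return a [recording] whose channels are labelled `"ANODE-CATHODE"`
#' @examples
#' rec <- recording(matrix(1:8, 2, byrow = TRUE), 2000, c("C4", "P4"))
#' to_bipolar(rec, "C4-P4")$samples
#' @export
to_bipolar <- function(rec, pairs) {
  stopifnot(inherits(rec, "recording"))
  pairs <- as_montage_pairs(pairs)
  # a pair of a channel with itself is allowed and gives a zero channel
  ai <- channel_index(rec, pairs$anode)
  ci <- channel_index(rec, pairs$cathode)
  samples <- rec$samples[ai, , drop = FALSE] -
    rec$samples[ci, , drop = FALSE]
  recording(samples, rec$fs_hz,
            paste0(pairs$anode, "-", pairs$cathode), rec$annotations)
}

as_montage_pairs <- function(pairs) {
  if (is.character(pairs)) {
    parts <- strsplit(pairs, "-", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("invalid-argument: montage strings must be 'ANODE-CATHODE'")
    pairs <- data.frame(anode = vapply(parts, `[`, "", 1L),
                        cathode = vapply(parts, `[`, "", 2L))
  } else if (is.list(pairs) && !is.data.frame(pairs)) {
    stopifnot(all(lengths(pairs) == 2L))
    pairs <- data.frame(anode = vapply(pairs, `[`, "", 1L),
                        cathode = vapply(pairs, `[`, "", 2L))
  } else {
    pairs <- as.data.frame(pairs)
    names(pairs)[1:2] <- c("anode", "cathode")
  }
  pairs$anode <- as.character(pairs$anode)
  pairs$cathode <- as.character(pairs$cathode)
  pairs
}
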