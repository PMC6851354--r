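#' Read a recording from an EDF file
#'
#' Parses European Data Format (EDF) files: 16-bit samples scaled by the
#' per-signal physical/digital calibration. If the file contains an
#' `"EDF Annotations"` signal (EDF+), its time-stamped annotation lists are
#' parsed into the recording's annotation table. Independently, a CSV
#' sidecar (columns `label,start_s,end_s`) is read when present; by default
#' it is looked up at `<path without .edf>.annotations.csv`.
#'
#' @param path path to the EDF file
#' @param channel_subset optional character vector of channel labels to
#'   keep; an absent label is an error
#' @param annotations_path optional explicit path to the CSV sidecar
#' @return a [recording]
#' @export
read_recording <- function(path, channel_subset = NULL,
                           annotations_path = NULL) {
  if (!file.exists(path)) stop("io-error: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_fixed <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr_fixed, type = "bytes") < 256L)
    stop("format-error: truncated EDF header")
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  n_records <- as.integer(fld(hdr_fixed, 237, 8))
  record_dur <- as.numeric(fld(hdr_fixed, 245, 8))
  ns <- as.integer(fld(hdr_fixed, 253, 4))
  if (is.na(ns) || ns < 1L) stop("format-error: bad signal count")
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256L * ns)
    stop("format-error: truncated EDF signal header")
  grab <- function(offset, width) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, offset * ns + (i - 1L) * width + 1L,
                    offset * ns + i * width)), "")
  }
  labels <- grab(0L, 16L)
  phys_min <- as.numeric(grab(16L + 80L + 8L, 8L))
  phys_max <- as.numeric(grab(16L + 80L + 8L + 8L, 8L))
  dig_min <- as.numeric(grab(16L + 80L + 8L + 16L, 8L))
  dig_max <- as.numeric(grab(16L + 80L + 8L + 24L, 8L))
  spr <- as.integer(grab(16L + 80L + 8L + 32L + 80L, 8L))
  total <- sum(spr) * n_records
  raw16 <- readBin(con, "integer", n = total, size = 2L,
                   signed = TRUE, endian = "little")
  if (length(raw16) < total) stop("format-error: truncated EDF data")
  is_annot <- labels == "EDF Annotations"
  data <- lapply(seq_len(ns), function(i) numeric(0))
  offs <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(seq_len(spr[i]) + offs[i],
                           (seq_len(n_records) - 1L) * rec_len, `+`))
    data[[i]] <- raw16[idx]
  }
  annotations <- NULL
  if (any(is_annot)) {
    tal_raw <- unlist(lapply(which(is_annot), function(i) {
      v <- data[[i]]
      rbind(bitwAnd(v, 255L), bitwAnd(bitwShiftR(v, 8), 255L))
    }))
    annotations <- parse_edf_tal(as.raw(tal_raw %% 256L))
  }
  keep <- which(!is_annot)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  sig <- lapply(keep, function(i)
    phys_min[i] + (data[[i]] - dig_min[i]) * gain[i])
  nmin <- min(lengths(sig))
  samples <- do.call(rbind, lapply(sig, function(x) x[seq_len(nmin)]))
  fs <- spr[keep[1L]] / record_dur
  rec <- recording(samples, fs_hz = fs, channel_labels = labels[keep],
                   annotations = annotations)
  if (is.null(annotations_path)) {
    annotations_path <- paste0(sub("\\.edf$", "", path, ignore.case = TRUE),
                               ".annotations.csv")
    if (!file.exists(annotations_path)) annotations_path <- NA_character_
  }
  if (!is.na(annotations_path) && file.exists(annotations_path)) {
    side <- utils::read.csv(annotations_path, stringsAsFactors = FALSE)
    stopifnot(all(c("label", "start_s", "end_s") %in% names(side)))
    rec$annotations <- rbind(rec$annotations,
                             side[, c("label", "start_s", "end_s")])
  }
  if (!is.null(channel_subset)) {
    idx <- channel_index(rec, channel_subset)
    rec$samples <- rec$samples[idx, , drop = FALSE]
    rec$channel_labels <- rec$channel_labels[idx]
  }
  rec
}

# EDF+ time-stamped annotation list parser: "+onset[\x15dur]\x14text\x14...\x00"
parse_edf_tal <- function(bytes) {
  # rawToChar cannot carry embedded NULs; split on them first
  zero <- which(bytes == as.raw(0))
  bounds <- c(0L, zero, length(bytes) + 1L)
  chunks <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i] + 1L; hi <- bounds[i + 1L] - 1L
    if (hi >= lo) chunks <- c(chunks, rawToChar(bytes[lo:hi]))
  }
  out <- data.frame(label = character(0), start_s = numeric(0),
                    end_s = numeric(0))
  for (ch in chunks) {
    if (!nzchar(ch)) next
    parts <- strsplit(ch, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(parts[1])) next
    od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(od[1]))
    dur <- if (length(od) > 1L) suppressWarnings(as.numeric(od[2])) else 0
    labs <- parts[-1][nzchar(parts[-1])]
    if (is.na(onset) || length(labs) == 0L) next
    out <- rbind(out, data.frame(label = labs, start_s = onset,
                                 end_s = onset + max(dur, 0)))
  }
  out
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits with a per-channel physical range
#' covering the signal extrema, so the roundtrip error is at most one
#' quantization step. Annotations are written to a CSV sidecar
#' (`<path without .edf>.annotations.csv`, columns `label,start_s,end_s`),
#' keeping the signal file plain EDF.
#'
#' @param rec a [recording]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  n <- ncol(rec$samples)
  if (n == 0L || nrow(rec$samples) == 0L)
    stop("format-error: refusing to write an empty recording")
  fs <- rec$fs_hz
  # 1-second data records when the sample count allows, else one record
  if (n %% fs == 0 && fs == round(fs)) {
    record_dur <- 1
    n_records <- n / fs
    spr <- as.integer(fs)
  } else {
    record_dur <- n / fs
    n_records <- 1L
    spr <- n
  }
  ns <- nrow(rec$samples)
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  # numeric header fields are fixed 8-byte ASCII: reduce precision until
  # the representation fits
  num8 <- function(x) vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, digits = d, width = 1, format = "g")
      if (nchar(s) <= 8L) return(pad(s, 8))
    }
    stop("io-error: header value does not fit in 8 bytes: ", v)
  }, "")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad("X X X X", 80), pad("Startdate X", 80),
                "01.01.00", "00.00.00",
                pad(256L * (1L + ns), 8), pad("", 44),
                pad(n_records, 8), num8(record_dur), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmax_ <- apply(abs(rec$samples), 1L, max)
  pmax_[pmax_ == 0] <- 1
  # the stored range is the parsed-back header value; nudge it up until
  # it covers the extrema so no sample clips
  pmax_ <- vapply(pmax_, function(v) {
    stored <- as.numeric(num8(v))
    while (stored < v) {
      v <- v * 1.001
      stored <- as.numeric(num8(v))
    }
    stored
  }, 0)
  field <- function(vals, w) writeChar(paste(pad(vals, w), collapse = ""),
                                       con, eos = NULL)
  field(substr(rec$channel_labels, 1L, 16L), 16)   # label
  field(rep("", ns), 80)                           # transducer
  field(rep("uV", ns), 8)                          # physical dimension
  field(num8(-pmax_), 8)                           # physical min
  field(num8(pmax_), 8)                            # physical max
  field(rep(-32767L, ns), 8)                       # digital min
  field(rep(32767L, ns), 8)                        # digital max
  field(rep("", ns), 80)                           # prefiltering
  field(rep(spr, ns), 8)                           # samples per record
  field(rep("", ns), 32)                           # reserved
  dig <- round(sweep(rec$samples, 1L, 32767 / pmax_, `*`))
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con,
             size = 2L, endian = "little")
  }
  if (nrow(rec$annotations) > 0L) {
    side <- paste0(sub("\\.edf$", "", path, ignore.case = TRUE),
                   ".annotations.csv")
    utils::write.csv(rec$annotations, side, row.names = FALSE)
  }
  invisible(path)
}
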