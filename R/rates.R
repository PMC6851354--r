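#' Per-channel HFO rate
#'
#' Counts accepted events on one channel and divides by the clean NREM
#' minutes of the recording (the exact rate denominator); rejected events
#' never count.
#'
#' @param events event data frame from [detect_hfo]
#' @param channel channel label
#' @param clean_minutes clean NREM minutes (> 0)
#' @param band optional band name to restrict to
#' @return one-row data frame: `channel`, `band`, `n_events`,
#'   `clean_minutes`, `rate` (events/min)
#' @export
channel_rate <- function(events, channel, clean_minutes, band = NULL) {
  if (!is.numeric(clean_minutes) || clean_minutes <= 0)
    stop("invalid-denominator: clean_minutes must be > 0")
  sel <- events$channel == channel & events$status == "accepted"
  if (!is.null(band)) sel <- sel & events$band == band
  n <- sum(sel)
  data.frame(channel = channel,
             band = if (is.null(band)) NA_character_ else band,
             n_events = n, clean_minutes = clean_minutes,
             rate = n / clean_minutes)
}

#' Aggregate channel rates over a hemisphere
#'
#' Scalp convention: unweighted arithmetic mean over the hemisphere's
#' bipolar channels. ECoG convention: maximum over channels.
#'
#' @param channel_rates data frame with columns `channel` and `rate`
#' @param channels_of_side channel labels belonging to the hemisphere
#' @param method `"mean"` (scalp) or `"max"` (ECoG)
#' @return the aggregated rate in events/min
#' @export
aggregate_rate <- function(channel_rates, channels_of_side,
                           method = c("mean", "max")) {
  method <- match.arg(method)
  if (length(channels_of_side) == 0L)
    stop("invalid-argument: empty hemisphere channel set")
  idx <- match(channels_of_side, channel_rates$channel)
  if (anyNA(idx))
    stop("invalid-argument: missing channel rate for ",
         paste(channels_of_side[is.na(idx)], collapse = ", "))
  r <- channel_rates$rate[idx]
  switch(method, mean = mean(r), max = max(r))
}

#' Assemble one clinical-table row from channel rates
#'
#' Fills the affected and (for scalp) non-affected hemisphere aggregates
#' using the modality's convention: mean over channels for scalp,
#' maximum for ECoG (which has no non-affected aggregate). The `active`
#' label is left unset; [label_activity] fills it.
#'
#' @param meta list or one-row data frame with `patient_id`, `stage`
#'   (`"pre"`/`"post"`), `modality` (`"scalp"`/`"ecog"`), `seizure_freq`
#'   (per month), and optional `ilae` (1-6)
#' @param affected_channels,nonaffected_channels channel labels per
#'   hemisphere (non-affected may be empty for ECoG)
#' @param channel_rates data frame with columns `channel`, `rate`
#' @return one-row data frame of class `recording_summary`
#' @export
summarize_recording <- function(meta, affected_channels,
                                nonaffected_channels, channel_rates) {
  stage <- match.arg(meta$stage, c("pre", "post"))
  modality <- match.arg(meta$modality, c("scalp", "ecog"))
  if (length(intersect(affected_channels, nonaffected_channels)) > 0L)
    stop("invalid-argument: channel on both hemispheres")
  method <- if (modality == "scalp") "mean" else "max"
  aff <- aggregate_rate(channel_rates, affected_channels, method)
  nonaff <- if (modality == "scalp")
    aggregate_rate(channel_rates, nonaffected_channels, method)
  else NA_real_
  ilae <- if (is.null(meta$ilae)) NA_real_ else as.numeric(meta$ilae)
  if (!is.na(ilae) && !(ilae %in% 1:6))
    stop("invalid-argument: ilae must be in 1..6")
  out <- data.frame(patient_id = meta$patient_id, stage = stage,
                    modality = modality, affected_rate = aff,
                    nonaffected_rate = nonaff,
                    seizure_freq = as.numeric(meta$seizure_freq),
                    ilae = ilae, active = NA)
  class(out) <- c("recording_summary", class(out))
  out
}

#' Score detected events against simulator ground truth
#'
#' Matches accepted events to true injected HFO by channel and time
#' overlap. Sensitivity (recall) is the fraction of true HFO matched by
#' an accepted event; precision is the fraction of accepted events
#' matching a true HFO.
#'
#' @param events event data frame from [detect_hfo]
#' @param truth ground-truth data frame from [make_recording] (only rows
#'   with `kind == "hfo"` count as targets)
#' @param band optional band restriction applied to both sides
#' @return list with `sensitivity`, `precision`, `n_truth`, `n_detected`,
#'   `n_matched`
#' @export
score_detection <- function(events, truth, band = NULL) {
  tr <- truth[truth$kind == "hfo", , drop = FALSE]
  ev <- events[events$status == "accepted", , drop = FALSE]
  if (!is.null(band)) {
    tr <- tr[tr$band == band, , drop = FALSE]
    ev <- ev[ev$band == band, , drop = FALSE]
  }
  hit_truth <- logical(nrow(tr))
  hit_event <- logical(nrow(ev))
  for (i in seq_len(nrow(tr))) {
    ov <- ev$channel == tr$channel[i] &
      iv_overlaps(tr$start_s[i], tr$end_s[i], ev$start_s, ev$end_s)
    if (any(ov)) {
      hit_truth[i] <- TRUE
      hit_event[ov] <- TRUE
    }
  }
  list(sensitivity = if (nrow(tr)) mean(hit_truth) else NA_real_,
       precision = if (nrow(ev)) mean(hit_event) else NA_real_,
       n_truth = nrow(tr), n_detected = nrow(ev),
       n_matched = sum(hit_truth))
}
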