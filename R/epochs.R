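#' Select clean NREM analysis epochs
#'
#' Keeps the NREM-sleep annotated intervals of a recording minus all
#' artifact-annotated intervals, then tiles the remaining time into
#' analysis epochs of at most `epoch_len_s` (default 300 s, i.e. 5-minute
#' epochs). A trailing partial epoch is retained with its true duration,
#' so `clean_minutes` is the exact denominator for event rates.
#'
#' @param rec a [recording] with annotations (`sleep_nrem`, `artifact`)
#' @param epoch_len_s maximal epoch length in seconds
#' @return a list of class `epoch_set` with elements `epochs` (data frame
#'   `start_s`, `end_s`) and `clean_minutes`
#' @examples
#' ann <- data.frame(label = c("sleep_nrem", "artifact"),
#'                   start_s = c(0, 100), end_s = c(720, 220))
#' rec <- recording(matrix(0, 1, 720 * 200), 200, "C4-P4", ann)
#' clean_epochs(rec)$clean_minutes   # 10 minutes
#' @export
clean_epochs <- function(rec, epoch_len_s = 300) {
  stopifnot(inherits(rec, "recording"), epoch_len_s > 0)
  ann <- rec$annotations
  nrem <- iv_normalize(ann[ann$label == "sleep_nrem", , drop = FALSE])
  if (nrow(nrem) == 0L) {
    warning("no NREM sleep annotation; returning an empty epoch set")
    return(structure(list(epochs = iv_empty(), clean_minutes = 0),
                     class = "epoch_set"))
  }
  # clip to the recording and remove artifacts
  dur <- duration_s(rec)
  nrem$start_s <- pmin(pmax(nrem$start_s, 0), dur)
  nrem$end_s <- pmin(pmax(nrem$end_s, 0), dur)
  art <- ann[ann$label == "artifact", , drop = FALSE]
  clean <- iv_setdiff(nrem, art)
  epochs <- iv_empty()
  for (i in seq_len(nrow(clean))) {
    cuts <- seq(clean$start_s[i], clean$end_s[i], by = epoch_len_s)
    if (cuts[length(cuts)] < clean$end_s[i]) cuts <- c(cuts, clean$end_s[i])
    epochs <- rbind(epochs, data.frame(start_s = cuts[-length(cuts)],
                                       end_s = cuts[-1L]))
  }
  structure(list(epochs = epochs,
                 clean_minutes = iv_total(epochs) / 60),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epoch(s), %.2f clean minutes\n",
              nrow(x$epochs), x$clean_minutes))
  invisible(x)
}
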