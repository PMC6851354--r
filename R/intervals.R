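#' Interval arithmetic on half-open time intervals
#'
#' All time intervals in the package are half-open, `[start, end)`, in
#' seconds from recording start. These helpers operate on two-column
#' data frames with columns `start_s` and `end_s`.
#'
#' @param x data frame with columns `start_s`, `end_s`
#' @return `iv_normalize()` returns the sorted union of the input with
#'   overlapping or touching intervals merged; `iv_setdiff()` removes `y`
#'   from `x`; `iv_total()` returns the summed length in seconds.
#' @keywords internal
#' @name intervals
NULL

iv_empty <- function() data.frame(start_s = numeric(0), end_s = numeric(0))

iv_check <- function(x) {
  stopifnot(is.data.frame(x), all(c("start_s", "end_s") %in% names(x)))
  if (any(x$end_s < x$start_s)) stop("interval with end < start")
  x[, c("start_s", "end_s")]
}

#' @rdname intervals
iv_normalize <- function(x) {
  x <- iv_check(x)
  x <- x[x$end_s > x$start_s, , drop = FALSE]
  if (nrow(x) == 0L) return(iv_empty())
  x <- x[order(x$start_s, x$end_s), , drop = FALSE]
  out_s <- out_e <- numeric(0)
  cs <- x$start_s[1L]; ce <- x$end_s[1L]
  if (nrow(x) > 1L) {
    for (i in 2L:nrow(x)) {
      if (x$start_s[i] <= ce) {
        ce <- max(ce, x$end_s[i])
      } else {
        out_s <- c(out_s, cs); out_e <- c(out_e, ce)
        cs <- x$start_s[i]; ce <- x$end_s[i]
      }
    }
  }
  data.frame(start_s = c(out_s, cs), end_s = c(out_e, ce))
}

#' @rdname intervals
#' @param y data frame of intervals to subtract
iv_setdiff <- function(x, y) {
  x <- iv_normalize(x)
  y <- iv_normalize(y)
  if (nrow(x) == 0L || nrow(y) == 0L) return(x)
  res <- iv_empty()
  for (i in seq_len(nrow(x))) {
    segs <- data.frame(start_s = x$start_s[i], end_s = x$end_s[i])
    for (j in seq_len(nrow(y))) {
      nxt <- iv_empty()
      for (k in seq_len(nrow(segs))) {
        s <- segs$start_s[k]; e <- segs$end_s[k]
        ys <- y$start_s[j]; ye <- y$end_s[j]
        if (ye <= s || ys >= e) {
          nxt <- rbind(nxt, data.frame(start_s = s, end_s = e))
        } else {
          if (ys > s) nxt <- rbind(nxt, data.frame(start_s = s, end_s = ys))
          if (ye < e) nxt <- rbind(nxt, data.frame(start_s = ye, end_s = e))
        }
      }
      segs <- nxt
      if (nrow(segs) == 0L) break
    }
    res <- rbind(res, segs)
  }
  iv_normalize(res)
}

#' @rdname intervals
iv_total <- function(x) {
  x <- iv_normalize(x)
  sum(x$end_s - x$start_s)
}

# TRUE where [a_start, a_end) and [b_start, b_end) overlap (vectorized on b)
iv_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}
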