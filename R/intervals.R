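#' Half-open interval sets
#'
#' An `interval_set` is an ordered collection of disjoint half-open
#' intervals `[start, end)` on the time axis (seconds). It is the carrier
#' for all flow / no-flow algebra: the flow set is the union of
#' inter-compression spans, and no-flow time is the measure of its
#' complement within an analysis window.
#'
#' @param starts,ends Numeric vectors of equal length; each pair must
#'   satisfy `end > start`. Overlapping or abutting intervals are merged.
#' @return An object of class `interval_set`: a data frame with columns
#'   `start` and `end`, sorted, pairwise disjoint.
#' @examples
#' s <- interval_set(c(0, 10, 5), c(4, 12, 11))
#' interval_total(s)  # 0-4 and 5-12 merged: 4 + 7 = 11
#' @export
interval_set <- function(starts = numeric(), ends = numeric()) {
  if (length(starts) != length(ends))
    stop("starts and ends must have equal length")
  keep <- is.finite(starts) & is.finite(ends) & ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) {
    out <- data.frame(start = numeric(), end = numeric())
    class(out) <- c("interval_set", "data.frame")
    return(out)
  }
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  # merge overlapping / abutting spans in one pass
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(); out_e <- numeric()
  if (length(starts) > 1L) {
    for (i in 2:length(starts)) {
      if (starts[i] <= me) {
        me <- max(me, ends[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  out <- data.frame(start = out_s, end = out_e)
  class(out) <- c("interval_set", "data.frame")
  out
}

#' Total measure of an interval set
#'
#' @param x An `interval_set`.
#' @return Sum of interval lengths in seconds (0 for an empty set).
#' @export
interval_total <- function(x) {
  if (nrow(x) == 0L) return(0)
  sum(x$end - x$start)
}

#' Clip an interval set to a window
#'
#' @param x An `interval_set`.
#' @param window Numeric length-2, the half-open window `[start, end)`.
#' @return The `interval_set` of intersections with the window.
#' @export
interval_clip <- function(x, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  if (nrow(x) == 0L) return(x)
  s <- pmax(x$start, window[1])
  e <- pmin(x$end, window[2])
  interval_set(s, e)
}

#' Complement of an interval set within a window
#'
#' @param x An `interval_set`.
#' @param window Numeric length-2 half-open window.
#' @return The `interval_set` of the window not covered by `x`.
#' @export
interval_complement <- function(x, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  x <- interval_clip(x, window)
  if (nrow(x) == 0L) return(interval_set(window[1], window[2]))
  starts <- c(window[1], x$end)
  ends <- c(x$start, window[2])
  interval_set(starts, ends)
}
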