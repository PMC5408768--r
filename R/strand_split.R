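#' Abasic current threshold of a read
#'
#' The hairpin adapter joining the two strands contains abasic DNA, whose
#' current is well above the 50-90 pA range of regular DNA. Because the
#' absolute level is distorted by the unknown per-read shift/scale, the
#' threshold is estimated from the read itself: the current level larger
#' than 99% of all event levels (nearest-rank order statistic), plus 5 pA.
#'
#' @param events data.frame of events with a `mean` column.
#' @return threshold in pA.
#' @export
abasic_threshold <- function(events) {
  n <- nrow(events)
  if (is.null(n) || n < 1L) stop("need at least one event")
  sort(events$mean)[ceiling(0.99 * n)] + 5.0
}

#' Find abasic islands
#'
#' Maximal runs of at least 5 consecutive events whose mean exceeds the
#' threshold; islands separated by fewer than 50 events (edge gap) are then
#' merged transitively into one interval. At this stage no bases exist yet,
#' so the 50-unit merge distance is measured in events (one event is
#' approximately one base).
#'
#' @inheritParams abasic_threshold
#' @param threshold current threshold in pA, from [abasic_threshold()].
#' @param min_len minimum island length in events.
#' @param merge_gap merge islands closer than this many events.
#' @return integer matrix with columns `start`, `end`: half-open 1-based
#'   event-index intervals `[start, end)`, one row per island.
#' @export
find_islands <- function(events, threshold, min_len = 5L, merge_gap = 50L) {
  stopifnot(is.finite(threshold))
  above <- events$mean > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  iv <- cbind(start = starts[keep], end = ends[keep] + 1L)
  if (nrow(iv) > 1L) {
    merged <- iv[1L, , drop = FALSE]
    for (i in 2L:nrow(iv)) {
      gap <- iv[i, "start"] - merged[nrow(merged), "end"]
      if (gap < merge_gap) {
        merged[nrow(merged), "end"] <- iv[i, "end"]
      } else {
        merged <- rbind(merged, iv[i, , drop = FALSE])
      }
    }
    iv <- merged
  }
  iv
}

#' Split a read into template and complement strands
#'
#' Detects the abasic hairpin and, when found near the centre of the read,
#' splits the event sequence: events before the island are the template
#' strand, events after it the complement. Among all islands the one whose
#' midpoint is closest to the middle of the event sequence is considered
#' (ties go to the earlier island); it triggers a split only if its
#' midpoint lies within the middle third of the read, `[n/3, 2n/3)`.
#' Otherwise the whole read is treated as a template strand. Island events
#' belong to neither strand.
#'
#' @inheritParams abasic_threshold
#' @return list of class `split_result` with 1-based half-open intervals
#'   `template_range`, `complement_range` (NULL if no split),
#'   `hairpin_island` (NULL if none used), plus `threshold` and `n_events`.
#' @export
split_read <- function(events) {
  n <- nrow(events)
  if (is.null(n) || n < 1L) stop("need at least one event")
  thr <- abasic_threshold(events)
  iv <- find_islands(events, thr)
  res <- list(template_range = c(1L, n + 1L), complement_range = NULL,
              hairpin_island = NULL, threshold = thr, n_events = n)
  class(res) <- "split_result"
  if (nrow(iv) == 0L) return(res)
  mid <- (iv[, "start"] + iv[, "end"] - 1) / 2   # island midpoint (index)
  centre <- (n + 1) / 2
  best <- which.min(abs(mid - centre))           # ties -> earlier island
  lo <- floor(n / 3); hi <- floor(2 * n / 3)
  if (mid[best] - 1 < lo || mid[best] - 1 >= hi) return(res)  # 0-based rule
  s <- unname(iv[best, "start"]); e <- unname(iv[best, "end"])
  res$hairpin_island <- c(s, e)
  res$template_range <- c(1L, s)
  res$complement_range <- c(e, n + 1L)
  res
}

#' @export
print.split_result <- function(x, ...) {
  if (is.null(x$hairpin_island)) {
    cat(sprintf("split_result: no hairpin (n=%d, threshold %.1f pA)\n",
                x$n_events, x$threshold))
  } else {
    cat(sprintf(
      "split_result: template [%d,%d), island [%d,%d), complement [%d,%d)\n",
      x$template_range[1], x$template_range[2],
      x$hairpin_island[1], x$hairpin_island[2],
      x$complement_range[1], x$complement_range[2]))
  }
  invisible(x)
}

# events of one strand given a half-open 1-based range (NULL -> empty)
strand_events <- function(events, range) {
  if (is.null(range) || range[2] <= range[1])
    return(events[integer(0), , drop = FALSE])
  events[range[1]:(range[2] - 1L), , drop = FALSE]
}
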