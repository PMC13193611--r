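# Post-processing: frame probabilities -> binary calls -> merged division
# events -> replicative lifespan and cell-cycle-length series.

#' Threshold frame probabilities into binary calls
#'
#' @param probs Numeric vector of per-frame budding probabilities.
#' @param threshold Probability threshold in `(0, 1)`; a frame is called
#'   positive when `prob >= threshold`.
#' @return Integer 0/1 vector with attribute `threshold`.
#' @export
binarize <- function(probs, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  structure(as.integer(probs >= threshold), threshold = threshold)
}

#' Merge consecutive positive calls into division events
#'
#' Each maximal run of consecutive positive frames becomes one division
#' event so that a budding transition spanning several frames is counted
#' once. The representative frame of a run is its first frame (bud-emergence
#' semantics) or its midpoint.
#'
#' @param calls Integer 0/1 vector of per-frame calls (0-based frames).
#' @param representative `"first"` or `"midpoint"`.
#' @param min_gap Optional refractory filter: a merged event closer than
#'   `min_gap` frames to the previous retained event is dropped (0 = off,
#'   the default; merging only).
#' @param cell_id Identifier for the resulting timeline.
#' @param frame_interval_min Minutes per frame.
#' @return A [division_timeline()] with one event per run.
#' @export
collapse_runs <- function(calls, representative = c("first", "midpoint"),
                          min_gap = 0L, cell_id = "cell",
                          frame_interval_min = 15) {
  representative <- match.arg(representative)
  calls <- as.integer(calls)
  n <- length(calls)
  if (n == 0) return(division_timeline(cell_id, integer(0), 1L,
                                       frame_interval_min))
  r <- rle(calls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values == 1L)
  events <- if (representative == "first") starts[pos] - 1L else {
    as.integer(floor((starts[pos] + ends[pos]) / 2)) - 1L
  }
  if (min_gap > 0 && length(events) > 1) {
    keep <- events[1]
    for (e in events[-1]) if (e - keep[length(keep)] >= min_gap) keep <- c(keep, e)
    events <- keep
  }
  division_timeline(cell_id, events, n, frame_interval_min)
}

#' Replicative lifespan of a timeline
#'
#' The RLS of a mother cell is the number of detected division events.
#'
#' @param timeline A [division_timeline()].
#' @return Integer event count.
#' @export
compute_rls <- function(timeline) {
  length(timeline$event_frames)
}

#' Cell-cycle length series of a timeline
#'
#' Successive inter-division gaps, in frames and minutes, with each cycle's
#' position along the lifespan expressed as a percentage (cycle `k` of
#' `RLS - 1` cycles sits at `100 * k / (RLS - 1)` percent).
#'
#' @param timeline A [division_timeline()].
#' @param frame_interval_min Minutes per frame (defaults to the timeline's
#'   own value).
#' @return Data frame with columns `cycle_index`, `gap_frames`, `gap_min`,
#'   `pct_lifespan`; empty when the timeline holds fewer than two events.
#' @export
cell_cycle_lengths <- function(timeline, frame_interval_min = NULL) {
  iv <- frame_interval_min %||% timeline$frame_interval_min
  ev <- timeline$event_frames
  if (length(ev) < 2) {
    return(data.frame(cycle_index = integer(0), gap_frames = integer(0),
                      gap_min = numeric(0), pct_lifespan = numeric(0)))
  }
  gaps <- diff(ev)
  k <- seq_along(gaps)
  data.frame(cycle_index = k, gap_frames = as.integer(gaps),
             gap_min = gaps * iv,
             pct_lifespan = 100 * k / length(gaps))
}
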