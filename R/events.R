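#' Detect heel-strike and toe-off events
#'
#' Coordinate-based event detection: for each leg, the anterior-posterior
#' ankle trajectory relative to the pelvis reference,
#' `r(t) = x_ankle(t) - x_pelvis(t)`, peaks positively at heel-strike (the
#' foot is maximally ahead of the pelvis) and negatively at toe-off (the
#' foot is maximally behind). The pelvis reference is the midhip keypoint
#' for pose data and the ASIS/PSIS midpoint for marker data, both exposed
#' as the `pelvis` point of a `trajectory_set`. Peaks are constrained by a
#' minimum separation and a minimum prominence expressed as a fraction of
#' the robust amplitude of `r` (half the central 90% range). Detection is
#' invariant to coordinate translation and uniform scaling, so it can run
#' on pixel or metric trajectories alike.
#'
#' Events within `boundary_s` of the record edges are flagged as boundary
#' events (still reported, but excluded from parameter summaries by
#' default downstream).
#'
#' @param ts A `trajectory_set`.
#' @param min_period_s Minimum separation between successive events of the
#'   same type on one leg, seconds (default 0.4, about two-thirds of a
#'   typical step time).
#' @param prominence_frac Minimum peak prominence as a fraction of the
#'   robust amplitude of `r` (default 0.25).
#' @param boundary_s Margin at either record edge within which events are
#'   flagged `boundary` (default 0.4 s, on the order of the filter
#'   warm-up).
#' @return A data frame of class `gait_events` with columns `side`
#'   (`"left"`/`"right"`), `event` (`"heel_strike"`/`"toe_off"`), `time_s`,
#'   `frame_index` (1-based), `boundary` (logical), sorted by time.
#'   Attribute `"alternation_violations"` lists sides where heel-strikes
#'   and toe-offs fail to alternate.
#' @export
detect_gait_events <- function(ts, min_period_s = 0.4,
                               prominence_frac = 0.25, boundary_s = 0.4) {
  stopifnot(inherits(ts, "trajectory_set"))
  fs <- ts$sampling_rate
  min_dist <- max(1L, round(min_period_s * fs))
  span <- range(ts$time)
  rows <- list()
  for (side in c("left", "right")) {
    sfx <- if (side == "left") "l" else "r"
    r <- ts$x[, paste0("ankle_", sfx)] - ts$x[, "pelvis"]
    amp <- diff(stats::quantile(r, c(0.05, 0.95), na.rm = TRUE)) / 2
    if (!is.finite(amp) || amp <= .Machine$double.eps^0.5) {
      warning("flat relative ankle trajectory on ", side, " side; no events")
      next
    }
    min_prom <- prominence_frac * amp
    hs_idx <- find_peaks(r, min_distance = min_dist, min_prominence = min_prom)
    to_idx <- find_peaks(-r, min_distance = min_dist, min_prominence = min_prom)
    if (length(hs_idx) == 0L && length(to_idx) == 0L) {
      warning("fewer than one full gait oscillation on ", side, " side")
      next
    }
    mk <- function(idx, ev) if (length(idx))
      data.frame(side = side, event = ev, time_s = ts$time[idx],
                 frame_index = idx,
                 boundary = ts$time[idx] < span[1] + boundary_s |
                            ts$time[idx] > span[2] - boundary_s)
    rows[[length(rows) + 1L]] <- mk(hs_idx, "heel_strike")
    rows[[length(rows) + 1L]] <- mk(to_idx, "toe_off")
  }
  ev <- if (length(rows)) do.call(rbind, rows)
        else data.frame(side = character(), event = character(),
                        time_s = numeric(), frame_index = integer(),
                        boundary = logical())
  ev <- ev[order(ev$time_s, ev$side, ev$event), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("gait_events", "data.frame")
  attr(ev, "alternation_violations") <- .check_alternation(ev)
  ev
}

# Consecutive same-side heel-strikes should bracket exactly one toe-off;
# violations are reported, not silently fixed.
.check_alternation <- function(ev) {
  bad <- character()
  for (side in unique(ev$side)) {
    hs <- sort(ev$time_s[ev$side == side & ev$event == "heel_strike"])
    to <- sort(ev$time_s[ev$side == side & ev$event == "toe_off"])
    if (length(hs) < 2L) next
    n_between <- vapply(seq_len(length(hs) - 1L), function(k)
      sum(to > hs[k] & to < hs[k + 1L]), numeric(1))
    if (any(n_between != 1L)) bad <- c(bad, side)
  }
  bad
}

#' Find local maxima with prominence and separation constraints
#'
#' A sample is a candidate peak if it exceeds its left neighbour and is at
#' least as large as its right neighbour. Prominence is the height of the
#' peak above the higher of the two minima separating it from higher
#' terrain (or the record edge) on each side. Candidates below
#' `min_prominence` are dropped; remaining peaks are kept greedily in
#' order of decreasing height subject to `min_distance` spacing.
#'
#' @param x Numeric vector (may contain `NA`, which block peaks).
#' @param min_distance Minimum index separation between kept peaks.
#' @param min_prominence Minimum prominence in the units of `x`.
#' @return Sorted integer vector of peak indices.
#' @export
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer())
  xl <- c(Inf, x[-n]); xr <- c(x[-1L], Inf)
  cand <- which(!is.na(x) & !is.na(xl) & !is.na(xr) & x > xl & x >= xr)
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    lo_l <- x[i]; j <- i - 1L
    while (j >= 1L && !is.na(x[j]) && x[j] <= x[i]) {
      lo_l <- min(lo_l, x[j]); j <- j - 1L
    }
    lo_r <- x[i]; j <- i + 1L
    while (j <= n && !is.na(x[j]) && x[j] <= x[i]) {
      lo_r <- min(lo_r, x[j]); j <- j + 1L
    }
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer())
  keep <- integer()
  for (i in cand[order(-x[cand])])
    if (!length(keep) || all(abs(keep - i) >= min_distance))
      keep <- c(keep, i)
  sort(keep)
}
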