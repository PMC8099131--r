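#' Compute per-step spatiotemporal gait parameters
#'
#' One row per step, a step being the interval ending at a heel-strike and
#' labelled by the side of that heel-strike (a "right step" ends at right
#' heel-strike). Definitions:
#' \itemize{
#'   \item step time: duration between consecutive bilateral heel-strikes;
#'   \item stance time: heel-strike to toe-off of the same leg;
#'   \item swing time: toe-off to heel-strike of the same leg (the swing
#'     that ends at this row's heel-strike);
#'   \item double support time: heel-strike of one leg to toe-off of the
#'     contralateral leg;
#'   \item step length: anterior-posterior distance between the two ankle
#'     points at heel-strike (leading minus trailing ankle);
#'   \item walkway position: anterior-posterior position of the trunk
#'     reference (C7 marker / neck keypoint) at heel-strike.
#' }
#' Steps whose defining events are missing or out of order get `NA` in the
#' affected columns and are listed in the `"omissions"` attribute; rows
#' whose defining events carry a boundary flag are marked `boundary` and
#' excluded from participant means by default.
#'
#' @param events A `gait_events` data frame.
#' @param ts Optional `trajectory_set` for step length and walkway
#'   position (omit for purely temporal parameters).
#' @return Data frame of class `step_table` with columns `side`,
#'   `hs_time`, `step_time`, `stance_time`, `swing_time`,
#'   `double_support_time`, `step_length`, `walkway_position`, `boundary`.
#' @export
compute_step_table <- function(events, ts = NULL) {
  ev <- as.data.frame(events)
  hs <- ev[ev$event == "heel_strike", ]
  hs <- hs[order(hs$time_s), ]
  to <- ev[ev$event == "toe_off", ]
  if (nrow(hs) < 2L) stop("need at least two heel-strikes to form a step")
  omissions <- character()
  rows <- list()
  # one row per heel-strike; the first has no step interval but still
  # anchors a stance phase, so it is kept with step_time = NA
  for (k in seq_len(nrow(hs))) {
    side <- hs$side[k]
    contra <- if (side == "left") "right" else "left"
    t_k <- hs$time_s[k]
    boundary <- hs$boundary[k]

    # step time requires the preceding heel-strike to be contralateral
    step_time <- NA_real_
    if (k >= 2L) {
      if (hs$side[k - 1L] == contra) {
        step_time <- t_k - hs$time_s[k - 1L]
        boundary <- boundary || hs$boundary[k - 1L]
      } else {
        omissions <- c(omissions, sprintf(
          "step ending at %.3f s: preceding heel-strike not contralateral",
          t_k))
      }
    }

    to_same <- to[to$side == side, ]
    to_contra <- to[to$side == contra, ]

    # stance: this heel-strike to the leg's next toe-off
    nx <- to_same$time_s[to_same$time_s > t_k]
    stance <- if (length(nx)) min(nx) - t_k else NA_real_
    # swing: the leg's previous toe-off to this heel-strike
    pv <- to_same$time_s[to_same$time_s < t_k]
    swing <- if (length(pv)) t_k - max(pv) else NA_real_
    # double support: this heel-strike to the contralateral toe-off
    nc <- to_contra$time_s[to_contra$time_s > t_k]
    dsup <- if (length(nc)) min(nc) - t_k else NA_real_
    # guard: the contralateral toe-off must precede its own next heel-strike
    if (!is.na(dsup)) {
      nch <- hs$time_s[hs$side == contra & hs$time_s > t_k]
      if (length(nch) && min(nch) < t_k + dsup) {
        dsup <- NA_real_
        omissions <- c(omissions, sprintf(
          "step ending at %.3f s: contralateral toe-off missing", t_k))
      }
    }

    step_len <- NA_real_
    walkway <- NA_real_
    if (!is.null(ts)) {
      i <- hs$frame_index[k]
      lead <- paste0("ankle_", if (side == "left") "l" else "r")
      trail <- paste0("ankle_", if (side == "left") "r" else "l")
      if (i >= 1L && i <= nrow(ts$x)) {
        step_len <- ts$x[i, lead] - ts$x[i, trail]
        walkway <- ts$x[i, "trunk"]
      }
    }
    rows[[k]] <- data.frame(
      side = side, hs_time = t_k, step_time = step_time,
      stance_time = stance, swing_time = swing,
      double_support_time = dsup, step_length = step_len,
      walkway_position = walkway, boundary = boundary)
  }
  st <- do.call(rbind, rows)
  rownames(st) <- NULL
  class(st) <- c("step_table", "data.frame")
  attr(st, "omissions") <- omissions
  st
}

#' Participant-level summary of a step table
#'
#' Column means of the per-step parameters plus gait speed, defined as the
#' participant's mean step length divided by mean step time. Boundary
#' steps are excluded by default; each parameter's mean uses the steps for
#' which it is defined, so the per-parameter `n` can differ.
#'
#' @param steps A `step_table`.
#' @param exclude_boundary Drop boundary-flagged steps first
#'   (default `TRUE`).
#' @return Named list: per-parameter `mean`, `sd` and `n`, plus
#'   `gait_speed` (m/s) and total `n_steps` used.
#' @export
participant_summary <- function(steps, exclude_boundary = TRUE) {
  st <- as.data.frame(steps)
  if (exclude_boundary) st <- st[!st$boundary, , drop = FALSE]
  pars <- c("step_time", "stance_time", "swing_time",
            "double_support_time", "step_length")
  out <- list()
  for (p in pars) {
    v <- st[[p]][!is.na(st[[p]])]
    out[[p]] <- list(mean = if (length(v)) mean(v) else NA_real_,
                     sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                     n = length(v))
  }
  out$gait_speed <- out$step_length$mean / out$step_time$mean
  out$n_steps <- nrow(st)
  out
}
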