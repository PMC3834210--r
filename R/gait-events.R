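# Kinematic event and timing definitions: foot events from sign changes of
# the vertical marker velocity, gait-cycle and stance metrics, and reach
# timing from the hand-to-origin distance.

#' Detect foot events from a vertical marker trajectory
#'
#' Foot events are located at sign changes of the (optionally low-pass
#' filtered) vertical velocity. For a toe marker the downward-to-upward
#' crossing (the minimum of the position) marks toe lift-off; for a heel
#' marker the upward-to-downward crossing (the maximum) marks heel strike.
#' Event times are refined below the sample period by linear interpolation
#' between the bracketing samples, and crossings closer than `refractory`
#' seconds to the previous kept event of the same type are discarded as
#' noise-induced double crossings.
#'
#' @param x Numeric series: vertical position (default) or velocity.
#' @param rate Sampling rate in Hz.
#' @param marker `"toe"`, `"heel"`, or `"both"` (keep both crossing
#'   directions; types become `<foot>TL` / `<foot>HS`).
#' @param foot `"R"` or `"L"` label used to type the events.
#' @param input `"position"` (velocity by central differences) or
#'   `"velocity"`.
#' @param cutoff Zero-phase low-pass cutoff in Hz applied to the velocity
#'   before detection; `NULL` disables smoothing. Default 10.
#' @param refractory Minimum separation between same-type events (s).
#' @param min_swing Minimum velocity swing, as a fraction of the largest
#'   absolute velocity, that must be reached on both sides of a crossing.
#'   Rejects crossing pairs created by noise near position extrema, where
#'   the true velocity is close to zero. Default 0.05.
#' @return An `event_timeline` tibble with columns `time` (seconds,
#'   strictly increasing) and `type`; empty (with a warning) when no
#'   crossing is found.
#' @export
detect_foot_events <- function(x, rate, marker = c("toe", "heel", "both"),
                               foot = "R", input = c("position", "velocity"),
                               cutoff = 10, refractory = 0.2,
                               min_swing = 0.05) {
  marker <- match.arg(marker)
  input <- match.arg(input)
  if (length(x) < 10L) abort("Series too short for event detection.")
  v <- if (input == "position") {
    c(x[2L] - x[1L], (x[-(1:2)] - x[-((length(x) - 1):length(x))]) / 2,
      x[length(x)] - x[length(x) - 1L]) * rate
  } else x
  if (!is.null(cutoff) && cutoff < rate / 2) {
    bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
    v <- signal::filtfilt(bf, v)
  }
  s <- sign(v)
  idx <- which(s[-length(s)] * s[-1L] < 0)
  if (length(idx) == 0L) {
    warn("No velocity sign changes found; empty timeline.")
    return(new_event_timeline(tibble::tibble(time = numeric(), type = character())))
  }
  # between consecutive crossings the velocity must swing appreciably on
  # both sides, otherwise the pair is a noise artefact near an extremum
  if (min_swing > 0 && length(idx) > 1L) {
    thr <- min_swing * max(abs(v))
    bounds <- c(1L, idx, length(v))
    seg_peak <- vapply(seq_len(length(idx) + 1L), function(k)
      max(abs(v[bounds[k]:bounds[k + 1L]])), numeric(1))
    # outermost segments are truncated by the record: don't judge them
    seg_peak[c(1L, length(seg_peak))] <- Inf
    keep_sw <- pmin(seg_peak[-length(seg_peak)], seg_peak[-1L]) >= thr
    idx <- idx[keep_sw]
    if (length(idx) == 0L) {
      warn("No velocity sign changes found; empty timeline.")
      return(new_event_timeline(tibble::tibble(time = numeric(),
                                               type = character())))
    }
  }
  t_cross <- (idx - 1 + v[idx] / (v[idx] - v[idx + 1L])) / rate
  up <- v[idx] < 0
  df <- tibble::tibble(time = t_cross,
                       type = paste0(foot, ifelse(up, "TL", "HS")))
  df <- switch(marker,
               toe = df[up, ],
               heel = df[!up, ],
               both = df)
  df <- dplyr::arrange(df, .data$time)
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$type), function(ii) {
    tt <- df$time[ii]
    k <- logical(length(ii)); last <- -Inf
    for (q in seq_along(ii)) {
      if (tt[q] - last >= refractory) { k[q] <- TRUE; last <- tt[q] }
    }
    ii[k]
  }), use.names = FALSE)
  new_event_timeline(dplyr::arrange(df[sort(keep), ], .data$time))
}

new_event_timeline <- function(df) {
  structure(df, class = c("event_timeline", class(tibble::tibble())))
}

#' Assemble an event timeline from typed event times
#'
#' @param time Numeric vector of event times in seconds.
#' @param type Character vector of event types (conventionally RTL, RHS,
#'   LTL, LHS).
#' @return An `event_timeline` tibble ordered by time.
#' @export
event_timeline <- function(time, type) {
  new_event_timeline(dplyr::arrange(tibble::tibble(time = time,
                                                   type = as.character(type)),
                                    .data$time))
}

#' Merge event timelines
#'
#' @param ... `event_timeline` tibbles (e.g. one per marker channel).
#' @return A single `event_timeline` ordered by time.
#' @export
merge_timelines <- function(...) {
  new_event_timeline(dplyr::arrange(dplyr::bind_rows(...), .data$time))
}

#' Gait cycle durations for one foot
#'
#' One gait cycle is the interval between two successive toe lift-offs of
#' the same foot.
#'
#' @param timeline An `event_timeline`.
#' @param foot `"R"` or `"L"`.
#' @return Numeric vector of cycle durations (seconds).
#' @export
gait_cycle_durations <- function(timeline, foot = "R") {
  lifts <- timeline$time[timeline$type == paste0(foot, "TL")]
  if (length(lifts) < 2L)
    abort(sprintf("Need at least 2 %sTL events to form a gait cycle.", foot))
  diff(sort(lifts))
}

#' Stance-phase durations as a percentage of the gait cycle
#'
#' The stance phase runs from a foot strike to the successive lift-off of
#' the same foot; each is expressed as a percentage of the duration of the
#' gait cycle (lift-to-lift) it terminates. Strikes without a matching
#' cycle are skipped with a warning.
#'
#' @param timeline An `event_timeline`.
#' @param foot `"R"` or `"L"`.
#' @return Numeric vector of stance percentages, one per complete cycle.
#' @export
stance_fractions <- function(timeline, foot = "R") {
  lifts <- sort(timeline$time[timeline$type == paste0(foot, "TL")])
  strikes <- sort(timeline$time[timeline$type == paste0(foot, "HS")])
  if (length(lifts) < 2L) abort("Need at least one complete gait cycle.")
  out <- numeric(0)
  skipped <- 0L
  for (k in seq_len(length(lifts) - 1L)) {
    hs <- strikes[strikes >= lifts[k] & strikes < lifts[k + 1L]]
    if (length(hs) == 0L) { skipped <- skipped + 1L; next }
    out <- c(out, 100 * (lifts[k + 1L] - hs[1L]) / (lifts[k + 1L] - lifts[k]))
  }
  n_orphan <- sum(strikes < lifts[1L])
  if (skipped > 0L || n_orphan > 0L)
    warn(sprintf("%d unpaired event(s) skipped.", skipped + n_orphan))
  out
}

#' Reach timing from the hand-to-origin distance
#'
#' The hand-to-origin distance oscillates with the gait and is maximal at
#' the time the target is reached. The reach time is the global maximum
#' (rejected if it sits on the series boundary), the reach duration is the
#' interval between the local maxima bracketing it, and the couplings are
#' the signed intervals from the reach time to the next `n_couplings` foot
#' events.
#'
#' @param hand_distance Numeric series of hand-to-origin distances.
#' @param rate Sampling rate in Hz.
#' @param timeline An `event_timeline` of foot events covering the reach.
#' @param n_couplings Number of following foot events to couple to
#'   (default 4).
#' @return A `reach_timing` tibble with one row: `reach_time` (s),
#'   `reach_duration` (s) and a `couplings` list-column of the sorted
#'   signed intervals (s).
#' @export
reach_timing <- function(hand_distance, rate, timeline, n_couplings = 4L) {
  n <- length(hand_distance)
  if (n < 10L) abort("Hand-distance series too short.")
  peak <- which.max(hand_distance)
  if (peak == 1L || peak == n)
    abort("Global hand-distance maximum lies on the series boundary; invalid trial.")
  d1 <- diff(hand_distance)
  maxima <- which(d1[-length(d1)] > 0 & d1[-1L] <= 0) + 1L
  prev <- maxima[maxima < peak]
  nxt <- maxima[maxima > peak]
  if (length(prev) == 0L || length(nxt) == 0L)
    abort("No local maxima bracket the reach peak; cannot define a duration.")
  reach_time <- (peak - 1L) / rate
  reach_duration <- (nxt[1L] - prev[length(prev)]) / rate
  after <- sort(timeline$time[timeline$time >= reach_time])
  if (length(after) < n_couplings)
    abort(sprintf("Need %d foot events after the reach; found %d.",
                  n_couplings, length(after)))
  structure(tibble::tibble(reach_time = reach_time,
                           reach_duration = reach_duration,
                           couplings = list(after[seq_len(n_couplings)] - reach_time)),
            class = c("reach_timing", class(tibble::tibble())))
}

#' @method autoplot event_timeline
#' @export
autoplot.event_timeline <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$type)) +
    ggplot2::geom_point(shape = 3) +
    ggplot2::labs(x = "time (s)", y = NULL)
}
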