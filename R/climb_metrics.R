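#' Segment climbing events
#'
#' A climb is counted when a fly reverses travel from climbing up to climbing
#' down. An event opens at the local minimum preceding an upward movement, its
#' peak is the maximum height reached before the next downward movement, and
#' it closes at that down-reversal. Pauses (zero-delta seconds) between upward
#' movements do not close an event. An event still open at the final sample
#' (a fly that climbed and stayed up) is counted iff `count_terminal_ascent`.
#'
#' @param traj a [trajectory()] or numeric height vector.
#' @param count_terminal_ascent logical; count an ascent left open at the end
#'   of the recording as an event (default `TRUE`).
#' @param geom an [assay_geometry()].
#' @return Data frame, one row per event, with columns `start_t_s`,
#'   `peak_t_s`, `start_h_mm`, `peak_h_mm`, `height_gained_mm`, `reached_top`,
#'   `closed_by` (`"reversal"` or `"end_of_recording"`).
#' @examples
#' segment_climbs(c(3, 6, 9, 6))  # one event: 3 -> 9, gain 6
#' @export
segment_climbs <- function(traj, count_terminal_ascent = TRUE,
                           geom = assay_geometry()) {
  h <- as_heights(traj)
  empty <- data.frame(start_t_s = integer(0), peak_t_s = integer(0),
                      start_h_mm = numeric(0), peak_h_mm = numeric(0),
                      height_gained_mm = numeric(0), reached_top = logical(0),
                      closed_by = character(0), stringsAsFactors = FALSE)
  if (length(h) < 2) return(empty)
  d <- diff(h)
  open <- FALSE
  start_i <- peak_i <- NA_integer_
  rows <- list()
  push <- function(closed_by) {
    rows[[length(rows) + 1L]] <<- data.frame(
      start_t_s = start_i, peak_t_s = peak_i,
      start_h_mm = h[start_i + 1L], peak_h_mm = h[peak_i + 1L],
      height_gained_mm = h[peak_i + 1L] - h[start_i + 1L],
      reached_top = h[peak_i + 1L] == geom$tube_length_mm,
      closed_by = closed_by, stringsAsFactors = FALSE)
  }
  for (i in seq_along(d)) {
    if (d[i] > 0) {
      if (!open) { open <- TRUE; start_i <- i - 1L }
      peak_i <- i  # the peak is first attained at the last upward arrival
    } else if (d[i] < 0 && open) {
      push("reversal")
      open <- FALSE
    }
  }
  if (open && count_terminal_ascent) push("end_of_recording")
  if (!length(rows)) empty else do.call(rbind, rows)
}

#' Count complete ascents
#'
#' A complete ascent is a climb from the bottom of the detection zone (the
#' lowest recordable height, one increment) to the top of the tube with zero
#' intervening downward movements; pauses within the run are permitted.
#'
#' @inheritParams segment_climbs
#' @return Integer count.
#' @export
count_complete_ascents <- function(traj, geom = assay_geometry()) {
  h <- as_heights(traj)
  if (length(h) < 2) return(0L)
  d <- diff(h)
  downs <- which(d < 0)  # arrival sample (0-based time) of each down movement
  starts <- c(0L, downs)
  ends <- c(downs - 1L, length(h) - 1L)
  n <- 0L
  for (k in seq_along(starts)) {
    s <- starts[k]; e <- ends[k]
    if (e <= s) next
    if (h[s + 1L] == geom$increment_mm &&
        max(h[(s:e) + 1L]) == geom$tube_length_mm) n <- n + 1L
  }
  n
}

#' Compute the per-fly climbing metric vector
#'
#' All per-fly climbing metrics over the assay window:
#' event counts and climbs reaching the tube top, mean height gained per
#' climbing event and mean event peak height, total height climbed (the sum
#' of all positive per-second height changes), complete ascents, dwell times
#' in the three tube sections, total movements, and ascending/descending
#' velocities (means of the per-second height changes over seconds with
#' movement in that direction). Mean-of-empty-set metrics (a motionless fly's
#' velocities or event averages) are reported as `NA`, never zero, so group
#' means are not biased.
#'
#' @inheritParams segment_climbs
#' @return One-row data frame with columns `fly_id`, `n_climb_events`,
#'   `n_climbs_to_top`, `avg_height_per_climb_mm`, `total_height_climbed_mm`,
#'   `avg_peak_height_mm`, `n_complete_ascents`, `dwell_lower_s`,
#'   `dwell_middle_s`, `dwell_top_s`, `n_movements`,
#'   `ascending_velocity_mm_s`, `descending_velocity_mm_s`.
#' @examples
#' compute_metrics(trajectory("f1", c(3, 12, 6, 15, 9)))
#' @export
compute_metrics <- function(traj, geom = assay_geometry(),
                            count_terminal_ascent = TRUE) {
  h <- as_heights(traj)
  id <- if (inherits(traj, "fly_trajectory")) traj$fly_id else "fly"
  ev <- segment_climbs(h, count_terminal_ascent, geom)
  d <- diff(h)
  up <- d[d > 0]
  down <- -d[d < 0]
  dw <- dwell_times(h, geom)
  data.frame(
    fly_id = id,
    n_climb_events = nrow(ev),
    n_climbs_to_top = sum(ev$reached_top),
    avg_height_per_climb_mm = if (nrow(ev)) mean(ev$height_gained_mm) else NA_real_,
    total_height_climbed_mm = sum(up),
    avg_peak_height_mm = if (nrow(ev)) mean(ev$peak_h_mm) else NA_real_,
    n_complete_ascents = count_complete_ascents(h, geom),
    dwell_lower_s = unname(dw["lower"]),
    dwell_middle_s = unname(dw["middle"]),
    dwell_top_s = unname(dw["top"]),
    n_movements = length(up) + length(down),
    ascending_velocity_mm_s = if (length(up)) mean(up) else NA_real_,
    descending_velocity_mm_s = if (length(down)) mean(down) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Metrics table for a set of flies
#'
#' One [compute_metrics()] row per fly, with the experimental metadata
#' (genotype, age, dose, start day) appended for downstream group statistics.
#' Flies flagged by the gap policy are excluded by default, with a message.
#'
#' @param trajs list of [trajectory()] objects.
#' @param geom an [assay_geometry()].
#' @param count_terminal_ascent see [segment_climbs()].
#' @param include_flagged logical; keep gap-flagged flies.
#' @return Data frame, one row per retained fly.
#' @export
compute_metrics_table <- function(trajs, geom = assay_geometry(),
                                  count_terminal_ascent = TRUE,
                                  include_flagged = FALSE) {
  trajs <- as_trajectory_list(trajs)
  flagged <- vapply(trajs, function(x) x$flagged, logical(1))
  if (!include_flagged && any(flagged)) {
    message(sum(flagged), " fly(ies) excluded by the gap policy: ",
            paste(vapply(trajs[flagged], function(x) x$fly_id, character(1)),
                  collapse = ", "))
    trajs <- trajs[!flagged]
  }
  if (!length(trajs)) stop("no trajectories to analyse")
  rows <- lapply(trajs, function(tr) {
    m <- compute_metrics(tr, geom, count_terminal_ascent)
    m$genotype <- tr$genotype
    m$age_days <- tr$age_days
    m$dose_ug_per_ml <- tr$dose_ug_per_ml
    m$start_day <- tr$start_day
    m
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
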