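#' Descent classifier parameters
#'
#' Thresholds for classifying descents. Defaults follow the video-validated
#' rules: both descent types must cover more than 3 mm (the minimum distance
#' the monitor can record), drops are descents faster than 8.97 mm/s, and
#' descending climbs are slower than 6 mm/s. Descents whose mean velocity
#' falls in the closed band `[6, 8.97]` mm/s cannot be differentiated and are
#' labelled `unclassified` (all inequalities are strict). Internal pauses up
#' to `max_internal_pause_s` are absorbed into a descent: at 3 mm resolution a
#' genuine sub-6 mm/s descent necessarily shows zero-delta seconds between
#' successive 3 mm steps, so pause-free segmentation would shatter slow
#' descents into below-threshold fragments.
#'
#' @param min_descent_distance_mm minimum (strict) descent distance, mm.
#' @param drop_velocity_min_mm_s drops are strictly faster than this, mm/s.
#' @param descclimb_velocity_max_mm_s descending climbs are strictly slower
#'   than this, mm/s.
#' @param max_internal_pause_s longest zero-movement run absorbed into an
#'   ongoing descent, seconds.
#' @return Object of class `classifier_params`.
#' @export
classifier_params <- function(min_descent_distance_mm = 3,
                              drop_velocity_min_mm_s = 8.97,
                              descclimb_velocity_max_mm_s = 6,
                              max_internal_pause_s = 2L) {
  if (descclimb_velocity_max_mm_s >= drop_velocity_min_mm_s)
    stop("'descclimb_velocity_max_mm_s' must be below 'drop_velocity_min_mm_s'")
  if (min_descent_distance_mm <= 0)
    stop("'min_descent_distance_mm' must be positive")
  max_internal_pause_s <- check_count(max_internal_pause_s, "max_internal_pause_s")
  structure(list(min_descent_distance_mm = min_descent_distance_mm,
                 drop_velocity_min_mm_s = drop_velocity_min_mm_s,
                 descclimb_velocity_max_mm_s = descclimb_velocity_max_mm_s,
                 max_internal_pause_s = max_internal_pause_s),
            class = "classifier_params")
}

#' Segment descents
#'
#' A descent opens at the first downward movement after non-descent,
#' accumulates downward movements, tolerates internal pauses up to
#' `max_internal_pause_s`, and closes at an upward movement, a longer pause,
#' or the end of the recording. Duration spans the first to the last downward
#' movement inclusive of internal pauses; a fall completed within one
#' inter-sample gap is attributed 1 s (the resolution floor). Velocity is
#' total distance over total duration.
#'
#' @param traj a [trajectory()] or numeric height vector.
#' @param params a [classifier_params()].
#' @return Data frame with columns `start_t_s`, `end_t_s`, `distance_mm`,
#'   `duration_s`, `velocity_mm_s`.
#' @examples
#' segment_descents(c(51, 39, 45))        # 12 mm in 1 s
#' segment_descents(c(24, 21, 21, 18, 15)) # 9 mm over 4 s
#' @export
segment_descents <- function(traj, params = classifier_params()) {
  h <- as_heights(traj)
  empty <- data.frame(start_t_s = integer(0), end_t_s = integer(0),
                      distance_mm = numeric(0), duration_s = integer(0),
                      velocity_mm_s = numeric(0))
  if (length(h) < 2) return(empty)
  d <- diff(h)
  rows <- list()
  open <- FALSE
  start_i <- last_down <- NA_integer_
  pause <- 0L
  close_descent <- function() {
    dist <- h[start_i + 1L] - h[last_down + 1L]
    dur <- last_down - start_i
    rows[[length(rows) + 1L]] <<- data.frame(
      start_t_s = start_i, end_t_s = last_down,
      distance_mm = dist, duration_s = dur,
      velocity_mm_s = dist / dur)
  }
  for (i in seq_along(d)) {
    if (d[i] < 0) {
      if (!open) { open <- TRUE; start_i <- i - 1L }
      last_down <- i
      pause <- 0L
    } else if (d[i] > 0) {
      if (open) { close_descent(); open <- FALSE }
    } else if (open) {
      pause <- pause + 1L
      if (pause > params$max_internal_pause_s) { close_descent(); open <- FALSE }
    }
  }
  if (open) close_descent()
  if (!length(rows)) empty else do.call(rbind, rows)
}

#' Classify segmented descents
#'
#' Applies the strict distance and velocity thresholds in `params`:
#' `below_min_distance` when the descent does not exceed the minimum
#' recordable distance; otherwise `drop` when faster than the drop threshold,
#' `descending_climb` when slower than the descending-climb ceiling, and
#' `unclassified` in between (excluded from both behavioural counts, as
#' non-differentiable descents were excluded in the video validation).
#'
#' @param descents data frame from [segment_descents()].
#' @param params a [classifier_params()].
#' @return `descents` with a `label` factor column appended (levels `drop`,
#'   `descending_climb`, `unclassified`, `below_min_distance`).
#' @export
classify_descents <- function(descents, params = classifier_params()) {
  lv <- c("drop", "descending_climb", "unclassified", "below_min_distance")
  v <- descents$velocity_mm_s
  lab <- ifelse(descents$distance_mm <= params$min_descent_distance_mm,
                "below_min_distance",
         ifelse(v > params$drop_velocity_min_mm_s, "drop",
         ifelse(v < params$descclimb_velocity_max_mm_s, "descending_climb",
                "unclassified")))
  descents$label <- factor(lab, levels = lv)
  descents
}

#' @rdname classify_descents
#' @param distance_mm,duration_s scalars describing a single descent.
#' @export
classify_descent <- function(distance_mm, duration_s,
                             params = classifier_params()) {
  d <- data.frame(start_t_s = 0L, end_t_s = as.integer(duration_s),
                  distance_mm = distance_mm, duration_s = duration_s,
                  velocity_mm_s = distance_mm / duration_s)
  classify_descents(d, params)$label[1]
}

#' Per-fly descent counts
#'
#' Segments and classifies all descents for each fly and tallies drops,
#' descending climbs and unclassified descents over the full assay window.
#'
#' @param trajs a [trajectory()] or list of them.
#' @param params a [classifier_params()].
#' @return Data frame with columns `fly_id`, `n_drops`,
#'   `n_descending_climbs`, `n_unclassified`, plus metadata columns.
#' @export
descent_summary <- function(trajs, params = classifier_params()) {
  trajs <- as_trajectory_list(trajs)
  rows <- lapply(trajs, function(tr) {
    lab <- classify_descents(segment_descents(tr, params), params)$label
    data.frame(fly_id = tr$fly_id,
               n_drops = sum(lab == "drop"),
               n_descending_climbs = sum(lab == "descending_climb"),
               n_unclassified = sum(lab == "unclassified"),
               genotype = tr$genotype,
               age_days = tr$age_days,
               dose_ug_per_ml = tr$dose_ug_per_ml,
               start_day = tr$start_day,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descent table for a set of flies
#'
#' Long-format table of every segmented, classified descent.
#'
#' @inheritParams descent_summary
#' @return Data frame with columns `fly_id`, `start_t_s`, `end_t_s`,
#'   `distance_mm`, `duration_s`, `velocity_mm_s`, `label`.
#' @export
descent_table <- function(trajs, params = classifier_params()) {
  trajs <- as_trajectory_list(trajs)
  rows <- lapply(trajs, function(tr) {
    d <- classify_descents(segment_descents(tr, params), params)
    if (!nrow(d)) return(NULL)
    cbind(fly_id = tr$fly_id, d, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(fly_id = character(0), start_t_s = integer(0),
                      end_t_s = integer(0), distance_mm = numeric(0),
                      duration_s = integer(0), velocity_mm_s = numeric(0),
                      label = factor(character(0),
                                     levels = c("drop", "descending_climb",
                                                "unclassified",
                                                "below_min_distance"))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
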