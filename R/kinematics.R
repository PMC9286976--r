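#' Extract second-to-second movements
#'
#' A movement is any positional change captured from one second to the next.
#' The returned table has one row per consecutive sample pair with unequal
#' heights; `t_s` is the (0-based) second at which the new position is first
#' observed.
#'
#' @param traj a [trajectory()] or numeric height vector.
#' @return Data frame with columns `t_s`, `delta_h_mm`, `direction`
#'   (`"up"`/`"down"`). Zero rows for a constant trajectory.
#' @examples
#' extract_movements(c(3, 6, 6, 9, 6))  # up 3, up 3, down 3
#' @export
extract_movements <- function(traj) {
  h <- as_heights(traj)
  d <- diff(h)
  keep <- which(d != 0)
  data.frame(t_s = keep,
             delta_h_mm = d[keep],
             direction = factor(ifelse(d[keep] > 0, "up", "down"),
                                levels = c("up", "down")),
             stringsAsFactors = FALSE)
}

#' Dwell time in each tube section
#'
#' Each 1 Hz sample contributes one second to the section containing its
#' height (no interpolation across transitions), so the three dwell times
#' always sum to the trajectory duration.
#'
#' @param traj a [trajectory()] or numeric height vector.
#' @param geom an [assay_geometry()].
#' @return Named numeric vector `c(lower = , middle = , top = )` in seconds.
#' @examples
#' dwell_times(c(3, 18, 51, 51))  # lower 1, middle 1, top 2
#' @export
dwell_times <- function(traj, geom = assay_geometry()) {
  h <- as_heights(traj)
  counts <- table(section_of(h, geom))
  out <- as.numeric(counts)
  names(out) <- names(counts)
  out[c("lower", "middle", "top")]
}
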