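#' Per-fly climbing trajectory
#'
#' The canonical unit of analysis: one fly's height (mm) sampled once per
#' second over the assay, together with its experimental metadata. Heights
#' must lie on the monitor's quantization grid (multiples of `increment_mm`
#' between one increment and the tube length).
#'
#' @param fly_id character scalar identifying the fly.
#' @param heights_mm numeric vector, one height per second.
#' @param genotype `"control"` or `"park25"`.
#' @param age_days non-negative integer age at assay.
#' @param dose_ug_per_ml non-negative nicotine dose in food (ug/mL).
#' @param start_day post-eclosion day treatment began, or `NA`.
#' @param flagged logical; `TRUE` when the recording contained a gap longer
#'   than the gap policy allows (such flies are excluded from metric tables by
#'   default).
#' @param geom an [assay_geometry()].
#' @return An object of class `fly_trajectory`.
#' @examples
#' tr <- trajectory("f1", c(3, 6, 9, 6))
#' @export
trajectory <- function(fly_id, heights_mm, genotype = "control",
                       age_days = 20L, dose_ug_per_ml = 0,
                       start_day = NA_integer_, flagged = FALSE,
                       geom = assay_geometry()) {
  if (!is.character(fly_id) || length(fly_id) != 1 || !nzchar(fly_id))
    stop("'fly_id' must be a non-empty string")
  genotype <- match.arg(genotype, c("control", "park25"))
  if (!is.numeric(heights_mm) || length(heights_mm) < 1 || anyNA(heights_mm))
    stop("'heights_mm' must be a non-empty numeric vector without missing values")
  p <- heights_mm / geom$increment_mm
  if (!all(is_whole(p)) || any(p < 1) || any(p > geom$n_positions))
    stop(sprintf("heights must be multiples of %g mm in [%g, %g]",
                 geom$increment_mm, geom$increment_mm, geom$tube_length_mm))
  age_days <- check_count(age_days, "age_days")
  if (!is.numeric(dose_ug_per_ml) || length(dose_ug_per_ml) != 1 || dose_ug_per_ml < 0)
    stop("'dose_ug_per_ml' must be a single non-negative number")
  if (!is.na(start_day)) start_day <- check_count(start_day, "start_day")
  structure(
    list(fly_id = fly_id,
         genotype = genotype,
         age_days = age_days,
         dose_ug_per_ml = as.numeric(dose_ug_per_ml),
         start_day = as.integer(start_day),
         heights_mm = as.numeric(heights_mm),
         flagged = isTRUE(flagged)),
    class = "fly_trajectory")
}

#' @export
print.fly_trajectory <- function(x, ...) {
  cat(sprintf("<fly_trajectory> %s (%s, %d d, %g ug/mL%s): %d s, heights %g-%g mm%s\n",
              x$fly_id, x$genotype, x$age_days, x$dose_ug_per_ml,
              if (is.na(x$start_day)) "" else sprintf(", start day %d", x$start_day),
              length(x$heights_mm), min(x$heights_mm), max(x$heights_mm),
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' @export
as.data.frame.fly_trajectory <- function(x, ...) {
  data.frame(fly_id = x$fly_id,
             t_s = seq_along(x$heights_mm) - 1L,
             height_mm = x$heights_mm,
             genotype = x$genotype,
             age_days = x$age_days,
             dose_ug_per_ml = x$dose_ug_per_ml,
             start_day = x$start_day,
             stringsAsFactors = FALSE)
}

# Accept either a fly_trajectory or a bare numeric height vector.
as_heights <- function(x) {
  if (inherits(x, "fly_trajectory")) x$heights_mm
  else if (is.numeric(x)) x
  else stop("expected a 'fly_trajectory' or a numeric vector of heights")
}

# Coerce the input of table-level functions to a list of trajectories.
as_trajectory_list <- function(x) {
  if (inherits(x, "fly_trajectory")) return(list(x))
  if (is.list(x) && all(vapply(x, inherits, logical(1), "fly_trajectory"))) return(x)
  stop("expected a 'fly_trajectory' or a list of them")
}
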