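#' Assay tube geometry
#'
#' Describes the detection geometry of a vertical multibeam activity monitor
#' tube: the length of the infrared detection zone, the position bin size, and
#' the boundaries splitting the tube into lower/middle/top sections for dwell
#' times. The defaults describe the standard monitor: a 51 mm detection zone
#' in 3 mm increments (17 unique positions) divided into three equal 17 mm
#' sections.
#'
#' @param tube_length_mm length of the detection zone in mm.
#' @param increment_mm height resolution (bin size) in mm.
#' @param section_boundaries_mm numeric pair: upper edges of the lower and
#'   middle sections, in mm, strictly increasing and inside
#'   `(0, tube_length_mm)`.
#' @return An object of class `assay_geometry`.
#' @examples
#' geom <- assay_geometry()
#' geom$n_positions  # 17
#' @export
assay_geometry <- function(tube_length_mm = 51, increment_mm = 3,
                           section_boundaries_mm = c(17, 34)) {
  if (!is.numeric(tube_length_mm) || length(tube_length_mm) != 1 || tube_length_mm <= 0)
    stop("'tube_length_mm' must be a single positive number")
  if (!is.numeric(increment_mm) || length(increment_mm) != 1 || increment_mm <= 0)
    stop("'increment_mm' must be a single positive number")
  n <- tube_length_mm / increment_mm
  if (!is_whole(n))
    stop("'tube_length_mm' must be an integer multiple of 'increment_mm'")
  b <- section_boundaries_mm
  if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2] ||
      b[1] <= 0 || b[2] >= tube_length_mm)
    stop("'section_boundaries_mm' must be two increasing values inside (0, tube_length_mm)")
  structure(
    list(tube_length_mm = tube_length_mm,
         increment_mm = increment_mm,
         n_positions = as.integer(round(n)),
         section_boundaries_mm = as.numeric(b)),
    class = "assay_geometry")
}

#' @export
print.assay_geometry <- function(x, ...) {
  cat(sprintf("Assay geometry: %g mm tube, %g mm bins (%d positions); sections at %g/%g mm\n",
              x$tube_length_mm, x$increment_mm, x$n_positions,
              x$section_boundaries_mm[1], x$section_boundaries_mm[2]))
  invisible(x)
}

#' Convert a beam position index to a height
#'
#' The monitor reports a position index `p` in `1..n_positions`; heights use
#' the convention `h = p * increment_mm`, so the top position maps to the full
#' tube length (51 mm by default) and the lowest observable height is one
#' increment (3 mm).
#'
#' @param p integer vector of position indices.
#' @param geom an [assay_geometry()].
#' @return Numeric vector of heights in mm.
#' @examples
#' position_to_height(17)  # 51
#' @export
position_to_height <- function(p, geom = assay_geometry()) {
  if (length(p) == 0) return(numeric(0))
  if (!all(is_whole(p)) || any(p < 1) || any(p > geom$n_positions))
    stop(sprintf("position index must be an integer in [1, %d]", geom$n_positions))
  as.numeric(p) * geom$increment_mm
}

#' Tube section of a height
#'
#' Assigns a height to the lower, middle or top section of the tube. With the
#' default geometry the sections are 1-17 mm, 18-34 mm and 35-51 mm; under the
#' `h = 3p` height convention no observable height falls on a boundary gap
#' (positions 1-5 lower, 6-11 middle, 12-17 top).
#'
#' @param h numeric vector of heights in mm, each in `(0, tube_length_mm]`.
#' @param geom an [assay_geometry()].
#' @return Factor with levels `lower`, `middle`, `top`.
#' @export
section_of <- function(h, geom = assay_geometry()) {
  if (length(h) == 0)
    return(factor(character(0), levels = c("lower", "middle", "top")))
  if (!is.numeric(h) || any(!is.finite(h)) || any(h <= 0) || any(h > geom$tube_length_mm))
    stop(sprintf("height must lie in (0, %g] mm", geom$tube_length_mm))
  b <- geom$section_boundaries_mm
  out <- ifelse(h <= b[1], "lower", ifelse(h <= b[2], "middle", "top"))
  factor(out, levels = c("lower", "middle", "top"))
}
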