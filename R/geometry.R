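#' Drusen geometry
#'
#' Describes one artificial druse: the physical position of its center in the
#' image and the diameter of the illuminated area that produced it. All
#' region assignments are radial distances (in micrometers) from this center.
#'
#' @param center_xy Numeric length-2, physical (x, y) position of the drusen
#'   center in micrometers.
#' @param illumination_diameter Diameter of the illuminated area in
#'   micrometers (100 and 300 are the two characterized conditions).
#' @param condition_label Free-text label carried into outputs.
#' @return An object of class `drusen_geometry`.
#' @examples
#' geom <- drusen_geometry(c(180, 180), 100)
#' @export
drusen_geometry <- function(center_xy, illumination_diameter,
                            condition_label = paste0(illumination_diameter, "um")) {
  if (!is.numeric(center_xy) || length(center_xy) != 2L || any(!is.finite(center_xy))) {
    stop_invalid("`center_xy` must be two finite physical coordinates (um)")
  }
  check_positive(illumination_diameter, "illumination_diameter")
  structure(
    list(center_xy = as.numeric(center_xy),
         illumination_diameter = as.numeric(illumination_diameter),
         condition_label = as.character(condition_label)),
    class = "drusen_geometry"
  )
}

#' @export
print.drusen_geometry <- function(x, ...) {
  cat(sprintf("<drusen_geometry> center (%g, %g) um, illumination %g um [%s]\n",
              x$center_xy[1], x$center_xy[2], x$illumination_diameter,
              x$condition_label))
  invisible(x)
}

#' Radial region specification (Top / Edge / Outside)
#'
#' Builds the three radial annuli used for all region-wise statistics around
#' a druse. Top always spans 0-25 um from the center and Outside 150-175 um.
#' The Edge band extends 25 um radially inwards from the illumination radius:
#' 25-50 um for the 100 um condition and 125-150 um for the 300 um condition.
#' Annuli are half-open `[inner, outer)` so that a distance exactly on a
#' shared boundary belongs to the outer band only.
#'
#' @param illumination_diameter Illuminated-area diameter in micrometers.
#'   Any diameter > 50 um is accepted via the generic rule
#'   `Edge = [D/2 - 25, D/2)`; diameters <= 50 would make Edge collide with
#'   Top and are rejected.
#' @return An object of class `region_spec`: a data frame with columns
#'   `name`, `inner`, `outer` (um).
#' @examples
#' make_region_spec(100)
#' make_region_spec(300)
#' @export
make_region_spec <- function(illumination_diameter) {
  check_positive(illumination_diameter, "illumination_diameter")
  r <- illumination_diameter / 2
  if (r - 25 <= 0 || illumination_diameter <= 50) {
    stop_invalid("generic Edge rule [D/2 - 25, D/2) overlaps Top for diameter ",
                 illumination_diameter, " um; need D > 50")
  }
  spec <- data.frame(
    name = c("Top", "Edge", "Outside"),
    inner = c(0, r - 25, 150),
    outer = c(25, r, 175),
    stringsAsFactors = FALSE
  )
  validate_region_spec(spec)
}

#' Construct a region spec from explicit annuli
#'
#' @param name,inner,outer Parallel vectors of region names and half-open
#'   radial bounds in micrometers.
#' @return A `region_spec`.
#' @export
region_spec <- function(name, inner, outer) {
  spec <- data.frame(name = as.character(name), inner = as.numeric(inner),
                     outer = as.numeric(outer), stringsAsFactors = FALSE)
  validate_region_spec(spec)
}

validate_region_spec <- function(spec) {
  if (anyDuplicated(spec$name)) stop_invalid("region names must be unique")
  if (any(!is.finite(spec$inner)) || any(!is.finite(spec$outer)) ||
      any(spec$inner < 0)) {
    stop_invalid("region radii must be finite and non-negative")
  }
  if (any(spec$inner >= spec$outer)) {
    stop_invalid("each region needs inner < outer")
  }
  o <- order(spec$inner)
  s <- spec[o, ]
  if (nrow(s) > 1L && any(s$outer[-nrow(s)] > s$inner[-1L] + 1e-9)) {
    stop_invalid("regions overlap: annuli must be pairwise disjoint")
  }
  class(spec) <- c("region_spec", "data.frame")
  spec
}

#' Assign points to radial regions
#'
#' Computes the Euclidean distance of each query point from the drusen center
#' and bins it into the half-open annuli of `spec`. Points outside every
#' annulus are returned as `"unassigned"`.
#'
#' @param point_xy Numeric length-2 (x, y) in micrometers, or an n x 2 matrix
#'   of points.
#' @param geometry A [drusen_geometry()].
#' @param spec A [make_region_spec()] result.
#' @return Character vector of region names (`"unassigned"` where no annulus
#'   matches).
#' @export
assign_region <- function(point_xy, geometry, spec) {
  stopifnot(inherits(geometry, "drusen_geometry"), inherits(spec, "region_spec"))
  pts <- if (is.matrix(point_xy)) point_xy else matrix(point_xy, ncol = 2)
  d <- sqrt((pts[, 1] - geometry$center_xy[1])^2 +
            (pts[, 2] - geometry$center_xy[2])^2)
  assign_region_dist(d, spec)
}

# Distance-based binning, vectorized; half-open [inner, outer).
assign_region_dist <- function(dist_um, spec) {
  out <- rep("unassigned", length(dist_um))
  for (i in seq_len(nrow(spec))) {
    hit <- dist_um >= spec$inner[i] & dist_um < spec$outer[i]
    out[hit] <- spec$name[i]
  }
  out
}
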