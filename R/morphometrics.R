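# Perimeter estimation: marching-squares segment counting over 2x2 pixel
# neighbourhoods. Each boundary-crossing 2x2 configuration contributes a
# straight (axis-parallel) or corner (diagonal half-step) segment; the two
# segment weights are calibrated so that a 10x10 axis-aligned square and a
# radius-50 digital disc are measured exactly, which keeps arbitrary convex
# shapes within a few percent (Proffitt-Rosen style calibration).
PERIM_W_STRAIGHT <- 1.04350889
PERIM_W_CORNER <- 0.60842

perimeter_px <- function(mask_bin) {
  p <- matrix(0L, nrow(mask_bin) + 2L, ncol(mask_bin) + 2L)
  p[2:(nrow(mask_bin) + 1L), 2:(ncol(mask_bin) + 1L)] <- mask_bin
  nr <- nrow(p); nc <- ncol(p)
  a <- p[-nr, -nc]; b <- p[-nr, -1]; cc <- p[-1, -nc]; d <- p[-1, -1]
  s <- a + b + cc + d
  n_corner <- sum(s == 1L | s == 3L)
  two <- s == 2L
  diag2 <- two & ((a == 1L & d == 1L) | (b == 1L & cc == 1L))
  n_straight <- sum(two & !diag2)
  n_corner <- n_corner + 2L * sum(diag2)
  PERIM_W_STRAIGHT * n_straight + PERIM_W_CORNER * n_corner
}

#' Angle-to-origin orientation metric
#'
#' The angle between a cell's major axis and the direction from its centroid
#' to the drusen center: `theta = acos(|u . v|)` in degrees, where `u` is
#' the unit vector along the (axial) orientation and `v` the unit vector
#' from centroid to center. 0 deg means the cell points at the center
#' (radial alignment), 90 deg means circumferential alignment; the absolute
#' dot product folds the 180 deg axial ambiguity so the metric always lies
#' in [0, 90].
#'
#' @param orientation_axis Axial orientation(s) in degrees, [0, 180).
#' @param centroid_xy Length-2 vector or n x 2 matrix of centroids (um).
#' @param center_xy Drusen center (um).
#' @return Angle(s) in degrees in [0, 90]; `NA` where the centroid
#'   coincides with the center (metric undefined).
#' @export
angle_to_origin <- function(orientation_axis, centroid_xy, center_xy) {
  cen <- if (is.matrix(centroid_xy)) centroid_xy else
    matrix(centroid_xy, ncol = 2)
  vx <- center_xy[1] - cen[, 1]
  vy <- center_xy[2] - cen[, 2]
  nv <- sqrt(vx^2 + vy^2)
  th <- orientation_axis * pi / 180
  dot <- abs(cos(th) * vx + sin(th) * vy) / nv
  out <- acos(pmin(pmax(dot, 0), 1)) * 180 / pi
  out[nv == 0] <- NA_real_
  out
}

#' Per-cell morphometrics from a label mask
#'
#' Measures every labelled cell: area (pixel count x pitch^2), perimeter
#' (corner-corrected marching-squares estimator), shape factor `P/sqrt(A)`,
#' centroid, axial orientation from the principal axis of the second central
#' moments, distance to the drusen center, region assignment, and
#' angle-to-origin. Cells touching the image border are measured but
#' flagged (`border = TRUE`) so they can be excluded from area/shape
#' statistics while still being counted. Labels with fewer than `min_px`
#' pixels are skipped; the skipped count is in the `"n_skipped"` attribute.
#'
#' @param mask A [label_mask()].
#' @param geometry A [drusen_geometry()].
#' @param spec A [region_spec()]; defaults to the one for the geometry's
#'   illumination diameter.
#' @param min_px Minimum pixel count for a measurable cell (default 4).
#' @return Data frame of class `cell_records`, one row per cell: `label,
#'   area, perimeter, shape_factor, centroid_x, centroid_y,
#'   orientation_deg, aspect_ratio, distance_um, angle_to_origin, region,
#'   border`. (`aspect_ratio` is the principal-axis ratio; near 1 the
#'   orientation, and hence the angle-to-origin, is poorly defined.)
#' @export
measure_cells <- function(mask, geometry, spec = NULL, min_px = 4L) {
  stopifnot(inherits(mask, "label_mask"), inherits(geometry, "drusen_geometry"))
  if (is.null(spec)) spec <- make_region_spec(geometry$illumination_diameter)
  lab <- mask$labels
  pitch <- mask$pixel_pitch
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (!length(ids)) {
    out <- data.frame(label = integer(), area = numeric(),
                      perimeter = numeric(), shape_factor = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      orientation_deg = numeric(), distance_um = numeric(),
                      angle_to_origin = numeric(), region = character(),
                      border = logical(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    class(out) <- c("cell_records", class(out))
    return(out)
  }
  idx <- which(lab > 0L)
  ri <- ((idx - 1L) %% nrow(lab)) + 1L
  ci <- ((idx - 1L) %/% nrow(lab)) + 1L
  lv <- lab[idx]
  by_lab <- split(seq_along(idx), lv)
  n_skipped <- 0L
  rows <- vector("list", length(by_lab))
  for (j in seq_along(by_lab)) {
    sel <- by_lab[[j]]
    id <- as.integer(names(by_lab)[j])
    if (length(sel) < min_px) {
      n_skipped <- n_skipped + 1L
      next
    }
    rr <- ri[sel]; cx <- ci[sel]
    # physical coordinates, pixel-center convention
    x <- (cx - 1) * pitch
    y <- (rr - 1) * pitch
    mux <- mean(x); muy <- mean(y)
    m20 <- mean((x - mux)^2); m02 <- mean((y - muy)^2)
    m11 <- mean((x - mux) * (y - muy))
    theta <- (0.5 * atan2(2 * m11, m20 - m02) * 180 / pi) %% 180
    disc <- sqrt((m20 - m02)^2 + 4 * m11^2)
    lam1 <- (m20 + m02 + disc) / 2
    lam2 <- (m20 + m02 - disc) / 2
    aspect <- if (lam2 > 0) sqrt(lam1 / lam2) else Inf
    r0 <- min(rr); r1 <- max(rr); c0 <- min(cx); c1 <- max(cx)
    sub <- matrix(0L, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rr - r0 + 1L, cx - c0 + 1L)] <- 1L
    per <- perimeter_px(sub) * pitch
    area <- length(sel) * pitch^2
    d <- sqrt((mux - geometry$center_xy[1])^2 + (muy - geometry$center_xy[2])^2)
    border <- r0 == 1L || c0 == 1L || r1 == nrow(lab) || c1 == ncol(lab)
    rows[[j]] <- data.frame(
      label = id, area = area, perimeter = per,
      shape_factor = per / sqrt(area),
      centroid_x = mux, centroid_y = muy, orientation_deg = theta,
      aspect_ratio = aspect, distance_um = d,
      angle_to_origin = angle_to_origin(theta, c(mux, muy), geometry$center_xy),
      region = assign_region_dist(d, spec), border = border,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("cell_records", class(out))
  out
}

#' Normalize cell areas by the per-replicate mean
#'
#' Adds `area_normalized = area / mean(area)` within each group (border
#' cells are excluded from the group mean but still normalized).
#'
#' @param records [measure_cells()] output, optionally with a
#'   `replicate_id` column.
#' @param group Grouping column; if absent all rows form one group.
#' @return Records with `area_normalized` added.
#' @export
normalize_areas <- function(records, group = "replicate_id") {
  if (nrow(records) == 0L) stop_invalid("no cell records")
  g <- if (group %in% names(records)) records[[group]] else rep("all", nrow(records))
  keep <- !records$border
  mu <- tapply(records$area[keep], g[keep], mean)
  records$area_normalized <- records$area / as.numeric(mu[as.character(g)])
  records
}

#' Relative-frequency area distribution per region
#'
#' Pools normalized cell areas for one region, bins them into a
#' relative-frequency histogram (frequencies sum to one) and overlays a
#' Gaussian kernel density with Silverman's rule-of-thumb bandwidth.
#'
#' @param records Output of [normalize_areas()].
#' @param region Region name to pool, or `NULL` for all assigned cells.
#' @param bins Number of histogram bins (default 20).
#' @param value Column to analyse (default `"area_normalized"`).
#' @return List with `breaks`, `mids`, `rel_freq`, `density` (a
#'   [stats::density()] object) and `n`.
#' @export
area_distribution <- function(records, region = NULL, bins = 20,
                              value = "area_normalized") {
  if (!value %in% names(records)) {
    stop_invalid("column `", value, "` not found; run normalize_areas() first?")
  }
  x <- records[[value]][!records$border]
  if (!is.null(region)) {
    x <- records[[value]][!records$border & records$region == region]
  }
  x <- x[is.finite(x)]
  if (!length(x)) stop_invalid("no cells to pool")
  h <- graphics::hist(x, breaks = bins, plot = FALSE)
  rel <- h$counts / sum(h$counts)
  dens <- stats::density(x, bw = "nrd0")
  list(breaks = h$breaks, mids = h$mids, rel_freq = rel, density = dens,
       n = length(x))
}

#' Count local maxima of a density estimate
#'
#' @param dens A [stats::density()] object (or list with `y`).
#' @param min_prominence Peaks lower than this fraction of the tallest peak
#'   are ignored.
#' @return Integer number of modes.
#' @export
count_density_modes <- function(dens, min_prominence = 0.05) {
  y <- dens$y
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  loc <- loc[y[loc] > min_prominence * max(y)]
  length(loc)
}
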