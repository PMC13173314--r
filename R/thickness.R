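#' Reslice a stack into XZ planes
#'
#' Extracts orthogonal (XZ) planes at 10% intervals of the frame height with
#' a 5% offset from the frame edge, i.e. at fractional y positions 0.05,
#' 0.15, ..., 0.95. Fractional positions map to 0-based row indices by
#' round-half-down. This mirrors orthogonal reslicing of a confocal stack
#' before drawing vertical line profiles.
#'
#' @param stack An [image_stack()].
#' @return List of planes; each element has `plane` (x-by-z intensity
#'   matrix), `row` (0-based y pixel index) and `y_um` (physical y).
#' @export
reslice_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  ny <- dim(stack$voxels)[1]
  rows <- grid_indices(ny)
  lapply(rows, function(r) {
    list(plane = stack$voxels[r + 1L, , ], row = r,
         y_um = r * stack$pixel_pitch)
  })
}

#' Apical and basal boundary from one vertical line profile
#'
#' Implements the mean-threshold boundary rule: the threshold is the
#' arithmetic mean grey value of the profile; the basal boundary is the
#' first strictly-above-threshold crossing scanning up from the substrate
#' side (z index 0), the apical boundary the first crossing scanning down
#' from the far side. Crossings are refined to sub-voxel positions by linear
#' interpolation between the bracketing samples (disable with
#' `interpolate = FALSE` to get plain plane positions).
#'
#' @param profile Numeric vector of intensities along z.
#' @param z_step um per z sample.
#' @param z_origin Physical z of sample 1, um.
#' @param interpolate Sub-voxel refinement flag.
#' @return Named numeric `c(basal_z, apical_z)` in um, or `NULL` if the
#'   profile never crosses its mean from both sides ("undetected").
#' @export
profile_height <- function(profile, z_step, z_origin = 0, interpolate = TRUE) {
  thr <- mean(profile)
  above <- profile > thr
  if (!any(above) || all(above)) return(NULL)
  k1 <- which(above)[1]
  k2 <- which(above)[sum(above)]
  kk <- which(above)
  k2 <- kk[length(kk)]
  basal <- (k1 - 1) * z_step
  apical <- (k2 - 1) * z_step
  if (interpolate) {
    if (k1 > 1L) {
      denom <- profile[k1] - profile[k1 - 1L]
      basal <- basal - z_step + (thr - profile[k1 - 1L]) / denom * z_step
    }
    if (k2 < length(profile)) {
      denom <- profile[k2] - profile[k2 + 1L]
      apical <- apical + (profile[k2] - thr) / denom * z_step
    }
  }
  if (apical <= basal) return(NULL)
  c(basal_z = z_origin + basal, apical_z = z_origin + apical)
}

#' Measure monolayer thickness over a stack
#'
#' Applies [reslice_stack()] and then [profile_height()] at 10%-interval
#' x positions (5% offset) within each resliced plane, yielding up to a
#' 10 x 10 grid of measurements. Each measurement records its physical
#' position, distance to the drusen center, region assignment, and raw
#' height (apical minus basal boundary). Undetected profiles and heights
#' below `min_height` (degenerate single-band detections) are dropped; the
#' dropped count is kept in the `"n_dropped"` attribute.
#'
#' @param stack An [image_stack()] (F-actin channel).
#' @param geometry A [drusen_geometry()].
#' @param spec A [region_spec()]; defaults to the spec for the geometry's
#'   illumination diameter.
#' @param min_height Minimum plausible monolayer height in um (default 2).
#' @param interpolate Sub-voxel boundary refinement (default TRUE).
#' @param replicate_id Identifier stored with every measurement; the default
#'   normalization groups by it.
#' @return Data frame of class `thickness_measurements`, one row per
#'   detected measurement: `replicate_id, row, y_um, col, x_um,
#'   distance_um, region, basal_z, apical_z, height_um`.
#' @export
measure_monolayer <- function(stack, geometry, spec = NULL, min_height = 2,
                              interpolate = TRUE, replicate_id = "r1") {
  stopifnot(inherits(stack, "image_stack"),
            inherits(geometry, "drusen_geometry"))
  if (is.null(spec)) spec <- make_region_spec(geometry$illumination_diameter)
  planes <- reslice_stack(stack)
  nx <- dim(stack$voxels)[2]
  cols <- grid_indices(nx)
  rows_out <- list()
  dropped <- 0L
  for (pl in planes) {
    for (cc in cols) {
      prof <- pl$plane[cc + 1L, ]
      hz <- profile_height(prof, stack$z_step, stack$z_origin, interpolate)
      if (is.null(hz) || (hz["apical_z"] - hz["basal_z"]) < min_height) {
        dropped <- dropped + 1L
        next
      }
      x_um <- cc * stack$pixel_pitch
      d <- sqrt((x_um - geometry$center_xy[1])^2 +
                (pl$y_um - geometry$center_xy[2])^2)
      rows_out[[length(rows_out) + 1L]] <- data.frame(
        replicate_id = replicate_id, row = pl$row, y_um = pl$y_um,
        col = cc, x_um = x_um, distance_um = d,
        region = assign_region_dist(d, spec),
        basal_z = unname(hz["basal_z"]), apical_z = unname(hz["apical_z"]),
        height_um = unname(hz["apical_z"] - hz["basal_z"]),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows_out)) do.call(rbind, rows_out) else
    data.frame(replicate_id = character(), row = integer(), y_um = numeric(),
               col = integer(), x_um = numeric(), distance_um = numeric(),
               region = character(), basal_z = numeric(), apical_z = numeric(),
               height_um = numeric(), stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- dropped
  class(out) <- c("thickness_measurements", class(out))
  out
}

#' Normalize heights by the per-replicate mean
#'
#' Adds a `height_norm` column: each raw height divided by the mean raw
#' height of its replicate (technical-replicate normalization). By
#' construction the mean normalized height within each replicate is exactly
#' one.
#'
#' @param measurements Output of [measure_monolayer()] (rows from several
#'   replicates may be concatenated).
#' @param group Column name used as the normalization group
#'   (default `"replicate_id"`).
#' @return The measurements with `height_norm` added.
#' @export
normalize_heights <- function(measurements, group = "replicate_id") {
  if (nrow(measurements) == 0L) stop_invalid("no measurements to normalize")
  if (!group %in% names(measurements)) {
    stop_invalid("grouping column `", group, "` not found")
  }
  g <- measurements[[group]]
  mu <- tapply(measurements$height_um, g, mean)
  if (any(!is.finite(mu)) || any(mu <= 0)) {
    stop_invalid("non-positive group mean; cannot normalize")
  }
  measurements$height_norm <-
    measurements$height_um / as.numeric(mu[as.character(g)])
  measurements
}

#' Per-region height summary with deltas versus Outside
#'
#' @param measurements Normalized measurements ([normalize_heights()]).
#' @param value Column to summarize (default `"height_norm"`).
#' @return Data frame with one row per region: `region, n, mean, sem,
#'   delta_pct` where `delta_pct = 100 * (mean - mean_Outside) /
#'   mean_Outside` (NA when Outside is empty).
#' @export
region_height_summary <- function(measurements, value = "height_norm") {
  if (!value %in% names(measurements)) {
    stop_invalid("column `", value, "` not found; run normalize_heights() first?")
  }
  v <- measurements[[value]]
  reg <- measurements$region
  regions <- unique(reg)
  out <- do.call(rbind, lapply(regions, function(r) {
    x <- v[reg == r]
    data.frame(region = r, n = length(x), mean = mean(x),
               sem = stats::sd(x) / sqrt(length(x)), stringsAsFactors = FALSE)
  }))
  mu_out <- out$mean[out$region == "Outside"]
  out$delta_pct <- if (length(mu_out) == 1L) {
    100 * (out$mean - mu_out) / mu_out
  } else {
    NA_real_
  }
  out
}
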