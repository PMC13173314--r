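#' Parameters for the synthetic cell mosaic
#'
#' Describes an epithelial mosaic rendered as an integer label mask: seed
#' points placed by dart-throwing with per-cell target sizes drawn from a
#' one- or two-component lognormal mixture, labels assigned by a
#' multiplicatively-weighted anisotropic nearest-seed rule (a weighted
#' Voronoi tessellation). Anisotropic seed metrics elongate cells along a
#' configurable orientation field.
#'
#' @param n_cells Number of cells. Default scales the 400 um frame at a
#'   mean area of 200 um^2 per cell with ~75% occupancy of seeds.
#' @param frame_size Field of view, um.
#' @param pixel_pitch um/px of the rendered mask.
#' @param mean_area Mean target cell area, um^2.
#' @param area_modality `"unimodal"` or `"bimodal"`.
#' @param mode_means For bimodal mosaics, the two component means as
#'   multiples of `mean_area` (default 0.7 and 1.5).
#' @param mixing_fraction Fraction of cells in the first (small) mode.
#' @param area_cv Lognormal coefficient of variation within a component.
#' @param orientation_field `"random"`, `"circumferential_ring"` or
#'   `"radial_cap"`.
#' @param ring_radii Length-2 inner/outer radii (um) of the oriented ring
#'   (circumferential field only).
#' @param cap_radius Radius (um) of the radially-oriented cap
#'   (radial field only).
#' @param elongation Axis ratio imposed on every cell (1 = isotropic).
#' @param seed Integer seed.
#' @return A `mosaic_params` list.
#' @export
mosaic_params <- function(n_cells = 600,
                          frame_size = 400,
                          pixel_pitch = 0.5,
                          mean_area = 200,
                          area_modality = c("unimodal", "bimodal"),
                          mode_means = c(0.7, 1.5),
                          mixing_fraction = 0.5,
                          area_cv = 0.25,
                          orientation_field = c("random",
                                                "circumferential_ring",
                                                "radial_cap"),
                          ring_radii = c(25, 50),
                          cap_radius = 25,
                          elongation = 1.8,
                          seed = 1L) {
  area_modality <- match.arg(area_modality)
  orientation_field <- match.arg(orientation_field)
  check_positive(n_cells, "n_cells")
  check_positive(frame_size, "frame_size")
  check_positive(mean_area, "mean_area")
  check_positive(elongation, "elongation")
  if (mixing_fraction <= 0 || mixing_fraction >= 1) {
    stop_invalid("mixing_fraction must be in (0, 1)")
  }
  if (length(ring_radii) != 2L || ring_radii[1] >= ring_radii[2]) {
    stop_invalid("ring_radii must be ordered (inner, outer)")
  }
  if (n_cells * mean_area > 4 * frame_size^2) {
    stop_invalid("n_cells too large for the frame at this mean_area")
  }
  structure(list(
    n_cells = as.integer(n_cells), frame_size = frame_size,
    pixel_pitch = pixel_pitch, mean_area = mean_area,
    area_modality = area_modality, mode_means = mode_means,
    mixing_fraction = mixing_fraction, area_cv = area_cv,
    orientation_field = orientation_field, ring_radii = ring_radii,
    cap_radius = cap_radius, elongation = elongation,
    seed = as.integer(seed)
  ), class = "mosaic_params")
}

#' Generate a synthetic cell mosaic with ground truth
#'
#' @param params A [mosaic_params()].
#' @param geometry A [drusen_geometry()] giving the center the orientation
#'   fields refer to.
#' @return List: `mask` ([label_mask()]) and `truth`, a data frame with one
#'   row per cell: seed position, intended (target) area and mode, realized
#'   pixel area, intended axial orientation, intended angle-to-origin, and
#'   orientation class (`"oriented"` for ring/cap members, `"background"`
#'   otherwise).
#' @export
generate_cell_mosaic <- function(params, geometry) {
  stopifnot(inherits(params, "mosaic_params"),
            inherits(geometry, "drusen_geometry"))
  p <- params
  with_seed(p$seed, {
    # target areas: lognormal mixture with component means fixed in um^2
    sdl <- sqrt(log(1 + p$area_cv^2))
    n <- p$n_cells
    if (p$area_modality == "bimodal") {
      mode_id <- ifelse(stats::runif(n) < p$mixing_fraction, 1L, 2L)
      mu_lin <- p$mean_area * p$mode_means[mode_id]
    } else {
      mode_id <- rep(1L, n)
      mu_lin <- rep(p$mean_area, n)
    }
    target <- stats::rlnorm(n, meanlog = log(mu_lin) - sdl^2 / 2, sdlog = sdl)
    r_eff <- sqrt(target / pi)

    # dart-throwing seed placement with pairwise separation
    sx <- numeric(n); sy <- numeric(n)
    placed <- 0L
    tries <- 0L
    max_tries <- 4000L * n
    while (placed < n) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop_invalid("n_cells too large for frame: seed placement failed")
      }
      cx <- stats::runif(1, 0, p$frame_size)
      cy <- stats::runif(1, 0, p$frame_size)
      if (placed > 0L) {
        j <- seq_len(placed)
        if (any((sx[j] - cx)^2 + (sy[j] - cy)^2 <
                (0.75 * (r_eff[j] + r_eff[placed + 1L]))^2)) next
      }
      placed <- placed + 1L
      sx[placed] <- cx; sy[placed] <- cy
    }

    # orientation field
    phi <- atan2(geometry$center_xy[2] - sy, geometry$center_xy[1] - sx)
    d_seed <- sqrt((sx - geometry$center_xy[1])^2 +
                   (sy - geometry$center_xy[2])^2)
    theta <- stats::runif(n, 0, pi)
    class_v <- rep("background", n)
    if (p$orientation_field == "circumferential_ring") {
      in_ring <- d_seed >= p$ring_radii[1] & d_seed < p$ring_radii[2]
      theta[in_ring] <- (phi[in_ring] + pi / 2) %% pi
      class_v[in_ring] <- "oriented"
    } else if (p$orientation_field == "radial_cap") {
      in_cap <- d_seed < p$cap_radius
      theta[in_cap] <- phi[in_cap] %% pi
      class_v[in_cap] <- "oriented"
    }

    # anisotropic multiplicatively weighted nearest-seed labelling,
    # windowed per seed for speed
    npx <- round(p$frame_size / p$pixel_pitch)
    best <- matrix(Inf, npx, npx)
    lab <- matrix(0L, npx, npx)
    ax <- (seq_len(npx) - 1) * p$pixel_pitch
    e <- p$elongation
    a_sc <- sqrt(e); b_sc <- 1 / sqrt(e)
    win <- 3.5 * max(r_eff) * a_sc
    for (k in seq_len(n)) {
      ix <- which(ax >= sx[k] - win & ax <= sx[k] + win)
      iy <- which(ax >= sy[k] - win & ax <= sy[k] + win)
      if (!length(ix) || !length(iy)) next
      ddx <- outer(rep(1, length(iy)), ax[ix] - sx[k])
      ddy <- outer(ax[iy] - sy[k], rep(1, length(ix)))
      u <- ddx * cos(theta[k]) + ddy * sin(theta[k])
      v <- -ddx * sin(theta[k]) + ddy * cos(theta[k])
      d2 <- ((u / a_sc)^2 + (v / b_sc)^2) / r_eff[k]^2
      sub_b <- best[iy, ix]
      upd <- d2 < sub_b
      sub_l <- lab[iy, ix]
      sub_l[upd] <- k
      sub_b[upd] <- d2[upd]
      best[iy, ix] <- sub_b
      lab[iy, ix] <- sub_l
    }

    mask <- label_mask(lab, pixel_pitch = p$pixel_pitch)
    area_px <- tabulate(lab, nbins = n)
    theta_deg <- theta * 180 / pi
    truth <- data.frame(
      label = seq_len(n), seed_x = sx, seed_y = sy,
      target_area_um2 = target, mode = mode_id,
      area_um2 = area_px * p$pixel_pitch^2,
      orientation_deg = theta_deg,
      angle_to_origin = angle_to_origin(theta_deg, cbind(sx, sy),
                                        geometry$center_xy),
      distance_um = d_seed, class = class_v,
      stringsAsFactors = FALSE
    )
    list(mask = mask, truth = truth)
  })
}
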