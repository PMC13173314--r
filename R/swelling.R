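#' Illumination protocol
#'
#' @param intensity LED intensity, mW cm^-2.
#' @param exposure Exposure per cycle, s.
#' @param cycles Number of illumination cycles.
#' @param gap_h Break between cycles, h.
#' @return An `illumination_protocol`.
#' @examples
#' illumination_protocol(3.83, 60)          # single 60 s dose
#' illumination_protocol(3.83, 4, 15, 1)    # additive 15 x 4 s protocol
#' @export
illumination_protocol <- function(intensity, exposure, cycles = 1L, gap_h = 1) {
  check_positive(intensity, "intensity")
  if (exposure < 0) stop_invalid("exposure must be >= 0")
  check_positive(cycles, "cycles")
  structure(list(intensity = intensity, exposure = exposure,
                 cycles = as.integer(cycles), gap_h = gap_h),
            class = "illumination_protocol")
}

#' Illumination dose
#'
#' Per-cycle dose is intensity times exposure (mW cm^-2 x s = mJ cm^-2);
#' total dose multiplies by the cycle count, so e.g. 3.83 mW cm^-2 for 60 s
#' gives ~230 mJ cm^-2, and fifteen 4 s cycles accumulate the same total.
#'
#' @param protocol An [illumination_protocol()].
#' @return List with `per_cycle` and `total` doses in mJ cm^-2.
#' @export
dose <- function(protocol) {
  stopifnot(inherits(protocol, "illumination_protocol"))
  per <- protocol$intensity * protocol$exposure
  list(per_cycle = per, total = per * protocol$cycles)
}

#' Min-max normalize a swelling height series
#'
#' Rescales raw bulge heights per druse so the minimum maps to 0 and the
#' maximum to 1 (`heights_norm`), with `heights_pct = 100 * heights_norm`
#' as percentage swelling height.
#'
#' @param times Sampling times in hours (0 = illumination event; negative =
#'   pre-illumination reference). Must be strictly increasing.
#' @param heights_raw Raw apex heights, um.
#' @param druse_id Identifier carried into the result.
#' @return A `swelling_series` data frame with columns `druse_id, time_h,
#'   height_um, height_norm, height_pct`.
#' @export
normalize_series <- function(times, heights_raw, druse_id = "d1") {
  if (length(times) != length(heights_raw) || length(times) < 2L) {
    stop_invalid("need matching times and heights (>= 2 samples)")
  }
  if (any(diff(times) <= 0)) stop_invalid("times must be strictly increasing")
  rng <- range(heights_raw)
  if (diff(rng) == 0) stop_invalid("degenerate series: max equals min")
  hn <- (heights_raw - rng[1]) / diff(rng)
  out <- data.frame(druse_id = druse_id, time_h = times,
                    height_um = heights_raw, height_norm = hn,
                    height_pct = 100 * hn, stringsAsFactors = FALSE)
  class(out) <- c("swelling_series", class(out))
  out
}

#' Generate a saturating swelling time series
#'
#' Height follows `plateau * (1 - exp(-t / tau))` for `t >= 0` and 0 before
#' illumination, with optional Gaussian noise. Emulates the observed
#' kinetics where swelling is nearly immediate but plateaus only after
#' several hours.
#'
#' @param plateau Plateau height (um or %, caller's convention).
#' @param tau_h Exponential time constant, h.
#' @param sample_times Times in hours (0 = illumination).
#' @param noise_sd Gaussian noise sd in the same unit as `plateau`.
#' @param seed Integer seed.
#' @param druse_id Identifier.
#' @return Data frame `time_h, height_um`.
#' @export
generate_swelling_series <- function(plateau, tau_h, sample_times,
                                     noise_sd = 0, seed = 1L,
                                     druse_id = "d1") {
  check_positive(plateau, "plateau")
  check_positive(tau_h, "tau_h")
  h <- ifelse(sample_times >= 0, plateau * (1 - exp(-sample_times / tau_h)), 0)
  h <- with_seed(seed, h + if (noise_sd > 0)
    stats::rnorm(length(h), sd = noise_sd) else 0)
  data.frame(druse_id = druse_id, time_h = sample_times, height_um = h,
             stringsAsFactors = FALSE)
}

# Per-plane focus metric: intensity variance within the apex window.
focus_curve <- function(stack, window_px) {
  v <- stack$voxels
  vapply(seq_len(dim(v)[3]),
         function(k) stats::var(as.vector(v[window_px$rows, window_px$cols, k])),
         numeric(1))
}

#' Apex height from a brightfield focus-stack pair
#'
#' Estimates the surface z at the bulge apex in each stack as the plane
#' maximizing the focus metric (per-plane intensity variance inside a small
#' window centered on the apex), optionally refined to sub-plane precision
#' by parabolic interpolation of the metric across the best plane and its
#' neighbours. The apex height is the difference `z_post - z_ref`.
#'
#' @param reference,post [image_stack()]s before and after swelling.
#' @param center_xy Apex position, um. Defaults to the frame center.
#' @param window Side length of the apex window, um (default 20).
#' @param refine Parabolic sub-plane refinement (default TRUE).
#' @return List with `height_um`, `z_ref`, `z_post` (um).
#' @export
apex_height <- function(reference, post, center_xy = NULL, window = 20,
                        refine = TRUE) {
  stopifnot(inherits(reference, "image_stack"), inherits(post, "image_stack"))
  if (!all(dim(reference$voxels)[1:2] == dim(post$voxels)[1:2])) {
    stop_invalid("stacks must share lateral dimensions")
  }
  d <- dim(reference$voxels)
  pitch <- reference$pixel_pitch
  if (is.null(center_xy)) {
    center_xy <- c((d[2] - 1) / 2, (d[1] - 1) / 2) * pitch
  }
  half <- window / 2
  cols <- which(abs((seq_len(d[2]) - 1) * pitch - center_xy[1]) <= half)
  rows <- which(abs((seq_len(d[1]) - 1) * pitch - center_xy[2]) <= half)
  if (!length(rows) || !length(cols)) stop_invalid("apex window outside frame")
  win <- list(rows = rows, cols = cols)
  zf <- function(stack) {
    fc <- focus_curve(stack, win)
    if (max(fc) <= 0 || !any(is.finite(fc)) || stats::sd(fc) == 0) {
      stop_invalid("no focus contrast in the apex window")
    }
    k <- which.max(fc)
    z <- (k - 1) * stack$z_step
    if (refine && k > 1L && k < length(fc)) {
      y0 <- fc[k - 1L]; y1 <- fc[k]; y2 <- fc[k + 1L]
      denom <- y0 - 2 * y1 + y2
      if (denom < 0) z <- z + 0.5 * (y0 - y2) / denom * stack$z_step
    }
    stack$z_origin + z
  }
  z_ref <- zf(reference)
  z_post <- zf(post)
  list(height_um = z_post - z_ref, z_ref = z_ref, z_post = z_post)
}

#' Generate a brightfield-like focus stack
#'
#' Renders a textured surface imaged through a stack of focal planes: a
#' fixed random texture whose local contrast decays with defocus distance
#' `|z - z_surface|`. The surface is flat at `surface_z` plus an optional
#' dome bulge, matching the way swelling height is read from the
#' brightfield focus plane at the top of a forming druse.
#'
#' @param surface_z Flat surface height, um.
#' @param bulge_apex Additional apex height of a dome at the frame center,
#'   um (0 = flat).
#' @param bulge_diameter Dome footprint, um.
#' @param frame_size,pixel_pitch,z_step,n_planes Stack geometry (defaults:
#'   120 um frame at 2 um/px, 40 planes of 4 um).
#' @param depth_of_field Defocus decay length (Gaussian sd), um.
#' @param noise_sd Additive Gaussian noise sd.
#' @param texture_seed Seed for the surface texture: use the same value for
#'   a reference/post pair so only the surface height changes.
#' @param seed Seed for the noise.
#' @return An [image_stack()] (channel `"brightfield"`).
#' @export
generate_focus_stack <- function(surface_z, bulge_apex = 0,
                                 bulge_diameter = 100, frame_size = 120,
                                 pixel_pitch = 2, z_step = 4, n_planes = 40,
                                 depth_of_field = 6, noise_sd = 0.02,
                                 texture_seed = 99L, seed = 1L) {
  n <- round(frame_size / pixel_pitch)
  tex <- with_seed(texture_seed, matrix(stats::runif(n * n, -1, 1), n, n))
  ax <- (seq_len(n) - 1) * pixel_pitch
  cx <- (n - 1) / 2 * pixel_pitch
  r <- sqrt(outer((ax - cx)^2, rep(1, n)) + outer(rep(1, n), (ax - cx)^2))
  zs <- surface_z + if (bulge_apex > 0) {
    bulge_height(r, bulge_diameter, bulge_apex, "spherical_cap")
  } else 0
  zmax <- (n_planes - 1) * z_step
  if (max(zs) > zmax) stop_invalid("surface exceeds stack depth")
  vox <- array(0, dim = c(n, n, n_planes))
  for (k in seq_len(n_planes)) {
    z <- (k - 1) * z_step
    vox[, , k] <- 0.5 + tex * exp(-(z - zs)^2 / (2 * depth_of_field^2))
  }
  vox <- with_seed(seed, vox + if (noise_sd > 0)
    array(stats::rnorm(length(vox), sd = noise_sd), dim = dim(vox)) else 0)
  image_stack(pmax(vox, 0), pixel_pitch = pixel_pitch, z_step = z_step,
              channel = "brightfield")
}
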