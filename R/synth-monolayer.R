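#' Parameters for the monolayer thickness phantom
#'
#' Describes a confocal-like F-actin phantom: an epithelial monolayer of
#' baseline thickness `baseline_thickness` draped over a dome-shaped
#' substrate bulge, rendered as two bright bands (basal and apical cortical
#' actin) plus a dimmer cytoplasmic fill. Per-region thickness multipliers
#' encode the ground-truth effect sizes the analysis should recover.
#'
#' Defaults emulate the characterized imaging setup: a 400 um field sampled
#' at 2 um/px laterally and 0.25 um axially (super-resolution z-slicing),
#' a ~20 um bulge apex, and a 12 um baseline monolayer thickness (the
#' absolute thickness is not a reported quantity; 12 um is a plausible
#' epithelial value and is a free choice of the phantom).
#'
#' @param frame_size_xy Field of view in um (square frame).
#' @param pixel_pitch um/px.
#' @param z_step um/plane.
#' @param z_depth Axial extent of the stack in um.
#' @param bulge_diameter Dome footprint diameter in um.
#' @param bulge_apex_height Dome apex height in um.
#' @param bulge_profile `"spherical_cap"` (default) or `"gaussian"`.
#' @param baseline_thickness Monolayer thickness outside any modifier, um.
#' @param thickness_modifiers Named list of per-region multiplicative
#'   thickness modifiers, e.g. `list(Top = 1.05, Edge = 1.03)`. Regions not
#'   named (and unassigned points) keep multiplier 1.
#' @param band_width Gaussian sd of each actin band along z, um.
#' @param band_inset Distance from the membrane surface to the band center,
#'   um (cortical actin sits just inside the cell).
#' @param cytoplasm_level Cytoplasmic fill intensity relative to band peak 1.
#' @param substrate_z Physical z of the flat gel surface, um.
#' @param noise_sd Additive Gaussian (dark/readout) noise sd relative to the
#'   band peak. Confocal dark noise is small compared to the signal; the
#'   default is 1%.
#' @param poisson_noise If `TRUE` (default), apply Poisson resampling (shot
#'   noise) at `poisson_scale` expected peak counts before the Gaussian
#'   term, so noise scales with sqrt(signal) and the background stays dark.
#' @param poisson_scale Photon count at band peak for the Poisson stage
#'   (200 counts gives ~7% relative noise at the band peak).
#' @param seed Integer seed; every run with the same params+seed is
#'   bit-identical.
#' @return A `monolayer_params` list.
#' @export
monolayer_params <- function(frame_size_xy = 400,
                             pixel_pitch = 2,
                             z_step = 0.25,
                             z_depth = 40,
                             bulge_diameter = 100,
                             bulge_apex_height = 20,
                             bulge_profile = c("spherical_cap", "gaussian"),
                             baseline_thickness = 12,
                             thickness_modifiers = list(),
                             band_width = 0.35,
                             band_inset = 0,
                             cytoplasm_level = 0.25,
                             substrate_z = 2,
                             noise_sd = 0.01,
                             poisson_noise = TRUE,
                             poisson_scale = 200,
                             seed = 1L) {
  bulge_profile <- match.arg(bulge_profile)
  for (nm in c("frame_size_xy", "pixel_pitch", "z_step", "z_depth",
               "bulge_diameter", "bulge_apex_height", "baseline_thickness",
               "band_width")) {
    check_positive(get(nm), nm)
  }
  mods <- unlist(thickness_modifiers)
  if (length(mods) && any(mods <= 0)) stop_invalid("thickness modifiers must be > 0")
  if (baseline_thickness <= 4 * band_width) {
    stop_invalid("baseline_thickness must exceed 4 x band_width to resolve two bands")
  }
  structure(list(
    frame_size_xy = frame_size_xy, pixel_pitch = pixel_pitch,
    z_step = z_step, z_depth = z_depth, bulge_diameter = bulge_diameter,
    bulge_apex_height = bulge_apex_height, bulge_profile = bulge_profile,
    baseline_thickness = baseline_thickness,
    thickness_modifiers = thickness_modifiers,
    band_width = band_width, band_inset = band_inset,
    cytoplasm_level = cytoplasm_level, substrate_z = substrate_z,
    noise_sd = noise_sd, poisson_noise = poisson_noise,
    poisson_scale = poisson_scale, seed = as.integer(seed)
  ), class = "monolayer_params")
}

#' Named phantom presets
#'
#' `"medium-drusen"`: 100 um illumination, ~20 um apex, ground-truth
#' thickness excess of 5% at Top and 3% at Edge. `"large-drusen"`: 300 um
#' illumination, 5% Top deficit, Edge unchanged. The presets carry the
#' recovered-effect-size targets of the analysis as ground truth, so
#' thickness-pipeline validation is a parameter-recovery exercise.
#'
#' @param name `"medium-drusen"` or `"large-drusen"`.
#' @param seed Integer seed forwarded to the params.
#' @param ... Overrides passed to [monolayer_params()].
#' @return List with elements `params` ([monolayer_params()]) and
#'   `geometry` ([drusen_geometry()] centered mid-frame).
#' @export
drusen_preset <- function(name = c("medium-drusen", "large-drusen"),
                          seed = 1L, ...) {
  name <- match.arg(name)
  base <- switch(name,
    "medium-drusen" = list(bulge_diameter = 100,
                           thickness_modifiers = list(Top = 1.05, Edge = 1.03)),
    "large-drusen" = list(bulge_diameter = 300,
                          thickness_modifiers = list(Top = 0.95, Edge = 1.00))
  )
  params <- do.call(monolayer_params, utils::modifyList(c(base, seed = seed),
                                                        list(...)))
  # center on the middle node of the 10x10 sampling grid so the grid
  # includes a distance-zero (Top) measurement
  n <- round(params$frame_size_xy / params$pixel_pitch)
  mid <- grid_indices(n)[5L] * params$pixel_pitch
  geometry <- drusen_geometry(c(mid, mid), params$bulge_diameter,
                              condition_label = name)
  list(params = params, geometry = geometry)
}

# dome surface height above the flat gel surface at radius r (um)
bulge_height <- function(r, diameter, apex, profile) {
  a <- diameter / 2
  if (profile == "spherical_cap") {
    R <- (a^2 + apex^2) / (2 * apex)
    h <- ifelse(r < a, sqrt(pmax(R^2 - r^2, 0)) - (R - apex), 0)
    pmax(h, 0)
  } else {
    # Gaussian dome with sd = a/2, truncated at 1% of apex
    h <- apex * exp(-r^2 / (2 * (a / 2)^2))
    ifelse(h > 0.01 * apex, h, 0)
  }
}

#' Generate a monolayer thickness phantom stack
#'
#' Renders the two-band F-actin phantom described by `params` over the dome
#' of `geometry`, and returns the exact analytic thickness map as ground
#' truth. The ground truth is the membrane-to-membrane thickness
#' `t(x, y) = baseline_thickness * modifier(region(x, y))`; no pipeline stage
#' may read it.
#'
#' @param params A [monolayer_params()].
#' @param geometry A [drusen_geometry()]; its illumination diameter is used
#'   to build the region spec for the thickness modifiers.
#' @param spec Optional [region_spec()]; defaults to
#'   `make_region_spec(geometry$illumination_diameter)`.
#' @return List: `stack` ([image_stack()]), `truth` (list with matrices
#'   `thickness`, `surface_z`, `region` and the generation parameters).
#' @export
generate_monolayer_stack <- function(params, geometry, spec = NULL) {
  stopifnot(inherits(params, "monolayer_params"),
            inherits(geometry, "drusen_geometry"))
  if (is.null(spec)) spec <- make_region_spec(geometry$illumination_diameter)
  n <- round(params$frame_size_xy / params$pixel_pitch)
  xy <- (seq_len(n) - 1) * params$pixel_pitch
  dx <- outer(rep(1, n), xy - geometry$center_xy[1])       # [y, x]
  dy <- outer(xy - geometry$center_xy[2], rep(1, n))
  r <- sqrt(dx^2 + dy^2)
  region <- matrix(assign_region_dist(as.vector(r), spec), n, n)
  mod <- matrix(1, n, n)
  for (nm in names(params$thickness_modifiers)) {
    mod[region == nm] <- params$thickness_modifiers[[nm]]
  }
  thick <- params$baseline_thickness * mod
  zs <- params$substrate_z +
    bulge_height(r, params$bulge_diameter, params$bulge_apex_height,
                 params$bulge_profile)
  w <- params$band_width
  top_extent <- max(zs + thick) + params$band_inset + 4 * w
  if (top_extent > params$z_depth) {
    stop_invalid(sprintf(
      "apex not representable: monolayer top reaches %.1f um but stack depth is %.1f um",
      top_extent, params$z_depth))
  }
  nz <- floor(params$z_depth / params$z_step) + 1L
  zg <- (seq_len(nz) - 1) * params$z_step
  zb <- zs + params$band_inset             # basal band center
  za <- zs + thick - params$band_inset     # apical band center
  vox <- array(0, dim = c(n, n, nz))
  for (k in seq_len(nz)) {
    z <- zg[k]
    vox[, , k] <- exp(-(z - zb)^2 / (2 * w^2)) + exp(-(z - za)^2 / (2 * w^2)) +
      params$cytoplasm_level * (z > zb & z < za)
  }
  vox <- with_seed(params$seed, {
    if (params$poisson_noise) {
      vox <- array(stats::rpois(length(vox), vox * params$poisson_scale),
                   dim = dim(vox)) / params$poisson_scale
    }
    if (params$noise_sd > 0) {
      vox <- vox + array(stats::rnorm(length(vox), sd = params$noise_sd),
                         dim = dim(vox))
    }
    pmax(vox, 0)
  })
  list(
    stack = image_stack(vox, pixel_pitch = params$pixel_pitch,
                        z_step = params$z_step, channel = "factin"),
    truth = list(thickness = thick, surface_z = zs, region = region,
                 params = params, geometry = geometry, spec = spec)
  )
}
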