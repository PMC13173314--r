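# Shared fixtures, all generated in code.

# binary digital disc mask of radius r px inside an n x n frame
disc_mask <- function(n, r, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    j <- which((i - cy)^2 + (seq_len(n) - cx)^2 <= r^2)
    m[i, j] <- 1L
  }
  m
}

# square cell mask: side s px starting at (r0, c0)
square_mask <- function(n, s, r0, c0) {
  m <- matrix(0L, n, n)
  m[r0:(r0 + s - 1), c0:(c0 + s - 1)] <- 1L
  m
}

# literal, index-by-index implementation of the mean-threshold boundary
# rule; independent oracle for profile_height()
profile_height_oracle <- function(profile, z_step) {
  thr <- mean(profile)
  basal <- NA
  for (k in seq_along(profile)) {
    if (profile[k] > thr) { basal <- k; break }
  }
  apical <- NA
  for (k in rev(seq_along(profile))) {
    if (profile[k] > thr) { apical <- k; break }
  }
  if (is.na(basal) || is.na(apical) || apical <= basal) return(NULL)
  c(basal = (basal - 1) * z_step, apical = (apical - 1) * z_step)
}

# small fast monolayer phantom for unit tests (no drusen regions needed)
flat_phantom <- function(thickness = 12, noise = FALSE, seed = 1,
                         z_step = 0.5) {
  params <- monolayer_params(
    frame_size_xy = 60, pixel_pitch = 2, z_step = z_step, z_depth = 30,
    bulge_diameter = 100, bulge_apex_height = 1e-6,
    baseline_thickness = thickness,
    noise_sd = if (noise) 0.01 else 0, poisson_noise = noise, seed = seed)
  # center on a sampling-grid node so a distance-zero measurement exists
  geometry <- drusen_geometry(c(26, 26), 100)
  generate_monolayer_stack(params, geometry)
}

circular_shift_cols <- function(m, dx) {
  m[, c((ncol(m) - dx + 1):ncol(m), 1:(ncol(m) - dx))]
}
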