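#' Smooth synthetic traction field with zero net force
#'
#' Builds a ground-truth traction field from paired Gaussian blobs of
#' opposite direction, so the net force over the periodic domain vanishes
#' (as required for a physical traction pattern). Useful as the forward
#' phantom for PIV/FTTC validation.
#'
#' @param n Grid size (n x n).
#' @param spacing Grid spacing, um.
#' @param magnitude Peak traction, Pa.
#' @param sigma Blob sd, um.
#' @param n_pairs Number of opposing blob pairs.
#' @param seed Integer seed.
#' @return List with `tx`, `ty` matrices (Pa) and `spacing`.
#' @export
synthetic_traction_field <- function(n = 64, spacing = 4, magnitude = 100,
                                     sigma = 20, n_pairs = 2, seed = 1L) {
  ax <- (seq_len(n) - 1) * spacing
  X <- outer(rep(1, n), ax)
  Y <- outer(ax, rep(1, n))
  L <- n * spacing
  tx <- matrix(0, n, n); ty <- matrix(0, n, n)
  with_seed(seed, {
    for (p in seq_len(n_pairs)) {
      cx <- stats::runif(1, 0.25 * L, 0.75 * L)
      cy <- stats::runif(1, 0.25 * L, 0.75 * L)
      th <- stats::runif(1, 0, 2 * pi)
      off <- stats::runif(1, 1.5, 2.5) * sigma
      for (s in c(-1, 1)) {
        bx <- cx + s * off * cos(th)
        by <- cy + s * off * sin(th)
        g <- magnitude * exp(-((X - bx)^2 + (Y - by)^2) / (2 * sigma^2))
        tx <- tx + s * g * cos(th)
        ty <- ty + s * g * sin(th)
      }
    }
  })
  list(tx = tx, ty = ty, spacing = spacing)
}

#' Traction field confined to one radial annulus
#'
#' Inward-pointing radial traction restricted to `[inner, outer)` um from
#' the center, tapered by a Gaussian edge. Net force is zero by symmetry.
#'
#' @param n,spacing Grid geometry.
#' @param center_xy Center, um (default frame center).
#' @param inner,outer Annulus bounds, um.
#' @param magnitude Peak traction, Pa.
#' @return List with `tx`, `ty`, `spacing`.
#' @export
annulus_traction_field <- function(n = 96, spacing = 4, center_xy = NULL,
                                   inner = 25, outer = 50, magnitude = 100) {
  ax <- (seq_len(n) - 1) * spacing
  if (is.null(center_xy)) center_xy <- rep((n - 1) * spacing / 2, 2)
  X <- outer(rep(1, n), ax) - center_xy[1]
  Y <- outer(ax, rep(1, n)) - center_xy[2]
  r <- sqrt(X^2 + Y^2)
  mid <- (inner + outer) / 2
  amp <- magnitude * exp(-(r - mid)^2 / (2 * ((outer - inner) / 4)^2))
  amp[r < 1e-9] <- 0
  rr <- pmax(r, 1e-9)
  list(tx = -amp * X / rr, ty = -amp * Y / rr, spacing = spacing)
}

#' Generate a reference/deformed bead image pair
#'
#' Renders random sub-pixel bead point sources with a Gaussian PSF, then
#' renders the same beads displaced by the forward Boussinesq surface
#' displacement of the supplied traction field (evaluated on the pixel grid
#' and bilinearly interpolated at each bead). The ground-truth displacement
#' field is returned alongside; no pipeline stage may read it.
#'
#' @param traction List with `tx`, `ty` (Pa) and `spacing` (um), e.g. from
#'   [synthetic_traction_field()]. The image covers the same physical
#'   domain at `pixel_pitch` resolution.
#' @param E,nu Substrate elastic parameters (Pa / unitless).
#' @param pixel_pitch um/px of the rendered images.
#' @param bead_density Beads per um^2 (default 0.05, a typical projected
#'   density for 0.1 um marker beads).
#' @param psf_sigma PSF sd in px.
#' @param noise_sd Additive Gaussian image noise sd (peak bead ~ 1).
#' @param seed Integer seed.
#' @return List: `reference`, `deformed` (matrices), `truth` (list with
#'   pixel-grid `ux`, `uy` in um and the bead table).
#' @export
generate_bead_pair <- function(traction, E = 4000, nu = 0.5,
                               pixel_pitch = 1, bead_density = 0.05,
                               psf_sigma = 1.5, noise_sd = 0.005,
                               seed = 1L) {
  L <- nrow(traction$tx) * traction$spacing
  n <- round(L / pixel_pitch)
  # displacement on the traction grid, then bilinear to bead positions
  disp <- forward_displacement(traction$tx, traction$ty, traction$spacing,
                               E = E, nu = nu)
  gx <- (seq_len(ncol(traction$tx)) - 1) * traction$spacing
  gy <- (seq_len(nrow(traction$tx)) - 1) * traction$spacing
  with_seed(seed, {
    n_beads <- stats::rpois(1, bead_density * L^2)
    bx <- stats::runif(n_beads, 0, L)
    by <- stats::runif(n_beads, 0, L)
    amp <- stats::runif(n_beads, 0.6, 1)
    ux <- bilinear(gx, gy, disp$ux, bx, by)
    uy <- bilinear(gx, gy, disp$uy, bx, by)
    ref <- render_beads(bx, by, amp, n, pixel_pitch, psf_sigma)
    def <- render_beads(bx + ux, by + uy, amp, n, pixel_pitch, psf_sigma)
    if (noise_sd > 0) {
      ref <- ref + matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
      def <- def + matrix(stats::rnorm(n * n, sd = noise_sd), n, n)
    }
    list(reference = ref, deformed = def,
         truth = list(ux = disp$ux, uy = disp$uy, grid_x = gx, grid_y = gy,
                      beads = data.frame(x = bx, y = by, ux = ux, uy = uy)))
  })
}

# Gaussian splat rendering at sub-pixel positions (positions in um).
render_beads <- function(bx, by, amp, n, pitch, sigma_px) {
  img <- matrix(0, n, n)
  half <- ceiling(4 * sigma_px)
  px <- bx / pitch   # 0-based pixel coords
  py <- by / pitch
  for (k in seq_along(bx)) {
    c0 <- floor(px[k]) - half; c1 <- floor(px[k]) + half
    r0 <- floor(py[k]) - half; r1 <- floor(py[k]) + half
    cs <- max(0, c0):min(n - 1, c1)
    rs <- max(0, r0):min(n - 1, r1)
    if (!length(cs) || !length(rs)) next
    gx <- exp(-(cs - px[k])^2 / (2 * sigma_px^2))
    gy <- exp(-(rs - py[k])^2 / (2 * sigma_px^2))
    img[rs + 1, cs + 1] <- img[rs + 1, cs + 1] + amp[k] * outer(gy, gx)
  }
  img
}

bilinear <- function(gx, gy, z, qx, qy) {
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  fx <- (qx - gx[1]) / dx
  fy <- (qy - gy[1]) / dy
  i0 <- pmin(pmax(floor(fx), 0), length(gx) - 2)
  j0 <- pmin(pmax(floor(fy), 0), length(gy) - 2)
  wx <- pmin(pmax(fx - i0, 0), 1)
  wy <- pmin(pmax(fy - j0, 0), 1)
  z00 <- z[cbind(j0 + 1, i0 + 1)]
  z01 <- z[cbind(j0 + 1, i0 + 2)]
  z10 <- z[cbind(j0 + 2, i0 + 1)]
  z11 <- z[cbind(j0 + 2, i0 + 2)]
  (1 - wy) * ((1 - wx) * z00 + wx * z01) + wy * ((1 - wx) * z10 + wx * z11)
}
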