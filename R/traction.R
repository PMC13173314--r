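# Boussinesq half-space kernel in Fourier space (flat-substrate traction
# cytometry). For wavevector k = (kx, ky), |k| = k, Poisson ratio nu and
# Young's modulus E (Pa), surface displacement and traction relate as
# u_hat = G(k) T_hat with the symmetric 2x2 kernel
#   G = 2 (1 + nu) / (E k^3) * [ (1-nu) k^2 + nu ky^2,  -nu kx ky
#                                -nu kx ky,  (1-nu) k^2 + nu kx^2 ].
# Lengths in um, tractions in Pa, displacements in um.
tfm_kernel <- function(ny, nx, spacing, E, nu) {
  fft_freq <- function(n, d) {
    f <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / (n * d)
    2 * pi * f
  }
  kx <- fft_freq(nx, spacing)
  ky <- fft_freq(ny, spacing)
  KX <- outer(rep(1, ny), kx)
  KY <- outer(ky, rep(1, nx))
  K <- sqrt(KX^2 + KY^2)
  K[1, 1] <- Inf                       # k = 0 handled as zero-mean mode
  pref <- 2 * (1 + nu) / (E * K^3)
  list(a = pref * ((1 - nu) * K^2 + nu * KY^2),
       b = pref * (-nu * KX * KY),
       c = pref * ((1 - nu) * K^2 + nu * KX^2))
}

#' Forward Boussinesq surface displacement of a traction field
#'
#' Evaluates the displacement field produced on the surface of an elastic
#' half-space by an in-plane traction field, via the Fourier-space
#' Boussinesq kernel (periodic boundary; the zero-frequency mode is set to
#' zero, i.e. displacements are reported about their mean). This is the
#' same kernel the FTTC inversion uses, run forward; the synthetic bead
#' generator uses it to displace beads by a known ground-truth field.
#'
#' @param tx,ty Traction components in Pa, matrices `[y, x]` on a regular
#'   grid.
#' @param spacing Grid spacing, um.
#' @param E Substrate Young's modulus, Pa.
#' @param nu Poisson ratio (default 0.5, incompressible).
#' @return List of matrices `ux`, `uy` (um).
#' @export
forward_displacement <- function(tx, ty, spacing, E, nu = 0.5) {
  stopifnot(is.matrix(tx), all(dim(tx) == dim(ty)))
  check_positive(spacing, "spacing")
  check_positive(E, "E")
  g <- tfm_kernel(nrow(tx), ncol(tx), spacing, E, nu)
  TX <- fft(tx); TY <- fft(ty)
  UX <- g$a * TX + g$b * TY
  UY <- g$b * TX + g$c * TY
  UX[1, 1] <- 0; UY[1, 1] <- 0
  n <- length(tx)
  list(ux = Re(fft(UX, inverse = TRUE)) / n,
       uy = Re(fft(UY, inverse = TRUE)) / n)
}

#' Displacement field container
#'
#' @param x,y Grid coordinate vectors, um.
#' @param ux,uy Displacement matrices `[y, x]`, um.
#' @param quality Optional per-vector correlation peak-ratio matrix.
#' @param flagged Optional logical matrix of low-quality/replaced vectors.
#' @param window_px,overlap PIV provenance metadata.
#' @return A `displacement_field`.
#' @export
displacement_field <- function(x, y, ux, uy, quality = NULL, flagged = NULL,
                               window_px = NA, overlap = NA) {
  stopifnot(is.matrix(ux), all(dim(ux) == dim(uy)),
            length(x) == ncol(ux), length(y) == nrow(ux))
  if (any(!is.finite(ux)) || any(!is.finite(uy))) {
    stop_invalid("displacement vectors must be finite")
  }
  structure(list(x = x, y = y, ux = ux, uy = uy, quality = quality,
                 flagged = flagged, window_px = window_px, overlap = overlap),
            class = "displacement_field")
}

#' PIV bead displacement by windowed cross-correlation
#'
#' Splits the images into interrogation windows, computes the normalized
#' cross-correlation of each reference/deformed window pair (FFT-based),
#' locates the correlation peak within `max_shift` and refines it to
#' sub-pixel precision by 3-point parabolic interpolation in each axis.
#' Vectors whose peak ratio (highest peak over second-highest outside its
#' 3 px neighbourhood) falls below `min_peak_ratio`, and featureless
#' windows, are replaced by the median of their 3x3 vector neighbourhood
#' and flagged.
#'
#' @param reference,deformed Numeric matrices (bead images).
#' @param pixel_pitch um/px.
#' @param window Interrogation window size, px (default 32).
#' @param overlap Window overlap fraction (default 0.5).
#' @param max_shift Largest recoverable displacement, px.
#' @param min_peak_ratio Quality threshold (default 1.3).
#' @return A [displacement_field()] in um.
#' @export
piv_displacement <- function(reference, deformed, pixel_pitch = 1,
                             window = 32L, overlap = 0.5, max_shift = 8L,
                             min_peak_ratio = 1.3) {
  stopifnot(is.matrix(reference), all(dim(reference) == dim(deformed)))
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  ny <- nrow(reference); nx <- ncol(reference)
  ys <- seq(1L, ny - window + 1L, by = step)
  xs <- seq(1L, nx - window + 1L, by = step)
  if (!length(ys) || !length(xs)) stop_invalid("window larger than image")
  U <- matrix(0, length(ys), length(xs))
  V <- matrix(0, length(ys), length(xs))
  Q <- matrix(Inf, length(ys), length(xs))
  flag <- matrix(FALSE, length(ys), length(xs))
  ny_img <- nrow(reference); nx_img <- ncol(reference)
  sft <- c(0:(window %/% 2 - 1L), -(window %/% 2):-1L)  # fft shift order
  excl <- 5L
  corr_plane <- function(a, b) {
    a <- (a - mean(a)) / stats::sd(a)
    b <- (b - mean(b)) / stats::sd(b)
    Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE)) / length(a)^2
  }
  peak_sub <- function(cs, pk, pv) {
    # 3-point Gaussian (log-parabola) fit, falling back to a parabola
    vapply(1:2, function(dim_i) {
      get <- function(off) {
        id <- pk
        id[dim_i] <- id[dim_i] + off
        if (id[dim_i] < 1L || id[dim_i] > dim(cs)[dim_i]) return(NA_real_)
        cs[id[1], id[2]]
      }
      y0 <- get(-1L); y2 <- get(1L)
      if (is.na(y0) || is.na(y2)) return(0)
      if (y0 > 0 && pv > 0 && y2 > 0) {
        l0 <- log(y0); l1 <- log(pv); l2 <- log(y2)
        den <- l0 - 2 * l1 + l2
        if (den < 0) return(0.5 * (l0 - l2) / den)
      }
      den <- y0 - 2 * pv + y2
      if (den >= 0) 0 else 0.5 * (y0 - y2) / den
    }, numeric(1))
  }
  for (i in seq_along(ys)) {
    for (j in seq_along(xs)) {
      a <- reference[ys[i]:(ys[i] + window - 1L), xs[j]:(xs[j] + window - 1L)]
      b <- deformed[ys[i]:(ys[i] + window - 1L), xs[j]:(xs[j] + window - 1L)]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        flag[i, j] <- TRUE
        Q[i, j] <- 0
        next
      }
      # pass 1: integer displacement from circular correlation
      # (indices reordered so shifts run -max_shift..max_shift)
      cc <- corr_plane(a, b)
      sel <- match(seq(-max_shift, max_shift), sft)
      cs <- cc[sel, sel, drop = FALSE]
      pk <- arrayInd(which.max(cs), dim(cs))
      dy0 <- pk[1] - max_shift - 1L
      dx0 <- pk[2] - max_shift - 1L
      # quality: peak ratio over the search region, excluding the peak lobe
      mask <- cs
      r0 <- max(1, pk[1] - excl); r1 <- min(nrow(cs), pk[1] + excl)
      c0 <- max(1, pk[2] - excl); c1 <- min(ncol(cs), pk[2] + excl)
      mask[r0:r1, c0:c1] <- -Inf
      second <- max(mask)
      pv <- cs[pk[1], pk[2]]
      Q[i, j] <- if (is.finite(second) && second > 1e-12) pv / second else Inf
      if (Q[i, j] < min_peak_ratio) flag[i, j] <- TRUE
      # pass 2: iteratively re-cut the deformed window at the integer
      # offset until the residual integer shift is zero; at zero residual
      # the correlation peak is symmetric and window-truncation / loss-of-
      # pairs biases vanish. The final sub-pixel fit uses zero-padded
      # linear correlation normalized by the window overlap.
      oy <- dy0; ox <- dx0
      for (it in 1:3) {
        oy <- min(max(ys[i] + oy, 1L), ny_img - window + 1L) - ys[i]
        ox <- min(max(xs[j] + ox, 1L), nx_img - window + 1L) - xs[j]
        b2 <- deformed[(ys[i] + oy):(ys[i] + oy + window - 1L),
                       (xs[j] + ox):(xs[j] + ox + window - 1L)]
        if (stats::sd(b2) == 0) break
        rad <- min(2L + max(abs(dy0 - oy), abs(dx0 - ox)), window %/% 2 - 1L)
        cc2 <- corr_plane(a, b2)
        sel2 <- match(-rad:rad, sft)
        cs2 <- cc2[sel2, sel2, drop = FALSE]
        pk2 <- arrayInd(which.max(cs2), dim(cs2))
        ry <- pk2[1] - rad - 1L
        rx <- pk2[2] - rad - 1L
        if (ry == 0L && rx == 0L) break
        oy <- oy + ry
        ox <- ox + rx
      }
      oy <- min(max(ys[i] + oy, 1L), ny_img - window + 1L) - ys[i]
      ox <- min(max(xs[j] + ox, 1L), nx_img - window + 1L) - xs[j]
      b2 <- deformed[(ys[i] + oy):(ys[i] + oy + window - 1L),
                     (xs[j] + ox):(xs[j] + ox + window - 1L)]
      if (stats::sd(b2) > 0) {
        a_n <- (a - mean(a)) / stats::sd(a)
        b_n <- (b2 - mean(b2)) / stats::sd(b2)
        n2 <- 2L * window
        A <- matrix(0, n2, n2); B <- matrix(0, n2, n2)
        A[1:window, 1:window] <- a_n
        B[1:window, 1:window] <- b_n
        ccl <- Re(fft(Conj(fft(A)) * fft(B), inverse = TRUE)) / length(A)
        sft2 <- c(0:(n2 %/% 2 - 1L), -(n2 %/% 2):-1L)
        # search radius covers any residual the border clamp left unapplied
        radf <- min(1L + max(1L, abs(dy0 - oy), abs(dx0 - ox)),
                    window %/% 4)
        sel3 <- match(-radf:radf, sft2)
        ovl <- outer(window - abs(-radf:radf), window - abs(-radf:radf))
        cs3 <- ccl[sel3, sel3, drop = FALSE] / ovl
        pk9 <- arrayInd(which.max(cs3), dim(cs3))
        sp <- pmin(pmax(peak_sub(cs3, pk9, cs3[pk9[1], pk9[2]]), -1), 1)
        V[i, j] <- oy + (pk9[1] - radf - 1L) + sp[1]
        U[i, j] <- ox + (pk9[2] - radf - 1L) + sp[2]
      } else {
        sp <- peak_sub(cs, pk, pv)
        V[i, j] <- dy0 + sp[1]
        U[i, j] <- dx0 + sp[2]
      }
    }
  }
  # replace flagged vectors by local median
  if (any(flag)) {
    U2 <- U; V2 <- V
    for (k in which(flag)) {
      ij <- arrayInd(k, dim(flag))
      r <- max(1, ij[1] - 1):min(nrow(flag), ij[1] + 1)
      cc2 <- max(1, ij[2] - 1):min(ncol(flag), ij[2] + 1)
      nb <- !flag[r, cc2]
      if (any(nb)) {
        U2[k] <- stats::median(U[r, cc2][nb])
        V2[k] <- stats::median(V[r, cc2][nb])
      } else {
        U2[k] <- 0; V2[k] <- 0
      }
    }
    U <- U2; V <- V2
  }
  ctr <- (window - 1) / 2
  displacement_field(
    x = (xs - 1 + ctr) * pixel_pitch, y = (ys - 1 + ctr) * pixel_pitch,
    ux = U * pixel_pitch, uy = V * pixel_pitch,
    quality = Q, flagged = flag, window_px = window, overlap = overlap
  )
}

#' Traction reconstruction by regularized FTTC
#'
#' Inverts the Boussinesq relation in Fourier space with zeroth-order
#' Tikhonov regularization: per wavevector,
#' `T_hat = (G^2 + lambda^2 I)^-1 G u_hat` (G is symmetric). The
#' displacement field is taken to zero mean (the k = 0 mode carries no
#' traction information on a periodic domain).
#'
#' @param field A [displacement_field()] on a regular grid.
#' @param E Substrate Young's modulus, Pa (default 4000, the hydrogel
#'   characterization value).
#' @param nu Poisson ratio (default 0.5).
#' @param lambda Tikhonov parameter in the kernel's displacement/traction
#'   units (um/Pa); 0 = unregularized inversion.
#' @return A `traction_field`: list with `x`, `y`, `tx`, `ty`, `magnitude`
#'   (Pa), and the elastic parameters.
#' @export
fttc_traction <- function(field, E = 4000, nu = 0.5, lambda = 0) {
  stopifnot(inherits(field, "displacement_field"))
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  sp <- unique(c(diff(field$x), diff(field$y)))
  if (max(sp) - min(sp) > 1e-6) stop_invalid("displacement grid must be regular")
  spacing <- mean(sp)
  g <- tfm_kernel(nrow(field$ux), ncol(field$ux), spacing, E, nu)
  UX <- fft(field$ux - mean(field$ux))
  UY <- fft(field$uy - mean(field$uy))
  # solve (G^2 + l^2 I) T = G u per wavevector, G = [[a,b],[b,c]]
  a <- g$a; b <- g$b; cc <- g$c
  m11 <- a * a + b * b + lambda^2
  m12 <- b * (a + cc)
  m22 <- cc * cc + b * b + lambda^2
  det <- m11 * m22 - m12^2
  r1 <- a * UX + b * UY                 # G u
  r2 <- b * UX + cc * UY
  TX <- (m22 * r1 - m12 * r2) / det
  TY <- (-m12 * r1 + m11 * r2) / det
  TX[1, 1] <- 0; TY[1, 1] <- 0
  n <- length(UX)
  tx <- Re(fft(TX, inverse = TRUE)) / n
  ty <- Re(fft(TY, inverse = TRUE)) / n
  structure(list(x = field$x, y = field$y, tx = tx, ty = ty,
                 magnitude = sqrt(tx^2 + ty^2), E = E, nu = nu,
                 lambda = lambda),
            class = "traction_field")
}

#' Choose the FTTC regularization parameter by the L-curve criterion
#'
#' Scans a logarithmic lambda grid, computing for each the residual norm
#' `||G T - u||` and solution norm `||T||`, and returns the lambda of
#' maximum curvature of the (log-residual, log-solution) curve -- the
#' L-curve corner.
#'
#' @param field A [displacement_field()].
#' @param E,nu Substrate elastic parameters.
#' @param lambdas Candidate grid (default `10^seq(-6, -1, length.out = 25)`).
#' @return List with `lambda` (the corner value) and the scan table.
#' @export
choose_lambda <- function(field, E = 4000, nu = 0.5,
                          lambdas = 10^seq(-6, -1, length.out = 25)) {
  stopifnot(inherits(field, "displacement_field"))
  rho <- eta <- numeric(length(lambdas))
  for (k in seq_along(lambdas)) {
    tr <- fttc_traction(field, E, nu, lambdas[k])
    fwd <- forward_displacement(tr$tx, tr$ty, mean(diff(field$x)), E, nu)
    rho[k] <- sqrt(mean((fwd$ux - (field$ux - mean(field$ux)))^2 +
                        (fwd$uy - (field$uy - mean(field$uy)))^2))
    eta[k] <- sqrt(mean(tr$tx^2 + tr$ty^2))
  }
  lr <- log(rho); le <- log(eta)
  # discrete curvature of the parametric curve (lr, le)
  t1 <- diff(lr); t2 <- diff(le)
  d1r <- (t1[-1] + t1[-length(t1)]) / 2
  d1e <- (t2[-1] + t2[-length(t2)]) / 2
  d2r <- diff(t1); d2e <- diff(t2)
  kappa <- (d1r * d2e - d1e * d2r) / (d1r^2 + d1e^2)^1.5
  best <- which.max(kappa) + 1L
  list(lambda = lambdas[best],
       scan = data.frame(lambda = lambdas, residual = rho, solution = eta))
}

#' Region-wise traction summary
#'
#' Pools traction magnitudes by the region of each grid position and
#' reports per-region mean and median plus the delta of the mean relative
#' to the Outside region. Regions with no grid points are flagged.
#'
#' @param traction A `traction_field` (from [fttc_traction()]) or any list
#'   with `x`, `y`, `magnitude`.
#' @param geometry A [drusen_geometry()].
#' @param spec A [region_spec()]; defaults to the geometry's diameter rule.
#' @return Data frame: `region, n, mean_Pa, median_Pa, delta_mean_Pa,
#'   no_data`.
#' @export
region_traction_summary <- function(traction, geometry, spec = NULL) {
  stopifnot(inherits(geometry, "drusen_geometry"))
  if (is.null(spec)) spec <- make_region_spec(geometry$illumination_diameter)
  X <- outer(rep(1, length(traction$y)), traction$x)
  Y <- outer(traction$y, rep(1, length(traction$x)))
  d <- sqrt((X - geometry$center_xy[1])^2 + (Y - geometry$center_xy[2])^2)
  reg <- assign_region_dist(as.vector(d), spec)
  mag <- as.vector(traction$magnitude)
  out <- do.call(rbind, lapply(spec$name, function(r) {
    x <- mag[reg == r]
    data.frame(region = r, n = length(x),
               mean_Pa = if (length(x)) mean(x) else NA_real_,
               median_Pa = if (length(x)) stats::median(x) else NA_real_,
               no_data = length(x) == 0L, stringsAsFactors = FALSE)
  }))
  mu_out <- out$mean_Pa[out$region == "Outside"]
  out$delta_mean_Pa <- if (length(mu_out) == 1L && is.finite(mu_out)) {
    out$mean_Pa - mu_out
  } else NA_real_
  out
}
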