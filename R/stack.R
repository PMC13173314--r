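#' Confocal-like image stack
#'
#' Container for a 3D intensity grid with physical calibration. Voxels are
#' stored as a numeric array indexed `[y, x, z]`; physical coordinates follow
#' the pixel-center convention: pixel/plane index `i` (0-based) sits at
#' `i * pitch` micrometers, plus `z_origin` for the axial axis.
#'
#' @param voxels 3D numeric array `[y, x, z]`.
#' @param pixel_pitch Lateral sampling in um/px.
#' @param z_step Axial sampling in um/plane.
#' @param channel Channel tag (e.g. `"factin"`, `"beads"`, `"brightfield"`).
#' @param z_origin Physical z of plane 0 in um (default 0).
#' @return An `image_stack`.
#' @export
image_stack <- function(voxels, pixel_pitch, z_step, channel = "factin",
                        z_origin = 0) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop_invalid("`voxels` must be a 3D array [y, x, z]")
  }
  check_positive(pixel_pitch, "pixel_pitch")
  check_positive(z_step, "z_step")
  if (dim(voxels)[3] < 2L) stop_invalid("a stack needs at least 2 z-planes")
  structure(
    list(voxels = voxels, pixel_pitch = pixel_pitch, z_step = z_step,
         channel = as.character(channel), z_origin = as.numeric(z_origin)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<image_stack> %d x %d px, %d planes | pitch %g um/px, z-step %g um | channel '%s'\n",
    d[2], d[1], d[3], x$pixel_pitch, x$z_step, x$channel))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Labelled segmentation mask
#'
#' 2D integer mask where 0 is background and each positive integer labels one
#' cell, with its physical pixel pitch.
#'
#' @param labels Integer matrix `[y, x]`, 0 = background.
#' @param pixel_pitch um/px.
#' @return A `label_mask`.
#' @export
label_mask <- function(labels, pixel_pitch) {
  if (!is.matrix(labels)) stop_invalid("`labels` must be a matrix")
  check_positive(pixel_pitch, "pixel_pitch")
  if (any(labels < 0)) stop_invalid("labels must be >= 0")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_pitch = pixel_pitch),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px, %d cells, pitch %g um/px\n",
              ncol(x$labels), nrow(x$labels),
              length(setdiff(unique(as.vector(x$labels)), 0L)), x$pixel_pitch))
  invisible(x)
}

#' Maximum-intensity projection of a stack
#'
#' @param stack An [image_stack()].
#' @return Numeric matrix `[y, x]`.
#' @export
max_projection <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  apply(stack$voxels, c(1, 2), max)
}

#' Rigid integer-pixel alignment of two images
#'
#' Estimates the integer (dx, dy) translation maximizing the cross-correlation
#' of `moving` against `reference` (FFT-based, periodic), and returns the
#' shifted image. Used to register reference/deformed bead projections before
#' PIV, mirroring template-matching alignment.
#'
#' @param reference,moving Numeric matrices of identical size.
#' @param max_shift Largest allowed shift in px.
#' @return List with `aligned` (shifted `moving`), `shift` = c(dx, dy) in px.
#' @export
align_rigid <- function(reference, moving, max_shift = 20L) {
  stopifnot(is.matrix(reference), is.matrix(moving),
            all(dim(reference) == dim(moving)))
  a <- reference - mean(reference)
  b <- moving - mean(moving)
  cc <- Re(fft(fft(a) * Conj(fft(b)), inverse = TRUE))
  ny <- nrow(cc); nx <- ncol(cc)
  # wrap to signed shifts, restrict search window
  sy <- c(0:(ny %/% 2), -((ny - 1) %/% 2):-1)
  sx <- c(0:(nx %/% 2), -((nx - 1) %/% 2):-1)
  ok_y <- abs(sy) <= max_shift
  ok_x <- abs(sx) <= max_shift
  sub <- cc[ok_y, ok_x, drop = FALSE]
  k <- arrayInd(which.max(sub), dim(sub))
  dy <- sy[ok_y][k[1]]
  dx <- sx[ok_x][k[2]]
  list(aligned = shift_matrix(moving, dx, dy), shift = c(dx = dx, dy = dy))
}

# Integer shift with zero fill: output[y, x] = input[y - dy, x - dx].
shift_matrix <- function(m, dx, dy) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(0, ny, nx)
  ys <- seq_len(ny) - dy
  xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny
  okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}
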