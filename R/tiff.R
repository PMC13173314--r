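# Minimal TIFF I/O: uncompressed, little-endian, 16-bit grayscale,
# one strip per page. Calibration travels in an ImageDescription JSON
# ({pixel_pitch, z_step, z_origin, channel, intensity_scale}) so a stack
# round-trips with its physical metadata. This is deliberately a small
# subset of TIFF; anything fancier (compression, tiles, RGB) is rejected.

TIFF_TYPE_SIZES <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' Write an image stack or label mask as multi-page TIFF
#'
#' Stores intensities as 16-bit unsigned samples (floats are scaled by
#' `65535 / max` and the factor recorded in the ImageDescription metadata so
#' [read_stack_tiff()] restores the original values to ~1e-4 relative
#' precision). Label masks are written losslessly as their integer values.
#'
#' @param x An [image_stack()] or [label_mask()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(x, path) {
  if (inherits(x, "label_mask")) {
    pages <- list(x$labels)
    meta <- list(kind = "label_mask", pixel_pitch = x$pixel_pitch,
                 intensity_scale = 1)
    if (max(x$labels) > 65535L) stop_invalid("label ids exceed 16-bit range")
    scale <- 1
  } else if (inherits(x, "image_stack")) {
    v <- x$voxels
    mx <- max(v)
    if (min(v) < 0) stop_invalid("negative intensities cannot be TIFF-encoded")
    scale <- if (mx > 0) 65535 / mx else 1
    pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k] * scale)
    meta <- list(kind = "image_stack", pixel_pitch = x$pixel_pitch,
                 z_step = x$z_step, z_origin = x$z_origin,
                 channel = x$channel, intensity_scale = scale)
  } else {
    stop_invalid("`x` must be an image_stack or label_mask")
  }
  desc <- as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(v, size) writeBin(as.integer(v), con, size = size,
                                  endian = "little")
  writeChar("II", con, eos = NULL)
  w(42L, 2)
  w(8L, 4)                                   # first IFD offset
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  desc_raw <- c(charToRaw(desc), as.raw(0L))
  n_pages <- length(pages)
  pos <- 8L
  for (k in seq_len(n_pages)) {
    tags <- list(                            # tag, type, count, value
      c(256L, 3L, 1L, nx), c(257L, 3L, 1L, ny), c(258L, 3L, 1L, 16L),
      c(259L, 3L, 1L, 1L), c(262L, 3L, 1L, 1L),
      c(273L, 4L, 1L, NA), c(277L, 3L, 1L, 1L),
      c(278L, 3L, 1L, ny), c(279L, 4L, 1L, 2L * nx * ny),
      c(339L, 3L, 1L, 1L)
    )
    has_desc <- k == 1L
    if (has_desc) tags <- append(tags, list(c(270L, 2L, length(desc_raw), NA)),
                                 after = 5L)
    n_tag <- length(tags)
    ifd_size <- 2L + n_tag * 12L + 4L
    data_off <- pos + ifd_size
    desc_off <- data_off
    strip_off <- data_off + if (has_desc) length(desc_raw) else 0L
    strip_len <- 2L * nx * ny
    next_ifd <- if (k < n_pages) strip_off + strip_len else 0L
    w(n_tag, 2)
    for (t in tags) {
      w(t[1], 2); w(t[2], 2); w(t[3], 4)
      val <- t[4]
      if (t[1] == 273L) val <- strip_off
      if (t[1] == 270L) val <- desc_off
      nbytes <- TIFF_TYPE_SIZES[t[2]] * t[3]
      if (t[2] == 3L && nbytes <= 4L) {      # SHORT packed into value field
        w(val, 2); w(0L, 2)
      } else {
        w(val, 4)
      }
    }
    w(next_ifd, 4)
    if (has_desc) writeBin(desc_raw, con)
    px <- round(t(pages[[k]]))               # TIFF is row-major
    px <- pmin(pmax(px, 0), 65535)
    # writeBin has no uint16: split into two bytes
    iv <- as.integer(px)
    writeBin(as.raw(rbind(iv %% 256L, iv %/% 256L)), con)
    pos <- strip_off + strip_len
  }
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path File path.
#' @return An [image_stack()] or [label_mask()] depending on the recorded
#'   metadata kind.
#' @export
read_stack_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II") stop_invalid("only little-endian TIFF supported")
  u16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  u32 <- function(off) {
    a <- as.numeric(raw[off + 1:4])
    a[1] + 256 * a[2] + 65536 * a[3] + 16777216 * a[4]
  }
  if (u16(2L) != 42L) stop_invalid("not a TIFF file")
  ifd <- u32(4L)
  pages <- list()
  desc <- NULL
  while (ifd != 0) {
    n_tag <- u16(ifd)
    entries <- list()
    for (i in seq_len(n_tag)) {
      off <- ifd + 2L + (i - 1L) * 12L
      tag <- u16(off); typ <- u16(off + 2L); cnt <- u32(off + 4L)
      val <- if (typ == 3L) u16(off + 8L) else u32(off + 8L)
      entries[[as.character(tag)]] <- list(type = typ, count = cnt, value = val)
    }
    g <- function(tag, default = NULL) {
      e <- entries[[as.character(tag)]]
      if (is.null(e)) default else e$value
    }
    if (!identical(g(259L, 1L), 1L) && g(259L, 1) != 1) {
      stop_invalid("compressed TIFF not supported")
    }
    nx <- g(256L); ny <- g(257L); bits <- g(258L, 16L)
    if (bits != 16L) stop_invalid("only 16-bit TIFF supported")
    soff <- g(273L)
    if (is.null(desc) && !is.null(entries[["270"]])) {
      e <- entries[["270"]]
      dstart <- if (e$count <= 4L) NULL else e$value
      if (!is.null(dstart)) {
        desc <- rawToChar(raw[dstart + seq_len(e$count - 1L)])
      }
    }
    npx <- nx * ny
    bytes <- as.integer(raw[soff + seq_len(2L * npx)])
    lo <- bytes[seq(1L, 2L * npx, by = 2L)]
    hi <- bytes[seq(2L, 2L * npx, by = 2L)]
    pages[[length(pages) + 1L]] <- matrix(lo + 256L * hi, nrow = ny,
                                          byrow = TRUE)
    ifd <- u32(ifd + 2L + n_tag * 12L)
  }
  meta <- if (!is.null(desc)) jsonlite::fromJSON(desc) else
    list(kind = "image_stack", pixel_pitch = 1, z_step = 1, z_origin = 0,
         channel = "unknown", intensity_scale = 1)
  if (identical(meta$kind, "label_mask")) {
    return(label_mask(pages[[1]], pixel_pitch = meta$pixel_pitch))
  }
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] / meta$intensity_scale
  image_stack(arr, pixel_pitch = meta$pixel_pitch, z_step = meta$z_step,
              channel = meta$channel, z_origin = meta$z_origin)
}
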