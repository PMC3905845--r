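#' Calibrated image time-stack
#'
#' The raw substrate of all image analyses: a 3-D numeric array indexed
#' \code{[y, x, t]} with the physical calibration attached. Pixel values are
#' photon counts (confocal photon-counting acquisitions) or arbitrary
#' intensity units (wide-field camera images).
#'
#' @param data numeric array \code{[y, x, t]}, or a matrix (a single frame).
#' @param pixel_size_um pixel edge length in micrometres. Required; there is
#'   no default because a silently assumed calibration corrupts every
#'   downstream physical quantity.
#' @param frame_interval_s time between frames in seconds.
#' @return an object of class \code{image_stack}.
#' @export
image_stack <- function(data, pixel_size_um, frame_interval_s) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (missing(pixel_size_um) || !is.numeric(pixel_size_um) ||
      length(pixel_size_um) != 1 || !is.finite(pixel_size_um) ||
      pixel_size_um <= 0) {
    stop("pixel_size_um calibration is required and must be a positive number")
  }
  if (missing(frame_interval_s) || !is.numeric(frame_interval_s) ||
      length(frame_interval_s) != 1 || !is.finite(frame_interval_s) ||
      frame_interval_s <= 0) {
    stop("frame_interval_s calibration is required and must be a positive number")
  }
  structure(data,
            pixel_size_um = pixel_size_um,
            frame_interval_s = frame_interval_s,
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("image_stack: %d x %d px, %d frame(s), %.4g um/px, %.4g s/frame\n",
              d[1], d[2], d[3],
              attr(x, "pixel_size_um"), attr(x, "frame_interval_s")))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack an \code{image_stack}.
#' @export
n_frames <- function(stack) dim(stack)[3]

#' Extract a single frame as a plain matrix
#' @param stack an \code{image_stack}.
#' @param i frame index (1-based).
#' @export
get_frame <- function(stack, i) {
  stopifnot(i >= 1, i <= dim(stack)[3])
  unclass(stack)[, , i]
}

# ---------------------------------------------------------------------------
# Minimal baseline TIFF I/O.
#
# No TIFF package is available in this toolchain, so the package carries a
# small reader/writer for the subset it needs: little- or big-endian baseline
# TIFF, uncompressed, single-sample grayscale, 8/16/32-bit unsigned integer
# or 32-bit IEEE float, one or more pages. Anything else (RGB, compressed,
# tiled) is rejected with a clear message.
# ---------------------------------------------------------------------------

.tiff_tag <- function(con, endian, id, type, count, value) {
  writeBin(as.integer(id), con, size = 2, endian = endian)
  writeBin(as.integer(type), con, size = 2, endian = endian)
  writeBin(as.integer(count), con, size = 4, endian = endian)
  writeBin(as.integer(value), con, size = 4, endian = endian)
}

#' Write an image stack as a multi-page TIFF
#'
#' Writes uncompressed grayscale TIFF, one page per frame. \code{uint16}
#' (default) rounds and clamps to 0..65535; \code{float32} preserves
#' fractional values.
#'
#' @param stack an \code{image_stack} (or numeric array/matrix).
#' @param path output file path.
#' @param format \code{"uint16"} or \code{"float32"}.
#' @export
write_stack <- function(path, stack, format = c("uint16", "float32")) {
  format <- match.arg(format)
  a <- unclass(stack)
  if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
  d <- dim(a)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  bps <- if (format == "uint16") 16L else 32L
  sfmt <- if (format == "uint16") 1L else 3L
  bytes_px <- bps / 8L
  con <- file(path, "wb")
  on.exit(close(con))
  endian <- "little"
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = endian)
  # pixel data of each page precedes its IFD, so the first IFD sits after
  # the first frame's strip
  writeBin(as.integer(8 + ny * nx * bytes_px), con, size = 4, endian = endian)
  pos <- 8L
  n_tags <- 9L
  for (t in seq_len(nt)) {
    frame <- a[, , t]
    strip_offset <- pos
    nbytes <- ny * nx * bytes_px
    # pixel data, row-major (TIFF rows = image rows)
    v <- as.numeric(t(frame))
    if (format == "uint16") {
      v <- pmax(0, pmin(65535, round(v)))
      writeBin(as.integer(v), con, size = 2, endian = endian)
    } else {
      writeBin(v, con, size = 4, endian = endian)
    }
    ifd_offset <- strip_offset + nbytes
    writeBin(n_tags, con, size = 2, endian = endian)
    .tiff_tag(con, endian, 256, 3, 1, nx)            # ImageWidth
    .tiff_tag(con, endian, 257, 3, 1, ny)            # ImageLength
    .tiff_tag(con, endian, 258, 3, 1, bps)           # BitsPerSample
    .tiff_tag(con, endian, 259, 3, 1, 1)             # Compression: none
    .tiff_tag(con, endian, 262, 3, 1, 1)             # Photometric: min-is-black
    .tiff_tag(con, endian, 273, 4, 1, strip_offset)  # StripOffsets
    .tiff_tag(con, endian, 278, 3, 1, ny)            # RowsPerStrip
    .tiff_tag(con, endian, 279, 4, 1, nbytes)        # StripByteCounts
    .tiff_tag(con, endian, 339, 3, 1, sfmt)          # SampleFormat
    # the next page's IFD sits after this IFD plus the next page's strip
    next_ifd <- if (t < nt) ifd_offset + 2L + n_tags * 12L + 4L + nbytes else 0L
    writeBin(as.integer(next_ifd), con, size = 4, endian = endian)
    pos <- ifd_offset + 2L + n_tags * 12L + 4L
  }
  invisible(path)
}

.read_tiff_array <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  get_u <- function(at, size) {
    b <- as.integer(raw_all[(at + 1):(at + size)])
    if (endian == "little") b <- rev(b)
    val <- 0
    for (x in b) val <- val * 256 + x
    val
  }
  magic <- rawToChar(raw_all[1:2])
  if (magic == "II") endian <- "little"
  else if (magic == "MM") endian <- "big"
  else stop("not a TIFF file: ", path)
  if (get_u(2, 2) != 42) stop("not a TIFF file: ", path)
  ifd <- get_u(4, 4)
  frames <- list()
  while (ifd != 0) {
    n_tags <- get_u(ifd, 2)
    tags <- list()
    for (i in seq_len(n_tags)) {
      at <- ifd + 2 + (i - 1) * 12
      id <- get_u(at, 2)
      type <- get_u(at + 2, 2)
      count <- get_u(at + 4, 4)
      tsize <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      inline <- tsize * count <= 4
      val_at <- if (inline) at + 8 else get_u(at + 8, 4)
      vals <- if (type %in% c(3, 4, 1)) {
        vapply(seq_len(count) - 1, function(j) get_u(val_at + j * tsize, tsize),
               numeric(1))
      } else NULL
      tags[[as.character(id)]] <- vals
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(id)]]
      if (is.null(v)) default else v
    }
    nx <- g(256); ny <- g(257)
    if (is.null(nx) || is.null(ny)) stop("malformed TIFF: missing dimensions")
    bps <- g(258, 1)[1]
    comp <- g(259, 1)
    spp <- g(277, 1)
    sfmt <- g(339, 1)[1]
    if (comp != 1) stop("unsupported TIFF: compressed data (only baseline uncompressed is supported)")
    if (spp != 1) stop("grayscale required: TIFF has ", spp, " samples per pixel")
    if (!bps %in% c(8, 16, 32)) stop("unsupported TIFF bit depth: ", bps)
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets)) stop("malformed TIFF: no strip offsets")
    bytes_px <- bps / 8
    v <- numeric(0)
    for (s in seq_along(offsets)) {
      nb <- if (!is.null(counts)) counts[s] else nx * ny * bytes_px
      chunk <- raw_all[(offsets[s] + 1):(offsets[s] + nb)]
      v <- c(v, if (sfmt == 3) {
        readBin(chunk, "double", n = nb / 4, size = 4, endian = endian)
      } else {
        # readBin only honours signed=FALSE for sizes 1 and 2
        readBin(chunk, "integer", n = nb / bytes_px, size = bytes_px,
                signed = bps == 32, endian = endian)
      })
    }
    frames[[length(frames) + 1]] <- matrix(v, nrow = ny, ncol = nx, byrow = TRUE)
    ifd <- get_u(ifd + 2 + n_tags * 12, 4)
  }
  array(unlist(frames), c(dim(frames[[1]]), length(frames)))
}

#' Read a TIFF file as a calibrated image stack
#'
#' Reads single- or multi-page grayscale TIFF; page order is time order.
#' The physical calibration must be supplied explicitly: TIFF metadata is
#' not trusted and there are no silent defaults.
#'
#' @param path TIFF file path.
#' @param pixel_size_um pixel size in micrometres (required).
#' @param frame_interval_s frame interval in seconds (required).
#' @return an \code{image_stack}.
#' @export
read_stack <- function(path, pixel_size_um, frame_interval_s) {
  if (missing(pixel_size_um) || missing(frame_interval_s)) {
    stop("pixel_size_um and frame_interval_s calibration must be supplied")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  image_stack(.read_tiff_array(path), pixel_size_um, frame_interval_s)
}
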