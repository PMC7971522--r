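# Minimal baseline TIFF codec (uncompressed, little-endian, 16-bit).
#
# The pipeline exchanges images as 16-bit TIFFs holding 12-bit counts.
# No TIFF package is available in the supported dependency set, so a
# small baseline-TIFF reader/writer is provided: single IFD, no
# compression, chunky planar layout, 1 or 3 samples per pixel.  This is
# the subset every scientific TIFF reader (ImageJ, tifffile, MATLAB)
# understands.

TIFF_TYPE_SHORT <- 3L
TIFF_TYPE_LONG <- 4L

#' Write a 16-bit grayscale or RGB TIFF
#'
#' @param x an H x W numeric matrix or H x W x 3 array of nonnegative
#'   integers (at most 65535; camera data uses 0--4095).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(x, path) {
  dims <- dim(x)
  spp <- if (length(dims) == 3L) dims[3] else 1L
  if (!(spp %in% c(1L, 3L)))
    stop("only 1- or 3-sample images are supported")
  h <- dims[1]; w <- dims[2]
  vals <- round(as.numeric(x))
  if (anyNA(vals) || min(vals) < 0 || max(vals) > 65535)
    stop("values must be integers in [0, 65535]")
  # interleave row-major: R,G,B per pixel, pixels left-to-right, rows top-down
  data16 <- if (spp == 3L) as.vector(aperm(x, c(3L, 2L, 1L))) else as.vector(t(x))
  data16 <- as.integer(round(data16))
  nbytes <- length(data16) * 2L
  data_offset <- 8L
  ifd_offset <- data_offset + nbytes + (nbytes %% 2L)

  entries <- list(
    list(256L, TIFF_TYPE_LONG, 1L, w),             # ImageWidth
    list(257L, TIFF_TYPE_LONG, 1L, h),             # ImageLength
    list(258L, TIFF_TYPE_SHORT, spp, rep(16L, spp)), # BitsPerSample
    list(259L, TIFF_TYPE_SHORT, 1L, 1L),           # Compression = none
    list(262L, TIFF_TYPE_SHORT, 1L, if (spp == 3L) 2L else 1L), # Photometric
    list(273L, TIFF_TYPE_LONG, 1L, data_offset),   # StripOffsets
    list(277L, TIFF_TYPE_SHORT, 1L, spp),          # SamplesPerPixel
    list(278L, TIFF_TYPE_LONG, 1L, h),             # RowsPerStrip
    list(279L, TIFF_TYPE_LONG, 1L, nbytes),        # StripByteCounts
    list(284L, TIFF_TYPE_SHORT, 1L, 1L)            # PlanarConfig = chunky
  )
  n_entries <- length(entries)
  extra_offset <- ifd_offset + 2L + n_entries * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(data16, con, size = 2, endian = "little", useBytes = TRUE)
  if (nbytes %% 2L) writeBin(0L, con, size = 1)

  writeBin(n_entries, con, size = 2, endian = "little")
  extra <- list()
  for (e in entries) {
    tag <- e[[1]]; type <- e[[2]]; count <- e[[3]]; value <- e[[4]]
    writeBin(tag, con, size = 2, endian = "little")
    writeBin(type, con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    type_size <- if (type == TIFF_TYPE_SHORT) 2L else 4L
    if (count * type_size <= 4L) {
      if (type == TIFF_TYPE_SHORT) {
        vv <- c(as.integer(value), rep(0L, 2L - count))
        writeBin(vv, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(value), con, size = 4, endian = "little")
      }
    } else {
      writeBin(extra_offset, con, size = 4, endian = "little")
      extra <- c(extra, list(list(type = type, value = as.integer(value))))
      extra_offset <- extra_offset + count * type_size
    }
  }
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  for (e in extra) {
    writeBin(e$value, con, size = if (e$type == TIFF_TYPE_SHORT) 2 else 4,
             endian = "little")
  }
  invisible(path)
}

read_ifd_value <- function(con, type, count, raw_value, endian) {
  type_size <- if (type == TIFF_TYPE_SHORT) 2L else 4L
  signed <- type_size == 4L  # readBin only supports unsigned for size <= 2
  if (count * type_size <= 4L) {
    readBin(raw_value, "integer", n = count, size = type_size,
            signed = signed, endian = endian)[seq_len(count)]
  } else {
    offset <- readBin(raw_value, "integer", n = 1, size = 4, endian = endian)
    pos <- seek(con)
    seek(con, offset)
    v <- readBin(con, "integer", n = count, size = type_size,
                 signed = signed, endian = endian)
    seek(con, pos)
    v
  }
}

#' Read a 16-bit grayscale or RGB TIFF written by [write_tiff16()]
#'
#' Supports uncompressed baseline TIFF with chunky planar layout and 16
#' bits per sample, 1 or 3 samples per pixel, possibly split into
#' multiple strips.
#'
#' @param path file path.
#' @return an H x W integer matrix or H x W x 3 integer array.
#' @export
read_tiff16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_mark <- readChar(con, 2, useBytes = TRUE)
  endian <- switch(order_mark, II = "little", MM = "big",
                   stop("not a TIFF file: ", path))
  magic <- readBin(con, "integer", 1, size = 2, endian = endian)
  if (magic != 42L) stop("not a TIFF file: ", path)
  seek(con, readBin(con, "integer", 1, size = 4, endian = endian))
  n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE,
                       endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    raw_value <- readBin(con, "raw", 4)
    if (type %in% c(TIFF_TYPE_SHORT, TIFF_TYPE_LONG))
      tags[[as.character(tag)]] <- read_ifd_value(con, type, count, raw_value,
                                                  endian)
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF is missing required tag ", tag)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 1L); spp <- need(277, 1L)
  if (need(259, 1L) != 1L) stop("compressed TIFF not supported")
  if (need(284, 1L) != 1L) stop("planar TIFF not supported")
  if (any(bits != 16L)) stop("only 16-bit samples are supported")
  if (!(spp %in% c(1L, 3L))) stop("only 1 or 3 samples per pixel supported")
  offsets <- need(273); counts <- need(279)
  data16 <- integer(0)
  for (i in seq_along(offsets)) {
    seek(con, offsets[i])
    data16 <- c(data16, readBin(con, "integer", n = counts[i] / 2L, size = 2,
                                signed = FALSE, endian = endian))
  }
  if (length(data16) != h * w * spp) stop("TIFF pixel data is truncated")
  if (spp == 1L) {
    matrix(data16, nrow = h, ncol = w, byrow = TRUE)
  } else {
    aperm(array(data16, dim = c(3L, w, h)), c(3L, 2L, 1L))
  }
}
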