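# MRC2014 binary I/O (little-endian). Volumes are written in mode 2
# (32-bit float); modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16)
# are accepted on read. Stacks use the same container with nz = n_images
# and ispg = 0.

MRC_HEADER_BYTES <- 1024L

mrc_read_header <- function(con) {
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  extra <- readBin(con, "raw", n = 100)
  origin <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  map_tag <- readChar(con, 4, useBytes = TRUE)
  machst <- readBin(con, "raw", n = 4)
  rms <- readBin(con, "numeric", n = 1, size = 4, endian = "little")
  nlabl <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  labels <- readBin(con, "raw", n = 800)
  if (!identical(substr(map_tag, 1, 3), "MAP"))
    stop("corrupt MRC header: missing MAP tag")
  list(nx = ints[1], ny = ints[2], nz = ints[3], mode = ints[4],
       nstart = ints[5:7], m = ints[8:10], cella = cella, cellb = cellb,
       mapcrs = mapcrs, dmin = dstats[1], dmax = dstats[2],
       dmean = dstats[3], ispg = ispg, nsymbt = nsymbt, origin = origin,
       rms = rms, nlabl = nlabl)
}

mrc_read_data <- function(con, hdr) {
  n <- as.numeric(hdr$nx) * hdr$ny * hdr$nz
  if (hdr$nsymbt > 0) readBin(con, "raw", n = hdr$nsymbt)
  vals <- switch(as.character(hdr$mode),
    "0" = as.numeric(readBin(con, "integer", n = n, size = 1,
                             signed = TRUE, endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             signed = FALSE, endian = "little")),
    stop("unsupported MRC mode ", hdr$mode))
  if (length(vals) != n) stop("truncated MRC data section")
  array(vals, dim = c(hdr$nx, hdr$ny, hdr$nz))
}

mrc_voxel_size <- function(hdr) {
  if (hdr$m[1] > 0 && hdr$cella[1] > 0) hdr$cella[1] / hdr$m[1] else 1
}

mrc_write <- function(data, path, voxel_size, is_stack = FALSE) {
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  mz <- d[3]
  writeBin(as.integer(c(d[1], d[2], d[3], 2L, 0L, 0L, 0L, d[1], d[2], mz)),
           con, size = 4, endian = "little")
  writeBin(as.numeric(c(d[1], d[2], mz) * voxel_size), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")
  writeBin(as.integer(c(1L, 2L, 3L)), con, size = 4, endian = "little")
  # header statistics from the float32 representation actually stored
  stored <- readBin(writeBin(as.numeric(data), raw(), size = 4,
                             endian = "little"),
                    "numeric", n = length(data), size = 4, endian = "little")
  writeBin(as.numeric(c(min(stored), max(stored), mean(stored))), con,
           size = 4, endian = "little")
  writeBin(as.integer(c(if (is_stack) 0L else 1L, 0L)), con, size = 4,
           endian = "little")
  extra <- raw(100)
  nver <- writeBin(20140L, raw(), size = 4, endian = "little")
  extra[9:12] <- nver  # nversion word
  writeBin(extra, con)
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  writeBin(as.numeric(stats::sd(stored)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(NULL)
}

#' Read an MRC2014 density map
#'
#' @param path Path to an MRC file holding a cubic 3D map.
#' @return A [volume_grid()] with the voxel size taken from the header
#'   (`cella / mx`; 1 A if the header leaves the cell unset).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- mrc_read_header(con)
  if (hdr$nx != hdr$ny || hdr$ny != hdr$nz)
    stop("non-cubic map (", hdr$nx, "x", hdr$ny, "x", hdr$nz,
         "); read_stack() reads image stacks")
  volume_grid(mrc_read_data(con, hdr), mrc_voxel_size(hdr))
}

#' Write a density map as MRC2014
#'
#' Data are stored as 32-bit floats (mode 2) with the voxel size recorded
#' in the cell dimensions and min/max/mean/rms statistics in the header.
#'
#' @param vol A [volume_grid()].
#' @param path Output path.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  mrc_write(vol$data, path, vol$voxel_size, is_stack = FALSE)
  invisible(path)
}

#' Read an MRC image stack
#'
#' @param path Path to an MRC/MRCS stack (nz = number of images).
#' @return An [image_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- mrc_read_header(con)
  if (hdr$nx != hdr$ny) stop("stack images must be square")
  image_stack(mrc_read_data(con, hdr), mrc_voxel_size(hdr))
}

#' Write an image stack as MRC
#'
#' @param stack An [image_stack()].
#' @param path Output path (conventionally `.mrcs`).
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mrc_write(stack$images, path, stack$pixel_size, is_stack = TRUE)
  invisible(path)
}

#' Read a binary mask from MRC
#'
#' Values are binarized at 0.5 (MRC masks are frequently stored as floats).
#'
#' @param path Path to an MRC mask.
#' @return A [vol_mask()].
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  vol_mask(array(as.numeric(v$data > 0.5), dim(v$data)))
}
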