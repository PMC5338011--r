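# Minimal baseline TIFF codec: uncompressed single-plane grayscale, 8/16-bit.
# Hand-rolled because the installed stack ships no TIFF reader; scope is
# deliberately narrow (no compression, no tiles, no palette/RGB, first IFD
# only) and anything outside it is rejected with an explicit error.

TAG_WIDTH <- 256L
TAG_LENGTH <- 257L
TAG_BITS <- 258L
TAG_COMPRESSION <- 259L
TAG_PHOTOMETRIC <- 262L
TAG_STRIP_OFFSETS <- 273L
TAG_SAMPLES <- 277L
TAG_ROWS_PER_STRIP <- 278L
TAG_STRIP_BYTES <- 279L
TAG_TILE_WIDTH <- 322L

#' Read a single-plane grayscale TIFF
#'
#' Reads an uncompressed, strip-organized, single-sample (grayscale) baseline
#' TIFF of bit depth 8 or 16, in either byte order. Multi-sample (RGB),
#' compressed, tiled or palette files are rejected.
#'
#' @param path Path to the TIFF file.
#' @return Integer matrix of pixel intensities (rows = image rows), with
#'   attribute `bit_depth` (8 or 16).
#' @keywords internal
read_gray_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF: file too short")
  order <- rawToChar(raw[1:2])
  endian <- switch(order, II = "little", MM = "big",
                   stop("not a TIFF: bad byte-order mark"))
  u16 <- function(off) readBin(raw[(off + 1L):(off + 2L)], "integer",
                               size = 2L, signed = FALSE, endian = endian)
  u32 <- function(off) readBin(raw[(off + 1L):(off + 4L)], "integer",
                               size = 4L, endian = endian)
  if (u16(2L) != 42L) stop("not a TIFF: bad magic number")
  ifd <- u32(4L)
  n_entries <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd + 2L + (i - 1L) * 12L
    tag <- u16(e)
    type <- u16(e + 2L)
    count <- u32(e + 4L)
    # value fits inline when total size <= 4 bytes, else e+8 holds an offset
    type_size <- c(1L, 1L, 2L, 4L, 8L)[type]
    if (is.na(type_size)) next
    vals <- if (count * type_size <= 4L) {
      off <- e + 8L
      if (type == 3L) vapply(seq_len(count), function(k) u16(off + 2L * (k - 1L)), 0L)
      else if (type == 4L) vapply(seq_len(count), function(k) u32(off + 4L * (k - 1L)), 0L)
      else as.integer(raw[(off + 1L):(off + count)])
    } else {
      off <- u32(e + 8L)
      if (type == 3L) vapply(seq_len(count), function(k) u16(off + 2L * (k - 1L)), 0L)
      else if (type == 4L) vapply(seq_len(count), function(k) u32(off + 4L * (k - 1L)), 0L)
      else if (type == 5L) vapply(seq_len(count), function(k) u32(off + 8L * (k - 1L)), 0L)
      else as.integer(raw[(off + 1L):(off + count)])
    }
    tags[[as.character(tag)]] <- vals
  }
  get_tag <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) default else v
  }
  if (!is.null(get_tag(TAG_TILE_WIDTH)))
    stop("unsupported: tiled TIFF")
  if (get_tag(TAG_COMPRESSION, 1L)[1] != 1L)
    stop("unsupported: compressed TIFF")
  samples <- get_tag(TAG_SAMPLES, 1L)[1]
  photometric <- get_tag(TAG_PHOTOMETRIC, 1L)[1]
  if (samples != 1L || photometric > 1L)
    stop("unsupported: not single-channel grayscale")
  bits <- get_tag(TAG_BITS, 1L)[1]
  if (!bits %in% c(8L, 16L)) stop("unsupported bit depth: ", bits)
  width <- get_tag(TAG_WIDTH)
  height <- get_tag(TAG_LENGTH)
  if (is.null(width) || is.null(height)) stop("not a TIFF image: missing dimensions")
  offsets <- get_tag(TAG_STRIP_OFFSETS)
  counts <- get_tag(TAG_STRIP_BYTES, width * height * bits %/% 8L)
  if (is.null(offsets)) stop("unsupported: no strip offsets")
  payload <- raw(0)
  for (s in seq_along(offsets))
    payload <- c(payload, raw[(offsets[s] + 1L):(offsets[s] + counts[s])])
  n_px <- width * height
  vals <- if (bits == 8L) as.integer(payload[seq_len(n_px)])
  else readBin(payload, "integer", n = n_px, size = 2L, signed = FALSE,
               endian = endian)
  m <- matrix(vals, nrow = height, ncol = width, byrow = TRUE)
  attr(m, "bit_depth") <- as.integer(bits)
  m
}

#' Write a single-plane grayscale TIFF
#'
#' Writes an uncompressed little-endian baseline TIFF (one strip) from an
#' integer-valued matrix.
#'
#' @param m Matrix of intensities in `[0, 2^bit_depth - 1]`.
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @keywords internal
write_gray_tiff <- function(m, path, bit_depth = 8L) {
  stopifnot(is.matrix(m), bit_depth %in% c(8L, 16L))
  v <- as.integer(round(t(m)))  # row-major order
  if (any(v < 0L) || any(v > 2^bit_depth - 1))
    stop("pixel values out of range for bit depth ", bit_depth)
  h <- nrow(m); w <- ncol(m)
  pixel_bytes <- if (bit_depth == 8L) as.raw(v)
  else as.raw(rbind(v %% 256L, v %/% 256L))  # little-endian uint16
  u16r <- function(x) as.raw(c(x %% 256L, x %/% 256L))
  u32r <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                               (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
  entry <- function(tag, type, count, value)
    c(u16r(tag), u16r(type), u32r(count), u32r(value))
  n_entries <- 8L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_entries * 12L + 4L
  ifd <- c(
    u16r(n_entries),
    entry(TAG_WIDTH, 4L, 1L, w),
    entry(TAG_LENGTH, 4L, 1L, h),
    entry(TAG_BITS, 3L, 1L, bit_depth),
    entry(TAG_COMPRESSION, 3L, 1L, 1L),
    entry(TAG_PHOTOMETRIC, 3L, 1L, 1L),  # BlackIsZero
    entry(TAG_STRIP_OFFSETS, 4L, 1L, data_offset),
    entry(TAG_ROWS_PER_STRIP, 4L, 1L, h),
    entry(TAG_STRIP_BYTES, 4L, 1L, length(pixel_bytes)),
    u32r(0L)  # no next IFD
  )
  header <- c(charToRaw("II"), u16r(42L), u32r(ifd_offset))
  writeBin(c(header, ifd, pixel_bytes), path)
  invisible(path)
}
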