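#' Construct a channel image
#'
#' A `channel_image` holds one genotype's grayscale fluorescence field: an
#' intensity matrix plus the physical pixel size and a channel label tying it
#' to a fluorophore (green = eGFP-tagged genotype, red = mCherry-tagged
#' genotype).
#'
#' @param pixels Numeric matrix of non-negative intensities
#'   (rows = image rows, 1-based, origin top-left).
#' @param bit_depth Integer, 8 or 16; intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param channel_label `"green"` or `"red"`.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, bit_depth, pixel_size_um,
                          channel_label = c("green", "red")) {
  channel_label <- match.arg(channel_label)
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (!is.matrix(pixels) || !is.numeric(pixels)) stop("pixels must be a numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1)
    stop("intensities outside [0, 2^bit_depth - 1]")
  structure(list(pixels = pixels, bit_depth = bit_depth,
                 pixel_size_um = pixel_size_um, channel_label = channel_label),
            class = "channel_image")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, %d-bit, %.4g um/px, range [%g, %g]\n",
              x$channel_label, nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              x$pixel_size_um, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Pair two registered channel images of one colony
#'
#' The unit of analysis: green and red channel images of the same colony
#' (registered, identical geometry) together with the inoculation-zone
#' geometry from which radial profiling starts.
#'
#' @param green,red `channel_image` objects with identical dimensions and
#'   pixel size.
#' @param center_px Numeric length-2 `(row, col)` of the inoculation-zone
#'   center, in 1-based pixel coordinates (fractional values allowed).
#' @param inoc_radius_um Inoculation-zone radius in micrometres (>= 0). The
#'   droplet inoculum in the source experiments is a disc of diameter
#'   about 2 mm, i.e. radius about 1000 um.
#' @return An object of class `colony_image_pair`.
#' @export
colony_image_pair <- function(green, red, center_px, inoc_radius_um) {
  stopifnot(inherits(green, "channel_image"), inherits(red, "channel_image"))
  if (green$channel_label != "green" || red$channel_label != "red")
    stop("channel labels must be green and red respectively")
  if (!identical(dim(green$pixels), dim(red$pixels)))
    stop("green and red images must have identical dimensions")
  if (green$pixel_size_um != red$pixel_size_um)
    stop("green and red images must have identical pixel_size_um")
  if (length(center_px) != 2 || !is.numeric(center_px))
    stop("center_px must be numeric (row, col)")
  d <- dim(green$pixels)
  if (center_px[1] < 1 || center_px[1] > d[1] || center_px[2] < 1 || center_px[2] > d[2])
    stop("center_px lies outside image bounds")
  if (!is.numeric(inoc_radius_um) || inoc_radius_um < 0)
    stop("inoc_radius_um must be >= 0")
  structure(list(green = green, red = red,
                 center_px = as.numeric(center_px),
                 inoc_radius_um = as.numeric(inoc_radius_um)),
            class = "colony_image_pair")
}

#' @export
print.colony_image_pair <- function(x, ...) {
  cat(sprintf("<colony_image_pair> %d x %d px, %.4g um/px, center (%.1f, %.1f), inoc radius %.0f um\n",
              nrow(x$green$pixels), ncol(x$green$pixels), x$green$pixel_size_um,
              x$center_px[1], x$center_px[2], x$inoc_radius_um))
  invisible(x)
}

#' Read one fluorescence channel from a grayscale TIFF
#'
#' Accepts only single-plane grayscale TIFFs (8- or 16-bit, uncompressed).
#' The pixel size is required metadata supplied by the caller; resolution
#' tags inside the file are ignored, since tile-scan exports often carry
#' wrong ones.
#'
#' @param path Path to the TIFF file.
#' @param pixel_size_um Physical pixel size in micrometres (> 0).
#' @param channel_label `"green"` or `"red"`.
#' @return A [channel_image].
#' @export
read_channel <- function(path, pixel_size_um, channel_label = c("green", "red")) {
  channel_label <- match.arg(channel_label)
  m <- read_gray_tiff(path)
  channel_image(unclass(m)[, , drop = FALSE], attr(m, "bit_depth"),
                pixel_size_um, channel_label)
}

#' Write one channel to a grayscale TIFF
#'
#' Intensities are rounded to integers; output is an uncompressed
#' little-endian baseline TIFF readable by [read_channel].
#'
#' @param img A [channel_image].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel <- function(img, path) {
  stopifnot(inherits(img, "channel_image"))
  write_gray_tiff(img$pixels, path, img$bit_depth)
}

#' Convert a channel image to 8-bit
#'
#' Linear rescale of an intensity window onto `[0, 255]`, clipping outside the
#' window. `mode = "minmax"` uses the full observed range; `mode =
#' "percentile"` uses the `(p_low, p_high)` percentile window, a reproducible
#' stand-in for interactive auto brightness/contrast adjustment.
#'
#' A constant image has a zero-width window; the result is then all zeros and
#' carries attribute `degenerate_window = TRUE` (with a warning).
#'
#' @param img A [channel_image].
#' @param mode `"minmax"` or `"percentile"`.
#' @param p_low,p_high Percentile window bounds in percent (percentile mode).
#' @return An 8-bit [channel_image]; monotonic in the input intensities.
#' @export
to_8bit <- function(img, mode = c("percentile", "minmax"),
                    p_low = 0.35, p_high = 99.65) {
  stopifnot(inherits(img, "channel_image"))
  mode <- match.arg(mode)
  p <- img$pixels
  win <- if (mode == "minmax") range(p)
  else stats::quantile(p, c(p_low, p_high) / 100, names = FALSE)
  degenerate <- win[2] <= win[1]
  out <- if (degenerate) {
    warning("degenerate intensity window (constant image); output is all zeros")
    matrix(0, nrow(p), ncol(p))
  } else {
    round(pmin(pmax((p - win[1]) / (win[2] - win[1]), 0), 1) * 255)
  }
  res <- channel_image(out, 8L, img$pixel_size_um, img$channel_label)
  attr(res, "degenerate_window") <- degenerate
  res
}

#' Write a cyan/magenta pseudo-color overlay
#'
#' Follows the conventional fluorescence merge: the eGFP (green) channel is
#' shown as cyan `(0, g, g)`, the mCherry (red) channel as magenta
#' `(r, 0, r)`, combined additively with clipping at 255, so areas where both
#' signals overlap appear white.
#'
#' @param pair A [colony_image_pair] with both channels 8-bit.
#' @param out_path Output PNG path.
#' @return The RGB array (rows x cols x 3, in `[0, 1]`), invisibly; the PNG is
#'   written to `out_path`.
#' @export
overlay_pseudocolor <- function(pair, out_path) {
  stopifnot(inherits(pair, "colony_image_pair"))
  if (pair$green$bit_depth != 8L || pair$red$bit_depth != 8L)
    stop("both channels must be 8-bit (see to_8bit)")
  g <- pair$green$pixels
  r <- pair$red$pixels
  rgb <- array(0, c(nrow(g), ncol(g), 3L))
  rgb[, , 1] <- r
  rgb[, , 2] <- g
  rgb[, , 3] <- pmin(g + r, 255)
  rgb <- rgb / 255
  png::writePNG(rgb, out_path)
  invisible(rgb)
}

#' Rotate a channel image or colony pair by 90 degrees
#'
#' Counter-clockwise rotation in image display coordinates, `k` times. For a
#' pair, the inoculation center is transformed consistently, so analysis
#' results are invariant. Mainly a QC/testing aid.
#'
#' @param x A [channel_image] or [colony_image_pair].
#' @param k Number of counter-clockwise quarter turns.
#' @return Object of the same class, rotated.
#' @export
rotate90 <- function(x, k = 1L) {
  k <- as.integer(k) %% 4L
  if (inherits(x, "channel_image")) {
    p <- x$pixels
    for (i in seq_len(k)) p <- t(p[, ncol(p):1, drop = FALSE])
    out <- x
    out$pixels <- p
    return(out)
  }
  if (inherits(x, "colony_image_pair")) {
    out <- x
    ctr <- x$center_px
    d <- dim(x$green$pixels)
    for (i in seq_len(k)) {
      ctr <- c(d[2] + 1 - ctr[2], ctr[1])  # (row, col) -> (ncol+1-col, row)
      d <- rev(d)
    }
    out$green <- rotate90(x$green, k)
    out$red <- rotate90(x$red, k)
    out$center_px <- ctr
    return(out)
  }
  stop("rotate90 expects a channel_image or colony_image_pair")
}

#' Fit the inoculation circle from a binary mask
#'
#' Estimates center and radius of a user-annotated inoculation zone: the
#' center is the mask centroid and the radius the equivalent-area circle
#' radius `sqrt(area / pi)`.
#'
#' @param mask Logical matrix marking inoculation-zone pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @return List with `center_px` (row, col) and `inoc_radius_um`.
#' @export
fit_inoc_circle <- function(mask, pixel_size_um) {
  stopifnot(is.matrix(mask), is.logical(mask), any(mask), pixel_size_um > 0)
  idx <- which(mask, arr.ind = TRUE)
  list(center_px = c(mean(idx[, 1]), mean(idx[, 2])),
       inoc_radius_um = sqrt(nrow(idx) / pi) * pixel_size_um)
}
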