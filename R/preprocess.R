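#' Preprocessing parameters
#'
#' @param coarsen_factor Integer downsampling factor (>= 1). Default 8, the
#'   factor used in the source quantification to cut computation time.
#' @param smooth_window_um Arc-length smoothing window in micrometres applied
#'   to each circular intensity profile. Default 10.
#' @return List of class `preprocess_params`.
#' @export
preprocess_params <- function(coarsen_factor = 8L, smooth_window_um = 10) {
  coarsen_factor <- as.integer(coarsen_factor)
  if (is.na(coarsen_factor) || coarsen_factor < 1L)
    stop("coarsen_factor must be a positive integer")
  if (!is.numeric(smooth_window_um) || smooth_window_um < 0)
    stop("smooth_window_um must be >= 0")
  structure(list(coarsen_factor = coarsen_factor,
                 smooth_window_um = smooth_window_um),
            class = "preprocess_params")
}

# Keys cubic convolution kernel, a = -0.5 (the classic bicubic kernel).
cubic_kernel <- function(x) {
  a <- -0.5
  ax <- abs(x)
  ifelse(ax <= 1, (a + 2) * ax^3 - (a + 3) * ax^2 + 1,
         ifelse(ax < 2, a * ax^3 - 5 * a * ax^2 + 8 * a * ax - 4 * a, 0))
}

# Weight matrix for 1D cubic resampling from n input samples to m = floor(n/f)
# output samples. For f > 1 the kernel is widened by f (antialias prefilter,
# as in MATLAB imresize). Out-of-range taps are clamped to the edge sample;
# weights are normalized to sum 1 so constants are reproduced exactly.
resample_weights <- function(n, f) {
  m <- n %/% f
  s <- max(f, 1)
  half <- 2 * s
  W <- matrix(0, m, n)
  for (i in seq_len(m)) {
    u <- (i - 0.5) * f + 0.5
    j0 <- floor(u - half) + 1
    j <- seq.int(j0, ceiling(u + half))
    w <- cubic_kernel((u - j) / s) / s
    keep <- w != 0
    j <- j[keep]; w <- w[keep]
    jc <- pmin(pmax(j, 1L), n)  # clamp = replicate edge
    for (k in seq_along(jc)) W[i, jc[k]] <- W[i, jc[k]] + w[k]
    W[i, ] <- W[i, ] / sum(W[i, ])
  }
  W
}

#' Coarsen a channel image by an integer factor
#'
#' Downsamples by bicubic interpolation (Keys kernel, 4x4 support, widened by
#' the factor as an antialias prefilter), mirroring the resize step used
#' before radial profiling. Output dimensions are `floor(input / factor)` per
#' axis and the pixel size is multiplied by the factor. Factor 1 returns an
#' identical copy.
#'
#' @param img A [channel_image].
#' @param factor Positive integer, at most the smaller image dimension.
#' @return A coarsened [channel_image]; values are clipped to the valid
#'   intensity range (bicubic kernels can overshoot at sharp edges).
#' @export
coarsen <- function(img, factor) {
  stopifnot(inherits(img, "channel_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (factor == 1L) return(img)
  p <- img$pixels
  if (factor > nrow(p) || factor > ncol(p))
    stop("factor exceeds image dimensions")
  Wr <- resample_weights(nrow(p), factor)
  Wc <- resample_weights(ncol(p), factor)
  out <- Wr %*% p %*% t(Wc)
  out <- pmin(pmax(out, 0), 2^img$bit_depth - 1)
  channel_image(out, img$bit_depth, img$pixel_size_um * factor,
                img$channel_label)
}

#' Smooth intensities on a closed circle
#'
#' Circular (wrap-around) moving average with a uniform window of
#' `round(window_um / spacing_um)` samples, forced odd with a minimum of 1.
#' The circular mean is preserved exactly and the value range never widens.
#' A window below one sample spacing degrades to the identity.
#'
#' @param values Numeric vector of intensities sampled on a closed circle.
#' @param spacing_um Arc length between consecutive samples (> 0).
#' @param window_um Smoothing window in micrometres (>= 0).
#' @return Numeric vector, same length as `values`.
#' @export
smooth_circular <- function(values, spacing_um, window_um) {
  if (length(values) == 0) stop("values must be non-empty")
  if (!is.numeric(spacing_um) || spacing_um <= 0) stop("spacing_um must be > 0")
  if (!is.numeric(window_um) || window_um < 0) stop("window_um must be >= 0")
  w <- round(window_um / spacing_um)
  if (w %% 2 == 0) w <- w + 1
  w <- max(1, w)
  if (w == 1 || length(values) == 1) return(values)
  n <- length(values)
  w <- min(w, if (n %% 2 == 1) n else n - 1)  # largest odd window that fits
  if (w == 1) return(values)
  as.numeric(stats::filter(values, rep(1 / w, w), method = "convolution",
                           sides = 2, circular = TRUE))
}
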