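#' Radial sweep parameters
#'
#' Controls the grid of circles along which intensity is measured, marching
#' outward from the edge of the inoculation zone.
#'
#' @param r_start_um First radius in micrometres; `NA` means "use the pair's
#'   inoculation radius".
#' @param r_end_um Last radius in micrometres (> `r_start_um`).
#' @param dr_um Radial step in micrometres (> 0). Default 10.
#' @param target_arc_spacing_um Desired arc length between consecutive angular
#'   samples; `NA` means "one (coarsened) pixel".
#' @return List of class `radial_sweep_params`.
#' @export
radial_sweep_params <- function(r_start_um = NA, r_end_um, dr_um = 10,
                                target_arc_spacing_um = NA) {
  if (!is.na(r_start_um) && r_start_um < 0) stop("r_start_um must be >= 0")
  if (!is.numeric(r_end_um) || (!is.na(r_start_um) && r_end_um <= r_start_um))
    stop("r_end_um must exceed r_start_um")
  if (!is.numeric(dr_um) || dr_um <= 0) stop("dr_um must be > 0")
  structure(list(r_start_um = r_start_um, r_end_um = r_end_um, dr_um = dr_um,
                 target_arc_spacing_um = target_arc_spacing_um),
            class = "radial_sweep_params")
}

# Angular samples per circle: arc spacing ~ target, at least 8 points, and a
# multiple of 4 so that quarter-turn image rotations land exactly on the same
# sample set (exact rotation equivariance).
n_points_for_radius <- function(radius_um, target_arc_spacing_um) {
  if (radius_um <= 0) return(8L)
  n <- 4L * max(2L, as.integer(round(2 * pi * radius_um /
                                       target_arc_spacing_um / 4)))
  max(8L, n)
}

# Bilinear interpolation of matrix m at fractional (row, col) positions.
bilinear <- function(m, row, col) {
  r0 <- pmin(pmax(floor(row), 1), nrow(m) - 1L)
  c0 <- pmin(pmax(floor(col), 1), ncol(m) - 1L)
  fr <- row - r0
  fc <- col - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Sample image intensity along a circle
#'
#' Returns intensities at `n_points` equally spaced angles
#' `theta_k = 2*pi*k / n_points` on the circle of the given physical radius,
#' by bilinear interpolation. Angle 0 points along +x (increasing column);
#' positive angles run counter-clockwise in physical coordinates (+y =
#' decreasing row, since image rows grow downward).
#'
#' @param img A [channel_image].
#' @param center_px Numeric `(row, col)` center, 1-based pixels.
#' @param radius_um Circle radius in micrometres (>= 0); radius 0 returns the
#'   interpolated center value.
#' @param n_points Number of angular samples (>= 8).
#' @return Numeric vector of length `n_points`, with attribute `thetas`.
#' @export
sample_circle <- function(img, center_px, radius_um, n_points) {
  stopifnot(inherits(img, "channel_image"))
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 8L) stop("n_points must be >= 8")
  if (radius_um < 0) stop("radius_um must be >= 0")
  thetas <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  rp <- radius_um / img$pixel_size_um
  row <- center_px[1] - rp * sin(thetas)
  col <- center_px[2] + rp * cos(thetas)
  d <- dim(img$pixels)
  bad <- which(row < 1 | row > d[1] | col < 1 | col > d[2])
  if (length(bad) > 0)
    stop(sprintf("circle of radius %.1f um exits image bounds, first at theta = %.4f rad",
                 radius_um, thetas[bad[1]]))
  out <- bilinear(img$pixels, row, col)
  attr(out, "thetas") <- thetas
  out
}

#' Extract circular intensity profiles at increasing radius
#'
#' For each radius `r = r_start, r_start + dr, ... <= r_end`, both channels
#' are sampled on an identical angular grid whose arc spacing approximates
#' `target_arc_spacing_um`, then smoothed with the circular moving average of
#' [smooth_circular] (window `pp$smooth_window_um`). Radii whose circles exit
#' the image are dropped from the end of the sweep with a warning.
#'
#' @param pair A [colony_image_pair].
#' @param params A [radial_sweep_params]; `r_start_um = NA` defaults to the
#'   pair's inoculation radius, `target_arc_spacing_um = NA` to one pixel.
#' @param pp A [preprocess_params] (only `smooth_window_um` is used here;
#'   coarsening belongs to [patch_width_curve]).
#' @return List of `radial_profile` objects, each with fields `radius_um`,
#'   `thetas`, `green_values`, `red_values`, `spacing_um`.
#' @export
radial_sweep <- function(pair, params, pp = preprocess_params()) {
  stopifnot(inherits(pair, "colony_image_pair"),
            inherits(params, "radial_sweep_params"))
  r_start <- if (is.na(params$r_start_um)) pair$inoc_radius_um else params$r_start_um
  if (params$r_end_um <= r_start) stop("r_end_um must exceed the start radius")
  target <- if (is.na(params$target_arc_spacing_um)) pair$green$pixel_size_um
  else params$target_arc_spacing_um
  radii <- seq(r_start, params$r_end_um, by = params$dr_um)
  profiles <- list()
  for (r in radii) {
    n <- n_points_for_radius(r, target)
    g <- try(sample_circle(pair$green, pair$center_px, r, n), silent = TRUE)
    if (inherits(g, "try-error")) {
      if (length(profiles) == 0)
        stop("start radius circle already exits image bounds")
      warning(sprintf("sweep truncated at %.1f um: circle exits image bounds", r))
      break
    }
    rd <- sample_circle(pair$red, pair$center_px, r, n)
    spacing <- 2 * pi * r / n
    sm_spacing <- if (spacing > 0) spacing else target
    profiles[[length(profiles) + 1L]] <- structure(
      list(radius_um = r,
           thetas = attr(g, "thetas"),
           green_values = smooth_circular(as.numeric(g), sm_spacing, pp$smooth_window_um),
           red_values = smooth_circular(as.numeric(rd), sm_spacing, pp$smooth_window_um),
           spacing_um = spacing),
      class = "radial_profile")
  }
  profiles
}

#' Flatten radial profiles to a long data frame
#'
#' @param profiles List of `radial_profile` objects from [radial_sweep].
#' @return Data frame with columns `radius_um`, `theta`, `green`, `red`.
#' @export
profiles_to_df <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p)
    data.frame(radius_um = p$radius_um, theta = p$thetas,
               green = p$green_values, red = p$red_values)))
}
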