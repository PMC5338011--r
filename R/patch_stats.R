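#' Otsu threshold of a 1D intensity sample
#'
#' Histograms the values into `n_bins` equal-width bins over `[min, max]` and
#' returns the bin-edge threshold maximizing the between-class variance
#' `sigma_b^2(t) = w0(t) w1(t) (mu0(t) - mu1(t))^2`, the criterion of Otsu's
#' method (as in MATLAB's `graythresh`). Ties are broken toward the smallest
#' maximizing edge. Values equal to the returned threshold fall in the lower
#' class.
#'
#' @param values Non-empty numeric vector.
#' @param n_bins Number of histogram bins (default 256, the 8-bit convention).
#' @return The threshold (an interior bin edge), with attributes `degenerate`
#'   (`TRUE` when the input is constant; the constant itself is then returned)
#'   and `effectiveness` (Otsu's effectiveness metric
#'   `eta = sigma_b^2(t*) / sigma_total^2` in `[0, 1]`; `graythresh`'s second
#'   output). A sample that is only unimodal noise has `eta` near `2/pi`;
#'   a genuinely bimodal sample approaches 1.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  if (length(values) == 0) stop("values must be non-empty")
  mn <- min(values); mx <- max(values)
  if (mx <= mn) {
    out <- mn
    attr(out, "degenerate") <- TRUE
    attr(out, "effectiveness") <- 0
    return(out)
  }
  n_bins <- as.integer(n_bins)
  idx <- pmin(n_bins, floor((values - mn) / (mx - mn) * n_bins) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  sums <- numeric(n_bins)
  rs <- rowsum(values, idx)
  sums[as.integer(rownames(rs))] <- rs
  N <- length(values)
  total <- sum(sums)
  c0 <- cumsum(counts)[-n_bins]   # class 0 = bins 1..k
  s0 <- cumsum(sums)[-n_bins]
  w0 <- c0 / N
  w1 <- 1 - w0
  mu0 <- ifelse(c0 > 0, s0 / c0, 0)
  mu1 <- ifelse(N - c0 > 0, (total - s0) / (N - c0), 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  k <- which.max(sigma_b)  # which.max returns the first (smallest) maximizer
  thr <- mn + k * (mx - mn) / n_bins
  sigma_tot <- sum(values^2) / N - (total / N)^2
  attr(thr, "degenerate") <- FALSE
  attr(thr, "effectiveness") <- if (sigma_tot > 0) sigma_b[k] / sigma_tot else 0
  thr
}

#' Threshold-corrected signal
#'
#' Subtracts the per-radius threshold from the intensity values; patches are
#' then arcs where the corrected signal is above zero.
#'
#' @param values Numeric vector.
#' @param threshold Finite scalar.
#' @return `values - threshold`.
#' @export
corrected_signal <- function(values, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  values - as.numeric(threshold)
}

#' Circular runs and crossing count of a signed signal
#'
#' Binarizes the signal as `above = signal > 0` (exact zeros fall below) and
#' computes maximal runs on circular topology: a run may wrap through the
#' first index. Crossings are sign changes between consecutive samples around
#' the circle, so the count is always even; crossings delimit patches.
#'
#' @param signal Non-empty numeric vector on a closed circle.
#' @param spacing_um Arc length per sample (> 0).
#' @return List with `n_crossings` (even integer) and `run_lengths_um`
#'   (lengths of above-zero runs in micrometres; a fully-above circle is one
#'   run of the whole circumference, a fully-below circle has none).
#' @export
circular_runs <- function(signal, spacing_um) {
  if (length(signal) == 0) stop("signal must be non-empty")
  if (!is.numeric(spacing_um) || spacing_um <= 0) stop("spacing_um must be > 0")
  above <- signal > 0
  n <- length(above)
  if (all(above))
    return(list(n_crossings = 0L, run_lengths_um = n * spacing_um))
  if (!any(above))
    return(list(n_crossings = 0L, run_lengths_um = numeric(0)))
  nxt <- c(2:n, 1L)
  n_crossings <- sum(above != above[nxt])
  prev <- c(n, seq_len(n - 1L))
  start <- which(above != above[prev])[1]  # first index opening a run
  rot <- above[c(seq.int(start, n), seq_len(start - 1L))]
  r <- rle(rot)
  list(n_crossings = as.integer(n_crossings),
       run_lengths_um = r$lengths[r$values] * spacing_um)
}

# Per-channel statistics on one smoothed circular profile. A circle whose
# per-radius Otsu separation is no better than unimodal noise (effectiveness
# below eta_min, or a constant circle) is degenerate: there is no two-genotype
# alternation to threshold at this radius. Such circles are classified
# against the channel's global image threshold when one is supplied (a
# uniformly bright front then reads covered_fraction 1, a vanished genotype
# 0) and are always flagged unreliable.
channel_stats <- function(values, spacing_um, radius_um,
                          global_threshold = NULL, eta_min = 0.70) {
  thr <- otsu_threshold(values)
  degenerate <- isTRUE(attr(thr, "degenerate")) ||
    attr(thr, "effectiveness") < eta_min
  use_thr <- if (degenerate && !is.null(global_threshold)) global_threshold
  else as.numeric(thr)
  runs <- circular_runs(corrected_signal(values, use_thr), spacing_um)
  n <- length(values)
  n_above <- sum(values > use_thr)
  n_patches <- length(runs$run_lengths_um)
  mean_width <- if (n_patches > 0) mean(runs$run_lengths_um) else NA_real_
  list(threshold = use_thr,
       n_crossings = runs$n_crossings,
       n_patches = n_patches,
       mean_patch_width_um = mean_width,
       covered_fraction = n_above / n,
       reliable = runs$n_crossings > 0L && !degenerate)
}

#' Patch statistics at one radius
#'
#' Applies, per channel independently, the per-radius pipeline: Otsu
#' threshold of the circle's own intensities, threshold subtraction, and
#' circular crossing statistics. The mean clonal patch width is the mean
#' above-zero run length (an arc length along the front line). A channel with
#' no crossings (uniformly above — e.g. a genotype dominating the whole front
#' — or uniformly below, or a constant circle beyond the colony edge) is
#' flagged `reliable = FALSE`: the crossing statistic cannot measure a width
#' there.
#'
#' @param profile A `radial_profile` from [radial_sweep].
#' @param global_thresholds Optional named numeric `c(green =, red =)` of
#'   whole-image Otsu thresholds used to classify degenerate circles (see
#'   Details); without them a degenerate circle keeps its own (meaningless)
#'   per-circle threshold.
#' @param eta_min Minimum Otsu effectiveness below which a circle is treated
#'   as degenerate (no genotype alternation). Default 0.70, between the
#'   unimodal Gaussian value `2/pi ~ 0.64` and the `~0.81` of a heavily
#'   smoothed sinusoidal alternation.
#' @return Object of class `patch_stats_at_radius`: list with `radius_um`,
#'   `spacing_um`, and per-channel sublists `green`/`red` holding `threshold`,
#'   `n_crossings`, `n_patches`, `mean_patch_width_um`, `covered_fraction`,
#'   `reliable`.
#' @export
patch_stats_at_radius <- function(profile, global_thresholds = NULL,
                                  eta_min = 0.70) {
  stopifnot(inherits(profile, "radial_profile"))
  sp <- profile$spacing_um
  gthr <- function(ch) if (is.null(global_thresholds)) NULL
  else unname(global_thresholds[[ch]])
  structure(list(
    radius_um = profile$radius_um,
    spacing_um = sp,
    green = channel_stats(profile$green_values, sp, profile$radius_um,
                          gthr("green"), eta_min),
    red = channel_stats(profile$red_values, sp, profile$radius_um,
                        gthr("red"), eta_min)),
    class = "patch_stats_at_radius")
}

#' Mean clonal patch width versus radial distance
#'
#' The end-to-end statistic: both channels are coarsened, circular profiles
#' are extracted at increasing radius from the inoculation zone, and
#' per-radius crossing statistics yield the mean patch (strand) width per
#' genotype as a function of radial distance R. Intermixing appears as widths
#' decreasing with R; demixing as widths increasing until crossings vanish.
#'
#' Degenerate circles (no detectable alternation at that radius — e.g. a
#' single genotype dominating the whole front, or background beyond the
#' colony edge) are classified against each channel's whole-image Otsu
#' threshold and flagged `reliable = FALSE`, mirroring the loss of crossings
#' once demixing is complete.
#'
#' @param pair A [colony_image_pair].
#' @param sweep A [radial_sweep_params].
#' @param pp A [preprocess_params] (coarsening factor and smoothing window).
#' @param eta_min Degeneracy cutoff, see [patch_stats_at_radius].
#' @return A data frame of class `patch_width_curve`, one row per
#'   (radius, channel): `radius_um`, `channel`, `threshold`, `n_crossings`,
#'   `n_patches`, `mean_patch_width_um`, `covered_fraction`, `reliable`.
#'   Attribute `combined` holds the per-radius patch-count-weighted mean of
#'   the two channels' widths over reliable channels (columns `radius_um`,
#'   `mean_patch_width_um`, `n_patches`, `reliable`); attribute `params`
#'   records the parameters used.
#' @export
patch_width_curve <- function(pair, sweep, pp = preprocess_params(),
                              eta_min = 0.70) {
  stopifnot(inherits(pair, "colony_image_pair"))
  f <- pp$coarsen_factor
  if (f > 1L) {
    cg <- coarsen(pair$green, f)
    cr <- coarsen(pair$red, f)
    # input coordinate u maps to output coordinate (u - 0.5)/f + 0.5
    ctr <- (pair$center_px - 0.5) / f + 0.5
    pair <- colony_image_pair(cg, cr, ctr, pair$inoc_radius_um)
  }
  gthr <- c(green = as.numeric(otsu_threshold(as.numeric(pair$green$pixels))),
            red = as.numeric(otsu_threshold(as.numeric(pair$red$pixels))))
  profiles <- radial_sweep(pair, sweep, pp)
  stats <- lapply(profiles, patch_stats_at_radius,
                  global_thresholds = gthr, eta_min = eta_min)
  rows <- do.call(rbind, lapply(stats, function(s) {
    per_ch <- function(ch, lab) data.frame(
      radius_um = s$radius_um, channel = lab, threshold = ch$threshold,
      n_crossings = ch$n_crossings, n_patches = ch$n_patches,
      mean_patch_width_um = ch$mean_patch_width_um,
      covered_fraction = ch$covered_fraction, reliable = ch$reliable,
      stringsAsFactors = FALSE)
    rbind(per_ch(s$green, "green"), per_ch(s$red, "red"))
  }))
  combined <- do.call(rbind, lapply(stats, function(s) {
    chs <- Filter(function(ch) ch$reliable && ch$n_patches > 0,
                  list(s$green, s$red))
    w <- vapply(chs, `[[`, 0, "mean_patch_width_um")
    np <- vapply(chs, `[[`, 0, "n_patches")
    data.frame(radius_um = s$radius_um,
               mean_patch_width_um = if (length(chs)) sum(w * np) / sum(np) else NA_real_,
               n_patches = if (length(chs)) sum(np) else 0,
               reliable = length(chs) > 0)
  }))
  structure(rows, class = c("patch_width_curve", "data.frame"),
            combined = combined,
            params = list(sweep = sweep, preprocess = pp))
}

#' Per-radius combined patch-width summary
#'
#' @param curve A `patch_width_curve`.
#' @return The per-radius combined data frame (patch-count-weighted mean width
#'   over reliable channels).
#' @export
combined_width <- function(curve) {
  stopifnot(inherits(curve, "patch_width_curve"))
  attr(curve, "combined")
}

#' Per-radius genotype coverage fractions
#'
#' Fraction of the circumference above each channel's per-radius threshold —
#' a proxy for genotype abundance along the front (dominance of one genotype
#' shows as its fraction approaching 1 while the other's approaches 0).
#'
#' @inheritParams patch_width_curve
#' @return Data frame with `radius_um`, `green_fraction`, `red_fraction`,
#'   `green_reliable`, `red_reliable`.
#' @export
abundance_profile <- function(pair, sweep, pp = preprocess_params()) {
  curve <- patch_width_curve(pair, sweep, pp)
  g <- curve[curve$channel == "green", ]
  r <- curve[curve$channel == "red", ]
  data.frame(radius_um = g$radius_um,
             green_fraction = g$covered_fraction,
             red_fraction = r$covered_fraction,
             green_reliable = g$reliable,
             red_reliable = r$reliable)
}

#' @export
print.patch_width_curve <- function(x, ...) {
  rel <- x$reliable
  cat(sprintf("<patch_width_curve> %d radii (%.0f-%.0f um), %d/%d channel-radii reliable\n",
              length(unique(x$radius_um)), min(x$radius_um), max(x$radius_um),
              sum(rel), length(rel)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Plot a patch-width curve
#'
#' Mean patch width versus radial distance, one line per channel plus the
#' combined summary; unreliable radii are omitted.
#'
#' @param x A `patch_width_curve`.
#' @param ... Further arguments passed to [graphics::plot].
#' @export
plot.patch_width_curve <- function(x, ...) {
  df <- as.data.frame(x)
  df <- df[df$reliable & !is.na(df$mean_patch_width_um), ]
  comb <- combined_width(x)
  comb <- comb[comb$reliable, ]
  if (nrow(df) == 0) {
    graphics::plot(0, 0, type = "n", xlab = "radial distance R (um)",
                   ylab = "mean patch width (um)", main = "no reliable radii", ...)
    return(invisible(x))
  }
  ylim <- range(c(df$mean_patch_width_um, comb$mean_patch_width_um), na.rm = TRUE)
  graphics::plot(range(df$radius_um), ylim, type = "n",
                 xlab = "radial distance R (um)", ylab = "mean patch width (um)", ...)
  for (ch in c("green", "red")) {
    d <- df[df$channel == ch, ]
    graphics::lines(d$radius_um, d$mean_patch_width_um,
                    col = if (ch == "green") "darkcyan" else "magenta3", lwd = 1.5)
  }
  graphics::lines(comb$radius_um, comb$mean_patch_width_um, col = "black", lty = 2)
  graphics::legend("topright", c("green (eGFP)", "red (mCherry)", "combined"),
                   col = c("darkcyan", "magenta3", "black"),
                   lty = c(1, 1, 2), lwd = c(1.5, 1.5, 1), bty = "n")
  invisible(x)
}
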