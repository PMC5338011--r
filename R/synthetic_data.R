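# Synthetic two-channel colony images with exact per-radius ground truth.
# The geometry is stated in polar coordinates as thin radial rings, each
# partitioned into alternating-genotype angular sectors; rendering paints each
# ring and the analysis pipeline can be checked against the recorded sectors.

#' Specification of a synthetic colony image pair
#'
#' Describes a two-genotype colony: a well-mixed inoculation disc surrounded
#' by an annulus of alternating radial strands, rendered into registered
#' green/red channel images with a simple signal/background/noise intensity
#' model.
#'
#' @param mode `"fixed_sectors"` (constant sector angles, so physical widths
#'   grow linearly with radius), `"narrowing"`/`"widening"` (sector count is
#'   re-targeted per ring so mean physical width follows a linear profile
#'   between `width_profile["w_start_um"]` and `width_profile["w_end_um"]`),
#'   or `"boundary_walk"` (annihilating Gaussian random walk of sector
#'   boundaries, emulating neutral demixing; optional branching sustains
#'   intermixing).
#' @param image_size_px Side of the square image in pixels; `NA` sizes the
#'   image to hold the colony plus a small margin.
#' @param pixel_size_um Pixel size in micrometres.
#' @param inoc_radius_um Inoculation-disc radius (default 1000, i.e. the
#'   ~2 mm diameter droplet zone of the source experiments).
#' @param colony_radius_um Outer colony radius (> `inoc_radius_um`).
#' @param n_strands_initial Even number of alternating strands at the inner
#'   edge (fixed_sectors / boundary_walk).
#' @param width_profile Named numeric `c(w_start_um=, w_end_um=)`: target mean
#'   physical strand width at the inner and outer radius (narrowing/widening).
#' @param walk_sigma Boundary-walk step scale; per `walk_substep_um` of radial
#'   growth each boundary angle takes a Gaussian step of sd
#'   `walk_sigma / sqrt(R)`, keeping arc-scale diffusion comparable across
#'   radii. Default 12, calibrated so an 8-strand colony typically demixes
#'   completely within ~1-1.5 mm of expansion (the competition phenomenology).
#' @param walk_substep_um Radial distance per walk step (default 10); the
#'   recorded truth rings advance in `ring_dr_um`, which may span several walk
#'   steps.
#' @param branching_rate New-boundary-pair creation rate per micrometre of
#'   front per micrometre of radial growth (boundary_walk). Default 0.
#' @param signal_level,background_level,noise_sd Intensity model: a genotype's
#'   own channel reads `signal_level`, elsewhere `background_level`, plus
#'   additive Gaussian noise (sd `noise_sd`), clipped to the bit-depth range.
#' @param blur_sigma_um Optional Gaussian blur (applied before noise); 0 = off.
#' @param bit_depth 8 or 16.
#' @param speckle_grain_um Grain size of the 1:1 inoculation-disc speckle.
#' @param coffee_ring Logical: boost intensity at the inoculation-disc rim
#'   (drying-droplet "coffee-ring" accumulation).
#' @param pioneer_ring_um Width of an optional single-genotype (red) band at
#'   the colony periphery, for exercising no-crossing handling; 0 = off.
#' @param ring_dr_um Radial ring thickness of the ground-truth lattice.
#' @param seed Integer RNG seed; all generator randomness flows through it.
#' @return List of class `synthetic_colony_spec`.
#' @export
synthetic_colony_spec <- function(mode = c("fixed_sectors", "narrowing",
                                           "widening", "boundary_walk"),
                                  image_size_px = NA,
                                  pixel_size_um = 10,
                                  inoc_radius_um = 1000,
                                  colony_radius_um = 4000,
                                  n_strands_initial = 8L,
                                  width_profile = c(w_start_um = 100, w_end_um = 10),
                                  walk_sigma = 12,
                                  walk_substep_um = 10,
                                  branching_rate = 0,
                                  signal_level = 200,
                                  background_level = 20,
                                  noise_sd = 10,
                                  blur_sigma_um = 0,
                                  bit_depth = 8L,
                                  speckle_grain_um = 10,
                                  coffee_ring = FALSE,
                                  pioneer_ring_um = 0,
                                  ring_dr_um = 10,
                                  seed = 1L) {
  mode <- match.arg(mode)
  n_strands_initial <- as.integer(n_strands_initial)
  if (colony_radius_um <= inoc_radius_um)
    stop("colony_radius_um must exceed inoc_radius_um")
  if (n_strands_initial < 2L || n_strands_initial %% 2L != 0L)
    stop("n_strands_initial must be an even integer >= 2")
  if (signal_level <= background_level || background_level < 0)
    stop("need signal_level > background_level >= 0")
  if (is.na(image_size_px))
    image_size_px <- 2L * as.integer(ceiling(colony_radius_um / pixel_size_um)) + 5L
  if (image_size_px * pixel_size_um < 2 * colony_radius_um)
    stop("image_size_px too small to hold the colony")
  if (max(signal_level, background_level) > 2^bit_depth - 1)
    stop("intensity levels exceed bit depth range")
  structure(list(mode = mode, image_size_px = as.integer(image_size_px),
                 pixel_size_um = pixel_size_um, inoc_radius_um = inoc_radius_um,
                 colony_radius_um = colony_radius_um,
                 n_strands_initial = n_strands_initial,
                 width_profile = width_profile, walk_sigma = walk_sigma,
                 walk_substep_um = walk_substep_um,
                 branching_rate = branching_rate, signal_level = signal_level,
                 background_level = background_level, noise_sd = noise_sd,
                 blur_sigma_um = blur_sigma_um, bit_depth = as.integer(bit_depth),
                 speckle_grain_um = speckle_grain_um, coffee_ring = coffee_ring,
                 pioneer_ring_um = pioneer_ring_um, ring_dr_um = ring_dr_um,
                 seed = as.integer(seed)),
            class = "synthetic_colony_spec")
}

# Evaluate an expression with a locally seeded RNG, restoring global state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

opposite_genotype <- function(g) ifelse(g == "green", "red", "green")

# Ring lattice: ring k covers [inoc + (k-1) dr, inoc + k dr), midpoint radius
# r_k. Sector tables are lists with `ang` (boundary angles, circularly
# increasing after mod 2*pi), `gen_after` (genotype of the sector CCW of each
# boundary) and `survivor` (genotype of the whole ring when no boundary
# remains).
ring_radii <- function(spec) {
  K <- ceiling((spec$colony_radius_um - spec$inoc_radius_um) / spec$ring_dr_um)
  spec$inoc_radius_um + (seq_len(K) - 0.5) * spec$ring_dr_um
}

equal_sector_ring <- function(n) {
  list(ang = 2 * pi * (seq_len(n) - 1L) / n,
       gen_after = rep(c("green", "red"), length.out = n),
       survivor = NA_character_)
}

build_rings_deterministic <- function(spec) {
  radii <- ring_radii(spec)
  if (spec$mode == "fixed_sectors") {
    ring <- equal_sector_ring(spec$n_strands_initial)
    return(lapply(radii, function(r) ring))
  }
  w0 <- spec$width_profile[["w_start_um"]]
  w1 <- spec$width_profile[["w_end_um"]]
  if (spec$mode == "widening" && w1 < w0) { tmp <- w0; w0 <- w1; w1 <- tmp }
  if (spec$mode == "narrowing" && w1 > w0) { tmp <- w0; w0 <- w1; w1 <- tmp }
  lapply(radii, function(r) {
    f <- (r - spec$inoc_radius_um) / (spec$colony_radius_um - spec$inoc_radius_um)
    w <- w0 + f * (w1 - w0)
    n <- 2L * max(1L, as.integer(round(pi * r / w)))
    equal_sector_ring(n)
  })
}

# One annihilating-walk update of a sector ring across one walk substep. Gaps are
# updated from the angular steps; any non-positive gap means the two flanking
# boundaries crossed, and both annihilate (their sector vanishes; its
# neighbours, which share a genotype, merge). Branching inserts a thin sliver
# of the opposite genotype at a uniform angle.
walk_ring_step <- function(ring, r, spec, dr) {
  ang <- ring$ang
  gen_after <- ring$gen_after
  m <- length(ang)
  if (m > 0) {
    sd_step <- spec$walk_sigma / sqrt(r)
    step <- if (sd_step > 0)  # sd 0 must not consume RNG draws (determinism)
      pmin(pmax(stats::rnorm(m, 0, sd_step), -pi / 2), pi / 2)
    else rep(0, m)
    nxt <- c(seq_len(m)[-1], 1L)
    gaps <- (ang[nxt] - ang) %% (2 * pi)
    gaps <- gaps + step[nxt] - step
    a <- ang + step
    # annihilate crossed pairs until all gaps positive
    while (length(a) > 2 && any(gaps <= 0)) {
      m <- length(a)
      j <- which(gaps <= 0)[1]
      jn <- j %% m + 1L
      jp <- (j - 2L) %% m + 1L
      gaps[jp] <- gaps[jp] + gaps[j] + gaps[jn]
      drop <- c(j, jn)
      a <- a[-drop]; gen_after <- gen_after[-drop]; gaps <- gaps[-c(j, jn)]
      # after dropping boundary j and jn, sector jp's gap was merged in place
    }
    if (length(a) == 2 && any(gaps <= 0)) {
      j <- which(gaps <= 0)[1]           # sector j vanished; the other survives
      ring$survivor <- gen_after[j %% 2L + 1L]
      a <- numeric(0); gen_after <- character(0)
    }
    if (length(a) > 0) {
      a <- a %% (2 * pi)
      ord <- order(a)
      ang <- a[ord]; gen_after <- gen_after[ord]
    } else ang <- numeric(0)
  }
  # branching: insert a new boundary pair with probability rate * front * dr
  if (spec$branching_rate > 0 &&
      stats::runif(1) < min(1, spec$branching_rate * 2 * pi * r * dr)) {
    theta_new <- stats::runif(1, 0, 2 * pi)
    delta <- max(2 * spec$pixel_size_um, 5) / r
    m <- length(ang)
    if (m == 0) {
      host <- if (is.na(ring$survivor)) "green" else ring$survivor
      ang <- c(theta_new, theta_new + delta) %% (2 * pi)
      gen_after <- c(opposite_genotype(host), host)
      ord <- order(ang); ang <- ang[ord]; gen_after <- gen_after[ord]
      ring$survivor <- NA_character_
    } else {
      j <- findInterval(theta_new, ang)
      if (j == 0) j <- m
      host <- gen_after[j]
      jn <- j %% m + 1L
      gap <- (ang[jn] - ang[j]) %% (2 * pi)
      if (gap == 0) gap <- 2 * pi
      offset <- (theta_new - ang[j]) %% (2 * pi)
      if (offset + delta < gap) {  # skip when the sliver would not fit
        ins <- c(theta_new, theta_new + delta) %% (2 * pi)
        ang <- c(ang, ins)
        gen_after <- c(gen_after, opposite_genotype(host), host)
        ord <- order(ang); ang <- ang[ord]; gen_after <- gen_after[ord]
      }
    }
  }
  ring$ang <- ang
  ring$gen_after <- gen_after
  ring
}

build_rings_walk <- function(spec) {
  radii <- ring_radii(spec)
  rings <- vector("list", length(radii))
  ring <- equal_sector_ring(spec$n_strands_initial)
  rings[[1]] <- ring
  n_sub <- max(1L, as.integer(round(spec$ring_dr_um / spec$walk_substep_um)))
  dr_sub <- spec$ring_dr_um / n_sub
  r_cur <- radii[1]
  for (k in seq_along(radii)[-1]) {
    for (j in seq_len(n_sub)) {
      r_cur <- r_cur + dr_sub
      ring <- walk_ring_step(ring, r_cur, spec, dr_sub)
    }
    rings[[k]] <- ring
  }
  rings
}

rings_to_ground_truth <- function(rings, spec) {
  radii <- ring_radii(spec)
  rows <- lapply(seq_along(rings), function(k) {
    rg <- rings[[k]]
    m <- length(rg$ang)
    if (m == 0) {
      surv <- if (is.na(rg$survivor)) "green" else rg$survivor
      return(data.frame(ring = k, radius_um = radii[k], theta_start = 0,
                        theta_end = 2 * pi, genotype = surv,
                        stringsAsFactors = FALSE))
    }
    nxt <- c(seq_len(m)[-1], 1L)
    ends <- rg$ang[nxt]
    ends[m] <- rg$ang[1] + 2 * pi  # wrap sector closes past 2*pi
    data.frame(ring = k, radius_um = radii[k], theta_start = rg$ang,
               theta_end = ends, genotype = rg$gen_after,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("ground_truth", "data.frame"),
            inoc_radius_um = spec$inoc_radius_um,
            colony_radius_um = spec$colony_radius_um,
            ring_dr_um = spec$ring_dr_um)
}

# Separable Gaussian blur with edge replication, kernel radius 3 sigma.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  rad <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-rad:rad, sd = sigma_px)
  k <- k / sum(k)
  shift_rows <- function(x, s) {
    n <- nrow(x)
    idx <- pmin(pmax(seq_len(n) + s, 1L), n)
    x[idx, , drop = FALSE]
  }
  pass <- function(x) {
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * shift_rows(x, i - rad - 1L)
    out
  }
  t(pass(t(pass(m))))
}

render_colony <- function(spec, rings) {
  S <- spec$image_size_px
  px <- spec$pixel_size_um
  ctr <- (S + 1) / 2
  xs <- ((seq_len(S)) - ctr) * px
  x_um <- matrix(xs, S, S, byrow = TRUE)       # +x = +col
  y_um <- matrix(-xs, S, S)                    # +y = -row
  r_um <- sqrt(x_um^2 + y_um^2)
  theta <- atan2(y_um, x_um) %% (2 * pi)
  gen <- matrix(0L, S, S)                      # 0 none, 1 green, 2 red

  # inoculation disc: 1:1 speckle on a square grain lattice
  grain <- spec$speckle_grain_um
  bmin <- floor(-spec$inoc_radius_um / grain) - 1L
  bmax <- floor(spec$inoc_radius_um / grain) + 1L
  nb <- bmax - bmin + 1L
  bits <- matrix(stats::runif(nb * nb) < 0.5, nb, nb)
  in_disc <- which(r_um <= spec$inoc_radius_um)
  bi <- floor(x_um[in_disc] / grain) - bmin + 1L
  bj <- floor(y_um[in_disc] / grain) - bmin + 1L
  gen[in_disc] <- ifelse(bits[cbind(bi, bj)], 1L, 2L)

  # annulus: per-ring alternating sectors
  K <- length(rings)
  ring_idx <- floor((r_um - spec$inoc_radius_um) / spec$ring_dr_um) + 1
  in_annulus <- r_um > spec$inoc_radius_um & r_um <= spec$colony_radius_um
  ring_idx[!in_annulus] <- NA
  ring_idx <- pmin(ring_idx, K)
  for (k in seq_len(K)) {
    pix <- which(!is.na(ring_idx) & ring_idx == k)
    if (length(pix) == 0) next
    rg <- rings[[k]]
    m <- length(rg$ang)
    if (m == 0) {
      surv <- if (is.na(rg$survivor)) "green" else rg$survivor
      gen[pix] <- if (surv == "green") 1L else 2L
    } else {
      s <- findInterval(theta[pix], rg$ang)
      s[s == 0L] <- m
      gen[pix] <- ifelse(rg$gen_after[s] == "green", 1L, 2L)
    }
  }

  # optional single-genotype pioneer band at the periphery
  if (spec$pioneer_ring_um > 0) {
    band <- which(r_um > spec$colony_radius_um - spec$pioneer_ring_um &
                    r_um <= spec$colony_radius_um)
    gen[band] <- 2L
  }

  bg <- spec$background_level
  sig <- spec$signal_level
  g_px <- matrix(bg, S, S); g_px[gen == 1L] <- sig
  r_px <- matrix(bg, S, S); r_px[gen == 2L] <- sig
  if (spec$coffee_ring) {
    rim <- which(r_um > spec$inoc_radius_um * 0.9 & r_um <= spec$inoc_radius_um)
    boost <- min(1.25, (2^spec$bit_depth - 1) / sig)
    g_px[rim] <- g_px[rim] * boost
    r_px[rim] <- r_px[rim] * boost
  }
  if (spec$blur_sigma_um > 0) {
    g_px <- gaussian_blur(g_px, spec$blur_sigma_um / px)
    r_px <- gaussian_blur(r_px, spec$blur_sigma_um / px)
  }
  top <- 2^spec$bit_depth - 1
  if (spec$noise_sd > 0) {
    g_px <- g_px + stats::rnorm(S * S, 0, spec$noise_sd)
    r_px <- r_px + stats::rnorm(S * S, 0, spec$noise_sd)
  }
  g_px <- round(pmin(pmax(g_px, 0), top))
  r_px <- round(pmin(pmax(r_px, 0), top))
  colony_image_pair(
    channel_image(g_px, spec$bit_depth, px, "green"),
    channel_image(r_px, spec$bit_depth, px, "red"),
    c(ctr, ctr), spec$inoc_radius_um)
}

#' Generate a sector-structured synthetic colony
#'
#' Renders a colony whose annulus is partitioned into alternating-genotype
#' angular sectors following the spec's `fixed_sectors`, `narrowing` or
#' `widening` mode, plus a well-mixed speckled inoculation disc. Deterministic
#' given the spec's seed.
#'
#' @param spec A [synthetic_colony_spec] with a deterministic-sector mode.
#' @return List with `pair` (a [colony_image_pair]) and `truth` (a
#'   `ground_truth` data frame: one row per ring sector with `ring`,
#'   `radius_um` (ring midpoint), `theta_start`, `theta_end`, `genotype`).
#' @export
generate_sector_colony <- function(spec) {
  stopifnot(inherits(spec, "synthetic_colony_spec"))
  if (!spec$mode %in% c("fixed_sectors", "narrowing", "widening"))
    stop("generate_sector_colony requires mode fixed_sectors, narrowing or widening")
  rings <- build_rings_deterministic(spec)
  with_local_seed(spec$seed,
                  list(pair = render_colony(spec, rings),
                       truth = rings_to_ground_truth(rings, spec)))
}

#' Generate a boundary-random-walk synthetic colony
#'
#' Sector boundaries start as `n_strands_initial` equally spaced points on the
#' inoculation circle and diffuse angularly as the radius grows; boundaries
#' that cross annihilate in pairs (their sector vanishes — neutral demixing),
#' and, at rate `branching_rate`, new boundary pairs are inserted (splitting a
#' sector — sustained intermixing). A deliberately minimal stand-in for
#' drift-driven sector coarsening whose ground truth is exactly known per
#' radius.
#'
#' @param spec A [synthetic_colony_spec] with `mode = "boundary_walk"`.
#' @return As [generate_sector_colony].
#' @export
generate_boundary_walk_colony <- function(spec) {
  stopifnot(inherits(spec, "synthetic_colony_spec"))
  if (spec$mode != "boundary_walk")
    stop("generate_boundary_walk_colony requires mode boundary_walk")
  with_local_seed(spec$seed, {
    rings <- build_rings_walk(spec)
    list(pair = render_colony(spec, rings),
         truth = rings_to_ground_truth(rings, spec))
  })
}

#' Analytic mean strand width from ground truth
#'
#' Mean over a genotype's sectors of angular extent times radius, at the ring
#' containing the requested radius. A genotype with no sector at that radius
#' (annihilated) gets `NA`, mirroring the pipeline's no-crossing case.
#'
#' @param gt A `ground_truth` data frame.
#' @param radius_um Radius inside the ground-truth range.
#' @return Named numeric `c(green =, red =)` mean widths in micrometres.
#' @export
truth_patch_width <- function(gt, radius_um) {
  stopifnot(inherits(gt, "ground_truth"))
  inoc <- attr(gt, "inoc_radius_um")
  dr <- attr(gt, "ring_dr_um")
  if (radius_um < inoc || radius_um > attr(gt, "colony_radius_um"))
    stop("radius_um outside the ground-truth range")
  k <- min(max(1L, floor((radius_um - inoc) / dr) + 1L), max(gt$ring))
  sec <- gt[gt$ring == k, ]
  out <- c(green = NA_real_, red = NA_real_)
  for (g in c("green", "red")) {
    ext <- sec$theta_end[sec$genotype == g] - sec$theta_start[sec$genotype == g]
    if (length(ext) > 0) out[g] <- mean(ext) * radius_um
  }
  out
}

#' Ground-truth boundary count per ring
#'
#' Number of sector boundaries at each ring radius (a full-circle sector
#' counts as zero boundaries). Non-increasing in radius for a boundary walk
#' without branching.
#'
#' @param gt A `ground_truth` data frame.
#' @return Data frame with `radius_um` and `n_boundaries`.
#' @export
truth_boundary_counts <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  agg <- stats::aggregate(gt$theta_start, by = list(ring = gt$ring,
                                                    radius_um = gt$radius_um),
                          FUN = length)
  full <- stats::aggregate(gt$theta_end - gt$theta_start,
                           by = list(ring = gt$ring), FUN = max)
  n <- ifelse(full$x >= 2 * pi - 1e-12, 0L, agg$x)
  data.frame(radius_um = agg$radius_um[order(agg$ring)],
             n_boundaries = n[order(agg$ring)])
}

#' Write ground truth to CSV
#'
#' @param gt A `ground_truth` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.csv(as.data.frame(gt)[, c("radius_um", "theta_start",
                                         "theta_end", "genotype")],
                   path, row.names = FALSE)
  invisible(path)
}
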