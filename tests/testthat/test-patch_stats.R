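test_that("otsu_threshold equals the exhaustive brute-force maximizer", {
  # deterministic hand case from the contract examples
  v <- c(1, 1, 2, 2, 8, 9, 9)
  expect_equal(as.numeric(otsu_threshold(v)), oracle_otsu(v))
  # perfectly bimodal: any interior cut separates; smallest maximizing edge
  v2 <- c(rep(0, 10), rep(255, 10))
  t2 <- as.numeric(otsu_threshold(v2))
  expect_equal(t2, oracle_otsu(v2))
  expect_gt(t2, 0); expect_lt(t2, 255)
  expect_equal(sum(v2 > t2), 10)
  # random property sweep, mixed unimodal/bimodal, exact cut agreement
  set.seed(42)
  for (i in 1:60) {
    n <- sample(10:400, 1)
    v <- if (i %% 2 == 0) {
      c(rnorm(n, 50, 10), rnorm(n, 180, 15))
    } else {
      runif(n, 0, 255)
    }
    expect_equal(as.numeric(otsu_threshold(v)), oracle_otsu(v))
  }
})

test_that("otsu_threshold degenerate and effectiveness behaviour", {
  t0 <- otsu_threshold(c(5, 5, 5))
  expect_equal(as.numeric(t0), 5)
  expect_true(attr(t0, "degenerate"))
  # bimodal sample: effectiveness near 1; unimodal noise: near 2/pi
  set.seed(7)
  tb <- otsu_threshold(c(rnorm(500, 20, 3), rnorm(500, 200, 3)))
  expect_gt(attr(tb, "effectiveness"), 0.95)
  tu <- otsu_threshold(rnorm(2000, 100, 10))
  expect_lt(abs(attr(tu, "effectiveness") - 2 / pi), 0.05)
  expect_error(otsu_threshold(numeric(0)), "non-empty")
})

test_that("corrected_signal is plain subtraction with sign guarantees", {
  expect_equal(corrected_signal(c(10, 20), 15), c(-5, 5))
  v <- c(3, 9, 4, 7)
  expect_true(all(corrected_signal(v, min(v)) >= 0))
  expect_true(all(corrected_signal(v, max(v)) <= 0))
  expect_error(corrected_signal(v, NA), "finite")
})

test_that("circular_runs matches brute force on every circle up to length 10", {
  # exhaustive check on shorter circles here; the acceptance suite extends to 12
  mismatches <- 0L
  for (n in 1:10) {
    grids <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
    for (row in seq_len(nrow(grids))) {
      above <- as.logical(grids[row, ])
      got <- circular_runs(ifelse(above, 1, -1), spacing_um = 2)
      want <- oracle_circular_runs(above, spacing_um = 2)
      if (!identical(got$n_crossings, want$n_crossings) ||
          !isTRUE(all.equal(sort(got$run_lengths_um),
                            sort(want$run_lengths_um))))
        mismatches <- mismatches + 1L
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("circular_runs contract examples", {
  # signs [+,+,-,+,-,-], spacing 10 -> above runs {20, 10} (one wraps), 4 crossings
  r <- circular_runs(c(1, 1, -1, 1, -1, -1), 10)
  expect_identical(r$n_crossings, 4L)
  expect_equal(sort(r$run_lengths_um), c(10, 20))
  # alternating length 8 -> four runs of one spacing, 8 crossings
  r2 <- circular_runs(rep(c(1, -1), 4), 3)
  expect_identical(r2$n_crossings, 8L)
  expect_equal(r2$run_lengths_um, rep(3, 4))
  # all above: single full-circumference run; exact zeros fall below
  r3 <- circular_runs(rep(1, 10), 5)
  expect_identical(r3$n_crossings, 0L)
  expect_equal(r3$run_lengths_um, 50)
  r4 <- circular_runs(c(0, 0, 1, 0), 5)
  expect_equal(r4$run_lengths_um, 5)
})

test_that("patch_stats_at_radius recovers alternating sectors at one radius", {
  # synthetic profile: 8 equal alternating sectors at R = 200 um, noiseless
  R <- 200
  n <- 400
  th <- 2 * pi * (0:(n - 1)) / n
  sector <- floor(th / (2 * pi / 8))
  green <- ifelse(sector %% 2 == 0, 200, 20)
  profile <- structure(list(radius_um = R, thetas = th,
                            green_values = green,
                            red_values = 220 - green,
                            spacing_um = 2 * pi * R / n),
                       class = "radial_profile")
  st <- patch_stats_at_radius(profile)
  for (ch in list(st$green, st$red)) {
    expect_identical(ch$n_patches, 4L)
    expect_identical(ch$n_crossings, 8L)
    expect_equal(ch$mean_patch_width_um, 2 * pi * R / 8,
                 tolerance = 2 * profile$spacing_um / (2 * pi * R / 8))
    expect_equal(ch$covered_fraction, 0.5, tolerance = 0.02)
    expect_true(ch$reliable)
  }
  # invariant: n_crossings == 2 * n_patches when 0 < coverage < 1
  expect_identical(st$green$n_crossings, 2L * st$green$n_patches)
})

test_that("no-crossing circles are unreliable with coverage 1 / 0 against global thresholds", {
  n <- 64
  profile <- structure(list(radius_um = 100, thetas = 2 * pi * (0:(n - 1)) / n,
                            green_values = rep(200, n),
                            red_values = rep(20, n),
                            spacing_um = 2 * pi * 100 / n),
                       class = "radial_profile")
  st <- patch_stats_at_radius(profile, global_thresholds = c(green = 110, red = 110))
  expect_false(st$green$reliable)
  expect_equal(st$green$covered_fraction, 1)
  expect_identical(st$green$n_crossings, 0L)
  expect_equal(st$green$mean_patch_width_um, 2 * pi * 100)  # full circumference
  expect_false(st$red$reliable)
  expect_equal(st$red$covered_fraction, 0)
  expect_true(is.na(st$red$mean_patch_width_um))
  # noisy unimodal circle is also degenerate (effectiveness guard); use a
  # pipeline-realistic circle length (short noise circles can fluctuate above
  # the cutoff, see the vignette)
  set.seed(9)
  n2 <- 512
  profile2 <- structure(list(radius_um = 500,
                             thetas = 2 * pi * (0:(n2 - 1)) / n2,
                             green_values = rnorm(n2, 200, 8),
                             red_values = rnorm(n2, 20, 8),
                             spacing_um = 2 * pi * 500 / n2),
                        class = "radial_profile")
  st2 <- patch_stats_at_radius(profile2, global_thresholds = c(green = 110, red = 110))
  expect_false(st2$green$reliable)
  expect_equal(st2$green$covered_fraction, 1)
  expect_false(st2$red$reliable)
  expect_equal(st2$red$covered_fraction, 0)
})

test_that("patch_width_curve: conservation, scaling with R, channel swap", {
  spec <- synthetic_colony_spec(mode = "fixed_sectors", pixel_size_um = 4,
                                inoc_radius_um = 100, colony_radius_um = 800,
                                n_strands_initial = 8, noise_sd = 0, seed = 5)
  gen <- generate_sector_colony(spec)
  sw <- radial_sweep_params(r_start_um = 160, r_end_um = 720, dr_um = 80)
  pp <- preprocess_params(1, 10)
  curve <- patch_width_curve(gen$pair, sw, pp)
  df <- as.data.frame(curve)
  # conservation: above + below = circumference within one sample; here via
  # mean width * n_patches = covered_fraction * 2*pi*R
  for (i in seq_len(nrow(df))) {
    expect_equal(df$mean_patch_width_um[i] * df$n_patches[i],
                 df$covered_fraction[i] * 2 * pi * df$radius_um[i],
                 tolerance = 0.02)
  }
  # fixed angular pattern: width proportional to R (slope = 2*pi/8 per genotype)
  g <- df[df$channel == "green", ]
  fit <- stats::lm(mean_patch_width_um ~ 0 + radius_um, data = g)
  expect_equal(unname(stats::coef(fit)), 2 * pi / 8, tolerance = 0.03)
  # channel swap equivariance
  swapped_pair <- colony_image_pair(
    channel_image(gen$pair$red$pixels, 8L, 4, "green"),
    channel_image(gen$pair$green$pixels, 8L, 4, "red"),
    gen$pair$center_px, gen$pair$inoc_radius_um)
  curve2 <- as.data.frame(patch_width_curve(swapped_pair, sw, pp))
  for (col in c("mean_patch_width_um", "n_patches", "covered_fraction")) {
    expect_equal(curve2[curve2$channel == "green", col],
                 df[df$channel == "red", col])
    expect_equal(curve2[curve2$channel == "red", col],
                 df[df$channel == "green", col])
  }
})

test_that("patch_width_curve is invariant under 90-degree rotation", {
  spec <- synthetic_colony_spec(mode = "fixed_sectors", pixel_size_um = 4,
                                inoc_radius_um = 100, colony_radius_um = 600,
                                n_strands_initial = 6, noise_sd = 10, seed = 8)
  gen <- generate_sector_colony(spec)
  sw <- radial_sweep_params(r_start_um = 150, r_end_um = 550, dr_um = 100)
  pp <- preprocess_params(1, 10)
  base <- as.data.frame(patch_width_curve(gen$pair, sw, pp))
  rot <- as.data.frame(patch_width_curve(rotate90(gen$pair), sw, pp))
  expect_equal(rot$n_crossings, base$n_crossings)
  expect_equal(rot$mean_patch_width_um, base$mean_patch_width_um, tolerance = 1e-8)
  expect_equal(rot$covered_fraction, base$covered_fraction, tolerance = 1e-8)
})

test_that("abundance_profile reports coverage per genotype", {
  spec <- synthetic_colony_spec(mode = "fixed_sectors", pixel_size_um = 4,
                                inoc_radius_um = 100, colony_radius_um = 600,
                                n_strands_initial = 8, noise_sd = 0, seed = 2)
  gen <- generate_sector_colony(spec)
  ab <- abundance_profile(gen$pair,
                          radial_sweep_params(r_start_um = 200, r_end_um = 500,
                                              dr_um = 100),
                          preprocess_params(1, 10))
  expect_equal(ab$green_fraction, rep(0.5, nrow(ab)), tolerance = 0.02)
  expect_equal(ab$red_fraction, rep(0.5, nrow(ab)), tolerance = 0.02)
  expect_true(all(ab$green_reliable))
})
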