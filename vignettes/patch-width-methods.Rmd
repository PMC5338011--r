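---
title: "Measuring clonal patch widths along an expanding colony front"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring clonal patch widths along an expanding colony front}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonypatch)
```

## The model and its assumptions

A two-genotype colony expanding radially from a circular inoculum organizes
into radial strands: contiguous arcs of the front occupied by one genotype.
`colonypatch` measures the mean strand (patch) width as a function of radial
distance R, per fluorescence channel, under these assumptions:

* the two channel images are **registered** (sequential acquisition on a
  fixed stage) and share pixel size; no alignment is attempted;
* expansion is **radial from a circular inoculation zone** whose center and
  radius the user supplies (or fits from a binary mask with
  `fit_inoc_circle()`); non-circular fronts are out of scope;
* a strand is operationally **a maximal arc where the threshold-corrected
  fluorescence of a channel exceeds zero**, with the threshold recomputed at
  every radius. Channels are analyzed independently; arcs bright in both
  channels count toward both (no arbitration rule is imposed for
  double-positive pixels);
* width is **arc length along the front line**, not chord length.

The per-radius pipeline is: bicubic coarsening of both images → circular
sampling at radius R (bilinear interpolation, uniform angles) → circular
boxcar smoothing over ≈10 μm of arc → per-circle Otsu threshold → threshold
subtraction → circular crossing statistics (runs and sign changes).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `coarsen_factor` | 8 | – | resolution reduction used by the original quantification; cuts computation without changing measured patterns |
| `smooth_window_um` | 10 | μm | arc-length smoothing of each circular profile; suppresses pixel noise below the strand scale |
| `dr_um` | 10 | μm | radial step of the sweep |
| `target_arc_spacing_um` | one coarsened pixel | μm | angular sampling density; Nyquist-adequate for ≥10 μm strands |
| `eta_min` | 0.70 | – | Otsu-effectiveness cutoff below which a circle is declared degenerate (see below) |
| `n_bins` (Otsu) | 256 | – | 8-bit histogram convention, as in MATLAB `graythresh` |

The angular sample count at radius R is `max(8, n)` with `n` rounded to a
multiple of 4, so that a 90° rotation of the input image maps the sample set
onto itself exactly — rotation invariance of the whole curve then holds to
machine precision and is asserted in the tests.

## Numerical choices

**Otsu on the circle, not the image.** The threshold is recomputed from each
circle's own intensities (256 equal-width bins over the circle's [min, max]),
making the statistic adaptive to the radial intensity decay of colony
images. Ties in the between-class variance are broken toward the smallest
maximizing bin edge; values equal to the threshold fall in the lower class,
so above-threshold runs have strictly positive corrected signal.

**Degenerate circles.** A per-circle min–max Otsu always returns *some* cut,
even for a circle that is pure noise around a single level — it would split
the noise roughly in half and fabricate dozens of spurious crossings. The
biologically meaningful reading of such a circle is "no two-genotype
alternation here": a front fully owned by one genotype, or background beyond
the colony edge. We therefore compute Otsu's effectiveness metric
η = σ²_b(t*)/σ²_tot (the second output of MATLAB's `graythresh`) and declare
the circle degenerate when η < 0.70. The cutoff sits between two analytic
anchors: a unimodal Gaussian sample has η = 2/π ≈ 0.64 regardless of its
variance, while the weakest genuinely bimodal profile the pipeline should
still resolve — a sinusoidal alternation left by smoothing strands about one
window wide — has η ≈ 0.81. Empirically, noise-only circles in the synthetic
worlds measure η ∈ [0.62, 0.65] and the weakest real alternation ≥ 0.77.
The guard is calibrated for circles of a few hundred samples or more; on very
short circles (tens of samples) η fluctuates upward and the guard loses
power, which is irrelevant at colony scale (such circles fit inside the
inoculation zone). Degenerate circles are classified against the channel's
**whole-image** Otsu threshold — so a uniformly bright front reads coverage 1
(one full-circumference run) and a vanished genotype reads coverage 0 — and
are always flagged `reliable = FALSE` and excluded from curve summaries: this
reproduces the loss of measurable patch width "due to the absence of
crossings" once demixing is complete.

**Coarsening.** Separable Keys bicubic (a = −0.5) with the kernel widened by
the integer factor as an antialias prefilter, edge-replicated and
weight-normalized; this is the standard resize behaviour of the MATLAB-style
"bicubic interpolation of 16 pixels". Bicubic overshoot at sharp edges is
clipped back to the valid intensity range.

**Smoothing** is a uniform (boxcar) circular moving average of
`round(window/spacing)` samples, forced odd — the simplest kernel that
preserves the circular mean exactly and never widens the value range. The
field does not dictate a kernel; smoothing is applied to the 1D circle
samples before thresholding (fixed, documented order), not to the 2D image.

**Coordinates.** Matrices are indexed 1-based (R convention), origin top-left;
angle 0 points along +column, counter-clockwise positive with +y = −row.
Physical units are μm via the user-supplied pixel size; resolution tags in
TIFF files are deliberately ignored (tile-scan exports often carry wrong
ones).

**Combined curve.** Per radius, the two channels' mean widths are combined
weighted by their patch counts — equivalent to pooling all patches of both
genotypes — over reliable channels only. Per-channel curves remain the
primary output.

## What the synthetic generator emulates — and what it does not

`generate_sector_colony()` paints a speckled 1:1 inoculation disc
(grain 10 μm, emulating a well-mixed inoculum; optional "coffee-ring" rim
boost) surrounded by an annulus of alternating-genotype angular sectors laid
out on a lattice of thin radial rings, with an 8-bit intensity model
(signal 200, background 20, Gaussian noise sd 10 by default — comfortably
Otsu-separable but non-trivial), optional Gaussian blur (applied before
noise, as an optical PSF would act), and an optional single-genotype pioneer
band at the periphery. Modes:

* `fixed_sectors` — constant sector angles; physical widths grow exactly
  linearly with R (slope = sector angle);
* `narrowing` / `widening` — the per-ring sector count is retargeted so the
  mean physical width follows a linear profile between `w_start_um` and
  `w_end_um` (the mutualism-like and merging regimes);
* `boundary_walk` — sector boundaries diffuse angularly (Gaussian step of sd
  `walk_sigma/√R` per 10 μm substep, truncated at ±π/2), annihilate in pairs
  when adjacent boundaries cross, and optionally branch at a per-front-length
  rate. With zero branching this is neutral drift: boundary count is
  non-increasing and the colony coarsens toward a single genotype.

The ground truth (exact sector table per ring, hence exact per-genotype mean
width at any radius) is recorded alongside the images, so parameter-recovery
tests compare pipeline output against analytic truth rather than against the
pipeline itself.

Deliberate non-realisms: no mechanistic growth (no nutrient fields, shoving
or cross-feeding kinetics); boundaries are staircase-constant within each
recording ring, so at demixing-capable step sizes adjacent rings can be
offset by large arcs — analyses of walk colonies should sample at ring
centers with the sweep step matched to `ring_dr_um` (the tests do). The
default `walk_sigma = 12` was calibrated once, on ground truth alone, so that
an 8-strand colony at the experimental scale (1 mm inoculum radius) demixes
completely within ~1–1.5 mm of expansion in most runs — the reported
competition phenomenology — and was not revisited afterwards. A green test on
synthetic colonies therefore establishes that the *measurement* is correct
for fronts with crisp two-level sectors plus noise and blur; it does not
establish anything about real colonies' growth dynamics, uneven illumination,
or autofluorescence, none of which the generator emulates.

## Design choices where the design was open

* **Auto brightness/contrast stand-in:** `to_8bit()` defaults to a
  percentile window (0.35%, 99.65%) — an explicit, reproducible approximation
  of interactive auto-adjustment; `minmax` is available.
* **Radial step, arc density, interpolation:** not dictated by the source
  procedure; defaults (10 μm, one coarsened pixel, bilinear) are declared,
  not inferred.
* **Degenerate handling** (above) follows the behavioural contract — loss of
  crossings must be detected under realistic noise — rather than a literal
  min–max Otsu, which cannot detect it.
* **Exact zeros** of the corrected signal belong to the below class, keeping
  above-runs strictly positive.
* **Sub-resolution branching slivers** are inserted with an initial angular
  width of two pixels of arc, the smallest width the renderer can represent.

## Known limitations

* Strands narrower than ~3 arc samples are below the resolution floor; the
  recovery guarantee (≤10% error at signal/background ≥ 5) holds only above
  it.
* The degeneracy guard needs a few hundred samples per circle to be sharp.
* Only circular fronts; only two channels; no replicate-level statistics
  (single-colony curves are the unit of output).
* TIFF support covers uncompressed single-plane grayscale files (8/16-bit,
  both byte orders), which is what microscope grayscale exports produce;
  compressed or tiled TIFFs are rejected rather than misread.

## A compact demonstration

```{r demo, fig.width = 6, fig.height = 4}
spec <- synthetic_colony_spec(mode = "narrowing", pixel_size_um = 4,
                              inoc_radius_um = 200, colony_radius_um = 800,
                              width_profile = c(w_start_um = 80, w_end_um = 15),
                              seed = 42)
gen <- generate_sector_colony(spec)
curve <- patch_width_curve(gen$pair,
                           radial_sweep_params(r_start_um = 225,
                                               r_end_um = 775, dr_um = 50),
                           preprocess_params(coarsen_factor = 1,
                                             smooth_window_um = 10))
plot(curve)
# measured vs analytic truth at R = 425 um
c(measured = combined_width(curve)$mean_patch_width_um[5],
  truth = unname(truth_patch_width(gen$truth, 425)["green"]))
```
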