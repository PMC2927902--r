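---
title: "Wide-field tomography methods: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wide-field tomography methods: models, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(widefieldct)
```

This vignette documents the physical model, the numerical conventions
and the deliberate simplifications behind `widefieldct`. The package
README shows the workflow; this document explains *why* each piece is
computed the way it is, so results can be interpreted — and reproduced —
without reading the source.

## 1. Acquisition model and geometry

The model is ideal parallel-beam CT with a line detector:

- The rotation axis defines detector coordinate `s = 0`. A subscan with
  lateral offset `o` (px) and detector width `W_d` (px) samples rays at
  `s = o − W_d/2 + j − 1/2` for `j = 1 … W_d` — a 1-px lattice of pixel
  *centers*.
- Subscan offsets are spaced by `W_d − overlap`, symmetric about the
  axis, so an `n`-subscan geometry covers
  `n·W_d − Σ overlaps` pixels. `plan_widefield()` picks the smallest
  odd `n` that covers the requested field of view; odd counts keep one
  subscan centered on the axis.
- Angles are equiangular over `[0°, 180°)` (`subscan_angles()`), or
  `[0°, 360°)` for the off-center flip-and-stitch mode.

Because offsets are exact multiples of the pixel pitch, a subscan's ray
lattice is a *subset* of the lattice of a virtual wide detector.
Stitching is therefore lattice-exact: on noiseless data the merged
projections equal a direct wide-detector scan to floating-point
precision (a property the test suite asserts).

Physical units enter only through the pixel size (default 1.48 µm):
`fov_mm(1024, 1.48)` = `r fov_mm(1024, 1.48)` mm.

## 2. Sampling-theorem protocol arithmetic

A width-`D`-px reconstruction requires about `D·π/2` equiangular
projections (`required_projections()`, kept *unrounded*). The
gold-standard wide-field protocol must satisfy the theorem everywhere in
the covered width `W`, so each of the `n` subscans supplies the full
merged count and the exposure total is

```
reference_total = round(n · W · π/2)
```

**Rounding convention.** Totals are rounded once, at the end, with
*half-away-from-zero* rounding (`round_half_up()`), not R's banker's
rounding: `874 × 1.25` must report 1093, and per-term rounding of the
three-subscan gold standard would give 13533 instead of 13534. All
intermediate quantities stay in double precision.

Protocol ladders (`make_protocol_ladder()`) express per-subscan counts
as multiples of a base unit (half-integers allowed). Two constraints
keep merging well-posed: the two lateral multiples must be equal, and
the central multiple must be equal to or half the lateral one (so the
reduced subscan's angles form a 2:1 subset of the merged grid and can be
midpoint-interpolated).

## 3. Phantom simulator: realism and limits

`shepp_logan()` uses the canonical ten-ellipse head phantom on the
`[-1, 1]²` square. `forward_project()` computes the discrete Radon
transform by stepping each ray in 1-px increments and accumulating
bilinear image samples (compiled code). The ray-parameter lattice is
symmetric (`n_t = ⌈√(h² + w²) + 2⌉` steps centered on zero), which makes
the parallel-beam identity `p(θ+180°, s) = p(θ, −s)` hold to machine
precision — the flip-and-stitch merge depends on it.

Accuracy limit: the bilinear 1-px-step ray sum carries a few-percent
angle-dependent error at sharp binary edges (a uniform disc's projection
profile varies by up to ~5 % across angles near its rim). Smooth
phantoms and angle-averaged quantities are accurate to ~1 % against a
brute-force oracle. Tests and quality metrics are designed around this:
exactness is asserted only for lattice-aligned operations, not for the
projector itself.

Transmittance mode simulates detector counts as

```
I = (flat − dark) · exp(−µ · L) + dark
```

with defaults `flat = 1000`, `dark = 50` counts, `µ = 0.005` per unit
line integral, optional additive Gaussian noise. A blank beam reads the
flat level exactly, so `(I − D)/(F − D)` returns the transmittance and
`absorption_from_transmittance()` recovers `L` exactly in the noiseless
case. Not modeled: beam hardening (monochromatic synchrotron beam),
photon-counting (Poisson) statistics, detector point-spread, ring
artifacts, phase contrast.

## 4. Merging conventions

- **Normalization**: `(I − D)/(F − D)` with averaged dark/flat frames,
  clipped to `[0, 2]`; a dead column (`F − D ≤ 0`) is an error, not a
  silent `Inf`.
- **Angular interpolation** (`interpolate_missing()`): a reduced subscan
  is brought to the merged count by repeated midpoint doubling
  (pixel-wise linear interpolation between angular neighbours); measured
  projections are preserved bit-exactly at their angles. Across the
  180° wrap the inserted row needs an "upper neighbour": a *centered*
  subscan uses its horizontally mirrored first projection (the
  parallel-beam identity); a *laterally offset* subscan repeats its last
  row, because the mirrored band lies outside that subscan's detector
  window. This convention is the package's choice; alternatives (e.g.
  extrapolation) were not implemented.
- **Cutline detection** (`find_cutline()`): over lateral shifts within
  ±5 px of nominal registration, the mean-squared difference (MSD) of
  the overlapping bands is minimized; at the best shift the per-column
  MSD picks the cut column, ties broken toward the overlap center. A
  featureless overlap yields a warning and the nominal center.
- **Stitching** (`stitch_projections()`): hard cut, no feathering — each
  merged column comes from exactly one subscan (recorded in
  `provenance`). The merged width is always `n·W_d − Σ overlaps`,
  independent of where the cuts fall.

## 5. Reconstruction

`reconstruct_slice()` implements filtered backprojection: zero-pad each
sinogram row to the next power of two ≥ `max(64, 2W)`, filter in the
frequency domain, backproject with linear detector interpolation, scale
by `π/(2P)`, and zero everything outside the inscribed circle.

**Filter kernel.** The ramp is the DFT of the discrete Ram–Lak spatial
kernel (`h(0) = 1/4`, `h(n) = −1/(π²n²)` for odd `n`), *not* the
continuous ramp `2|f|` sampled on the FFT grid. Sampling the continuous
ramp underweights DC and biases every reconstruction by a constant
offset (≈ −2.4 % of the object value on a unit disc, independent of the
projection count); the kernel form removes it (interior mean 0.9999,
background mean ~10⁻⁵ on the disc test). Shepp–Logan and Hann variants
apodize this ramp.

## 6. Quality metrics

- `otsu_threshold()` maximizes between-class variance on 256 equal-width
  bins spanning the data range; the returned threshold is the upper edge
  of the winning bin and foreground means `value > threshold`.
- `protocol_error()` compares volumes slice-wise: slices
  `1, 6, 11, …` (stride 5 by default — 205 slices of a 1024-slice
  volume), each pair Otsu-binarized *independently*, scored by the
  disagreement count `E = Σ|slice_i − slice_B|`.
- `normalize_quality()` maps mean `E` affinely onto a quality scale
  (default 16–116 %, the dose-ladder span), order-reversed so smaller
  differences mean higher quality.
- `simulate_quality_curve()` scores a simulated protocol against the
  noisy reference image by the **summed absolute gray-value difference**
  (L1) by default. The Otsu-binarized count (`metric = "binarized"`) is
  available but on a smooth phantom it is dominated by the support edge
  and nearly blind to angular-undersampling streaks; the gray-value L1
  responds monotonically (Spearman 1.0 under the study conditions
  below). Experimental volume comparison (`protocol_error()`) keeps the
  binarized convention.

## 7. Scaled-down study conditions

Full-size conditions (1024-px detector, 3072-px volumes) are too heavy
for routine testing, so the package fixes one scaled configuration and
uses it everywhere (tests, acceptance script, examples):

| parameter        | value                                        |
|------------------|----------------------------------------------|
| phantom width    | 384 px                                       |
| detector width   | 160 px                                       |
| overlap          | 48 px (covered width exactly 384)            |
| base unit        | 100 projections                              |
| ladder multiples | (6,6,6), (4,4,4), (3,3,3), (2,1,2), (1,0.5,1)|
| noise            | Gaussian, sd 0.02 on the reference image     |

These values were chosen once, before results were inspected, and are
not tuned. The quality-versus-dose replication on this configuration
runs in well under a minute on one CPU.

## 8. Morphometry

Binary-volume operators are hand-written 3-D implementations:
breadth-first flood fill (26- or 6-connectivity) behind `region_grow()`
and `label_components()`; the exact separable lower-envelope Euclidean
distance transform (Felzenszwalb–Huttenlocher) behind
`euclidean_distance_transform()` — exact for isotropic voxels, using a
large finite sentinel (10²⁰) instead of `Inf` to keep envelope
intersections finite. All three are tested for exact agreement with
brute-force oracles.

## 9. Known limitations

- Parallel-beam only; no cone/fan geometry, no center-of-rotation
  estimation beyond the ±5-px cutline search.
- The projector's few-percent edge error (Section 3) bounds how sharply
  simulated quality differences can be resolved.
- `interpolate_missing()` requires power-of-two count ratios (matching
  the same-or-half ladder constraint); arbitrary ratios are rejected.
- The pipeline stores projections as windowed 16-bit TIFF, so round
  trips are exact only to 1/2¹⁵ of the data range.
- Dose is modeled as proportional to the exposure count; no photon-flux
  or exposure-time weighting.
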