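---
title: "Methods: models, phantoms and numerical choices in drusenmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, phantoms and numerical choices in drusenmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(drusenmorph)
```

# Scope

`drusenmorph` quantifies how an epithelial monolayer — the motivating
system is stem-cell-derived retinal pigment epithelium (RPE) — adapts to a
drusen-like substrate bulge raised in a photodegradable hydrogel. The
package covers the measurement side only: region geometry, monolayer
thickness from confocal stacks, per-cell morphometrics from segmentation
masks, swelling kinetics and dosimetry, Hertz indentation fits, and
traction force microscopy. Substrate chemistry, cell culture, staining,
segmentation itself (masks are inputs), and inferential statistics (ANOVA
and post-hoc testing belong in a general statistics environment) are out
of scope.

Because no image data are deposited with the motivating study, every
stage is validated against the package's own synthetic generators, which
emit exact ground truth. A green test therefore establishes that the
implementation recovers known truth under the generator's assumptions —
not that those assumptions exhaust real microscope data.

# Region geometry

All statistics are binned into three radial annuli around the drusen
center: Top `[0, 25)` µm, Edge `[D/2 − 25, D/2)` for illumination diameter
D, and Outside `[150, 175)` µm. For the two characterized conditions this
gives Edge `[25, 50)` (100 µm) and `[125, 150)` (300 µm).

Numerical choices:

* **Half-open intervals.** The published ranges touch ("0–25", "25–50").
  We fix membership as `inner <= r < outer`, so a distance exactly on a
  shared boundary belongs to the outer band. Any other convention changes
  results only on a measure-zero set.
* **Generic diameters.** The Edge band "extends 25 µm radially inwards
  from the illumination radius"; we adopt that as a general rule and
  reject D ≤ 50 µm, where Edge would collide with Top.
* **Distances are physical.** All distances are computed in µm
  (pixel index × pitch, pixel-center convention with index 0 at 0 µm),
  never in raw pixels.

# Monolayer thickness

## The measurement rule

The thickness algorithm mirrors a Fiji-style script: reslice the F-actin
stack into XZ planes, draw vertical intensity profiles, threshold each
profile at its own mean grey value, and take the monolayer height as the
distance between the first above-threshold crossing from the substrate
side (basal) and the first from the far side (apical). Heights are then
normalized to the mean of their technical replicate, making the
per-replicate mean exactly 1 by construction.

Sampling positions follow the 10%-interval / 5%-offset rule. The source
procedure states it for the in-plane line positions but not how many
resliced planes were used; we apply the same rule to both axes, giving a
symmetric 10 × 10 measurement grid with a defined measurement count.
Fractional positions map to pixel indices by round-half-down (recorded in
logs).

* **Threshold comparison** is strict (`> mean`); whether the original
  used `>` or `>=` is unknowable and only matters on exact ties.
* **Sub-voxel refinement**: the crossing is linearly interpolated between
  the bracketing z samples (can be disabled), reducing z-step
  quantization.
* **Degenerate detections**: profiles with no two-sided crossing are
  dropped ("undetected"); heights below 2 µm (single-band detections) are
  filtered. Both counts are reported, never silently discarded.

## The phantom and its bias

The synthetic monolayer renders two Gaussian bands in z (basal and apical
cortical actin) on top of a spherical-cap dome, with a dimmer cytoplasmic
fill between them, plus Poisson shot noise (200 counts at band peak) and
1% Gaussian dark noise. Defaults: 400 µm frame at 2 µm/px, 0.25 µm
z-sampling (super-resolution-mode slicing), band sd 0.35 µm, baseline
thickness 12 µm. The absolute monolayer thickness is not a reported
quantity anywhere; 12 µm is a plausible epithelial value and is a free
choice of the phantom. The bulge is a spherical cap by default (the
swelling is osmotic and the true profile unstated); a Gaussian dome is
available and the choice is a recorded parameter.

The mean-threshold rule measures the distance between the *outer* edges
of the two bands, i.e. truth plus twice the threshold-crossing offset
(~0.55 µm per edge at the default band width). Two consequences, both
inherent to the measurement rule rather than to this implementation:

1. A multiplicative ground-truth effect is compressed: a +5% Top preset
   is recovered as ≈ +4.5% (excess × t/(t + c) with c ≈ 1.1 µm).
2. The compression is slightly asymmetric between thicker and thinner
   regions, because the profile mean (the threshold) itself shifts with
   monolayer thickness; the large-drusen −5% preset is recovered as
   ≈ −4.1%.

Both biases are well inside the ±1.5 percentage-point acceptance band and
shrink with narrower bands or deeper normalization windows. The shot-noise
model was chosen over flat additive noise because flat noise in the empty
z-range above the monolayer produces spurious threshold crossings that no
dark confocal background shows.

The ground-truth thickness map is the analytic membrane-to-membrane
thickness `t(x, y) = baseline × modifier(region)`, emitted alongside every
stack; no pipeline stage reads it.

# Cell morphometrics

* **Area** is pixel count × pitch². **Perimeter** uses marching-squares
  segment counting over 2 × 2 neighbourhoods with two weights (straight
  1.0435, corner 0.6084) calibrated so a 10 × 10 axis-aligned square and
  a radius-50 digital disc are exact; ellipses and rotated squares land
  within ~3%. A plain 4-direction Crofton count was rejected because it
  underestimates axis-aligned squares by ~8%, outside the 5% contract on
  the shape factor P/√A.
* **Orientation** is the principal axis of the second central moments of
  the filled cell, axial in [0°, 180°). The reported `aspect_ratio`
  flags near-isotropic cells whose orientation (and hence angle metric)
  is ill-defined.
* **Angle-to-origin** is `acos(|û·v̂|)` in degrees between the cell axis
  and the centroid-to-center direction: 0° radial, 90° circumferential;
  the absolute value folds the axial ambiguity so the range is exactly
  [0°, 90°]. Under uniformly random orientations its expectation is 45°
  (the metric is uniform in |θ| mod 90°), which the tests verify by Monte
  Carlo. Cells whose centroid coincides with the center are flagged NA.
* **Border cells** are measured but flagged and excluded from area/shape
  statistics (they are truncated by the frame); they still count toward
  totals.
* **Modality.** The frequency distribution of normalized areas is
  summarized by a relative-frequency histogram plus a Gaussian kernel
  density (Silverman bandwidth). The unimodal/bimodal call fits one- and
  two-component Gaussian mixtures on log areas (deterministic
  quantile-initialized EM) and reports "bimodal" only when
  ΔBIC = BIC₁ − BIC₂ > 10 *and* the component means are more than one
  pooled sd apart; below 30 cells the result is "insufficient-n". The
  source work shows curves but names no test; ΔBIC > 10 ("decisive"
  evidence) with a separation guard keeps the false-positive rate below
  5% on single-lognormal nulls (verified over 200 seeded runs).

The mosaic generator places seeds by dart-throwing with per-cell target
areas from a one- or two-component lognormal mixture and labels pixels by
an anisotropic multiplicatively-weighted nearest-seed rule, which
elongates cells along a configurable orientation field (random,
circumferential ring, or radial cap). Ground truth records intended area,
mode, orientation, and the realized pixel area of every cell.

# Swelling kinetics and dosimetry

Dose is intensity × exposure (mJ cm⁻² from mW cm⁻² × s), per cycle and
total; the characterized single 60 s exposure at 3.83 mW cm⁻² and the
additive 15 × 4 s protocol both total ≈ 230 mJ cm⁻².

Bulge height over time is normalized min–max per druse (0 = minimum,
1 = maximum; percentage = 100 × normalized). "Percentage swelling height"
is read as this min–max percentage, following the normalization statement
in the source methods; percent-of-initial is the alternative reading and
would differ only by an affine rescaling per druse.

Apex height is read from a brightfield focus-stack pair as the z of
maximum focus metric — per-plane intensity variance in a 20 × 20 µm apex
window (the metric itself is our choice; none is named), with optional
parabolic sub-plane refinement across the best three planes. On 40-slice,
4-µm-step phantoms the 20 µm apex is recovered within one z-step.

# Hertz indentation

The model is spherical-tip Hertz contact,
`F = (4/3) E_eff √R (δ − δ₀)^{3/2}` past the contact point, zero before.
`E_eff` lumps `E/(1 − ν²)` into one fitted parameter — the vendor
convention never separates the Poisson ratio, so none is asked of the
user. The contact point is *fitted jointly* (closed-form E given δ₀, 1D
minimization over δ₀ initialized at the depth of 5% Pmax); whether the
vendor's "single fit mode" instead pre-detects it is unknown. R² is
computed on force residuals over the window up to 100% of Pmax, and fits
with R² > 0.95 are flagged accepted, reproducing the published filter.
Noiseless recovery is exact to <1%; at 20% multiplicative force noise the
acceptance rate collapses (<1% over 200 seeded curves), which is the
intended behaviour of the filter.

# Traction force microscopy

* **PIV** is two-pass windowed cross-correlation: a circular FFT
  correlation finds the integer displacement, the deformed window is
  re-cut at that offset (iterating until the residual integer shift is
  zero), and the fractional part comes from a 3-point Gaussian fit on a
  zero-padded, overlap-normalized correlation. The window offset removes
  the classic loss-of-pairs bias (~0.15 px for single-pass FFT PIV);
  rigid shifts are recovered to better than 0.2 px and smooth fields to
  ~0.1 px RMS at the default bead density (0.05 µm⁻²). Vector quality is
  the first-to-second correlation peak ratio (second peak outside the
  peak lobe); low-quality and featureless vectors are replaced by the
  3 × 3 neighbourhood median and flagged.
* **FTTC** inverts the Boussinesq flat half-space kernel in Fourier space
  with zeroth-order Tikhonov regularization, solved as a per-wavevector
  2 × 2 system. The k = 0 mode carries no traction information on a
  periodic domain and is set to zero (displacements are taken about their
  mean). Defaults E = 4000 Pa (the hydrogel characterization) and ν = 0.5
  (incompressible gel; the source never states ν). λ can be chosen by the
  L-curve corner (`choose_lambda()`); the pipeline default (5 × 10⁻³ in
  kernel units) sits at the corner for the phantom suite and is recorded
  in output metadata.
* **Summaries** pool traction magnitudes ("normal stress magnitude" is
  read as in-plane |T|, the plugin's output convention) by region, with
  Δmean against Outside and per-region medians.
* **Known physics gap:** the kernel assumes a flat substrate. Over a
  20 µm dome this is a simplification — a curvature-corrected Green's
  function is an open problem the source does not address either; outputs
  carry that caveat rather than a correction.

The bead generator renders Gaussian-PSF point sources and displaces them
with the *same forward kernel* run forward on a known traction field —
forward–inverse consistency tests therefore validate the inversion, while
PIV is tested against the independent ground-truth displacement table.

# Determinism and I/O

Every generator is a pure function of (params, seed): randomness flows
through one seeded scope that restores the caller's RNG state, and seeded
pipeline runs are bit-identical (checked by file checksums). Stacks and
masks round-trip through a minimal uncompressed 16-bit multi-page TIFF
with calibration stored in the ImageDescription tag; measurements and
summaries are CSV/JSON. Manual outlier exclusion is supported only as an
explicit, logged exclusion list in the run config — never automatic.

# Limitations

* Phantoms have no optical realism (no 3D PSF, bleaching, or depth
  attenuation); thickness bias under real point-spread functions will
  differ in magnitude, though not in kind.
* The Voronoi mosaic approximates epithelial packing; it does not model
  junction mechanics, multimodal cell heights, or segmentation errors.
* The flat-substrate TFM kernel over a curved dome, and the absolute
  12 µm baseline thickness, are stated assumptions, not measurements.
* Acceptance is parameter recovery on synthetic presets; agreement with
  the motivating study's biological effect sizes is by construction of
  the presets, not an independent replication.
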