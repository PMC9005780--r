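---
title: "Comparing individual AFM-imaged amyloid fibrils with cryo-EM structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing individual AFM-imaged amyloid fibrils with cryo-EM structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmfibril)
```

## The problem

Amyloid fibrils are helical protein filaments whose cross-sectional fold and
protofilament arrangement differ between polymorphs, including polymorphs of
the same protein. Cryo-EM resolves these structures at high resolution but
only as averages over large, homogeneous sub-populations; atomic force
microscopy (AFM) images *individual* fibrils, at the cost of tip-convolved,
top-view-only data. This package implements a workflow that connects the
two: it simulates what a given cryo-EM structure *would* look like under an
AFM tip, reconstructs a three-dimensional surface envelope of a single
imaged fibril, and scores the structural similarity between the imaged
fibril and each candidate structure in a library, producing a ranked
comparison.

The pipeline has four layers:

1. **Map handling** — read an MRC/CCP4 density map, extract the iso-surface
   vertex cloud at the depositor's recommended isovalue, denoise it, align
   the filament axis with z, locate the helical screw axis, and extend the
   short map segment helically using the deposited twist/rise/handedness.
2. **Topograph simulation** — geometric contact imaging of the surface with
   a sphere-capped-cone tip model: the image is the grey-scale dilation of
   the top surface by the reflected tip.
3. **Envelope reconstruction** — from a straightened experimental (or
   simulated) fibril image: tip deconvolution (grey-scale erosion), helical
   phase accumulation into an `r(theta, z)` radial envelope, symmetry
   detection by re-simulation, and extraction of the mean cross-section with
   2.5/97.5 percentile bounds.
4. **Scoring** — an image correlation distance `d_img = 1 - r` plus
   normalized morphometric distances (symmetry order, handedness,
   cross-over distance, cross-sectional area, and cross-sectional
   symmetric-difference area), summed into `d_sum`; candidates are ranked
   ascending.

## The imaging model

The tip is a sphere of radius $R$ joined tangentially to a cone of
half-angle $\alpha$; its height profile is

$$z(d) = R - \sqrt{R^2 - d^2} \quad (d \le R\cos\alpha), \qquad
z(d) = R(1-\sin\alpha) + \frac{d - R\cos\alpha}{\tan\alpha} \quad
(d > R\cos\alpha).$$

For a pixel at lateral position $q$ the imaged height is
$\max_p \{p_z - z(\lVert p_{xy}-q\rVert)\}$ over all surface points $p$,
clamped at the substrate — grey-scale dilation by the reflected tip.
Deconvolution is the adjoint erosion,
$E(q) = \min_{q'} \{I(q') + z(\lVert q'-q\rVert)\}$, which recovers the
morphological closing of the surface: exact wherever the tip physically
touched, an upper bound elsewhere. The default tip half-angle (18 degrees)
matches a generic sharpened nitride probe; both parameters are arguments,
not constants, because the experimental values come from the probe
manufacturer and from `estimate_tip_radius()`.

Key parameters and defaults:

| parameter | default | meaning |
|---|---|---|
| `radius_nm` | — (11.7 used in the bundled analyses) | tip apex radius |
| `half_angle_deg` | 18 | cone half-angle from the probe axis |
| `pixel_size_nm` | — (1.46 = 3000/2048 in the bundled analyses) | image sampling |
| `k_neighbors`, `dist_factor` | 8, 3 | iso-surface outlier removal; map-noise dependent |
| `alpha_radius_nm` | 2 x voxel | connectivity radius for largest-region cleanup |
| scale bounds | [0.5, 2] | allowed axial dilation of a simulated image |

## Screw-axis fitting

The screw-axis position is found by maximizing the Jaccard overlap between
the voxelized surface and its own copy transformed by one helical subunit
(rotation by the twist, translation by the rise) about the candidate axis:
a coarse grid around the centre of mass, then Nelder–Mead. Because voxel
overlap is piecewise-constant below the voxel scale, a final sub-voxel
polish minimizes a continuous criterion instead: the pooled within-bin
variance of the untwisted cross-section radii. The true screw axis is
exactly the point about which untwisting collapses the surface into the
thinnest possible band, so this criterion sharpens the optimum without
changing its location. The fit is deterministic (fixed initialization, no
randomness) and refuses solutions whose overlap stays below 0.5, which in
practice signals inconsistent helical metadata.

## Envelope reconstruction choices

Several numerical choices matter and are deliberate:

* **Only points above the axis height are accumulated.** Below the axis the
  eroded surface blends into the wedge between the fibril flank and the
  substrate that no tip of finite radius can enter; there the closing no
  longer equals the true surface. Full angular coverage is recovered by
  phase accumulation over at least one cross-over distance, which is why
  images shorter than one cross-over are rejected.
* **Helical phase.** A fibril with C$_n$ cross-section symmetry repeats its
  appearance every $2\pi/n$ of rotation, so the apparent cross-over
  distance is one $n$-th of the full pitch and the base azimuth of a
  surface point at axial position $z$ is
  $\phi - \mathrm{hnd}\cdot 2\pi z/(n \cdot \mathrm{cod})$.
* **Erosion on a laterally upsampled image.** The convolved image is
  smooth, so bicubic upsampling (4 samples per pixel) before erosion is
  safe and samples the erosion minimum densely; the eroded surface itself
  has contact-switch kinks and must not be interpolated. Axial
  interpolation is never used: the cross-section rotates between scan
  rows, so interpolating across rows would mix azimuths.
* **Edge margins.** Rows within one tip footprint of the image ends are
  excluded: there the erosion window is truncated by the image boundary
  (and, for simulated map segments, contaminated by segment end caps).
* **Axis position.** The lateral axis position is initialized as the
  intensity-weighted footprint centroid over a whole number of cross-over
  periods (over whole periods a rotating, even asymmetric, cross-section
  averages onto its screw axis) and refined by maximizing the correlation
  between the input image and a re-simulated topograph of the candidate
  envelope, which peaks at the true axis. The axis height is half the peak
  deconvolved height: over one full cross-over every azimuth faces both the
  tip and the substrate, so the peak equals twice the maximal radius.
* **Noise handling.** Grey-scale erosion follows noise minima, biasing the
  recovered surface down by roughly two noise standard deviations. The
  image is therefore pre-smoothed with a Gaussian whose width adapts to the
  substrate noise estimate (no smoothing on noise-free input), targeting a
  residual noise level around 2% of the peak height.
* **Symmetry detection** reconstructs an envelope under each candidate
  order, re-simulates its topograph and scores the agreement with the input
  in direct space and on 2D Fourier magnitudes, after removing the static
  transverse ridge profile — the mean shape is model-independent, while the
  twist-modulation pattern discriminates the orders. Scores within 1% are
  flagged ambiguous.

## Morphometrics and scoring

Cross-sections are compared as *tip-accessible* boundaries: the cloud of
untwisted surface points is closed with a disc of the tip radius (rolling
the probe around the section), holes are suppressed, and the largest region
kept, so map-derived and AFM-derived sections carry the same resolution
limit. Rotational alignment is an exhaustive 1-degree search minimizing the
symmetrized nearest-point RMSD after centroid alignment, ties resolved to
the smallest angle. Area is the shoelace polygon area; the cross-sectional
difference is the symmetric-difference area of the aligned regions,
computed by rasterization. The combined score is the plain sum

$$d_\Sigma = d_\mathrm{img} + d_\mathrm{sym} + d_\mathrm{hnd} +
d_\mathrm{cod} + d_\mathrm{csa} + d_\mathrm{csd},$$

with each morphometric distance normalized by its observed maximum across
the candidate panel (handedness by its theoretical maximum of 2). A
consequence of panel-relative normalization, worth keeping in mind when
interpreting scores: adding or removing a candidate can change the other
candidates' normalized distances, though not the planted-truth property.
`d_img` is computed only at pixels above the estimated axis height, where
tip-convolution distortion is smallest, after the simulated image's
periodicity has been optimized within the bounded interval [0.5, 2]
(helical twist varies between individual fibrils; the bound keeps the
correction in the physically plausible range). An axial phase shift is
searched jointly, since phase misalignment would otherwise masquerade as a
scale error.

## What the phantom generator emulates

`make_phantom()` sweeps a star-shaped cross-section (given as a radial
function) helically, yielding a surface cloud, a voxelized density map
(binary occupancy with a 1-voxel Gaussian edge, recommended isovalue 0.5)
and a ground-truth record. `decoy_panel()` spans the morphometric space
(C1/C2, both handedness signs, cross-over 30-80 nm, at least two-fold area
spread) deterministically per seed. `simulate_noisy_afm()` adds white pixel
noise and optional per-scanline offsets.

What the phantoms do *not* emulate: real density maps are not binary
(atomic contrast, resolution anisotropy, masking artifacts); real AFM data
contain drift, feedback overshoot, adhering oligomers and substrate
roughness; real fibrils bundle and vary in twist along their length. Tests
passing on phantoms therefore demonstrate the correctness of the geometry
and scoring machinery under the stated imaging model, not robustness to
every experimental artifact.

## Validation at desk scale

Because the experimental dataset underlying the bundled analyses is not
redistributable and deposited density maps are too large to ship, the
package validates the reconstruction workflow on synthetic stand-in maps
built by its own generator and passed through the real MRC reader: a
two-lobed C2 filament (cross-over 75 nm) and an asymmetric C1 filament
whose screw axis lies off the cross-section centre of mass (cross-over
45 nm), both imaged with an 11.7 nm tip at 1.46 nm pixels after helical
extension to about six cross-over periods — the problem sizes used
throughout the test-suite and by `scripts/acceptance.R`. The reconstructed
cross-sections agree with the tip-accessible map cross-sections to roughly
0.1 nm (C2) and 0.25 nm (C1) RMSD on these fixtures, and the off-centre
axis position is recovered; the corresponding numbers are recomputed, not
quoted, by the acceptance script on every run.

## Known limitations

* Envelopes are contact-surface models: no detail below the tip radius is
  recovered, concavities narrower than the tip are bridged, and the
  under-side wedge is invisible by construction.
* Symmetry orders above C4 are not considered; the twist-modulation signal
  that discriminates orders weakens as the cross-section approaches
  circularity.
* The screw-axis fit trusts the deposited twist/rise values; it does not
  refine them.
* Scores carry no significance model; ranks are descriptive.
* Reconstruction accuracy for strongly asymmetric, off-centre-axis fibrils
  is limited by angular coverage and improves with imaged length; segments
  much shorter than two cross-over periods reconstruct poorly.
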