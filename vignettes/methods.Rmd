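---
title: "Label-free 3D biopsy reconstruction: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free 3D biopsy reconstruction: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Prostate cancer grading rests on glandular growth patterns whose
three-dimensional architecture is invisible in 4–5 µm sections.
Optically cleared tissue punches can be imaged intact, but confocal and
light-sheet approaches need fluorescent staining of the structures of
interest. `biopsy3d` implements a reconstruction pipeline for a cheaper,
faster alternative: multimodal transmission microscopy, where the tissue
architecture itself is recovered *without staining* from bright-field
(BF) focal-plane stacks, and dark-field (DF) plus two epifluorescence
(FL) channels are draped over that scaffold.

The pipeline's scientific core is a defocus-based tissue detector.
Transmission through a cleared punch produces, at each focal plane, a
projection to which out-of-focus planes also contribute — but the
further a structure is from the focal plane, the more its high spatial
frequencies are attenuated. Local high-frequency energy is therefore a
per-position *focus* measure: it is large where in-focus tissue texture
is present and small inside cavities and in the surrounding medium.
Thresholding it plane by plane yields a full 3D tissue segmentation, in
which glandular lumina (tubules, ducts) of sufficient size appear as
enclosed non-tissue components.

# The tissue-presence statistic

For a plane $I$ the package computes

$$E(y,x) \;=\; \sum_{|u|\le r,\ |v|\le r} \bigl[(h * I)(y+u,\ x+v)\bigr]^2,$$

where $h$ is a high-pass operator (default: the 3×3 discrete Laplacian,
the minimal isotropic choice; a difference-of-Gaussians alternative is
available via `filter_id`) and $r$ is the window radius
(`window_radius_px`, default 7 px ≈ 15 µm at 1 µm/px — larger than
cell-scale texture, well below the 50 µm cavity scale). Borders are
mirrored. $E$ is invariant to additive intensity offsets and scales
quadratically with gain, so flat-field calibrated stacks from the same
sensor are directly comparable.

A voxel is tissue when $E$ exceeds a single global threshold. With
`threshold = "auto"` the threshold is chosen by Otsu's criterion applied
to the histogram of $\log_{10} E$ pooled over the full 3D energy volume:
energies span several decades and are strongly bimodal on the log scale
(a defocused/noise floor and an in-focus tissue mode), where the linear
scale is dominated by the upper tail. The chosen value is still a single
global energy threshold.

Two post-processing choices matter:

* **Morphological cleanup (`cleanup_radius`, default 1).** A few percent
  of tissue voxels fall below the global threshold wherever the local
  texture happens to be weak. Under 26-connectivity such sparse holes
  percolate: in testing they connected distinct cavities to each other
  through thin chains. A radius-1 opening followed by closing removes
  them and restored one-to-one cavity recovery; we therefore enable it
  by default rather than shipping a default that fails its own central
  use case.
* **Boundary rule.** Non-tissue components touching the stack boundary
  are the surrounding medium and are flagged `enclosed = FALSE`; only
  enclosed components are candidate cavities. Cavity size is summarized
  as the equivalent spherical diameter $(6V/\pi)^{1/3}$ of the
  component's physical volume — the paperless ">50 µm" claim needs a
  concrete metric, and this one is closed-form testable.

Known bias: because the energy is a windowed sum, the tissue/cavity
transition is displaced into the cavity by roughly the window radius
plus the defocus transition width; recovered equivalent diameters run
about 10 µm below the geometric truth on phantoms. Detection (presence,
location) is unaffected; size readouts should be interpreted with this
in mind.

# The synthetic phantom

There is no public instrument data, so validation is built on a phantom
generator that reproduces the *physics the detector relies on*, not the
instrument. `phantom_spec()` describes a textured tissue slab (defaults:
64×256×256 voxels at (dz, dy, dx) = (3, 1, 1) µm — the lateral sampling
of the targeted instrument class and the one axial step its protocol
family states) containing enclosed spherical or tubular cavities;
defaults place five spheres of 30, 45, 60, 80 and 100 µm equivalent
diameter, bracketing the 50 µm claim.

Image formation, per modality:

* **BF** — attenuation projection: each source plane's optical depth is
  laterally blurred by a Gaussian of sd
  $\sigma(d) = \sigma_0 + g\,d$ (defocus distance $d$ in µm) and summed;
  the recorded intensity is $I_0 e^{-\mathrm{OD}}$ plus Gaussian sensor
  noise. The two-parameter defocus law is deliberately simple: it
  reproduces exactly the frequency-attenuation property the segmentation
  exploits, with interpretable knobs.
* **DF** — scattering proxy: intensity proportional to the lateral
  gradient magnitude of the textured tissue field, defocus-blurred and
  summed the same way; borders and inhomogeneities light up,
  homogeneous interiors do not.
* **FL** — linear imaging: the two label-density truths (channel 1 on
  cavity-lining shells, emulating luminal CK8-18; channel 2 at the
  tissue periphery, emulating basal CK5) convolved with a 3D PSF plus
  noise.
* **Beads** — 3 µm spheres convolved with the PSF, for calibrating
  `estimate_psf()`.

Simulator defaults and why (all fixed before the validation suite was
frozen, and not revisited since):

| parameter | default | rationale |
|---|---|---|
| `blur_growth_per_um` | 0.4 px/µm | geometric defocus cone of an NA 0.45 objective (blur radius ≈ NA·d) |
| `blur_sigma_at_focus_um` | 0.5 µm | in-focus blur at ~1 µm lateral resolution |
| `texture_grain_um` | 4 µm | cell/nucleus-scale detail; the low-pass sd is grain/6 so spectral power actually reaches the grain wavelength |
| `texture_coarse_grain_um`, weight | 24 µm, 0.5 | glandular/stromal density variation; gives volumes the multi-scale blob structure that scale-space landmark detection needs |
| `texture_contrast` | 0.9 | strong local refractive inhomogeneity after clearing |
| `attenuation_per_um` | 0.0085/µm | column optical depth ≈ 1 over a ~120 µm slab: transmission ~0.4, the low-contrast BF regime the instrument produces |
| `noise_sd` | 3×10⁻⁴ of unit background | a well-exposed CMOS frame; keeps the noise-floor energy an order below in-focus tissue energy |

What the phantom does **not** model: wave-optical diffraction,
refractive-index mismatch, clearing-induced shrinkage, spectral effects,
shot-noise scaling with intensity. Passing the phantom suite therefore
demonstrates that the algorithms implement the intended physics
correctly and recover known geometry under realistic contrast and noise
— it does not certify performance on any particular instrument's data.

# Supporting stages

**Drift correction.** The sample floats in imaging fluid; successive
focal planes are registered by zero-normalized cross-correlation over
integer shifts (default window ±32 px), refined by a 1-D parabolic fit
to subpixel precision, composed cumulatively to plane 1, and resampled
bilinearly. Exposed borders are filled with the plane's background
median so no artificial high-frequency edge confuses the segmentation.
`estimate_stack_drift()` pre-smooths plane pairs (Gaussian sd 1.5 px by
default): successive BF planes share their defocused projection content
but carry mutually uncorrelated in-focus detail, which otherwise acts as
structured noise on the correlation peak (cumulative error ~0.5 px
unsmoothed vs ~0.1 px smoothed on phantoms). Rotation of the sample is
not corrected — only translations are estimated. Shifts estimated on BF
are applied unchanged to the other channels of the acquisition.

**Deconvolution.** DF and FL stacks (never BF) are restored by
Richardson–Lucy iteration with a unit-flux PSF, either synthesized from
the defocus model (`defocus_psf()`) or estimated from a bead stack
(`estimate_psf()`: component detection well above background, patch
extraction around intensity centroids, background subtraction,
averaging, clipping, unit normalization — the result is the *bead
image*, sphere ⊛ PSF, which is the correct kernel for bead-calibrated
data). Convolutions run in the frequency domain after reflective
padding by half the PSF support. Defaults: 25 iterations with an early
stop when the mean relative change drops below 10⁻⁴; the ratio's
denominator is floored at 10⁻¹² (so a delta PSF is an exact fixed
point). The kernel must sum to one — the function refuses rather than
silently renormalizing, since a mis-scaled kernel silently destroys
flux.

**Two-tile stitching.** Landmarks are detected on the BF volumes as
difference-of-Gaussians scale-space extrema (volumes resampled to an
isotropic grid at the coarsest spacing first; positions mapped back).
One deliberate departure from the textbook detector: the classical
strict 3×3×3×3 extremum test rejects essentially everything on
volumetric texture, because adjacent DoG levels are strongly correlated
and blobs whose optimal scale falls between levels have monotone scale
response. We require a strict spatial 26-neighbor extremum at the
level, with tolerant (factor 0.9) magnitude dominance over the adjacent
levels at the same position, quadratic subvoxel localization, and
cross-level deduplication. Descriptors are magnitude-weighted gradient
orientation histograms (8 azimuth × 4 elevation bins over 2×2×2
subblocks), unit-normalized. Matching is mutual-best with Lowe's ratio
test (0.8); the affine transform is estimated by repeated 4-point
minimal samples with consensus counting and a final least-squares refit
— descriptor matching always yields outliers, so a robust wrapper
around the linear solve is not optional. Fusion resamples the moving
tile tri-linearly onto the union bounding box; where both tiles are
defined the *reference* tile's voxels are kept (deterministic and
seam-visible for QC; a linear blend is available behind a flag) and a
provenance mask is returned.

**Rendering.** An orthographic ray caster composites any number of
channels, each with an RGB color and a piecewise-linear
intensity-to-opacity transfer function, front to back with early
termination at accumulated opacity 0.99. All voxels are transparent, so
internal ducts remain visible through the tissue surface. Sampling
starts where each ray enters the voxel-extent bounding box, with
samples at midpoints of `step_vox` intervals — an axis-aligned camera
at `step_vox = 1` samples exactly at voxel centers, which makes the
compositing closed forms exactly testable. Opacity is corrected for
step length as $1-(1-\alpha)^{\Delta}$. Default palette follows the
composite convention: segmentation white, DF green, FL1 green, FL2 red.

**Pipeline.** `run_pipeline()` executes: load + flat-field calibration →
per-tile drift correction (estimated on BF) → optional two-tile
stitching → segmentation on the drift-corrected BF → RL deconvolution of
DF/FL (when a PSF or bead stack is configured) → cavity extraction →
composite rendering. Stages with absent inputs are skipped with a
warning; any stage error aborts naming the stage, keeping partial
outputs. One global seed fans out to per-stage derived seeds, and the
manifest records parameters, relative output names and per-file
checksums, so a run is bit-reproducible from config + seed alone.

# Numerical and degenerate-input choices

* Flat-field output is rescaled by the reference's spatial mean, keeping
  corrected stacks in the sensor's native intensity range.
* Integer TIFF stacks round-trip bit-exactly (8/16-bit); float stacks
  are stored as float32 scaled into [0, 1] with the scale in a YAML
  sidecar alongside spacing, channel and wavelength.
* A constant stack cannot be auto-thresholded (explicit error), and a
  zero-variance plane has no defined normalized correlation (explicit
  error).
* NCC ties are broken toward the smallest shift magnitude, then smallest
  dy, then dx.
* Coordinates: all ordered triples are (z, y, x); voxel centers sit at
  index × spacing with 0-based indices; z = 0 is nearest the objective.

# Validation scale and the demo

The validation suite runs on phantoms of 64×256×256 voxels (the
per-seed cavity-recovery scan, ten seeds) and smaller; the end-to-end
demo (`run_phantom_demo()`) uses a 32×128×128 phantom with a 60 µm and
a 36 µm cavity, in-fluid drift (injected as exact Fourier phase shifts
— a physically moving sample loses no spectral content, so interpolated
injection would penalize the pipeline for a simulation artifact), a
sensor vignette, and a two-bead calibration stack. These sizes are the
package's chosen validation conditions; they keep a full phantom→
segmentation cycle around twenty seconds.

Committed demo baselines: cavity recall and precision 1.0, mean
residual drift < 0.3 px (typically ~0.05), segmentation Dice ~0.69
against the truth mask. The demo Dice is materially lower than the
0.92 reached at the 64-plane validation scale for a physical reason:
the detector's axial resolution is limited by the defocus law, so
medium within ~12 µm of the slab reads as tissue, and that boundary
shell weighs roughly twice as much at 32 planes. It is reported as a
regression baseline, not as an instrument-performance claim.

# Known limitations

* The segmentation's axial boundary localization is limited by the
  defocus physics itself (~10 µm); reported cavity diameters are biased
  low by about the energy-window radius.
* Rotational sample drift is not corrected.
* Stitching covers two tiles; multi-tile global optimization is out of
  scope.
* The phantom validates algorithmic correctness, not instrument
  performance; parameters of the defocus law are simulator settings,
  not measured values.
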