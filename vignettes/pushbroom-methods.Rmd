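---
title: "Models and methods behind pushbroom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pushbroom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pushbroom)
```

This vignette records the models, parameter choices and numerical decisions
behind the package: what the processing chain assumes, what the synthetic
scanner emulates (and deliberately does not), and where the design was
genuinely open.

## The acquisition model

A pushbroom hyperspectral laparoscope images one spatial line at a time.
Each raw frame is a 960 × 780 (spatial × spectral-pixel) readout; 640 frames
are recorded at 140 fps while the spectrograph traverses the image plane, so
a full scan takes 640/140 ≈ 4.6 s (`acquisition_time()`, reported at 0.1-s
resolution to match how such figures are usually quoted). The field of view
is anchored at 55 × 48 mm² for a 5-cm working distance and scales linearly
with distance. The true 10-cm field of a real instrument deviates from
linearity by roughly 10%; linear scaling was chosen for simplicity and is
confined to `fov_mm()`.

### Spectral axis and calibration

The spectrograph maps spectral-pixel index to wavelength. We model this map
as a polynomial (default degree 2, the usual model for a grating
spectrograph over a 500-nm span; configurable) fitted by least squares to
emission-line anchors — seven krypton-line wavelengths from standard atomic
line tables in the simulator's default (`krypton_anchors()`). The fit must
be strictly increasing over the readout; a non-monotone fit raises a
calibration failure rather than producing a scrambled axis. Channel centers
follow the convention `lo + k · spacing`: the 500-channel 1-nm calibration
axis has centers 500…999 nm, the binned 100-channel output axis 500, 505, …,
995 nm. Each spectral pixel is assigned to the *nearest* channel center;
pixels sharing a channel are averaged and empty channels are filled by
linear interpolation between their populated neighbors (constant
continuation at the ends). Whether co-assigned pixels should be averaged or
summed is not observable downstream (balancing divides it out); averaging
was chosen because it keeps constants invariant. Binning is a plain
non-overlapping block mean (2 spatial × 5 spectral), which preserves the
grand mean exactly.

Because channel assignment, interpolation and binning are all linear in the
pixel values, the assembly loop uses a single precomputed 780 × 100
operator; a unit test pins its equivalence to the explicit two-stage path.

### Balancing, reflectance and absorbance

Reflectance is the classic dark/white normalisation
`I_R = (I0 − I_dark)/(I_white − I_dark)`. The dark pattern (acquired with
illumination off) already contains the black level, so no separate offset is
subtracted. Pixels whose denominator does not exceed ε = 10⁻⁶ counts are
masked invalid instead of dividing; values are clipped to [0, 4] so glare
pixels can exceed 1 without running away. Absorbance is `−log10(I_R)` with
`I_R` floored at 10⁻⁴, bounding the optical density at 4. All three guards
are configurable.

Two consequences are worth stating explicitly. First, everything
multiplicative that is common to scene and reference — illumination
spectrum, spot profile, distance falloff, sensor quantum efficiency
including its ripple above 800 nm — cancels in the ratio; the test suite
verifies cancellation of the QE ripple to 10⁻¹⁰. Second, `I_R` is
reflectance *relative to the white reference* (white paper, reflectance
0.9, recorded as `white_reflectance` in the `reference_set`): the white
scene itself balances to exactly 1. Comparisons against absolute
ground-truth reflectance therefore multiply by 0.9.

### White reference representation

The white reference is measured per working distance, averaged over scan
lines to a single 480 × 100 frame and broadcast across the lines of the
object scan. This is exact here because the illumination model does not
vary along the scan: the spot is centered on the entrance slit and
characterized within a frame, which mirrors how a real system measures both
its falloff profile and its SNR line groups — at a fixed slit position,
where the 480 "sensor lines" are the in-frame spatial positions. The spot
is therefore a function of the in-frame distance from the slit center (in
native output-pixel units), Gaussian, equal to 0.5 at the half-intensity
radius (default 150 px). Distance falloff follows `(d_ref/d)^p` with
p = 1.8 by default, close to the inverse-square law of a point source.

## The synthetic scanner

Scenes are planar targets: non-overlapping rectangles in mm with
reflectance spectra on a fine 1-nm grid, over a uniform background.
Provided scenes: white paper (flat 0.9), a scattering phantom (flat 0.95,
absorber-free), 24 ColorChecker-like patches with smooth synthetic
sigmoid/Gaussian spectra (not the published patch reflectances), tissue
patches whose absorbance mixes two Gaussian chromophore bands at 540 and
575 nm (emulating oxy/deoxyhemoglobin) over a flat NIR baseline, and
USAF-style bar triplets. Light-source spectra are qualitative shapes
(LED visible + NIR emitter bands; broad xenon with mild NIR peaks;
blackbody-like halogen at 3200 K), max-normalized; no attempt is made to
reproduce any instrument's printed spectra. The sensor applies a smooth QE
curve with a sinusoidal ripple above 800 nm (8 % depth, 25-nm period),
scales to counts (3000 counts per unit radiance, folding the fixed exposure
and gain whose true values are not public — the absolute count scale is
arbitrary but documented), adds the 64-count black level and Gaussian read
noise (σ = 3 counts), and clips to the 4095-count full scale. Noise is
additive only — no shot-noise scaling — because the SNR estimator under
test is noise-model-agnostic; σ was set so that default SNR lands in the
tens of dB, the plausible range for such systems. Saturated pixels are
clipped, not modeled as specular glare.

Every frame derives its own RNG substream from `(seed, line, stream)`, so
scans are bit-reproducible frame by frame and independent of evaluation
order; renders restore the caller's RNG state.

An optional scene-side PSF models optical blur as an anisotropic Gaussian.
Because patches are rectangles, the blur is applied analytically
(differences of normal CDFs on the patch membership weights), avoiding any
raster convolution. The across-scan (slit) σ can grow linearly with
wavelength (`slit_nir_factor`) to emulate reduced NIR resolution; the
default PSF is off, and resolution experiments set it explicitly.

What passing tests on this simulator do **not** show: performance on real
tissue (no scattering physics, no specular glare, no motion), absolute
radiometry, or agreement with any commercial device's absolute index
values.

## Organ hemoglobin index

`OHI = clip(100 · 0.5 · (r − a)/(b − a), 0, 100)` with
`r = Ā(530–590 nm)/Ā(785–825 nm)`, window membership by channel center,
inclusive at both ends (13 and 9 channels on the default grid). The printed
form of this index is typographically ambiguous about the parenthesization
and does not state the calibration constants; we read it as the affine map
above and ship `a = 0, b = 2` as explicitly *uncalibrated placeholders*
(under them, r = 1 maps to OHI 25). Pixels whose NIR-window mean absorbance
is below 10⁻⁶ are masked rather than divided. The 0–100 range is enforced
by clipping; clipping (rather than exact rescaling) is what guarantees the
bound for arbitrary finite input, which the acceptance experiment measures.

## Registration

Homographies are estimated by RANSAC over 4-point minimal samples
(threshold 3 px, up to 2000 iterations, adaptive stop at 99.5 %
confidence — values chosen as common practice since none are dictated by
the problem), with Hartley point normalization before the DLT and a final
least-squares refit on the inlier set; the null vector comes from the
smallest eigenvector of the 9 × 9 normal matrix, which also covers the
exactly-determined 4-point case. Matrices are normalized to H₃₃ = 1. Pixel
centers sit at integer coordinates, origin top-left, x = column. Warping
samples the source at `H⁻¹(x, y)` with bilinear interpolation (nearest-
neighbor is available for index/label images to avoid mixing values);
out-of-bounds pixels carry a fill value and a mask. Both warp directions
are therefore available by passing H or its inverse.

## Characterization

**SNR.** Per pixel over N repeated frames:
`20 · log10(mean / mean|I − mean|)` dB. The deviation term is interpreted
as the mean absolute deviation over the stack — the printed form of such
estimators rarely pins this down; under Gaussian noise it equals
σ√(2/π), giving the closed form `20·log10(μ/(σ√(2/π)))` that the tests
check to ±0.2 dB at N = 1000. Zero-deviation pixels are capped at 120 dB.
Group curves average the SNR map over sensor lines 0–10 (border), the 11
central lines (240–250 on the 480-line geometry) and all lines.

**Spot falloff.** Azimuthal averages over integer-radius annuli, normalized
at r = 0; the half-intensity radius interpolates linearly between the
bracketing radii and is reported as not-reached when the profile never
drops below 0.5 inside the image.

**Distance falloff.** Ordinary least squares on (log d, log I); exact on
exact power laws for any exponent and unbiased to ±0.02 under 2 %
multiplicative noise.

**Michelson resolution.** For each bar-triplet element the across-bar
profile (averaged along the central 60 % of the bar length, one full period
centered on the middle bar) is fitted with a sine whose period is fixed by
the known bar pitch — only mean, amplitude and phase are free, which
stabilizes fits near the cutoff. Contrast is `(Imax − Imin)/(Imax + Imin)`
from the fitted extremes *clipped to the observed profile range*: for an
unblurred two-level target the raw fundamental-harmonic amplitude is 4/π
times the square-wave amplitude and would push the contrast above 1;
clipping restores the plain two-level value (0.895 for levels 0.05/0.9)
while leaving the near-sinusoidal blurred regime — where the Gaussian MTF
closed form `exp(−2π²σ²f²)` applies — untouched. The finest element at or
above the 20 % cutoff is the reported resolution, converted to µm through
the pixel pitch (field of view divided by image size per axis). Elements
with too few profile samples at the current pixel pitch are flagged
unmeasurable instead of fitted.

## Numerical and scale choices

* Cube axis order is (line, sample, channel); all pixel coordinates in the
  registration module are 0-based.
* Cube I/O uses a plain-text ENVI-style header plus little-endian float32
  BSQ binary; the validity mask travels as a uint8 sidecar and metadata as
  `meta.*` header keys, making the round trip lossless at float32
  precision.
* Full-scale scans are assembled from a frame *generator* (one raw
  960 × 780 frame in memory at a time); list input remains for small scans,
  and the two paths are bit-identical.
* Test and acceptance experiments use reduced problem sizes chosen to keep
  the statistical tolerances meaningful: 1000-frame stacks on 30 × 12
  frames for SNR, 1000 seeds for falloff bias, scans of 16–64 lines for
  identity and recovery checks, and one full 640-line streamed acquisition
  for the end-to-end geometry contract.
* The command-line interface is a thin wrapper over the same functions;
  exit codes are 0 (ok), 2 (configuration) and 3 (data), and `simulate`
  writes a manifest with the seed and a config hash so runs can be
  reproduced exactly.

## Known limitations

No fluorescence or autofluorescence modes, no live-video electronics, no
hardware control, no nonrigid registration, no automatic feature matching
(correspondences are assumed annotated), and no claim of quantitative
agreement with any commercial instrument's absolute OHI or SNR values —
those depend on hardware this package deliberately does not model.
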