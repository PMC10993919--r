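---
title: "Methods: orientational order mapping with polOrder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orientational order mapping with polOrder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Excitation-resolved fluorescence polarization microscopy probes the
in-plane orientation of fluorophore transition dipoles by exciting the
sample with linearly polarized light at four angles (0°, 45°, 90°, 135°
from the +x image axis) and recording one emission image per angle. A
single dipole at azimuth φ absorbs in proportion to cos²(θ − φ) for
excitation angle θ; an ensemble of dipoles in a pixel responds with the
population average ⟨cos²(θ − φ)⟩. For a wrapped normal azimuth
distribution with mean μ and spread σ this average has the closed form
½(1 + c₂ cos 2(θ − μ)) with c₂ = exp(−2σ²), which is what the package's
simulator renders and what its analytic ground truth is computed from.

The pipeline applies, in order: division of the raw stack by a normalized
flat-field stack; pixel-wise normalization of each four-intensity set by
its maximum; and the per-pixel equations A = I0 − I90, B = I45 − I135,
OF = √(A² + B²), α = arctan2(B, A)/2. Azimuths are axial (defined modulo
180°) and are reported in degrees on (−90°, +90°].

Two properties of this estimator deserve emphasis, because the package
deliberately preserves them rather than "fixing" them:

* **OF is not rotation invariant.** The per-pixel max normalization makes
  the OF of a perfectly aligned population depend on its orientation:
  1 on the image axes, 4 − 2√2 ≈ 1.17 at 22.5°. Clipping OF at 1 would
  silently change the published estimator, so OF is reported as computed.
  The property test that pins this behaviour evaluates the cos² responses
  at both angles in closed form.
* **α is undefined at OF = 0.** `arctan2(0, 0)` is a convention, not a
  measurement. Such pixels are flagged invalid and excluded from all
  downstream statistics, so that disorder estimates never ingest
  fabricated angles.

## Object-level statistics

Segmentation follows the average-intensity image: a white top-hat with a
disk-shaped structuring element of radius 3 px removes smooth background,
Otsu's threshold binarizes the top-hat image, and connected components
with 4-pixel connectivity become objects. The object OF is the mean pixel
OF over member pixels with defined orientation.

Azimuthal disorder per object uses the standard axial-data device: angles
are doubled (α ↦ 2α), mapped to unit vectors, and averaged to the mean
resultant vector r̄ with length R. The circular standard deviation of the
doubled angles is √(−2 ln R); halving maps it back to the azimuth scale,
giving s0 in degrees. The halving factor is fixed by a consistency
requirement the test suite enforces: sampling a wrapped normal with
spread σ and pushing it through the estimator must return σ (for σ = 10°,
within 0.5°). With equal weights on axial antipodes the resultant
vanishes and s0 is reported as the +Inf sentinel, never silently.

The local signal-to-background ratio takes the mean average-intensity
over the object as signal, and as background the mean over a 2-px-wide
ring separated from the object by a 3-px-wide buffer. Widths are realized
as successive morphological dilations. The distance metric is city-block
(the 4-connected cross) by default, chosen to match the 4-connectivity
used for components; a Chebyshev (8-connected) variant is available via
`dilationMetric`. Ring pixels that fall inside another object's
object-plus-buffer zone are excluded from the background, since puncta
cluster along borders and neighbouring signal would inflate the
background estimate. Objects with S/B < 3 are excluded; the rule is
strict, so S/B exactly 3 is retained. Edge objects are kept unless
clipping empties their ring.

Pixels invalid in the orientation maps (including OF = 0 pixels) are
excluded from both the object OF and the disorder statistic; an object is
dropped when fewer than 2 member pixels carry a defined azimuth.

## Line scans and border pairing

Border profiles sample the OF map along 18 parallel lines with 1-px
lateral spacing (≈ 2 μm at the instrument scale the design mirrors),
bilinearly interpolated at 1-px steps and averaged across lines per
position. Masking is conservative: a sample contributes only when all
four interpolation neighbours lie inside the binary mask, the stricter
reading of "only pixels within the mask". Anchor points are explicit
coordinates, which makes scans reproducible instead of hand-drawn.

For wound-edge borders, the object nearest the leading edge (point-line
distance from its centroid) forms group A and the farthest group B, one
pair per border, compared by a two-sided paired t-test. In confluent
regions there is no edge; objects on each border are randomly split into
two groups (seeded, reproducible) and each group summarized by its mean
OF before pairing.

## Group comparisons

Object metrics across condition labels are compared by a Kruskal–Wallis
omnibus test followed by Dunn's pairwise z-tests on the pooled midranks
with the standard tie correction. Comparisons are restricted to the
neighbor-and-control set — consecutive timepoints plus each timepoint
against the control — and the Bonferroni adjustment is applied over
exactly the comparisons made, reading the restricted-before-adjustment
design literally. Fragment-style count tables use ordinary one-way ANOVA
with Sidak-adjusted pairwise t-tests on the pooled residual variance over
the same comparison set. Degenerate inputs (zero within-group variance,
zero-variance paired differences) are flagged rather than returned as
infinite statistics.

Kruskal–Wallis, ANOVA and the paired t-test call the base `stats`
implementations; Dunn's post hoc and the Sidak pairwise step are
implemented in the package.

## The simulator: what it emulates and what it does not

`renderScene()` draws each punctum as a hard disk of given diameter whose
four-channel expected signal follows the wrapped-normal response above,
adds a diffuse unpolarized background, multiplies by a radial vignetting
field (1 at the centre, 1 − depth at the corner), blurs with an isotropic
Gaussian PSF, and applies Poisson shot noise plus Gaussian read noise.
Key defaults, chosen once as typical for puncta imaged on a sCMOS camera
with a high-NA oil objective: amplitude 5000 expected photons per pixel,
background 50, PSF σ = 1.2 px (near-diffraction-limited puncta at
60×/1.49 NA scale), read noise σ = 2 photon-equivalents, vignette depth
0.2, punctum diameter 5 px. Rendering is deterministic given the spec
(the seed is part of the spec) and restores the caller's RNG state.

The wrapped normal was chosen as the dipole population model because its
second circular moment has the closed form exp(−2σ²), which gives every
stage an analytic oracle; it is a model, not a claim about the underlying
biology (a cone distribution would serve similarly but lacks the clean
moment). Not modeled, deliberately: out-of-plane dipole tilt (the method
measures in-plane projections only), vectorial high-NA excitation
corrections, emission-side anisotropy, photobleaching, and registration
error between polarization frames (a single-camera excitation-side
system acquires co-registered frames). Passing tests therefore
demonstrate correctness of the published estimator and pipeline logic on
in-plane wrapped-normal ensembles — not robustness to tilt, bleaching or
misregistration in real data.

`renderAssemblySeries()` encodes maturation presets as per-label spread
schedules (a gradual preset decreases σ across labels; a constant preset
fixes it), and `renderScratchScene()` places near/far punctum pairs on
borders receding from a straight leading edge with σ a function of
distance. These are the scenes the acceptance checks run end-to-end.

## Numerical choices

* **Flat-field safety.** Elements ≤ 1e−6 of the stack maximum are
  rejected at construction; division by a near-zero flat element is an
  error, never a silent Inf.
* **Zero-maximum pixels.** A pixel whose four corrected intensities are
  all 0 has no meaningful normalization; it carries 0 in all channels and
  is flagged invalid downstream.
* **Otsu binning.** 256 equal-width bins spanning min..max of the
  top-hat image; candidate thresholds on bin boundaries; class means from
  bin midpoints; ties in the between-class variance break toward the
  lower threshold (`which.max` takes the first maximizer). The test suite
  checks the result against an exhaustive search over all candidate cuts.
* **Label order.** Components are labeled in row-major order of their
  first pixel, making object ids deterministic.
* **R slightly above 1.** Floating-point accumulation can leave the
  resultant length marginally above 1 for identical angles; R is clamped
  to 1 before the log so s0 is exactly 0 rather than NaN.
* **TIFF dialect.** Multi-page grayscale, page order I0/I45/I90/I135;
  16-bit unsigned for simulated raw counts (round-trips bit-exactly),
  32-bit float for corrected and derived rasters. Exposure time and laser
  power are metadata only and never enter computation.

## Problem sizes used in the checks

The packaged verification runs at desk scale, chosen so the full suite
completes in minutes while leaving the statistical checks well powered:
equation fidelity on a 1000 × 1000 random stack against a scalar loop;
assembly series of 5 labels × 5 fields × 40 puncta (200 objects per
label) on 256² images; scratch scenes with 15 (gradient) and 12
(confluent) borders, the flat-scene null calibrated over 100 replicates;
estimator recovery at n = 10⁴ samples per spread; segmentation recall
over 20 seeded 128² scenes; and 1000-replicate null calibration of the
omnibus test.

## Known limitations

The S/B measurement uses the average-intensity image (the natural reading
of the protocol it mirrors); a single-channel variant is not provided.
Touching puncta are not watershed-split, objects are not tracked over
time, and the leading edge and border anchors are explicit inputs rather
than detected from brightfield. The confluent-mode random pairing
averages group members per border, which is one of several defensible
readings of a random flanking-group design; the seeded assignment makes
whichever reading is used reproducible.
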