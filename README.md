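# polOrder

Orientational order mapping from excitation-resolved fluorescence
polarization microscopy (FPM).

Punctate cell–cell junctions such as desmosomes are built from cadherins
whose extracellular domains become progressively more ordered as the
junction matures. Excitation-resolved FPM reads this order out optically:
a field is imaged four times under linear excitation polarizations of 0°,
45°, 90° and 135° (measured from the +x image axis), and the modulation of
fluorescence with excitation angle reports the in-plane alignment of the
fluorophore transition dipoles in each pixel. `polOrder` implements the
full analysis from raw four-polarization stacks to group-level statistics,
together with a forward simulator that renders such stacks from scenes
with known ground truth, so that every stage of the pipeline can be
validated without access to microscope data.

## The model

After flat-field correction and pixel-wise normalization (each pixel's
four intensities divided by their maximum), each pixel yields

```
A  = I0 − I90
B  = I45 − I135
OF = √(A² + B²)               (Order Factor)
α  = arctan2(B, A) / 2        (azimuth, axial: α ≡ α + 180°)
```

`OF` is 0 for an isotropic dipole population and 1 for perfectly aligned
dipoles parallel to an image axis. Because the normalization divides by
the per-pixel four-channel maximum, the estimator is not rotation
invariant — aligned dipoles at 22.5° give OF = 4 − 2√2 ≈ 1.17 — and
`polOrder` reports OF exactly as defined, without clipping.

Objects (puncta) are segmented from the average-intensity image by a
white top-hat transform (disk radius 3 px) followed by Otsu thresholding,
labeled with 4-connectivity, and filtered by a local signal-to-background
ratio (3-px buffer, 2-px background ring; objects with S/B < 3 are
excluded). Per object, the pipeline reports the object OF (mean pixel OF)
and the azimuthal disorder `s0`: the circular standard deviation of the
member azimuths, computed on doubled angles through the mean resultant
length R as `s0 = √(−2 ln R) / 2`, in degrees. Line scans (18 parallel
lines, 1-px spacing, bilinear sampling) profile OF along cell borders, and
the statistics layer reproduces the study-design group comparisons:
Kruskal–Wallis with Dunn's post hoc over a neighbor-and-control
comparison set, one-way ANOVA with Sidak pairwise tests, and paired
t-tests for border-flanking objects.

The simulator renders each punctum as a disk of dipoles with a wrapped
normal azimuth distribution (mean μ, spread σ); the expected signal at
excitation angle θ is `amplitude · ½(1 + c₂ cos 2(θ − μ))` with
`c₂ = exp(−2σ²)`, plus diffuse background, multiplied by a radial
vignetting field, blurred by a Gaussian PSF, and subjected to Poisson shot
noise and Gaussian read noise. The analytic OF/azimuth implied by each
punctum's parameters is stored as ground truth.

## Worked example

Simulate a field with two puncta — one disordered (σ = 40°) and one
well-ordered (σ = 10°) — and run the full analysis:

```r
library(polOrder)

pk <- data.frame(row = c(20, 44), col = c(24, 40), diameter = 5,
                 amplitude = 3000, muDeg = c(0, 60), sigmaDeg = c(40, 10))
spec <- sceneSpec(pk, imageSize = c(64L, 64L), rngSeed = 2L)
sc <- renderScene(spec)

res <- analyzeField(sc$stack, flat = sc$flat)
res$retained[, c("objectId", "nPixels", "meanOF", "azimuthCSD", "sbRatio")]
#>   objectId nPixels meanOF azimuthCSD sbRatio
#> 1        1      25  0.534      2.252    18.7
#> 2        2      25  1.003      0.813    18.7

sc$truth$puncta[, c("muDeg", "sigmaDeg", "ofTrue", "azimuthTrue")]
#>   muDeg sigmaDeg ofTrue azimuthTrue
#> 1     0       40  0.548           0
#> 2    60       10  1.037          60
```

The recovered object OFs (0.534 and 1.003) track the analytic
ground-truth values (0.548 and 1.037) for the two spreads, the ordered
punctum shows lower azimuthal disorder (0.81° vs 2.25°), and both puncta
pass the S/B ≥ 3 filter comfortably (S/B ≈ 19). Note the second object's
OF exceeds 1 because its dipoles sit at 60°, off the image axes — the
documented non-rotation-invariance of the estimator.

Group-level comparisons then run on stacked object tables, e.g.
`compareTimepoints(objects, "meanOF", levels = c("2h","4h","6h","8h"))`.

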