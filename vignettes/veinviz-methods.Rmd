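---
title: "Methods: phantom optics, enhancement operators and study statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom optics, enhancement operators and study statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinviz)
```

## What the package models

Near-infrared (NIR) vein finders exploit the strong absorption of
deoxygenated hemoglobin in the 740–760 nm band: subcutaneous veins appear
as dark curvilinear structures against back-scattered tissue light. A
handheld device of this kind is a chain of four stages — LED illumination,
a camera capture layer (gain, exposure, contrast), an image-enhancement
library (contrast stretch, difference of Gaussians, Laplacian, region of
interest), and an operator who decides whether a marked puncture site lies
over a vein. `veinviz` implements that chain offline, replacing the
physical arm with a rendered phantom whose ground truth is known exactly,
so that every stage can be tested quantitatively.

## The phantom's optical model

The renderer is deliberately not a photon-transport simulation. It uses a
single-scatter Beer–Lambert surrogate with closed forms, chosen because
every term can be verified against an independent numerical oracle:

$$I(x, y) = \mathrm{clip}_{[0,1]}\!\big( I_0 \, L(x,y)\, R_{bg} \,
(1 - A(x,y)) + n(x,y) \big)$$

* **Illumination** $L = \min(1, \sum_i e^{-r_i^2 / 2\sigma_L^2})$, a
  Gaussian radial falloff per LED. The default layout is four LEDs on a
  50 × 35 mm rectangle centred on the field with $\sigma_L = 30$ mm; at
  that width the four lobes overlap into a saturated, uniform field over
  the default 25.6 × 38.4 mm view — by design, since the LED rig exists to
  illuminate the camera's view evenly. Narrow $\sigma_L$ to study vignetting.
* **Absorption** $A = \min(1, \sum_v a_v)$. Each vein contributes its
  projected capsule footprint (width $2 \cdot \text{radius}$), scaled by
  $A_{max} e^{-(d + t_a)/\delta}$ — depth $d$, adipose thickness $t_a$,
  attenuation scale $\delta$ — and blurred with a Gaussian of
  $\sigma(d) = \sigma_0 + k (d + t_a)$, the depth-dependent widening that
  tissue scattering produces.
* **Noise** is zero-mean Gaussian, seeded from the spec, so renders are
  bit-reproducible. **Hair** is drawn as 1-pixel anti-aliased arcs that
  multiply intensity by 0.2, up to a target coverage fraction; hair on the
  puncture site is a documented failure mode of NIR devices.

Adipose tissue is modelled as a scalar added to every vein's effective
depth rather than as a separate scattering layer; it moves contrast and
blur in the physically right direction with one parameter.

Default parameters (all overridable through `PhantomSpec()`):

| parameter | default | unit | role |
|---|---|---|---|
| `baseIntensity` | 1.0 | – | source intensity $I_0$ |
| `backgroundReflectance` | 0.6 | – | tissue reflectance $R_{bg}$ |
| `maxAbsorption` | 0.85 | – | surface-contact vein contrast $A_{max}$ |
| `depthDecay` | 2.5 | mm | Beer–Lambert scale $\delta$ |
| `blurBase`, `blurSlope` | 0.3, 0.35 | mm, – | scatter blur $\sigma_0 + k d$ |
| `noiseSigma` | 0.01 | intensity | sensor noise sd |
| `pixelPitch` | 0.1 | mm/px | grid scale |

Coordinates are row-major pixels with the origin at the top-left; pixel
$(r, c)$ is centred at $x = (c - 0.5) \cdot \text{pitch}$,
$y = (r - 0.5) \cdot \text{pitch}$, and all footprints are computed in
continuous millimetres before rasterization at pixel centres.

## Capture layer

`applySettings()` is the linear model
$\mathrm{clip}((I \cdot e \cdot g - 0.5) c + 0.5)$ with the contrast pivot
fixed at mid-gray, the standard linear-contrast convention. Exposure is
treated as a multiplicative factor; real sensors integrate over time, but
nothing downstream distinguishes the two. The five named profiles (Low
light, Medium light, Very bright, LED profile, Custom) ship as package
data with placeholder values — field devices determine theirs on the
bench per lighting condition, which has no desk-scale counterpart — and
`Custom` deliberately refuses to resolve without explicit settings.

## Enhancement operators

All scales are specified in millimetres and divided by the pixel pitch,
so results are resolution-invariant. All convolutions use reflect
padding, which avoids the dark frame that zero padding would stamp onto
ridge maps. Signed responses (DoG, Laplacian) are renormalized
symmetrically — $0 \mapsto 0.5$, largest magnitude $\mapsto$ 0 or 1 — so
dark, vein-like structure always lands below 0.5 regardless of gain. A
response whose largest magnitude is below $10^{-12}$ is treated as zero
(FFT roundoff on constant frames would otherwise be amplified to full
range).

The operator variants are: `dog1` $(\sigma_n, \sigma_w) = (0.4, 2.0)$ mm,
tuned to 1–2 mm vein radii; `dog2` $(0.8, 4.0)$ mm for coarser vessels;
`log1` Laplacian-of-Gaussian at 1.0 mm; `log2` the raw 4-neighbour
Laplacian. Gaussian kernels are truncated at $4\sigma$ and renormalized.
ROI processing crops, runs the operator (whose reflect padding then acts
at the ROI borders), and pastes back, leaving outside pixels bit-identical.

## Detection and the marker-hit rule

`segmentVeins()` keeps the darkest `thresholdQuantile` (default 10%) of
the ridge response, cleans it morphologically (disc opening and closing,
radius 1 px), drops components under 40 px, and skeletonizes the
survivors with Zhang–Suen thinning. Components use 8-connectivity;
centerline arc length is counted as skeleton pixels × pitch, with no
subpixel fitting. A constant frame segments to an empty mask rather than
an error.

In an observational study, whether a marked site "has a vein underneath"
is adjudicated visually by supervising clinicians. `isVeinAt()`
operationalizes that judgement as a distance rule: the mark hits if any
segmented vein pixel lies within `hitTolerance` (default 2 mm, a typical
antecubital vein radius). This is a proxy, and the tolerance must remain
configurable precisely because no spatial precision standard exists for
the visual judgement it replaces.

## Depth-visibility sweep and its calibration

`maxVisibleDepth()` renders one straight 1.5 mm-radius vein per depth on
a 0.5–8.0 mm grid (0.1 mm steps), runs the default dog1 pipeline, and
declares a depth visible when (i) at least half of the truth centerline
is recovered within the hit tolerance and (ii) the vein's Michelson
contrast $(I_{bg} - I_{vein})/(I_{bg} + I_{vein})$ — measured on
centerline pixels against a vein-free render of the same seed — reaches
`contrastFloor`. Each depth uses a fresh noise seed derived from the
spec's seed.

Handheld NIR devices validated against ultrasound resolve veins to about
4.8 mm (SD 0.7 mm) of depth. The package treats that figure as a
calibration anchor: at the default optics the recall criterion is not
binding (a single straight vein is the only coherent structure, so the
darkest-decile threshold keeps tracking it beyond the anchor depth),
leaving the contrast floor as the calibration knob. The default
`contrastFloor = 0.033` pins the sweep's answer to the anchor; a lower,
bare just-noticeable-difference floor would admit visibly deeper veins.
This is a calibration, not an independent reproduction — the package
cannot re-run the physical ultrasound comparison, only pin its surrogate
to the published operating point.

## The synthetic study generator

`makeFixtures()` emulates the structure of an educational venipuncture
study: 25 subject phantoms in three BMI classes (4/18/3 subjects,
adipose presets 0/1.5/3.5 mm), 20 student clinicians each marking one
site per subject (500 attempts), a 20 × 4 Likert table, 4 SUS responses,
a 64-patient additional-veins table (27 difficult cases) and a two-week
usage log with 497 sessions. Everything derives from one seed.

Marker placement follows a two-component model: with probability `pVis`
(0.65 / 0.45 / 0 by class) the student perceived a vein — by faint
visibility or palpation — and marks near it with Gaussian jitter (2.0 /
2.5 / 3.0 mm); otherwise the mark is an uninformed uniform guess.
Adiposity therefore degrades site selection, not the ground truth: hits
are always adjudicated against the true vein footprint. The zero `pVis`
in class 3 mirrors the clinical observation that obese patients can show
no naked-eye-visible veins at all. Under this model per-class failure
rates rise monotonically with BMI class and the pooled rate lands in the
low-to-mid thirties of percent — the gradient and magnitude a field
study of this design reports. Subject phantoms are 192 × 256 px
(19.2 × 25.6 mm) with two veins, leaving most of the field vein-free as
on a real inner elbow.

What the generator does **not** emulate: vessel branching and
anastomoses, arm curvature and specular reflections, motion blur, skin
pigmentation and scar tissue, arterial structures, and any correlation
between a subject's vein geometry and their BMI class beyond the adipose
preset. Tests passing on these phantoms show the pipeline's internal
consistency and calibrated behaviour, not clinical performance.

## Statistics conventions

The evaluation functions reproduce descriptive clinical-table arithmetic
exactly: failure rates to 1 decimal, Likert means to 2, standard
deviations (sample, $n-1$) to 3, additional-veins summaries to 1, all
half-up rounded — the convention of printed clinical tables, where base
R's `round()` (half-to-even) would disagree on exact halves. Likert mode
ties break toward the larger score. SUS uses the standard scoring (odd
items $s-1$, even items $5-s$, sum × 2.5) with interpretation bands
"acceptable" above 70, "concern" below 50, and the inclusive 50–70 range
"marginal". BMI classes are opaque labels throughout; no numeric BMI
boundaries are assumed. Usage-log rankings sort by count with
alphabetical tie-breaks so reports are deterministic.

## Numerical and degenerate-input choices

* Reflect padding mirrors about the edge pixel (period $2n - 2$).
* Identity camera settings return the input bit-identically (the contrast
  pivot arithmetic is skipped at unit contrast).
* Constant images: contrast stretch returns them unchanged; DoG/LoG map
  them to the neutral 0.5; segmentation returns an empty mask.
* Depth maps store mm/64 in 32-bit float TIFF (float TIFF is only defined
  on [0, 1]); off-vein pixels store 1.0 and read back as `Inf`.
* Marker-hit comparisons add a $10^{-9}$ slack on the squared pixel
  distance so exact-boundary tolerances survive mm-to-pixel conversion.
* All stochastic stages draw from an explicit seed and restore the
  caller's RNG state.

## Problem sizes

Default phantoms are 256 × 384 px; the depth sweep runs 76 renders at
that size (about a minute on one core), and the synthetic study uses
192 × 256 px subjects so a full bundle builds in under half a minute.
All sizes are arguments, not constants.

## Known limitations

The optical surrogate has no wavelength dependence, no melanin or
oxygenation terms, and treats scattering as a single Gaussian blur; the
illumination model ignores the LEDs' true angular emission profile; the
capture layer is linear, with no sensor saturation curve or quantization;
skeleton-based centerlines can wobble one pixel around ridge plateaus;
and the usability statistics are purely descriptive, as in the study
design they mirror — no inference, reliability analysis or rater
agreement is attempted.
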