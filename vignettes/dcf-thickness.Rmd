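---
title: "Automatic DCF thickness measurement: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic DCF thickness measurement: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcfseg)
```

## The problem

The Deep Cervical Flexor (DCF) muscles — longus capitis and longus
colli — stabilize the cervical spine, and their thickness under
craniocervical flexion is a standard physiotherapeutic measurement made
on B-mode ultrasound. Manual caliper placement is the dominant source
of inter-operator variability: the DCF is a dark band whose fascia
borders have weak contrast, and the cervical vertebrae directly beneath
it are only moderately brighter than the muscle. `dcfseg` implements a
fully automatic pipeline that (i) segments the DCF band inside a
user-supplied rectangular ROI, (ii) extracts the cervical vertebra
echoes below it, (iii) anchors a measurement key point on the leftmost
vertebra, and (iv) reports the muscle thickness as the mean of three
vertical chords taken at the key-point column and 1 cm to either side.

A coordinate convention is fixed package-wide: 0-based pixel
coordinates, `x` = column growing rightward, `y` = row growing
downward, ROIs half-open on both axes. All rounding of fractional pixel
positions and intensities uses round-half-up (`floor(x + 0.5)`), so
results cannot depend on the parity tie-breaking of banker's rounding.

## Stage 1: DCF candidate extraction

Within the ROI the pipeline runs, in order:

1. **Ends-in search stretching.** A min–max linear contrast
   normalization with clamping at both ends:
   $P = 0$ for $G \le \min$, $P = 255$ for $G \ge \max$, and
   $P = 255 (G - \min)/(\max - \min)$ between. Unlike smoothing
   filters, this preserves the shape of the intensity distribution of
   the speckled sonogram — the histogram of a craniocervical scan is
   heavily skewed toward zero and the dark mass carries no anatomy of
   interest. A constant (blank) ROI is passed through unchanged with a
   warning, and the pipeline reports a graceful failure for it.
2. **Average binarization.** Threshold at the ROI mean (ties to
   foreground). Because the stretched histogram is dark-dominated, the
   mean sits well above the muscle intensities, and the bright fascia
   envelope of the DCF survives as a large connected object.
3. **Blob labeling and noise removal.** Connected components
   (8-connectivity by default) are filtered by the size/location
   criteria: object $O$ is removed iff
   $S(O) < 0.085\,S(\mathrm{ROI})$, or $O$ starts within the leftmost
   10 % of the ROI width while being narrower than half the ROI width.
   The inequalities are strict as printed; thresholds are rounded to 12
   significant digits so that, e.g., an object of exactly
   $0.085\,S(\mathrm{ROI})$ pixels is kept rather than falling to
   binary representation error. Both constants are configurable
   (`noise_size_frac`, `left_margin_frac`, `min_width_frac`) and are
   applied identically in the vertebra stage.
4. **Hole filling.** For every column, all pixels between the first
   foreground row from the top and the first from the bottom are set to
   foreground, closing the dark muscle interior between its bright
   fascia borders. The operation is idempotent.
5. **Gap bridging.** One pass (configurable) of 8-neighborhood
   dilation reconnects boundary lines broken by thresholding.
6. **4-directional contour tracing and spline reconnection.** The
   candidate's boundary is walked with a square-tracing turtle
   restricted to axial moves, starting at the object's top-leftmost
   pixel; the per-column extremes of the contour give the upper and
   lower boundary curves, and any columns the contour missed are filled
   by natural cubic-spline interpolation.

## Fuzzy sigma binarization (stage 2)

Near the vertebrae, mean and Otsu thresholding both fail for the same
reason: the histogram is not bimodal, and the vertebra margins are only
slightly brighter than the surrounding muscle. The fuzzy sigma
binarizer adapts to the image's own contrast. With $P_{\min}$,
$P_{\max}$ the intensity extremes and $P_{mid}$ their average:

* $P_{\min}^F = P_{mid} - P_{\min}$, $P_{\max}^F = P_{\max} - P_{mid}$;
* $P_{mid}^F = 255 - P_{mid}$ if
  $P_{mid} > P_{\min} + 0.75\,(P_{\max} - P_{\min})$, else
  $P_{mid}^F = P_{mid}$;
* the half-width $\beta$ is chosen by a nested conditional equivalent
  to $\min(P_{mid}^F, P_{\max}^F)$ or $\min(P_{mid}^F, P_{\min}^F)$
  depending on which side dominates (implemented verbatim as the
  conditional; the equivalence is asserted by a unit test);
* the support is $[P_{mid} - \beta,\; P_{mid} + \beta]$.

Membership rises linearly from 0 at $P_{\min}^{new}$ to 1 at $P_{mid}$
and a pixel is foreground iff its membership reaches the α-cut
(default 0.5, i.e. no prior preference). Two printed details deserve
note. First, the upper membership branch is implemented as $u = 1$ for
$P \ge P_{mid}$ — the only reading consistent with the denominator of
the linear branch. Second, with $P_{mid}$ *defined* as the midpoint of
$P_{\min}$ and $P_{\max}$, the bright-image compensation condition
reduces to $0.5 > 0.75$ and can never fire; the branch is implemented
verbatim anyway and a unit test documents that it is unreachable under
the midpoint definition. Parameters are global per image (no tiling),
and a constant image degenerates to a membership step at $P_{mid}$.

## Vertebra extraction and measurement (stages 2–3)

The enhanced ROI is fuzzy-sigma binarized, blob-labeled, noise-filtered
with the same criteria as stage 1, and dilated by a square element
(`expand_radius`, default 2 px) to heal fragmented echoes. Candidates
that do not reach below the DCF lower boundary are then discarded as
subcutaneous fat/fascia. This test is per pixel: a pixel is "below"
when $y \ge \text{boundary}(x) + \text{tolerance}$, and an object
counts as a vertebra only if more than `fat_min_below_frac` (default
5 %) of its pixels are below. The tolerance defaults to
`expand_radius + bridge_iterations + 1`: the bridging of the DCF mask
and the expansion of the vertebra candidates both systematically deepen
objects by a known number of rows, and the tolerance absorbs exactly
that growth. The fraction makes the decision robust to stray speckle
pixels fused to an object's underside by the dilation. (A
bottom-row-versus-centroid-column comparison was rejected: for a wide,
bowed fascia object the global bottom row is reached at the lateral
edges and exceeds the boundary height at the centroid column, so the
fascia would masquerade as a vertebra.)

If the surviving leading vertebra sits on the wrong half of the ROI,
the true leftmost vertebra was lost to thresholding. The pipeline then
applies distance-weighted restoration to the enhanced ROI — every pixel
is multiplied by $\alpha = 1 + d^2/1000$ with $d$ its distance from the
ROI center, clamped at 255 — and re-runs the candidate chain once with
average binarization on the boosted image before reporting failure.
The restoration is applied to the grayscale image: multiplying an
already-binary raster under a 255 clamp would be a no-op.

The key point is the rightmost pixel of the leftmost vertebra (ties:
smaller `y`). Chords are taken at the key column and at
$\pm\,\mathrm{round}(1\,\mathrm{cm}/\text{spacing}_x)$ pixels; each
chord spans from the DCF candidate's upper boundary to its lower
boundary, converted to cm with the y-axis spacing (anisotropic pixels
are handled by using each axis's own calibration). The reported
thickness is the arithmetic mean of the three chords. The upper
landmark is the candidate mask's top boundary — the fascia-to-fascia
outer extent — which is also how the phantom defines its ground truth.
Without any calibration (no DICOM `PixelSpacing` and no
`pixel_spacing` override) the chords are reported in pixels with a
warning and `thickness_cm` is `NA`.

For right-sided anatomy every left/right convention (margin clause,
leading vertebra, key-point side, restoration trigger) mirrors via
`pipeline_config(side = "right")`; a property test checks that
mirroring the image and the convention mirrors the key point to within
one pixel.

## The synthetic phantom

Clinical cervical sonograms are not redistributable, so the package
ships a generator that emulates the scene the pipeline targets on an
800 × 600 raster at 0.01 cm/px: a bright skin line; the dark SCM band
wrapped in a 7-px fascia envelope; a dark vessel ellipse between the
muscles; the DCF as a dark band inside a closed, mildly bowed 16-px
fascia sheath; three bright vertebra echoes below it with an acoustic
shadow; unit-mean gamma speckle (variance 0.02) followed by Gaussian
blur (σ = 1 px). Ground truth (masks, boundary curves, key point,
thickness) is recorded before the noise. The DCF thickness — the outer
fascia-to-fascia extent — is drawn uniformly from 0.6–1.4 cm unless
fixed.

Two geometric choices make the phantom exercise the pipeline's
discriminating steps rather than bypass them:

* the fascia sheath is a *closed* envelope, so its ring area
  (≈ 2 × width × 16 px) clears the 8.5 % area criterion at every
  thickness while remaining a single object whose column-wise fill
  reproduces the band;
* each vertebra is a bright core (≈ 10.5 k px, below the 8.5 %
  criterion, hence removed in the average-binarization stage) inside a
  dim halo whose intensity lies between the fuzzy α-cut threshold and
  the ROI mean. The full halo object (≈ 16.9 k px) survives the
  criterion only under fuzzy-sigma binarization — the low-contrast
  regime the binarizer exists for, and the basis of the paired
  recall comparison in the acceptance suite.

What the phantom does **not** model: physically simulated wave
propagation, depth-dependent attenuation and focusing, anatomical
variability of vertebra shape and fascia curvature, probe pressure, or
operator framing. Passing the phantom suite therefore demonstrates
the internal consistency of the pipeline under the stated scene
assumptions, not clinical accuracy; the published clinical figures were
obtained on 200 proprietary images that are not available.

Problem sizes in the test and acceptance suites were chosen to keep a
full run inside a few minutes on one core: 50 phantoms (seeds 1–50) for
end-to-end thickness recovery, 20 for the paired binarizer comparison,
100 random 20 × 20 rasters for the labeling oracle, 100 random knot
sets for the spline oracle, 1000 endpoint pairs for the DDA oracle, 200
random 64 × 64 images for the stretching oracle.

## Numerical and degenerate-input choices

* Round-half-up everywhere a fractional value becomes a pixel or an
  8-bit intensity; products of the restoration weight are rounded then
  clamped at 255.
* Natural cubic splines are solved with the Thomas algorithm on the
  knot second-derivative system, handle non-uniform spacing, and refuse
  to extrapolate; evaluation at a knot returns the stored knot value
  exactly. Two knots degenerate to the straight segment.
* The DDA emits one pixel per integer column including both endpoints;
  a vertical segment (undefined slope) emits every integer row between
  the endpoints.
* Otsu requires at least two distinct intensities; ties on the
  between-class variance go to the smallest threshold.
* A blank ROI, an empty binarization, no surviving candidate, or a
  measuring column outside a boundary's domain all yield a structured
  failure result naming the stage — never an exception.
* DICOM support covers the two uncompressed little-endian transfer
  syntaxes, single-frame grayscale; 8-bit pixel data pass through
  unchanged, deeper data are min–max rescaled to 8 bits. Color,
  multi-frame, and encapsulated files are rejected with errors naming
  the unsupported feature.

## Known limitations

* The DCF upper landmark (candidate mask top) is an operational
  definition; a clinician might place the caliper on the inner fascia
  edge instead, which differs by about one fascia thickness.
* The left-margin noise clause and the left-anchored key point encode
  the probe orientation of the source protocol; `side = "right"`
  mirrors them, but oblique framings are out of scope.
* The weighted-restoration retry recovers a lost leftmost vertebra only
  as well as average binarization of the boosted image allows; on
  scenes where the vertebra row lies fully right of center the pipeline
  prefers an explicit failure over guessing.
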