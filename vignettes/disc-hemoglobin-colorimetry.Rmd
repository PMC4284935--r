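---
title: "Optic disc hemoglobin colorimetry: model, design choices and validation"
author: "discHb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optic disc hemoglobin colorimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

The optic nerve head (papilla) is the one structure of the ocular fundus
whose color is governed by a single pigment: hemoglobin. Axonal loss -
whether glaucomatous or neurodegenerative - manifests as progressive
papillary pallor, but an examiner's eye cannot quantify pallor, and by the
time it is obvious a large share of the nerve fibers is already gone.
discHb turns an ordinary RGB fundus photograph into a quantitative map of
relative Hb content over the disc, summarized as a mean and 24 sector
percentages per eye, and provides the group-comparison statistics used to
contrast a patient cohort with controls.

The obstacle is that raw channel values confound tissue composition with
the intensity and spectral shape of the illumination, camera gain, and the
yellowing of the crystalline lens. The package's central idea, borrowed
from the colorimetric tradition it reimplements, is that the central
retinal vessels inside the disc are columns of essentially pure blood -
100% Hb by definition - exposed to exactly the same illumination and
ocular media as the tissue a fraction of a millimeter away. Referencing
every tissue pixel to the vessels cancels those shared factors.

## The Hb index

Hb-rich tissue reflects red light and absorbs green; pale (gliotic or
poorly perfused) tissue reflects both about equally. For a pixel with
reflectances $(r, g, b)$ the package uses the normalized red-green
contrast

$$h = \frac{r - \tilde g}{\max(r, \varepsilon)},\qquad
\text{Hb\%} = 100\,\frac{h_{\text{pixel}}}{h_{\text{vessel}}},$$

where $\tilde g$ is the lens-compensated green value,
$\varepsilon = 10^{-3}$ guards the division, and $h_{\text{vessel}}$ is
computed from the per-channel *medians* of the vessel pixels (medians
rather than means so that specular highlights on the vessel crowns do not
shift the reference). Two properties follow directly:

* **Illumination cancellation.** A multiplicative change of illumination
  scales $r$ and $g$ of a pixel equally, so $h$ is unchanged pixel by
  pixel; the index is exactly invariant under global intensity changes,
  which the test suite verifies at scale factors 0.6-1.0.
* **Anchors.** Achromatic tissue ($r = \tilde g$) maps to 0%; tissue with
  exactly the vessel color maps to 100%. Vessel pixels carry the defined
  value 100 and are excluded from all tissue aggregates.

Tissue values are clamped to $[0, 120]$ rather than $[0, 100]$: under
sensor noise, tissue redder than the vessel median is possible, and
destroying those values would bias sector means downward. The blue channel
never enters the index; it is reserved for lens assessment (below).

## Lens compensation

A yellowed (cataractous) lens absorbs short wavelengths: in the package's
lens model the blue channel is attenuated by a factor $\kappa \in (0, 1]$
and green, spectrally between blue and red, by $(1 + \kappa)/2$; red is
unaffected. Because the attenuation acts proportionally on vessels and
tissue alike, the vessels expose it: their observed blue:green ratio
equals the clear-lens vessel calibration ratio (default 0.55, the
blue:green ratio of whole blood in the packaged forward model) times
$2\kappa/(1+\kappa)$. `estimateLensCompensation()` inverts that relation
for $\hat\kappa$ (clamped to $[0.05, 1]$ and flagged when the raw estimate
is out of range, e.g. for a degenerate all-zero blue channel) and the Hb
estimator then multiplies green by $2/(1+\hat\kappa)$ - the exact inverse
of the assumed green coupling - for tissue pixels and vessel reference
alike.

A design note: an additive green offset calibrated from the tissue-vessel
green-blue difference gap was considered first, but no additive constant
can be the identity on a clear-lens image while correcting an attenuation
that is multiplicative in nature - the gap is nonzero even with clear
media, and a constant under-corrects bright tissue and over-corrects dark
tissue. The multiplicative form is the identity at $\hat\kappa = 1$ by
construction, which is the behavior the rest of the pipeline assumes.

## Segmentation

The disc is found by thresholding the red channel at its 95th percentile
within a search window (whole image, or a square window around a manual
seed - the "semi-automatic" path; a fully manual geometry from a JSON
sidecar bypasses segmentation entirely). A percentile cut deliberately
overshoots: it clips the dim side of the disc under uneven illumination
and the vessel tree slices the bright region into wedges. The candidate
is therefore refined once - re-threshold at the midpoint between the
median red inside and outside the candidate, bridge the vessel cuts with
a morphological closing, fill the holes - and an axis-aligned ellipse is
fitted from the second moments of the filled region ($a = 2\sigma_x$,
$b = 2\sigma_y$ for a filled ellipse). Moment fitting was chosen over a
boundary least-squares conic because the filled region's boundary is
ragged where vessels cross it, while its bulk moments are nearly
unaffected.

Vessels inside the disc are the darkest green structures. They are
classified by a threshold *relative to the disc's median green* (default:
0.55 of the median), followed by a 3x3 opening to remove speckle. A
dispersion-based rule (median minus a multiple of the MAD) was tried and
rejected: across subjects with realistic sector-to-sector Hb dispersion
the within-disc green MAD varies by an order of magnitude, so any fixed
multiplier either swallows the high-Hb tissue tail or misses the vessels
entirely, whereas the vessel:tissue green ratio is stable (vessels sit
near 0.4 of the tissue median, the darkest credible tissue near 0.7).
Both rules are scale-equivariant, so the mask is invariant under global
darkening - a property the tests check by darkening an image by 0.8 and
requiring an identical mask. Masks whose vessel fraction falls outside
[0.05, 0.60] of the disc area are returned flagged low-confidence with a
warning, never silently dropped.

## Sector geometry

The disc interior is divided into eight 45 degree wedges crossed with
three concentric rings bounded at 1/3 and 2/3 of the disc radius - 24
sectors. Rings are defined in *normalized elliptical radius* (scaled
copies of the fitted ellipse), so an oblique disc keeps the exact
1/9 : 3/9 : 5/9 ring area split. Labels are wedge-major and ring-minor,
`3*(wedge-1) + ring`, so the outer ring - the neuroretinal rim, where
axons live and group differences concentrate - is exactly the multiples
of 3. Wedges are counted from the temporal horizontal meridian, clockwise
for right eyes and counterclockwise for left eyes; this mirrors the
clock-hour convention of peripapillary OCT and makes sector indices
anatomically comparable across eyes, so cohorts can mix eyes without
re-indexing. `mirrorProfile()` converts profiles recorded in native
screen orientation (the wedge reflection $w \mapsto 9 - w$, rings
preserved) and is an involution. Per-sector means use tissue pixels only;
a sector fully covered by vessels is reported `NA` with a warning rather
than imputed.

## The synthetic generator

No public dataset pairs fundus photographs with per-sector Hb ground
truth, so validation rests on a forward optical model that is deliberately
*not* the estimator's inverse:

* Disc tissue color is a linear mix of a pale achromatic endmember
  (0.88, 0.88, 0.85) and a red-dominant blood endmember
  (0.80, 0.45, 0.2475), weighted by the true Hb fraction. The blood
  endmember's blue:green ratio is exactly the 0.55 lens calibration
  constant; its red deliberately differs from the pale red, which gives
  the estimator a known, mildly compressive nonlinearity (about 2 points
  at mid-range Hb) - recovery tests are therefore non-circular.
* The true Hb field is sector-piecewise (one draw per sector) smoothed by
  normalized Gaussian convolution within the disc (sigma = 4% of the disc
  radius, floor 1.5 px), emulating the gradual transitions of real tissue.
* A branching vessel tree (default 6 branches plus a central trunk,
  trunk width `max(3.5, 0.05 * radius)` px - narrower vessels would not
  survive the segmenter's 3x3 opening) is drawn at the blood color
  darkened by 0.55.
* Nuisance factors: a multiplicative linear illumination gradient
  (default relative amplitude 0.10), the lens model above (default
  kappa = 1, i.e. clear media - transparent media being the usual
  inclusion criterion for such cohorts), and additive Gaussian sensor
  noise (default SD 0.01, about 2.5 steps of an 8-bit camera), clipped to
  [0, 1].

Cohort draws take per-sector means and SDs per group from the packaged
defaults (24 sectors per group), RNFL thickness tables in the Cirrus
(mean + 4 quadrants + 12 clock hours) and Spectralis (mean + 4 quadrants
+ 4 oblique sectors) layouts, a Hoehn-Yahr severity stage for the disease
group (mean 2.68, SD 0.82, truncated to [1, 5]), ages, sex and disease
duration. Out-of-range normal draws are *truncated* (clamped), not
resampled - simpler and fully deterministic, at the cost of a slight bias
toward the bounds for extreme-SD sectors. Sector values are drawn
independently across sectors, which understates within-subject spatial
correlation; the per-subject mean therefore has a smaller SD than the
printed per-sector SDs would suggest, and group discrimination on the
synthetic cohorts is easier than on real data. Passing the discrimination
test shows the pipeline preserves group separation through the image
path; it does not certify power on real cohorts. RNFL values are drawn,
never imaged - the generator makes no attempt at OCT simulation - and the
renderer is likewise not photorealistic: no retinal texture, no cup
topography, no peripapillary atrophy.

All randomness flows from a master seed through per-subject seeds, so
cohorts regenerate value-identically; rendering is bit-deterministic
given a spec, and the analysis path uses no randomness at all.

## Statistics

Group comparisons use the pooled-variance Student t test (the literal
named test; a Welch variant sits behind `welch = TRUE` since group SDs
can differ markedly), two-sided, complete-case per variable, with
Bonferroni correction by the family size: `0.05/25 = 0.002` for the Hb
family (mean + 24 sectors), `0.05/17` (about 0.003) for Cirrus RNFL,
`0.05/9` (about 0.006) for Spectralis. The Kolmogorov-Smirnov normality
gate is Lilliefors-style (parameters estimated from the sample, via
nortest) and advisory: its verdict is logged, but the pipeline does not
silently switch tests. Pearson correlations (`correlateVariables()`)
serve the Hb-vs-RNFL and Hb-vs-severity questions; zero-variance columns
and pairs with fewer than 3 complete observations return `NA` with a
warning. Degenerate comparisons are explicit: zero pooled variance with
equal means gives t = 0, p = 1; with unequal means the row is flagged
rather than given a fabricated p value.

## Problem sizes used in validation

The packaged defaults render 512 x 512 px images with a disc radius near
80 px. The test suite exercises single images at 192-256 px (disc radii
30-40 px), where sector statistics remain stable, and runs the replicate
cohort study - 20 independent cohorts of 91 + 155 subjects pushed through
the full image pipeline - at 192 px; the acceptance script computes the
two headline cohort means at the full 512 px default. Oracle-equivalence
checks (naive per-pixel aggregation, textbook pooled t, hand-rolled
Pearson r) run on 64 x 64 instances at tolerance 1e-10.

## Numerical and degenerate-input choices

* Pixel values are treated as gamma-encoded sRGB as stored; no
  linearization is applied (the index is a within-pixel ratio of stored
  values, and no calibration data exist to do better).
* No contrast enhancement or color "improvement" is ever applied: the QC
  stage only gates (luminance within [0.15, 0.85], per-channel saturated
  fraction at most 0.01, saturation margin 1/255) because any enhancement
  would corrupt the colorimetry downstream. The gates are conservative
  defaults, config-overridable.
* Division guards: epsilon = 1e-3 in the Hb index; green clamped at 1e-3
  in the vessel blue:green ratio.
* A uniform image has no 95th-percentile exceedance (strict inequality),
  so disc segmentation fails with an instructive error instead of
  returning a bogus ellipse; a candidate filling more than 60% of the
  search window is likewise rejected.
* Ring boundaries use closed upper intervals (rho <= 1/3 inner), and the
  wedge at exactly 2*pi wraps to wedge 8; every interior pixel receives
  exactly one label.

## Limitations

Equivalence with any commercial colorimetry implementation is not claimed
and cannot be tested: the commercial formula set and its calibration are
unpublished, and no raw images are deposited alongside the reference
cohort tables. What the package reproduces is the published *procedure* -
spectral index, vessel reference, lens compensation via green-blue
relations, 24-sector geometry, t/Bonferroni/Pearson statistics - and its
printed parameter tables as generator defaults. Printed p values in such
tables are generally not recoverable from rounded summary statistics;
only the procedure, not the exact p column, is reproducible. Real fundus
photographs carry camera-specific color response, peripapillary atrophy,
media opacities and fixation artifacts that the synthetic generator does
not model; on real data the segmentation stage in particular should be
treated as a baseline to swap out, which is why both segmenters sit
behind interfaces and accept external geometries.
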