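---
title: "Vascular morphometry and plaque quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vascular morphometry and plaque quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamvasc)
```

# The analysis problem

Label-free photoacoustic microscopy (PAM) of the rodent cerebral cortex
produces maximum-amplitude-projection angiograms in which hemoglobin
contrast renders the full vascular hierarchy — pial trunks above 100 µm
down to single capillaries of a few µm — on a 2 × 2 mm field sampled at
512 × 512 points (3.906 µm/px). Confocal fluorescence microscopy (CFM) of
the same field shows amyloid plaques as bright punctate spots over a
diffuse dye background. The quantities of scientific interest are

* **vessel length density (VLD)** — centerline length per unit area
  (mm/mm²), stratified by vessel diameter bin
  ([0,10), [10,20), [20,30), [30,40), [40,50), [50,∞) µm), and
* **plaque density** — spots per mm² —

compared between groups (disease model vs. wild type, age strata) with an
unpaired pooled-variance Student's t-test.

# The vessel binarization model

No single binarization handles this modality. The pipeline builds three
maps on the histogram-equalized image and combines them:

* **MAP1, global threshold**: vessel iff intensity > 1.1 × background
  level. Follows the true vessel distribution closely but admits noise and
  diffuse hemorrhage.
* **MAP2, small-kernel vesselness**: single-scale Frangi filter at a
  3 px kernel (σ = 1.5 px), thresholded by Otsu on its nonzero values.
  Rejects noise and non-tubular structure and keeps capillaries connected,
  but wide vessels hollow out ("fragmented in the center") because the
  small kernel sees their interior as flat.
* **MAP3, large-kernel vesselness**: the same filter at a 30 px kernel
  (σ = 15 px). Keeps wide vessels whole, dilates small ones.

The final mask is the Boolean combination

$$\mathrm{MAP_{ult}} = (\mathrm{MAP1} \wedge \mathrm{MAP3}) \vee \mathrm{MAP2}:$$

the permissive global map is trusted only where the large-kernel map
confirms vessel-like structure at scale, and the high-precision small
map is added unconditionally.

## Vesselness details

At scale σ the image is smoothed by a sampled Gaussian (symmetric
boundary reflection), the Hessian is assembled from central second
differences and γ-normalized by σ², and its eigenvalues are ordered
|λ₁| ≤ |λ₂|. For bright vessels on a dark background the response is 0
where λ₂ ≥ 0 and otherwise

$$v = \exp\!\left(-\frac{R_b^2}{2\beta^2}\right)
      \left(1 - \exp\!\left(-\frac{S^2}{2c^2}\right)\right),
  \qquad R_b = \lambda_1/\lambda_2,\;\; S = \sqrt{\lambda_1^2+\lambda_2^2}.$$

Parameter choices, all overridable:

* **σ = kernel_px / 2** — the source workflow specifies kernel scales in
  pixels without a σ convention; this mapping places the response peak of
  a width-w ridge near kernel ≈ w.
* **β = 0.5** — the canonical blobness sensitivity.
* **c = half the maximum Frobenius norm of the Hessian over the image
  interior** (adaptive). The boundary band of width 2σ is excluded from
  the maximum: padding artifacts there would otherwise rescale the whole
  image's response. That band is also reported as unreliable
  (`border_px`).
* Images are anchored at zero before filtering, making additive-offset
  invariance hold to ~1e-12 (bitwise invariance is impossible in floating
  point); with adaptive c, multiplicative gain invariance holds to 1e-6.

## Numerical behavior worth knowing

* The λ₂ sign gate is a knife edge: on the flanks of a rotated ridge the
  discrete Hessian keeps λ₂ slightly negative where the axis-aligned
  ridge is exactly gated off. Peak and centerline responses are
  rotation-equivariant to well under 5 %, but the mean absolute profile
  difference can reach ~9 % of peak in the flanks.
* Otsu on the nonzero vesselness values presumes a background/structure
  mixture. On a noise-free synthetic image the nonzero values are all
  structure, and Otsu bisects *structure* — one reason the clean-phantom
  pipeline path uses the global map (see the recovery test below).
* A single-scale pair (3 px, 30 px) leaves a genuine coverage gap for
  intermediate (20–50 µm) vessels in noisy scenes: too wide for MAP2,
  down-weighted at σ = 15 by the γ-normalization relative to large
  trunks. The combination rule inherits that gap where MAP1 alone cannot
  be trusted. This is a property of the published design, reproduced
  faithfully, not repaired.

## Hole filling (a deliberate pipeline addition)

Otsu-binarized vesselness leaves isolated sub-threshold pixels (blobness
dips where λ₁ ≈ λ₂) inside wide vessels. Because thinning is
topology-preserving, every such pinhole forces a loop: a handful of
pinholes turn a trunk's skeleton into a web that books tens of mm of
spurious "capillary" length. The pipeline therefore fills enclosed
background components smaller than `fill_holes_px` (default 100 px ≈
0.04 % of the field) before thinning. Unlike opening/closing, filling
moves no object boundary; genuine inter-vessel gaps — the inside of a
capillary loop is typically many hundreds of px — are untouched. Set
`fill_holes_px = 0` to disable.

# Morphometry

The mask is thinned (Zhang–Suen, 8-connected, a strict subset of the
mask); the skeleton is cut into segments at branchpoints (pixels with ≥ 3
skeleton neighbours, adjacent ones merged into one junction);
terminal spurs *and isolated fragments* shorter than `prune_px`
(default 10 px ≈ 40 µm — far below any real unbranched vessel) are
discarded; junctions reduced to degree 2 by pruning are merged through.

* **Length**: chord-resampled polyline length (every 12th path pixel plus
  endpoints), which suppresses the ±½ px staircase jitter of discrete
  skeletons; terminal tips retracted by thinning are extended along the
  end tangent to the mask boundary minus the local radius. Straight tubes
  at arbitrary orientation recover length within 2 px.
* **Diameter**: per skeleton pixel, `(2·EDT − 0.5) × pitch`, where EDT is
  the exact Euclidean distance transform of the mask. The −0.5 px term is
  the half-pixel offset between the nearest background pixel *center*
  (what EDT measures) and the object boundary, partly returned by the
  skeleton's own off-axis jitter. Per segment, the mean is taken over the
  segment *interior* (a quarter of the path, capped at one local
  diameter, is trimmed at each end) because the distance transform is
  inflated where a segment plugs into a junction blob. Unblurred straight
  tubes recover diameter within 1 px across 6–60 µm.
* **Binning**: each segment's full length is assigned to the bin
  containing its mean diameter; a diameter exactly on an edge goes to the
  upper bin.

**Resolution floor.** At 3.906 µm/px, a 10 µm bin edge is 2.56 px. Any
mask-based width estimator quantizes at the pixel level, and the optical
blur (8 µm FWHM) plus the small-kernel map's dilation broaden
sub-resolution structures; the instrument's own characterization puts the
broadening at 0–16 µm. Capillaries of 5–8 µm therefore cannot be reliably
separated from the 10–20 µm bin — the source study draws exactly this
conclusion about its own 10–20 µm bin. The package asserts the *direction*
of the effect (estimated ≥ true for true ≤ 8 µm) rather than pretending
per-bin accuracy below the floor.

# The synthetic phantom world

`phantom_spec()` defaults state the emulated world: 2 × 2 mm / 512 px
field; branching trees grown from field-edge roots with child diameter =
parent × `branch_decay` (default roots 110 µm, decay 0.6, stopping below
5 µm), smooth spline centerlines with continuous per-branch taper
(0.78–0.95 over the run) — real vessels taper, and continuous diameters
avoid artificial wholesale bin migrations; children sprout at the
parent's *surface* so recorded centerlines are never buried inside the
parent tube; capillary twigs (5–9 µm) are grown from arteriole-sized
hosts until ~30 % of total length is sub-10 µm. Interior intensity is
constant per vessel (hemoglobin contrast saturates); the scene is blurred
by a Gaussian PSF (FWHM 8 µm); background noise is additive Gaussian with
s.d. `noise_sigma`, optionally bandlimited at `noise_corr_um` (default
8 µm — envelope-projected acoustic noise is bandlimited; the marginal
s.d. is preserved by construction). Hemorrhage is modeled as low-contrast
filled disks (radius 150 µm, 30 % of vessel amplitude) — bright enough to
trigger the global threshold, too flat and too weak for the vesselness
maps. Geometry, noise, amplitudes and hemorrhage placement draw from
independent sub-streams of one master seed, so geometry is invariant
under noise-seed or blur changes.

What the phantom does **not** emulate: depth-dependent fluence, acoustic
bandwidth and reconstruction artifacts, vessel pulsation/motion, and the
rank statistics of real tissue background. A green test establishes that
the implementation recovers known geometry under the stated image model —
not that the instrument's images satisfy that model.

One rank-statistics caveat found during development: global histogram
equalization is a rank transform, so *any* continuous background noise —
regardless of its amplitude — is stretched across the output range in
proportion to its pixel share. Equalized synthetic noise is therefore
aggressively contrast-enhanced, and binarization false positives are
governed by the noise's spatial correlation, not its s.d.

# Plaque quantification

Manual annotation ingest (`x_um,y_um` CSV) is the authoritative route,
mirroring the manual counting procedure; results carry
`method = "manual"`. The automated surrogate is difference-of-Gaussians
blob detection matched to a 15 µm spot FWHM, strict local maxima, a
threshold at 40 % of the strongest response (gain-invariant), an absolute
floor at 10 % of the image dynamic range (otherwise pure noise always
yields "detections"), and greedy non-maximum suppression at 30 µm.
The 40 % threshold encodes the stated contrast model: plaque-bound dye is
2–3× brighter than residual intravascular background. On phantoms with
25 spots over both flat and vessel-contaminated backgrounds the detector
attains recall = precision = 1.0; that figure is specific to the
phantom's contrast model.

# Cohort statistics

`unpaired_t_test()` is the pooled-variance two-sided Student's t with
df = nₐ + n_b − 2 (Welch behind a flag). `compare_cohort()` emits one row
per metric (each VLD bin, total VLD, plaque density) and group pair with
means, s.d., s.e., t, df, raw p, and a clearly-labeled Holm-corrected
column as an extension — the source procedure reports raw per-bin p.
Degenerate inputs: identical groups give t = 0, p = 1; zero pooled
variance with unequal means is an error.

Simulated cohorts scale each group's expected per-bin true VLD by a
multiplier (branch thinning for m < 1, jittered duplication for m > 1)
and draw per-subject plaque counts from Poisson(density × area). With
`render = FALSE` only geometry and ground truth are produced, making the
Monte-Carlo designs (100 null cohorts for type-I calibration, 50 effect
cohorts for power/localization) run in about a minute.

# Acceptance-test design choices

* **VLD recovery** is judged on the analysis mask of *clean* phantoms
  (noise-free, unblurred; the test asserts the global-threshold map
  equals the true mask exactly before using it), pooled over a 5-phantom
  set, for bins with pooled true VLD ≥ 0.5 mm/mm²; the phantom set's
  smallest diameter class is ~13 µm (≥ 3 px), per the resolution-floor
  argument above. Pooled per-bin errors measured: +4.0 %, −5.7 %, −9.6 %.
* **Failure-mode reproduction** runs at the stated world's noise and blur
  (fragmentation of an 80 µm vessel by the small kernel; > 90 % hemorrhage
  coverage by MAP1 vs < 20 % by MAPult). During design, permissive MAP3
  thresholds that would close the mid-size coverage gap were found to
  break hemorrhage rejection (coverage 0.6–0.85): at the large kernel
  scale, hemorrhage is distinguished by its low contrast, not its shape,
  so the Otsu threshold is retained.
* **Monte-Carlo statistics** run on ground-truth VLD (the phantom
  geometry is the random variable), which tests the statistical machinery
  at scale without 1000 image-pipeline runs.

# Known limitations

* Mid-size (20–50 µm) vessel coverage in noisy scenes (see above).
* Diameters below ~3 px are reported but upward-biased; the capillary /
  10–20 µm split is not quantitative at this pitch.
* Skeleton-based lengths underestimate truth by ~5–10 % in dense networks
  (junction consumption, branch crossings).
* The equalize-then-threshold order follows the published workflow; the
  background level is re-estimated on the equalized image. Both orders
  are available via `vessel_maps(equalize_first = )`.
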