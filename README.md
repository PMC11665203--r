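# pamvasc

Quantitative vascular morphometry and amyloid-plaque counting for
photoacoustic / fluorescence dual-modality microscopy of the rodent
cerebral cortex — with a synthetic phantom generator so the whole
pipeline is testable against exact ground truth, no animal data needed.

## Who this is for

Labs analyzing maximum-amplitude-projection PAM angiograms (2 × 2 mm
field, 512 × 512 px, ≈3.9 µm/px) together with confocal fluorescence
images of dye-labeled amyloid-β plaques, who want the vessel-size-resolved
length-density statistics and plaque densities used to characterize
Alzheimer's-model vasculature — and a way to validate every stage of that
analysis on images with known answers.

## The model at the core

Vessels are segmented by combining three binarizations of the
histogram-equalized image:

- **MAP1** — global threshold: vessel iff intensity > 1.1 × background
  level (background = sigma-clipped mean, or an explicit ROI);
- **MAP2** — single-scale Frangi vesselness at a 3 px kernel
  (capillary-matched), Otsu-binarized;
- **MAP3** — the same at a 30 px kernel (trunk-matched);

combined as **MAPult = (MAP1 ∧ MAP3) ∨ MAP2**. The mask is thinned to a
skeleton, cut into segments at branchpoints, and each segment gets a
length (chord-resampled centerline, µm) and a diameter (2·EDT − 0.5 px at
the skeleton, averaged over the segment interior). Vessel length density

VLD = centerline length / image area  (mm/mm²)

is reported per diameter bin [0,10), [10,20), [20,30), [30,40), [40,50),
[50,∞) µm. Plaques are counted manually (CSV ingest) or by a
difference-of-Gaussians spot detector. Groups are compared with the
pooled two-sample Student's t-test (Welch optional), one test per
(metric, bin, group pair).

The Frangi filter, at scale σ = kernel/2, uses the standard 2-D
vesselness `exp(-Rb²/2β²)·(1-exp(-S²/2c²))` on the σ²-normalized Hessian
eigenvalues (|λ₁| ≤ |λ₂|; zero where λ₂ > 0), β = 0.5, c adaptive.

## Worked example

Generate a phantom with known centerline lengths, binarize, skeletonize,
and compare estimated vs. true per-bin VLD:

```r
library(pamvasc)

spec <- phantom_spec(n_trees = 6, root_diameter_um = 65,
                     branch_decay = 0.52, capillary_fraction = 0,
                     psf_fwhm_um = 0, noise_sigma = 0,
                     min_diameter_um = 10, seed = 3)
ph <- generate_vessel_phantom(spec)
w  <- equalize(ph$image)
m1 <- map1_global(w, estimate_background(w))  # == true mask on a clean scene
g  <- build_graph(skeletonize_mask(m1), m1$mask, ph$image$pixel_pitch_um)
vld_profile(g)
#> <vld_profile> total 2.347 mm/mm2 on 4.00 mm2
#>    bin lo_um hi_um  length_mm        vld
#>   0-10     0    10 0.00000000 0.00000000
#>  10-20    10    20 3.00219116 0.75054779
#>  20-30    20    30 2.83250490 0.70812622
#>  30-40    30    40 0.08615656 0.02153914
#>  40-50    40    50 0.08793266 0.02198317
#>    >50    50   Inf 3.38066759 0.84516690

round(truth_vld(ph$truth, image_area_mm2(ph$image)), 3)
#>  0-10 10-20 20-30 30-40 40-50   >50
#> 0.150 0.662 0.712 0.000 0.000 0.872
```

The three populated bins recover truth within 13 %, 1 % and 3 %. (The
0.15 mm/mm² of true sub-10 µm length sits below the pixel-resolution
floor and surfaces in the 10–20 µm bin — the same 0–16 µm broadening the
instrument's edge-spread characterization predicts; see the methods
vignette.)

The full noisy-image pipeline is one call, and a two-group simulated
study is two more:

```r
res <- run_subject(generate_vessel_phantom(phantom_spec(seed = 7))$image)
res$vld            # per-bin VLD through equalize -> MAP1/2/3 -> MAPult
res$graph          # per-segment lengths and diameters

groups <- list(
  list(label = "WT", vld_multiplier_per_bin = 1,  plaque_density_per_mm2 = 2),
  list(label = "AD", vld_multiplier_per_bin = c(1, 0.8, 1, 1, 1, 1),
       plaque_density_per_mm2 = 9))
subs <- simulate_cohort(cohort_spec(5, groups, seed = 1), phantom_spec(seed = 1))
st <- run_study(subs)
st$report          # tidy table: metric, bin, means, sd, se, t, df, p, p_holm
```

Plaque counting on a fluorescence phantom:

```r
pp  <- generate_plaque_phantom(25, spot_fwhm_um = 15, "vessel_bleed", seed = 4)
det <- detect_plaques(pp$image)
det$count                                   # 25
match_plaques(det, pp$truth$plaque_xy, 15)  # recall 1.0, precision 1.0
plaque_density(det)                         # 6.25 per mm^2
```

A command-line driver ships in `inst/cli/pamvasc`
(`pamvasc phantom|plaques|vesselmap|morpho|plaque|study ...`).

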