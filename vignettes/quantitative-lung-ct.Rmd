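---
title: "Methods: quantitative lung CT under paired reconstruction algorithms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative lung CT under paired reconstruction algorithms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungqct)
```

## What the package models

Quantitative CT biomarkers of emphysema and small-airways disease are
computed from the attenuation histogram of the segmented lung and from
cross-sectional airway geometry. Because several of these biomarkers are
*threshold* statistics, they respond not only to anatomy but also to image
noise: a denoising reconstruction narrows the attenuation histogram and
pulls voxels back across fixed HU cut-offs. `lungqct` implements the full
measurement battery plus a synthetic phantom study that isolates exactly
this mechanism: identical anatomy rendered at two noise levels, measured
identically, compared within subject.

The moving parts, in pipeline order:

1. **Phantom generation** (`phantom_params()`, `generate_phantom()`) — a
   soft-tissue thorax with an ellipsoidal lung, spherical emphysema
   clusters and air-trapping regions, and a straight airway tube along the
   axial axis.
2. **Reconstruction rendering** (`recon_params()`,
   `apply_reconstruction()`) — additive Gaussian noise at an FBP level and
   at a fractionally reduced IR level.
3. **Lung segmentation** (`segment_lungs()`, `check_segmentation()`) —
   threshold + 3-D connected components with airway removal and typed
   failure signalling.
4. **Densitometry** (`compute_densitometry()` and the single-index
   functions) — IN₋₉₅₀, Perc15, EXP₋₈₅₆, RVC₋₈₆₀ ₜₒ ₋₉₅₀,
   E/I-ratio of mean lung density.
5. **Airway morphometry** (`measure_airway()`) — FWHM ray casting giving
   LA, WA, WA%, Pi.
6. **Agreement analysis** (`concordance_correlation()`,
   `wilcoxon_signed_rank()`, `compare_algorithms()`) and the orchestrating
   `run_study()`.

## The phantom: what it emulates, and what it does not

The phantom stands in for paired inspiratory/expiratory chest CT of a
screening-age smoking cohort. Its default geometry is a 128³ grid at
0.7 mm in-plane and 1.0 mm axial spacing — the anisotropy of a thin-slice
chest protocol at desk scale. Tissue classes are painted with mean
attenuations (defaults):

| class | inspiration | expiration | why |
|---|---|---|---|
| normal lung | −850 HU | −750 HU | physiologic MLD range; expiration densifies lung that empties |
| emphysema | −980 HU | −980 HU | below the −950 HU density mask; destroyed tissue does not empty |
| air trapping | −850 HU | −890 HU | invisible at inspiration, stays air-like (< −856 HU) at expiration |
| airway wall | −100 HU | −100 HU | soft-tissue-like wall against an air lumen |
| soft tissue | +40 HU | +40 HU | chest wall / mediastinum |

Around each class mean a per-voxel Gaussian texture (SD 30 HU) is added so
histograms are realistic unimodal curves rather than delta spikes.
Emphysema is placed as random spheres of radius 1.5–3.5 mm, air trapping as
larger 3–6 mm spheres, stamped into normal lung until the requested voxel
fractions are reached (the placement loop undershoots by at most a few
voxels; requesting more burden than the lung can host raises a parameter
error). The airway tube runs through the lung and continues superiorly into
the mediastinum, so that — as in a real scan — the most superior air
component of the body is airway, which is what the segmenter removes.

Cohorts draw per-subject parameters uniformly from
`cohort_severity_ranges()`: emphysema fraction 0.02–0.20, trapping fraction
0.05–0.25, lumen radius 1.4–2.6 mm, wall thickness 1.2–2.2 mm, and normal
lung attenuation varying by ±20 HU at each phase between subjects. These
ranges give the between-subject spread against which within-subject
reconstruction differences are judged; a degenerate range (min = max) pins
a parameter cohort-wide.

What the phantom does *not* emulate — and therefore what passing tests do
not establish about real data: projection-domain physics (beam hardening,
streaks, spatially varying noise), noise texture/correlation (noise here is
white; real FBP noise is correlated by the reconstruction kernel),
respiratory motion and inspiration-depth differences, lobar anatomy,
vessels and adjacent-airway clutter, and partial-volume blur at tissue
interfaces (class boundaries are voxel-sharp). The phantom study shows the
*mechanism* — threshold indices respond to noise width, mean-based measures
do not — not clinical effect sizes.

## The noise model

Reconstruction noise is independent zero-mean Gaussian per voxel with SD
`noise_sigma_hu` for FBP (default 80 HU, an expiratory-protocol-like level
at which threshold densitometry visibly responds) and
`noise_sigma_hu * (1 - noise_reduction)` for IR (default reduction 0.45).
IR is modeled *purely* as a narrower noise amplitude — no extra smoothing or
resolution change — matching the behaviour of a hybrid IR algorithm that
reduces noise without altering image characteristics. The absolute sigma is
a package choice (only the relative reduction is externally meaningful),
which is why the acceptance checks are directional and relative rather than
absolute.

When both renderings of one phase are produced with the same seed, the two
noise fields are the same standard-normal field scaled by their sigmas.
`run_study()` does exactly that, deliberately: two reconstructions of one
raw acquisition share their noise origin, so their residual noise is
correlated. This also makes the study maximally paired, as in a
reconstruct-twice design.

## Segmentation

`segment_lungs()` is a bespoke threshold-and-components method: voxels at
or below −320 HU are air-like; 3-D 26-connected components are built by
labeling each axial slice in 2-D and merging labels across adjacent slices
with a union-find (EBImage labels frames independently); components
touching the grid border are ambient air and discarded; the most superior
remaining component is removed as airway provided it is plausibly small
(`airway_cap_ml`, default 100 ml — a whole lung never qualifies); if image
noise has flipped enough wall voxels below the air threshold to bridge
lumen and lung into one fused component, the airway is instead extracted by
geodesic region growing from the most superior air voxel at progressively
stricter thresholds (−500, −650, −800 HU) until the grown region fits the
volume cap — the standard adaptive defence against trachea "leaks";
remaining components of at least `min_component_ml` form the lungs; small
in-plane holes are closed with a 3×3 morphological closing. The −320 HU threshold
sits comfortably between lung parenchyma (≈ −850 HU) and soft tissue
(≈ +40 HU) at the modeled noise levels.

Failure is a typed condition (`lungqct_segmentation_failure`), raised when
no lung-like component exists or when the segmented volume falls outside
plausibility bounds (defaults 5–9000 ml, spanning small phantoms to large
human lungs; a clinical deployment would narrow them). `check_segmentation()`
is the automated surrogate for a reader's visual check: volume bounds plus
a border-contact criterion (at most 1 % of mask voxels on the grid
boundary). In `run_study()` any failure excludes the subject with a logged
stage and reason — exclusion accounting mirrors how cohort studies report
segmentation failures — and never aborts the cohort.

## Densitometry conventions

Thresholds described as "below" are strict (`<`); the RVC band
[−950, −860] HU is inclusive at both ends, and voxels below −950 HU are
outside it. Percentiles (Perc15, and the median/IQR summaries) use linear
interpolation between order statistics at position `(n − 1)·p` — the
default convention of `stats::quantile()` (type 7) — documented because
percentile conventions differ between packages and shift Perc15 by a
fraction of an HU at histogram granularity. HU values stay real-valued
throughout; nothing is quantized before statistics. Inspiratory and
expiratory masks are segmented independently, as a real pipeline segments
each series.

Two invariances matter scientifically and are tested exactly: Perc15 is
translation-equivariant (adding c HU moves it by c), and the E/I-ratio is
invariant to a common rescaling of both volumes. The E/I-ratio is also the
one air-trapping measure whose expectation is untouched by zero-mean noise
of any width — means are preserved where tail shares are not — which is
precisely why it stays concordant across reconstructions in the study.

## Airway morphometry: FWHM details

The seed (in the phantom pipeline: the true tube centre; interactively: a
click in the lumen) is refined to the centroid of the connected lumen
region below −700 HU. 128 rays at equal angles sample the slice by bilinear
interpolation in 0.1 mm steps out to 10 mm. On each ray, the wall is the
*first* prominent maximum beyond the lumen: the profile must rise at least
250 HU above its running minimum to count as entering the wall, and the
peak window closes once the profile has fallen 250 HU below its running
maximum. The prominence threshold sits far below the ≈900 HU lumen-to-wall
contrast but above plausible noise excursions; taking the first peak (not
the global maximum) keeps the boundary on the airway wall when the ray
later crosses brighter structures such as the chest wall. The inner
boundary is the half-maximum crossing between lumen minimum and wall peak,
the outer boundary the half-crossing between peak and the parenchymal
minimum beyond it, both located to sub-step precision by linear
interpolation. Rays without a usable peak are invalid; rays whose radii
deviate more than 3 scaled MADs from the angular median are rejected as
outliers; if fewer than 75 % of rays survive, the measurement fails as a
typed condition. Surviving gaps are filled by circular interpolation, and
the radii are smoothed with a 5-ray circular moving average before the
polygons are assembled — half-max crossings carry sub-voxel sampling jitter
that is nearly unbiased for enclosed area but inflates the perimeter of a
jagged polygon; averaging a few neighbouring rays removes the jitter while
hardly biasing a smooth contour. LA and the outer area are shoelace polygon
areas, WA their difference, Pi the inner polygon perimeter, and
WA% = 100·WA/(WA+LA) holds as an arithmetic identity of the outputs.

Ray count, step, prominence and smoothing defaults are package choices (the
validated clinical implementations do not publish theirs at this
granularity); the test suite exercises their sensitivity through rotation
invariance, noise-pair agreement and analytic-annulus recovery at 5 %.

## Agreement statistics

Lin's concordance uses moment estimators with denominator *n* (the original
moment form; an n−1 convention shifts p_c slightly at small n — a
documented choice, not a discovery). It errors only when the denominator
s_x² + s_y² + (x̄−ȳ)² is zero, the genuinely undefined case. The
descriptive scale is applied with its boundaries exactly as stated:
poor < 0.90 ≤ moderate ≤ 0.95 < substantial ≤ 0.99 < almost perfect.

The Wilcoxon signed-rank test discards zero differences before ranking
(classic treatment; the count is reported) and is exact for up to 25
non-zero pairs: the permutation distribution over all 2ⁿ sign assignments
is computed by dynamic programming over doubled midranks, so *tied* ranks
are handled exactly too — the reason the test is implemented here rather
than delegated to `stats::wilcox.test()`, which falls back to a normal
approximation under ties. The two-sided p-value sums the probability of
deviations |W − E(W)| at least as extreme as observed (equal, by symmetry
of the null, to twice the one-sided tail). Beyond n = 25 a normal
approximation with tie-corrected variance and a 0.5 continuity correction
is used; the suite checks it against the exact null at the switch point.
The significance threshold is 0.05 with no multiplicity correction,
matching common practice in paired-agreement studies of this design.

## Problem sizes and determinism

The shipped study conditions are 30 subjects on 128³ grids — large enough
that densitometry runs over ≈250 k lung voxels per subject and cohort
statistics stabilise, small enough to run on a laptop in a few minutes.
Unit tests use 48³–64³ phantoms of identical structure. Every random draw
descends from a single master seed (per-subject seeds, then per-phase noise
seeds, are derived deterministically), so reruns of the same configuration
are bit-identical; this is asserted by tests.

## Known limitations

* White noise only; correlated noise (a reconstruction-kernel convolution)
  is a natural extension the architecture leaves room for, but is off by
  design because the modeled IR changes amplitude, not texture.
* One ellipsoidal "lung": no lobes, no left/right split, no vessels — so
  segmentation here is easier than clinical segmentation, and the Dice
  criterion speaks to the pipeline's correctness, not clinical robustness.
* The airway is measured on axial cross-sections of a z-aligned tube;
  oblique airways would need reformatting that is out of scope.
* Densitometry is not volume-corrected for inspiration depth, and no
  emphysema cluster-size analysis is attempted.
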