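# lungqct

Quantitative CT of the lungs — emphysema densitometry, air-trapping indices,
full-width-at-half-maximum (FWHM) airway morphometry — and the agreement
statistics needed to ask whether a change of image-reconstruction algorithm
changes those numbers.

## The problem

Quantitative CT turns chest images into biomarkers of chronic obstructive
pulmonary disease. From the attenuation histogram of the segmented lung one
computes, in Hounsfield units (HU):

* **IN₋₉₅₀** — emphysema extent: % of inspiratory lung voxels < −950 HU
  (the "density mask");
* **Perc15** — emphysema: the HU value at the 15th percentile of the
  inspiratory attenuation histogram;
* **EXP₋₈₅₆** — air trapping: % of expiratory lung voxels < −856 HU;
* **RVC₋₈₆₀ ₜₒ ₋₉₅₀** — air trapping: change (expiration − inspiration) of
  the relative lung volume with attenuation in [−950, −860] HU;
* **E/I-ratio<sub>MLD</sub>** — air trapping: 100 × MLD<sub>exp</sub> /
  MLD<sub>insp</sub>, the expiratory-to-inspiratory ratio of mean lung
  density (MLD).

Airway dimensions of a segmental bronchus are measured by the FWHM method:
rays are cast from the lumen centre outward, the inner wall boundary is
placed halfway between the lumen minimum and the wall attenuation peak, and
the outer boundary halfway between the peak and the parenchymal minimum
beyond it; the boundary polygons give lumen area (LA), wall area (WA),
WA% = 100·WA/(WA+LA) and internal perimeter (Pi).

Iterative reconstruction (IR) denoises CT images relative to classical
filtered back-projection (FBP) — a hybrid IR at a typical clinical setting
reduces noise by ~45 % without otherwise changing the image. Narrower noise
means fewer voxels spill across fixed HU thresholds, so threshold-based
indices shift even though the anatomy is identical, while mean-based
measures should not care. `lungqct` makes that mechanism reproducible
without patient data: a synthetic thoracic phantom generator produces paired
inspiratory/expiratory volumes with known emphysema and air-trapping burden
and an embedded airway of known annular geometry, renders each volume at an
FBP noise level and at a 45 %-reduced IR level, and a pipeline segments,
measures and compares the two renderings the way a paired clinical study
would:

* within-subject agreement by **Lin's concordance correlation**
  p<sub>c</sub> = 2·s<sub>xy</sub> / (s<sub>x</sub>² + s<sub>y</sub>² +
  (x̄ − ȳ)²), classified on the descriptive scale
  (poor < 0.90 ≤ moderate ≤ 0.95 < substantial ≤ 0.99 < almost perfect);
* paired differences by the **Wilcoxon signed-rank test**, with an exact
  permutation null (ties included) up to n = 25;
* cohort summaries as medians with interquartile ranges.

## Worked example

```r
library(lungqct)

cfg <- run_config(n_subjects = 10, seed = 42,
                  base_params = phantom_params(grid_shape = c(64, 64, 64)))
study <- run_study(cfg)
study
#> <lung_study> 10/10 subjects included (0 excluded)
#> # A tibble: 9 × 5
#>   measure      n    pc agreement_class wilcoxon_p
#>   <chr>    <int> <dbl> <chr>                <dbl>
#> 1 in950       10 0.532 poor               0.00195
#> 2 perc15      10 0.559 poor               0.00195
#> 3 exp856      10 0.770 poor               0.00195
#> 4 rvc         10 0.331 poor               0.00195
#> 5 ei_ratio    10 0.999 almost perfect     0.846
#> 6 la          10 1.000 almost perfect     0.131
#> 7 wa          10 0.999 almost perfect     0.00391
#> 8 wa_pct      10 0.997 almost perfect     0.00391
#> 9 pi          10 1.000 almost perfect     0.695
```

Read the table as a paired FBP-versus-IR comparison across ten simulated
subjects. The threshold-based indices (IN₋₉₅₀, Perc15, EXP₋₈₅₆, RVC) show
poor concordance and significant paired differences — the denoising moved
them — whereas the E/I-ratio of mean lung density and the airway dimensions
are almost perfectly concordant: means and FWHM boundary positions are
nearly noise-invariant. `autoplot(study)` draws the per-measure scatter
against the identity line; `study$densitometry`, `study$airway` and
`study$exclusions` hold the per-subject detail.

Airway morphometry recovers analytic truth on an ideal annulus
(r<sub>inner</sub> = 1.8 mm ⇒ LA = π·1.8² = 10.18 mm², Pi = 11.31 mm;
r<sub>outer</sub> = 3.8 mm ⇒ WA = 35.19 mm²):

```r
sl <- generate_annulus_slice(r_inner_mm = 1.8, r_outer_mm = 3.8, spacing_mm = 0.25)
measure_airway(sl, attr(sl, "center_xy_mm"))
#> <airway_measurement> LA 10.03 mm^2, WA 35.25 mm^2, WA% 77.9, Pi 11.50 mm (128/128 rays)
```

A command-line wrapper with `simulate`, `segment`, `densitometry`,
`airway`, `agreement`, `run-all` and `config` subcommands lives at
`inst/cli/lungqct.R` (volumes as NIfTI, tables as CSV/JSON).

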