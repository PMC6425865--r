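# gliomig

Quantification of immunohistochemistry, cell migration and spheroid
invasion assays in glioma research.

Studies of receptor expression in brain tumours typically chain together
four measurements: (1) DAB immunohistochemistry on a tissue microarray
(TMA) is scored per core, manually (intensity 0–3 plus stained-proportion
bin 0–4, composite out of 7) and digitally (positive-pixel "positivity"
mapped to a 0–7 score); (2) scores are dichotomized into low/high
expression and tested against clinicopathologic covariates with Pearson's
chi-squared or Fisher's exact test on r×c contingency tables; (3) 2D
time-lapse cell tracks are summarized as velocity, directionality
(displacement / path length) and rose plots, with fluorescence quantified
as CTCF = integrated density − area × background mean; and (4) 3D
spheroid outgrowth into collagen is indexed per zone as
MI(t) = (r(t) − r(0)) / r_core(0) for the dense migration *front* and the
outermost single-cell *edge*. gliomig implements that whole chain as
plain, tested R functions — for analysts who want the arithmetic behind
such studies to be reusable and checkable rather than buried in scanner
software and spreadsheets.

Every stage is paired with a seeded synthetic generator (cohorts with
exact replayed cross-tabulations, stained cores with ground-truth masks,
persistent-random-walk trajectories, spheroid mask series with known
radii), so the pipeline can be verified end to end without any external
data.

## Worked example

Replay a published localization-by-malignancy cross-tabulation through
the cohort generator and test it exactly:

```r
library(gliomig)

counts <- matrix(c(23L, 12L, 25L, 2L, 5L, 15L), ncol = 2,
                 dimnames = list(c("membranous", "cytoplasmic", "negative"),
                                 c("malignant", "benign")))
cohort <- gen_cohort(cohort_spec(counts, "localization", "tumor_type"))
tab <- build_table(cohort, "localization", "tumor_type")
fisher_exact_rxc(tab)
#> Fisher exact (Freeman-Halton)
#>   p-value = 0.024
```

The exact p of 0.024 says the uneven spread of membranous vs negative
staining across malignant and benign cores is unlikely under
independence — membranous localization is over-represented in malignancy.

Score a synthetic stained core closed-loop (40% of tissue pixels stained
at medium intensity; the pixel pipeline recovers the truth):

```r
core <- gen_core_image(core_image_spec(intensity_level = 2,
                                       stained_fraction = 40, seed = 7))
sep <- separate_stains(core$image)
pos <- positivity(sep$dab, core$tissue_mask)
c(positivity = pos, digital_score = digital_score(pos))
#>   positivity digital_score
#>         40.0             3
```

Simulate persistent-random-walk tracks at a realistic glioma speed and
measure them, then index a spheroid series:

```r
tr <- gen_tracks(prw_params(speed = 0.12, persistence_time = 30, dt = 1,
                            duration = 4320, n_cells = 50, seed = 3))
st <- track_stats(tr)
round(c(velocity = mean(st$velocity), directionality = mean(st$directionality)), 3)
#>       velocity directionality
#>          0.120          0.094

sim <- gen_spheroid_series(spheroid_sim_spec(250, front_rate = 250 * 0.32 / 72,
                                             edge_rate = 250 * 0.56 / 72, seed = 5))
measure_series(sim$masks, sim$truth$t_h, sim$pixel_size)
#> Spheroid series `spheroid` (condition: control)
#>  t_h core_radius front_radius edge_radius mi_front mi_edge
#>    0       250.0          250       250.0    0.000  0.0000
#>   24       276.7          278       297.0    0.112  0.1880
#>   48       303.4          304       344.0    0.216  0.3760
#>   72       329.9          330       390.3    0.320  0.5614
```

The mean measured velocity equals the simulated 0.12 μm/min, and the
72-hour migration indexes recover the calibrated front/edge targets
(0.32 / 0.56) to well within one pixel's worth of error.

`reproduce_tables()` replays every packaged published cross-tabulation
under the documented conventions (uncorrected chi-squared, "unknown"
excluded from tumour-type/grade tests, Freeman–Halton exact test for
localization) and reports recomputed statistics side by side with the
printed p-values. A thin CLI over these functions ships in
`inst/scripts/gliomig-cli.R` (subcommands `simulate`, `score-tma`,
`associate`, `tracks`, `spheroid`, `reproduce-tables`, `demo`).

## Layout

- `R/` — generators (`synthetic-*.R`), scoring (`ihc-scoring.R`,
  `stains.R`), statistics (`association.R`, `printed-tables.R`), track
  and spheroid analytics, pipeline orchestration.
- `vignettes/gliomig-methods.Rmd` — models, parameter choices, generator
  design, numerical conventions, limitations.
- `tests/testthat/` — unit, property and end-to-end suites with
  independent oracles.
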