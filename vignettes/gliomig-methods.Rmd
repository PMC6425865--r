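---
title: "Methods: how gliomig quantifies IHC, migration and invasion assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how gliomig quantifies IHC, migration and invasion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomig)
```

gliomig re-implements, as ordinary tested R code, the measurement chain
used in tissue-microarray (TMA) and migration studies of pediatric gliomas:
scoring DAB immunohistochemistry on tissue cores, testing scored cohorts
for clinicopathologic associations, quantifying 2D cell trajectories, and
indexing 3D spheroid outgrowth. This vignette explains each model, the
parameters that matter, what the synthetic generators do and do not
emulate, and the design decisions that were genuinely open.

## IHC scoring

### Stain model

Brightfield absorbance follows Beer–Lambert. An 8-bit channel value $v$ is
converted to optical density $OD = -\log_{10}((v+1)/256)$, and a stained
pixel's OD vector is modelled as a non-negative combination of unit stain
vectors: haematoxylin $(0.650, 0.704, 0.286)$ and DAB
$(0.269, 0.568, 0.872)$, the widely used published H/DAB values, completed
by an orthogonal residual. `separate_stains()` inverts this mixing (colour
deconvolution in the Ruifrok–Johnston sense) and clamps concentrations at
zero. The synthetic core generator mixes with the same matrix, so at zero
noise the separation is exactly invertible up to 8-bit quantization —
which is what makes closed-loop positivity tests meaningful.

### Positivity and the two score scales

`positivity()` is the percentage of tissue pixels whose DAB concentration
exceeds an OD threshold (default **0.15**, configurable). The commercial
scanner metric it replaces uses a proprietary threshold; the default here
was chosen once as a round value comfortably above quantization noise and
below the weakest synthetic stain level, and the closed-loop tests are
threshold-robust by construction (stained and unstained pixels are
separated by a wide OD gap).

Two score scales are computed, as in TMA practice:

* **manual composite (0–7)** = intensity grade (0–3) + stained-proportion
  bin (0–4, with bins 0, 1–25, 26–50, 51–75, 76–100%);
* **digital score (0–7)** from positivity via the fixed interval table
  with edges 12.5, 25, 37.5, 50, 62.5, 75, 87.5.

The printed interval tables use integer-percent labels and therefore have
gaps (25 → 26, 50 → 51, …). Both mappings are implemented with intervals
half-open on the left — $[0, 12.5], (12.5, 25], \dots, (87.5, 100]$ — which
preserves every printed integer anchor while leaving no fractional input
unmapped; totality and monotonicity are property-tested on a 0.1-step
grid.

`dichotomize()` splits scores at a cut-point, default the cohort median
with ties assigned "high". The source analyses dichotomized post hoc
without stating a threshold; the median is the convention that matches
that description without inventing a fixed cut, and it is exposed as a
parameter. The >50%/<50% split used for proliferation and apoptosis
markers is the same operation with an explicit cut-point.

`classify_localization()` operationalizes the negative / cytoplasmic /
membranous call from a membrane-ring OD and a cytoplasm OD: both below a
negative threshold (default 0.1 OD) → negative, otherwise membranous when
the ring/cytoplasm ratio reaches 1.5 (positive ring over zero cytoplasm is
membranous by convention). The published study made this call by eye; the
thresholds are declared stand-ins and are parameters, not claims.

Cores with an empty tissue mask are excluded and logged rather than
scored, mirroring how unanalysable TMA cores are handled.

## Association statistics

`build_table()` cross-tabulates a scored cohort, after dropping records in
excluded categories. Two conventions were fixed by reproducibility of the
published numbers and are documented in every report:

* **No Yates continuity correction.** The location table
  $[[33,50],[13,0]]$ yields $p \approx 5.3\times10^{-5}$ uncorrected
  (consistent with the printed $p < 0.0001$) but
  $\approx 1.8\times10^{-4}$ corrected.
* **"Unknown" categories are excluded from tumour-type and grade tests.**
  The digital tumour-type p reproduces as $<0.001$ only on the 2×2
  benign/malignant table, and the digital grade p as 0.02 on grades 1–4
  only.

`pearson_chi2()` computes $\sum (O-E)^2/E$ with
$E = \text{row total}\times\text{col total}/N$ on $(r-1)(c-1)$ degrees of
freedom. `fisher_exact_rxc()` implements the Freeman–Halton
generalization of Fisher's exact test: exhaustive depth-first enumeration
of all tables with the observed margins, summing multivariate
hypergeometric probabilities of tables *as or less probable* than the
observed one. Probabilities are compared with a relative tolerance of
$10^{-7}$ so floating-point ties count as ties; the enumeration is guarded
at $N \le 500$ (beyond that the chi-squared test is the right tool). In
tests the implementation is cross-checked against two independent routes:
direct hypergeometric enumeration for 2×2 tables and a vectorized
grid-materialization oracle for 3×3 tables, plus `fisher.test()`.

One published value resists reproduction: the 3×3 localization-by-grade
table prints $p = 0.010$, while the standard as-or-less-probable criterion
gives $p = 0.01095$ (0.011 at three decimals). Strict-inequality and
mid-p variants do round to 0.010 but are not the standard definition (and
tie-exclusion can produce $p = 0$ on degenerate tables), so the standard
criterion is kept and the replay report shows the divergence rather than
hiding it.

p-values are displayed to three decimals (scientific below $10^{-4}$),
and comparisons against printed two-decimal values use round-half-up, the
convention of the printed tables. No multiple-testing correction is
applied, matching the source analyses; reports say so in a footer.

`compare_conditions()` wraps the unpaired two-sample t-test (pooled
variance by default, matching a generic Prism-style analysis; Welch by
flag) and handles the zero-variance degenerate case explicitly.

## Track analytics

`track_stats()` derives, per cell: path length (sum of consecutive step
lengths, using actual $\Delta t$ with no interpolation across missing
frames), net displacement, **velocity** = path length / duration
(curvilinear speed), and **directionality** = displacement / path length —
1 for straight-line motion, 0 for closed paths, and 0 by convention for a
stationary cell. Velocity and displacement are both always reported
because "distance traveled" in the source figures is the
persistence-bearing quantity (net displacement over 72 h), distinct from
curvilinear speed. `rose_summary()` bins net-displacement angles into
equal sectors (default 12); zero-displacement tracks have no angle and
are counted separately rather than binned.

CTCF (corrected total cell fluorescence) is
`integrated_density − area × background mean`; it is affine in each
argument and may legitimately be negative (flagged with a warning).

## Spheroid migration

`measure_frame()` measures three radii about the centroid of the largest
connected component (labelled with EBImage):

* **core** — equivalent-circle radius $\sqrt{A/\pi}$ of that component;
* **front** — outer radius of the region where per-annulus (1 px wide)
  cell-pixel occupancy stays ≥ a threshold (default **0.2**), i.e. the
  dense collectively-migrating rim;
* **edge** — distance to the farthest cell pixel, the outermost single
  migrating cells.

The front/edge split follows the two measuring zones of collagen invasion
assays: a dense front with sparse single cells beyond it. A lone far
pixel moves the edge, never the front.

The **migration index** is computed per zone as
$$MI_{zone}(t) = \frac{r_{zone}(t) - r_{zone}(0)}{r_{core}(0)}.$$
The index cited in the source literature is not given in closed form
there; this definition — a zone's radius increase normalized to the
initial core radius — was chosen because it is dimensionless, exactly 0
at $t = 0$, and reproduces the reported 0–0.6 magnitude range. Using the
zone's *own* $t=0$ radius as baseline (rather than the core estimate)
keeps MI identically zero at $t = 0$ even though core and front radii are
measured by different estimators that can disagree by a fraction of a
pixel; on ground truth the two baselines coincide. The formula lives in
one small function (`migration_index()`) so an alternative index can be
swapped in. Imaging timepoints default to 0/24/48/72 h, the usual
schedule of these assays.

`treatment_effect()` compares per-spheroid MI between conditions at a
timepoint (nearest frame with a warning if absent), requires ≥ 3
replicate spheroids per condition, and flags each contrast as
anti-migratory or pro-migratory by the sign of the mean difference.

## Synthetic data: what it emulates, and what it does not

The generators exist so that every downstream stage has recoverable
ground truth; their defaults encode the study conditions.

* **Cohorts** (`gen_cohort()`): replay mode is an exact inverse of
  cross-tabulation — replaying a printed table and rebuilding it returns
  the printed counts cell for cell; sample mode draws multinomially. Each
  call replays one covariate-by-class margin, because that is all a
  printed cross-tabulation determines; the joint covariate structure of
  the real cohort is *not* emulated.
* **Cores** (`gen_core_image()`): a circular core on white background; a
  controllable fraction of tissue pixels carries DAB at one of four OD
  levels (0, 0.35, 0.7, 1.05 for intensity grades 0–3) over a light
  haematoxylin counterstain (0.2 OD), the rest haematoxylin only
  (0.5 OD); optional Gaussian OD noise. Real cores differ in everything
  the closed loop does not need: texture, nuclei, uneven illumination,
  stain gradients — so passing round-trip tests shows the *scoring
  arithmetic* is right, not that segmentation of real tissue would be.
* **Tracks** (`gen_tracks()`): a persistent random walk — constant step
  speed, Gaussian heading increments with variance $2\,dt/P$ so heading
  correlation decays as $e^{-t/P}$. It is the minimal model with
  independent speed and persistence knobs, which is exactly what velocity
  and directionality measure; default ensembles use 1-min frames over
  72 h with speeds in the reported 0.06–0.24 μm/min range. Cell–cell
  interactions, division, and drift are deliberately absent.
* **Spheroids** (`gen_spheroid_series()`): linear front/edge outgrowth
  rasterized as a filled disc plus sparse single-cell pixels (3% annulus
  occupancy, well under the 0.2 front threshold) with anchors exactly on
  the edge radius; presets calibrated so 72-h migration indexes span the
  reported 0.09–0.56 range. Projected 2D masks only, as the assays
  measure projected images.

All generators take mandatory seeds and are bitwise reproducible from
their spec.

## Numerical choices and problem sizes

Units are minutes/μm for tracks and hours/μm for spheroids, following the
reporting conventions of these assays. Test ensembles use 200 tracks ×
4320 one-minute frames for velocity recovery, 60-track ensembles for
persistence monotonicity, masks of roughly 400–500 px for spheroid
round-trips, an exhaustive sweep of all 2×2 tables with $N \le 40$ plus
200 random 3×3 tables with $N \le 30$ for the exact-test oracle, and 1000
simulated null pairs for t-test calibration — sizes chosen so the whole
suite runs comfortably on a laptop while keeping Monte-Carlo standard
errors well inside the asserted tolerances.

## Known limitations

* Localization calls and the migration-index operationalization are
  declared stand-ins for by-eye protocols that the source describes only
  qualitatively.
* The published per-cell-line velocities, distances and MI values derive
  from raw images and tracks that are not deposited anywhere; they are
  used here only as generator calibration ranges, never asserted as
  reproducible numbers.
* `score_tma()` scores single-core images; whole-slide pyramids and
  nucleus-level segmentation are out of scope.
* The exact test's enumeration is exponential in table size; the $N \le
  500$ guard keeps it in the regime where it is the right tool.
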