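---
title: "Quantitative cartilage MRI: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cartilage MRI: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmricart)
```

## What the package computes

`qmricart` implements a longitudinal quantitative-MRI analysis of femoral
condylar cartilage with two biomarker families:

* **T2 relaxation time** (ms), estimated per voxel from a multi-slice
  multi-echo (MSME) spin-echo acquisition by a monoexponential fit
  $S(\mathrm{TE}) = S_0\,e^{-\mathrm{TE}/T_2}$, and summarized as a robust
  median per anatomical volume of interest (VOI);
* **cartilage thickness** (mm), computed at each vertex of the subchondral
  bone mesh as the minimum Euclidean distance to the cartilage surface
  mesh, and summarized as a mean per VOI.

Each femoral condyle is split into anterior/central/posterior VOIs
(medial: Ma, Mc, Mp; lateral: La, Lc, Lp); the anterior VOIs are further
split into external/central/internal sub-VOIs (e.g. Mae, Mac, Mai).
Medial-lateral ratios (Ra = Ma/La, ..., Rai = Mai/Lai) sharpen opposing
changes between compartments. Knees are observed at three radiographic
severity timepoints (KL1, KL2, KL3, the first visits at each
Kellgren-Lawrence grade), and a repeated-measures statistical ladder tests
for timepoint effects per measure.

Because the motivating clinical data require credentialed access and
manual segmentation, the package ships a synthetic knee phantom
(`phantom_spec()`, `simulate_cohort()`) whose ground truth makes every
stage testable.

## T2 relaxometry

`fit_voxel_t2()` fits $\ln S$ against TE by ordinary least squares and
reports $T_2 = -1/\text{slope}$, $S_0 = e^{\text{intercept}}$ and the
log-domain $R^2$. Conventions:

* **First-echo exclusion** (default on): the first echo of a multi-echo
  train is contaminated by stimulated echoes; echoes 2..n are fitted. An
  excluded echo cannot influence the result, which the tests assert
  bitwise.
* **Non-decaying voxels**: a non-negative slope yields a negative or
  infinite T2 and is returned as-is; the aggregation step removes it. A
  non-positive signal at any used echo invalidates the voxel with a reason
  code.
* **Why log-linear**: it is deterministic, closed-form and fast. A profiled
  nonlinear least-squares fit (optimal $S_0$ closed-form, 1-D search over
  $T_2$) serves as an oracle in the tests: at SNR 50 the two estimators'
  median fitted T2 agree to a fraction of a percent, while the log-linear
  median absolute error is about 1.26x the nonlinear one. The package
  accepts that accuracy trade for determinism; users needing the last few
  percent of precision at low SNR should be aware of it.

`median_t2()` aggregates voxel values per (sub-)VOI with a two-step
exclusion: values strictly below 0 ms are removed; then values above
median + 3 IQR of the remainder are removed in a single pass, and the
median of the survivors is reported. Further conventions, each configurable
because the rule's source leaves them open:

* IQR quartiles use linear interpolation of order statistics
  (`stats::quantile` type 7);
* the median/IQR threshold is computed *after* negative removal
  (`iqr_on = "all_values"` reverses this);
* exactly 0 ms is kept ("strictly less than 0");
* infinite fitted T2 counts as an outlier above any finite cutoff;
* the outlier pass runs once, without iteration.

## Thickness mapping

`compute_thickness()` evaluates, for every bone vertex, the exact
point-to-triangle minimum distance to the cartilage mesh. A uniform-grid
spatial index accelerates queries while returning values identical to the
brute-force double loop (asserted exactly in the tests). Coverage rule: a
vertex counts as covered by cartilage when its distance is at most a cap
(default 8 mm) and the nearest cartilage face's outward normal faces away
from the bone; uncovered (denuded or non-articular) vertices are flagged
and excluded from VOI means rather than contributing zeros. The cap and
normal test are a package convention — the clinical methodology this
emulates does not publish its denuded-bone handling — so both are
configurable and flagged here.

## VOI partition and voxel assignment

`partition_vois()` assigns medial/lateral by the side of the intercondylar
plane, then splits each condyle along its anterior-posterior arc (angle
from the anterior axis within the sagittal plane, measured about the
condyle centroid) at configurable fractions, default thirds. Anterior
sub-VOIs split the condyle's medial-lateral extent in thirds, with
"external" farther from the notch. The boundary placement (thirds of arc
and extent) is a declared default, not an inferred one: the source
methodology's exact boundary convention is not reproducible from its
public description.

`assign_voxels()` labels each masked voxel with the VOI of its nearest
bone vertex (ties broken deterministically by lowest vertex index) and
computes relative depth $d_\mathrm{bone}/(d_\mathrm{bone} +
d_\mathrm{cart})$, 0 at bone and 1 at the articular surface;
`split_layers()` halves the slab at depth 0.5, with 0.5 itself superficial.
Voxel centers follow the NIfTI convention: zero-based indices, center at
the index coordinate.

Numerical stability: axis dot products are snapped to zero below
`1e-9 * extent` so that degenerate on-axis vertices (e.g. mesh poles)
receive the same label when mesh and frame are rotated together; without
the snap, `atan2(0, 0)` becomes `atan2(eps, eps)` after rotation and the
label would depend on rounding noise.

## The statistical ladder

Per measure, across knees (rows) and the three severity timepoints
(columns):

1. **Normality gate** (Shapiro-Wilk): applied per measure *family* (T2,
   thickness, and their ratio families), mirroring the practice of gating
   whole data families rather than individual measures. In `gate = "auto"`
   mode a family routes nonparametric when more than 20% of its
   per-measure, per-timepoint Shapiro-Wilk tests reject at 0.05 — well
   above the 5% false-positive background; explicit overrides are
   supported.
2. **Omnibus** at alpha = 0.05: Friedman (nonparametric route; mid-ranks,
   tie-corrected chi-squared, optional Monte-Carlo permutation p) or
   one-way repeated-measures ANOVA (sphericity assumed by default,
   Greenhouse-Geisser optional).
3. **Post-hoc pairwise** (KL1-KL2, KL1-KL3, KL2-KL3) *only when the
   omnibus is significant*, judged strictly at the Bonferroni-corrected
   printed value 0.017 (not 0.05/3 = 0.01667; the printed convention is
   matched deliberately): Wilcoxon signed-rank (exact two-sided p by
   convolution of the signed-rank distribution for n <= 25 without ties;
   tie- and continuity-corrected normal approximation otherwise; zero
   differences dropped by default, Pratt optional) or paired t.
4. **Effect sizes** per pairwise comparison: Cohen's $d_z$ =
   mean(d)/sd(d) (parametric) or $r = |Z|/\sqrt{n}$ (nonparametric). The
   effect-size formulas behind the emulated methodology are not published;
   these two standard choices are labelled in the output. Since $r$ is
   unsigned, every pairwise row also carries a `direction` column (sign of
   the mean paired change) — without it the output could not express
   whether a significant change was an increase or a decrease.

`annualized_change()` converts between-timepoint changes to the
percent-per-year scale used to compare longitudinal cartilage studies:
$100\,((v_\mathrm{end}-v_\mathrm{start})/v_\mathrm{start})/(\mathrm{months}/12)$.

## The synthetic phantom: what it emulates, and what not

Each condyle is a sphere (medial radius 16 mm, lateral 15 mm, centers
44 mm apart across the notch plane); cartilage is the bone surface offset
outward along radial normals by a smooth strictly positive thickness field
(base 2.2 mm, +-15% smooth anterior-posterior modulation). Ground-truth T2
is linear in relative depth, 35 ms at bone to 55 ms at the surface —
values typical of femoral cartilage at 3 T. The MSME rendering uses
TE = 10..70 ms in 10 ms steps and 0.313 x 0.446 x 3 mm voxels, the
protocol geometry this package targets; signal is
$S_0 e^{-\mathrm{TE}/T_2}$ with Rician corruption (magnitude of the
noiseless signal plus complex Gaussian noise, sigma = 15 signal units for
$S_0 = 1000$, i.e. echo-2 SNR of roughly 40), and background voxels carry
pure noise so masks are testable (their magnitudes are Rayleigh, which the
tests verify distributionally).

Longitudinal cohorts (`simulate_cohort()`) draw, per knee, lognormal
perturbations of size (sd of log 0.04), thickness (0.06) and T2 level
(0.06) — between-knee biological variability — and, per knee-timepoint,
per-(sub-)VOI lognormal "scan" factors (sd 0.02 for T2, 0.03 for
thickness) standing in for repositioning, registration and segmentation
error at magnitudes typical of published scan-rescan precision for these
biomarkers. Severity timepoints sit at 0, 18 and 36 months, matching the
median KL1-to-KL3 interval of the fast-progression setting this emulates.
The default progression injects the pattern such a cohort shows: medial T2
x1.10 from KL2 onward, anterior-lateral T2 x0.93 from KL2 onward, and
medial-central thickness x0.85 at KL3 — early compositional change, late
thinning. One cohort seed expands into per-knee, per-timepoint substreams,
so any cell can be regenerated in isolation, bit-identically.

Not emulated: realistic femoral shape (only the two-lobe topology),
the DESS sequence's signal (only its segmentation role), B0/B1 artefacts,
the magic-angle effect, multi-component T2, partial-volume mixing at the
cartilage rim. A green end-to-end test therefore establishes that the
*pipeline* recovers known effects through fitting, geometry, partition and
statistics — not that it reproduces any clinical cohort's numbers.

## Numerical and resolution choices

* **Mesh resolution** (default 1.5 mm target edge length): chosen so that
  discretization artefacts sit below the stated tolerances — thickness
  bias from chordal sag is O(edge^2 / 8R) (about 0.03 mm here), and
  nearest-vertex VOI label quantization stays below the in-plane voxel
  size, keeping voxel-label agreement with the analytic ground truth above
  98% at default settings.
* **Reduced-resolution testing**: the large simulation tests shrink the
  *geometry scale* (8 mm condyles, ~1.3 mm voxels), never the study design
  (19 knees, 3 timepoints, 100 seeds), to stay within compute budgets.
* **Exact vs approximate**: spatial-index distances are exact (shell
  search with a provable lower bound), Wilcoxon p is exact below n = 26
  without ties, Friedman p is asymptotic by default with a Monte-Carlo
  option, RM-ANOVA assumes sphericity unless Greenhouse-Geisser is
  requested. At n = 19 knees the Friedman chi-squared approximation runs
  at about 5.4% type-I error for nominal 5% (measured on iid null draws);
  the Monte-Carlo option removes this if it matters.
* **Substream seeds**: per-(knee, timepoint) seeds are derived from the
  cohort seed through an avalanche integer hash, not a linear formula —
  `set.seed()` streams from nearby seeds are weakly correlated, which is
  enough to de-calibrate a repeated-measures test on null cohorts (the
  type-I acceptance test caught exactly this during development).
* **File formats**: NIfTI-1 volumes are written as float64 so write/read
  round trips are lossless; meshes are ASCII PLY/OBJ printed at %.17g so
  serialized meshes are byte-stable; DICOM support is read-only and limited
  to the six geometry tags registration needs.

## Known limitations

* The condylar phantom's closed spherical lobes mean every bone vertex is
  cartilage-covered; the coverage rule's denuded-bone path is exercised
  only by constructed fixtures.
* The log-linear fit is used unweighted; at low SNR it is noisier than
  nonlinear fitting (quantified above) and Rician bias is not corrected.
* The statistical ladder treats measures independently (as does the
  emulated methodology); no across-measure multiplicity control is
  applied.
* Manual registration refinement is represented by a user-supplied rigid
  correction transform, not an interactive tool.
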