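# qmricart

Quantitative MRI analysis of femoral condylar cartilage for longitudinal
osteoarthritis studies: per-voxel **T2 relaxometry**, mesh-based
**cartilage thickness mapping**, anatomical **VOI partitioning** of the
condyles, robust per-region aggregation, and a **repeated-measures
statistical ladder** across radiographic severity timepoints — plus a
synthetic knee phantom that makes the whole chain testable without
clinical data.

## Who it is for

Researchers analyzing knee MRI biomarkers of cartilage degeneration:
composition (T2, sensitive to water content and collagen organization)
and morphology (thickness), tracked within knees as osteoarthritis
progresses through Kellgren–Lawrence grades KL1 → KL2 → KL3.

## The models at the core

**T2 mapping.** A multi-slice multi-echo acquisition gives per-voxel
magnitudes S(TE) at echo times TE = 10…70 ms. Each voxel is fitted with
the monoexponential

    S(TE) = S0 · exp(−TE / T2)

by log-linear least squares on echoes 2…7 (the first echo is excluded to
avoid stimulated-echo contamination). Per (sub-)VOI, the robust median
excludes values < 0 ms and values > median + 3·IQR.

**Thickness.** From bone and cartilage triangle meshes, thickness at each
subchondral bone vertex is the minimum point-to-triangle distance to the
cartilage surface (exact, spatial-index accelerated), averaged per VOI.

**Regions.** Each condyle splits into anterior/central/posterior VOIs
(Ma, Mc, Mp medial; La, Lc, Lp lateral); anterior VOIs split into
external/central/internal sub-VOIs; medial–lateral ratios (Ra = Ma/La, …)
contrast the compartments. Cartilage halves at 50% depth give deep and
superficial layers.

**Statistics.** Per measure: Shapiro–Wilk gate → Friedman + Wilcoxon
signed-rank (non-normal) or RM-ANOVA + paired t (normal); omnibus at
α = 0.05, pairwise KL1–KL2 / KL1–KL3 / KL2–KL3 only under a significant
omnibus, at Bonferroni α = 0.017; effect sizes d_z (parametric) or
r = |Z|/√n (nonparametric), with an explicit change direction.

## Worked example

Simulate a 19-knee cohort with the default progression (medial T2 ×1.10
from KL2, anterior-lateral T2 ×0.93 from KL2, medial-central thickness
×0.85 at KL3), measure it through the full imaging pipeline, and test:

```r
library(qmricart)
spec <- phantom_spec(condyle_radius_medial = 8, condyle_radius_lateral = 7.5,
                     condyle_separation = 26, mesh_resolution = 3,
                     spacing = c(1.3, 1.3, 2.6), margin = 3, seed = 42)
model <- progression_model()
cohort <- simulate_cohort(19, spec, model, render = TRUE, keep_cells = FALSE)
tab <- cohort_table(cohort, layers = FALSE)
res <- run_severity_analysis(tab)
res[res$significant & res$comparison != "omnibus" &
    res$measure %in% c("Ma","Mc","Mp","La","Lc","Lp"), ]
```

prints (seed 42):

```
    family measure comparison     test        p effect_size direction
        t2      Ma    KL1-KL2 paired_t 5.37e-12        3.63         1
        t2      Mc    KL1-KL2 paired_t 4.31e-12        3.67         1
        t2      Mp    KL1-KL2 paired_t 1.01e-15        5.96         1
        t2      La    KL1-KL2 paired_t 1.35e-10       -2.99        -1
        t2      Ma    KL1-KL3 paired_t 7.03e-13        4.09         1
        ...
 thickness      Mc    KL1-KL3 paired_t 6.46e-10       -2.71        -1
 thickness      Mc    KL2-KL3 paired_t 8.57e-12       -3.53        -1
```

Every injected effect is recovered with the right direction: medial T2
rises at KL2 and stays up, anterior-lateral T2 falls, and medial-central
thickness drops only in the late interval — while untouched VOIs stay
non-significant. Annualized rates follow the usual %/year convention:

```r
annualized_change_table(tab)   # e.g. thickness Mc: −5.1 %/year over KL1→KL3
```

## Command line

```sh
Rscript inst/cli/qmricart simulate --n-knees 4 --seed 1 --outdir out/
Rscript inst/cli/qmricart fit-t2 --volume out/knee01_KL1_msme.nii --outdir out/
Rscript inst/cli/qmricart thickness --bone out/knee01_KL1_bone.ply \
        --cartilage out/knee01_KL1_cartilage.ply --outdir out/
Rscript inst/cli/qmricart run-all --config config.json --seed 1 --outdir out/
```

Volumes are NIfTI-1 (4D, echo times in a JSON sidecar), meshes ASCII
PLY/OBJ, tables CSV; DICOM headers can be read for geometry extraction.

## Documentation

The methods vignette (`vignettes/qmricart-methods.Rmd`) documents the
model conventions (quantile type, exclusion order, tie handling, layer
boundary), the phantom's stated world and its limits, and every place
where the emulated methodology leaves a convention open.
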