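# shgfiber

Quantification of collagen-1 (Col1) fibers in second harmonic generation
(SHG) micrographs, and the downstream statistics used to relate fiber
content to cancer recurrence and survival.

SHG microscopy images fibrillar collagen label-free: the fibers'
non-centrosymmetric structure emits at half the excitation wavelength
(860 nm in, 430 nm detected), so Col1 appears as bright curvilinear
structures on a dark background. For each field of view (FOV) the package
computes the **percent fiber volume**,

    PFV = 100 * (fiber voxels) / (total voxels),

by (1) fuzzy c-means clustering of voxel intensities — minimizing
J = Σᵢ Σₖ u_ik^m (xᵢ − v_k)², with the brightest cluster taken as fiber and
strict arg-max defuzzification — and (2) a fibrillar shape filter that keeps
a connected component only if its skeleton length ≥ 10 µm, mean ridge width
≤ 10 µm and length/width aspect ≥ 2, removing blobs and stray signal.
Per-patient means over 6–18 FOVs feed a one-tailed two-sample t-test; the
FOV-level values feed a random-intercept model,
log(PFV) ~ group + (1 | patient), fit by REML with Satterthwaite degrees of
freedom; and a median split of patient means feeds Kaplan–Meier curves with
a log-rank test and an O/E hazard ratio. Quadrant tile scans are stitched
into whole-section mosaics by correlation-refined integer registration with
max blending. A threshold filter (|log2FC| > 0.5, padj ≤ 0.05) screens
differential-expression tables against curated ECM/CAF/immune-checkpoint/
T-cell gene panels. A synthetic-data module generates seeded SHG-like
images with ground truth, hierarchical two-group cohorts with survival, and
DE tables, so the whole pipeline runs with no external data.

Intended users: imaging scientists quantifying fibrillar collagen in tissue
sections, and biostatisticians analyzing the resulting per-FOV/per-patient
readouts.

## Worked example

```r
library(shgfiber)

## a 512x512 SHG-like image with 10% true fiber volume, plus blob confounders
sim <- simulateFiberImage(FiberImageParams(targetFraction = 0.10, seed = 7L))
percentFiberVolume(sim$truth)
#> [1] 10.10971

## segment, shape-filter, quantify
est <- extractFibers(sim$image)
est$percentFiberVolume
#> [1] 10.28633

## a 12 vs 14 patient cohort with a 0.5 log-scale group effect
co  <- simulateCohort(CohortParams(seed = 2L))
fit <- fitRandomIntercept(co$fovs)
c(beta = fit$beta_group, p_one_sided = fit$p_one_sided)
#>        beta p_one_sided
#>   0.4443816  0.05864174

## median-split survival
sv <- survivalByFiberVolume(co$patients)
c(hr = sv$test$hr, chi2 = sv$test$chi2)
#>       hr     chi2
#> 2.118994 3.124813

## gene-panel threshold filter on the shipped 39-gene table
fx  <- examplePanelDeTable()
sig <- filterSignificant(fx)       # |log2FC| > 0.5 and padj <= 0.05
nrow(sig); setdiff(fx$symbol, sig$symbol)
#> [1] 38
#> [1] "CD38"
```

The estimated fiber volume (10.29%) recovers the planted truth (10.11%)
to within 2%; the mixed model recovers the positive group effect
(beta ≈ 0.44 for a true effect of 0.5); the survival split recovers an
elevated hazard in the high-fiber group; and of the 39 panel genes exactly
one (CD38, padj 0.0531) fails the significance thresholds.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/shgfiber-cli.R` (subcommands `segment`, `quantify`, `stitch`,
`simulate`, `stats`, `de-filter`).

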