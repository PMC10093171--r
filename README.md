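# osteopose

Inference of locomotor mode and limb posture in reptiles from femoral
mid-diaphyseal cross-section microanatomy, with the comparative statistics
that belong around such an analysis.

Limb bones record how an animal carried its weight. On a single mid-shaft
femoral cross-section, the position of the medullocortical transition, the
abruptness of that transition, global bone compactness and the section's
geometric resistance properties differ between obligate bipeds (B), obligate
quadrupeds (Q) and facultative bipeds (FB), and between crouched, erect,
semi-erect and sprawling postures. Because those parameters also carry
phylogenetic signal, naive discriminant analysis conflates relatedness with
function; `osteopose` removes that bias and still lets fossils be classified
against an extant-dominated training sample.

## What the package computes

**Measurement layer.** From a binary cross-section raster (1 = mineralised
bone), the package locates the medullary centre, bins every enclosed pixel by
direction-normalised radius into 100 concentric rings, and fits the
compactness profile

    C(r) = Min + (Max - Min) / (1 + exp((P - r)/S))

globally and in 60 sectors of 6 degrees, yielding `C_obs, P, S, RP, RS,
RPSD, RSSD`. The geometric layer adds `Pe_min` (outer perimeter), `BCSA`,
`TCSA`, the principal second moments of area, `Ecc = I_max/I_min`,
`Z_pol = (I_max + I_min)/r_out`, and the slenderness ratio
`SR = bone length / sqrt(I_min/TCSA)` — thirteen parameters per specimen.

**Discriminant layer.** Phylogenetic flexible discriminant analysis (PFDA):
optimal-scoring FDA whose regression is whitened by the inverse Cholesky
factor of a Pagel-lambda-scaled tree covariance, with lambda optimised on a
grid by a GLS deviance criterion. At lambda = 0 on an ultrametric tree the
fit reduces exactly to ordinary LDA. Model selection runs leave-one-out
cross-validation for every non-empty variable subset on every tree of a
population of time-calibrated trees (the reference design: 9 retained
variables x 100 trees = 51,100 procedures) and ranks subsets by mean
percentage of correct classification. Fossils are grafted onto each tree at
stated divergence ages and classified per tree; results are reported as vote
fractions over the tree population.

**Statistics layer.** Simulation-based phylogenetic ANOVA with Bonferroni
post hocs, Pagel-lambda signal with LR tests, an entropy-based (delta)
signal statistic for categorical traits with tip-shuffle p-values, PGLS of
each parameter on log10 body mass, and ecology x mass linear models on the
discriminant axes with BH-corrected contrasts.

**Synthetic layer.** Parametric section and trait-dataset generators that
emit their own ground truth, so every stage has closed-form or planted-truth
tests without any external data.

## Worked example

Measure a synthetic hollow, slightly elliptical section (30 um/px,
bone length 120 mm):

```r
library(osteopose)
g <- make_section(size = 512, outer_radius = 220, inner_radius = 0.55,
                  axis_ratio = 1.3, s_true = 0.02, resolution = 30,
                  taxon = "Demo_taxon", bone_length = 120, seed = 7)
measure_section(g$section)
#>   C_obs     P     S    RP   RS  RPSD  RSSD Pe_min   BCSA    TCSA   Ecc
#> 1 0.696 0.552 0.021 0.552 0.02 0.004 0.003 36.864 73.228 105.282 1.691
#>     Z_pol     SR
#> 1 250.749 49.679
```

The section was generated with inner radius 0.55 and transition scale 0.02:
the fitted inflection `P = 0.552` and `S = 0.021` recover both, `C_obs =
0.696` is the bone-area fraction, `Ecc = 1.69` reflects the 1.3:1 outline
(eccentricity is a ratio of fourth-order moments, so it grows faster than
the axis ratio), and `SR = 49.7` says this would be a slender bone.

Run the whole pipeline on a generated bundle (trait table + tree population
+ two unlabelled "fossil" taxa):

```r
cfg <- simulate_bundle(file.path(tempdir(), "demo"), n_taxa = 28,
                       n_trees = 3, seed = 1)
res <- run_pipeline(cfg)
head(res$selection$table[, c("subset", "mean_pcc", "mean_aic")], 3)
#>         subset mean_pcc  mean_aic
#> 15 V1+V2+V3+V4 98.71795 -182.6395
#> 11    V1+V2+V4 98.71795 -181.5158
#> 7     V1+V2+V3 98.71795 -177.1933
round(res$inference[[1]]$votes, 2)
#>     c1 c2
#> t27  1  0
#> t28  1  0
```

The selection table averages the leave-one-out PCC of every variable subset
over the tree population (ties broken by mean AIC); the planted signal lives
in `V1` and `V2`, and every top-ranked subset contains them. The two
inference taxa are assigned class `c1` on all three trees — vote fractions
of 1. Per-stage CSVs, a log and a plain-text report land in the configured
output directory.

## Package layout

* `R/section.R`, `R/compactness.R`, `R/geometry.R` — measurement layer
* `R/phylo.R` — tree I/O, covariances, fossil grafting, Brownian simulation
* `R/pfda.R` — PFDA, cross-validation, subset selection, fossil inference
* `R/comparative.R` — ANOVA, signal statistics, PGLS, ecology x mass models
* `R/synthetic.R` — ground-truth generators and the fixture bundle writer
* `R/pipeline.R` — `run_pipeline()` end-to-end orchestration
* `vignettes/femoral-microanatomy-methods.Rmd` — the methods account
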