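---
title: "Methods: compactness profiles, cross-sectional geometry and phylogenetic discriminant inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compactness profiles, cross-sectional geometry and phylogenetic discriminant inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`osteopose` infers locomotor mode (obligate biped, obligate quadruped,
facultative biped) and limb posture (crouched, erect, semi-erect, sprawling)
of reptiles from the microanatomy of a single mid-diaphyseal femoral
cross-section, and provides the comparative statistics that usually accompany
such an analysis. This vignette is the package's own account of the models it
fits, the numerical choices behind them, and what the synthetic-data tests do
and do not demonstrate.

## The measurement model

A specimen enters the pipeline as a thresholded (binary) raster of its
mid-shaft cross-section: 1 = mineralised bone, 0 = everything else. Left
femora are mirrored so the whole sample is right-sided; every parameter we
measure is reflection-invariant, so this only standardises orientation
metadata. The *medulla* is found as the largest 4-connected component of
non-bone pixels enclosed by the outer boundary; smaller enclosed components
are treated as vascular canals and count as non-bone but not as medulla. A
solid section falls back to the section centroid with a degeneracy flag.

### Compactness profile

Every pixel enclosed by the outer contour receives a *direction-normalised
radius*: its distance from the medullary centre divided by the distance from
the centre to the outer boundary along the same direction (boundary radii are
taken per half-degree angular bin). Normalisation per direction, rather than
by a single outer radius, keeps the profile of an elliptical section
identical to that of a circular one, which is what makes the inflection
parameter comparable across sections of different size and eccentricity.
Pixels are binned into 100 concentric rings; per-ring compactness is the
bone-pixel fraction. The profile is then summarised by the four-parameter
logistic

$$C(r) = \mathrm{Min} + \frac{\mathrm{Max} - \mathrm{Min}}
{1 + e^{(P - r)/S}},$$

fitted by bounded weighted least squares (weights proportional to ring pixel
counts, since outer rings summarise far more pixels). $P \in [0,1]$ is the
radial position of the medullocortical inflection; $S$ is the transition
scale — the tangent slope at $P$ is $(\mathrm{Max}-\mathrm{Min})/4S$, so $S$
plays the role of a reciprocal slope: small $S$ means an abrupt transition,
large $S$ a cancellous, gradual one.

Numerical choices: the optimiser is L-BFGS-B with five deterministic starts
($P_0 \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$, $S_0 = 0.05$), bounds
$0 \le \mathrm{Min} \le \mathrm{Max} \le 1$, $0 \le P \le 1$ and a floor
$S \ge 10^{-4}$; the best SSE wins. Step-like profiles legitimately end with
$S$ on its floor, where the line search stops with a bound-hit code — that
outcome is treated as converged. A profile whose non-missing values are all
equal (a solid disc) is degenerate by contract: $\mathrm{Min} = \mathrm{Max}$,
$P = 0$, $S$ at its floor, flagged non-converged, and its $P$ is treated as
missing downstream.

The *radial* analysis repeats the fit in 60 sectors of 6 degrees. `RP` and
`RS` are the means, `RPSD` and `RSSD` the sample standard deviations, of the
per-sector $P$ and $S$ over sectors whose fits converged; failed sectors are
excluded rather than imputed, and fewer than 30 valid sectors raises a
low-confidence warning. Note one genuine subtlety exposed by the generator
tests: a strongly one-sided medulla pulls its own centroid off the section
centre, so per-sector $P$ measured from the medullary centroid compresses the
apparent angular variation relative to the generating inner-radius function;
anchoring the centre explicitly recovers it. This is behaviour, not error —
on real bone the medullary centroid is the reference the profile is defined
from.

### Geometry

On the same rasters the package measures total and bone cross-sectional area
(`TCSA`, `BCSA`), the outer perimeter `Pe_min` (length of the 0.5 iso-contour
of the lightly Gaussian-smoothed filled mask — a raw marching-squares contour
of binary data overestimates perimeters by several percent, the smoothed
contour is accurate to well under 1% at 512 px), the principal second moments
of area `I_max`, `I_min` of the bone pixels about the bone-area centroid
(per-pixel self-moments included), the eccentricity `Ecc = I_max / I_min`,
the polar section modulus `Z_pol = (I_max + I_min) / r_out`, and the
slenderness ratio

$$\mathrm{SR} = \frac{\text{bone length}}{\sqrt{I_{\min} / \mathrm{TCSA}}}.$$

Moments use bone pixels only (hollow geometry): they quantify bending
resistance of the bone material actually present. `Z_pol` is reported in
mm^3 as a true section modulus (the polar second moment `J` is kept
alongside); the convention is switch-free but recorded here because
"polar section modulus" is occasionally used loosely for `J` itself. All
outputs are in mm-based units derived from the image resolution in um/px;
`Ecc` and `SR` are dimensionless and resolution-invariant, which the test
suite asserts by rescaling fixtures.

## Phylogenetic flexible discriminant analysis

Linear discriminant analysis ignores phylogeny; closely related taxa enter as
if independent. The discriminant step used here is flexible discriminant
analysis via optimal scoring — a regression of class-indicator columns on the
predictors — which makes the phylogenetic correction a GLS problem: both
sides of the regression are whitened by the inverse lower Cholesky factor of
the tree covariance $C(\lambda)$, where off-diagonal entries of the Brownian
covariance are multiplied by Pagel's $\lambda \in [0,1]$ and the diagonal is
untouched. $C$ is normalised by its mean diagonal before whitening, so the
criterion below is tree-scale free and $\lambda = 0$ on an ultrametric tree
whitens by the identity — the fit then reduces *exactly* to ordinary LDA
(assignments identical to `MASS::lda`, priors included), which the test suite
asserts on random fixtures.

$\lambda$ is chosen on a grid (default step 0.01) by minimising the *model
error*, defined here as the Gaussian GLS deviance of the optimal-scoring
regression: $nK\log(\mathrm{RSS}/nK) + K\log\lvert C(\lambda)\rvert$. The
determinant term matters: whitening rescales the responses, so a raw
whitened RSS is not comparable across $\lambda$ and (we verified on iid
fixtures) systematically drags $\hat\lambda$ upward. With the deviance, iid
class structure drives $\hat\lambda$ to 0 and phylogenetically clustered
class structure drives it up, which is the behaviour the statistic is meant
to have. The same deviance plus $2k$ (with $k = \lvert\text{subset}\rvert
(K-1) + K$ parameters) is the per-subset AIC reported by the selection stage.

Training taxa are ordered before inference taxa, so the whitened training
rows depend only on training data while fossils are whitened conditionally on
their relatives — fossils therefore participate in the covariance but never
in the fit. Classification is nearest class centroid in the sphered
discriminant space with a $-2\log\pi_k$ prior adjustment; priors default to
training frequencies (switchable to equal — worth considering when one clade
dominates the sample, as birds do in the reference design). Ties break
deterministically by class-label order.

### Cross-validation and subset selection

Model selection scores every non-empty subset of the retained variables by
leave-one-out cross-validation on every tree of the population: hold out one
taxon, refit on the rest, predict it, repeat; `PCC` is the percentage
correct. Two tractability decisions: $\lambda$ is optimised once per
(subset, tree) on the full training data and held fixed within folds (100
trees x 511 subsets x n folds makes per-fold grids prohibitive, and the
held-out taxon contributes one row out of n to the criterion); and Cholesky
whitening matrices are cached per (tree, $\lambda$) and shared across
subsets. Subsets are ranked by mean PCC over trees, ties broken by mean AIC
then by size. Before selection, variables correlated above 0.95 in absolute
Pearson correlation are pruned by complete-linkage clustering on
$1 - \lvert r\rvert$ (cut at height $1 -$ threshold), keeping one
representative per cluster by a configurable priority order.

Fossil inference fits the selected subset on each tree of the population and
aggregates per-tree predictions into vote fractions — reporting, say, a taxon
inferred biped on 70% of the tree hypotheses rather than a single hard call.

## Comparative statistics

* **Phylogenetic ANOVA**: ordinary one-way F statistic referred to a null
  distribution of F values from Brownian simulations on the tree (rate and
  root by ML from the observed trait). Pairwise post hoc t statistics use
  the pooled ANOVA variance, take p-values from the same simulations, and
  are Bonferroni-corrected within the family. Outlier exclusion lists are
  applied to this analysis only. The implementation is cross-checked against
  `phytools::phylANOVA` (identical F, Monte-Carlo-equal p).
* **Pagel's lambda** for continuous traits: ML profile of the Gaussian
  phylogenetic likelihood over $\lambda \in [0,1]$, LR test against
  $\lambda = 0$ on one chi-square degree of freedom. Cross-checked against
  `phytools::phylosig`.
* **Delta statistic** for categorical traits: marginal ancestral state
  probabilities at every internal node by ML under an equal-rates Markov
  model (own pruning implementation, cross-checked against `ape::ace`),
  converted to normalised Shannon entropies $h_i$; the statistic is the
  ratio of means $\overline{(1-h)}/\overline{h}$ — confident (low-entropy)
  reconstructions mean strong signal and a large value. The published
  estimator of this entropy-ratio family samples beta-distribution
  parameters by MCMC; we use the deterministic moment form, which preserves
  the quantity's meaning, its strict positivity and its monotone response to
  clustering, and is orders of magnitude faster under the 1000-fold
  tip-shuffle test that provides the p-value. Delta values are therefore
  comparable within an analysis, not numerically against MCMC
  implementations.
* **PGLS**: GLS regression under $C(\lambda)$ with $\lambda$ by ML profile;
  slope t-test on $n - 2$ df; $R^2$ relative to the GLS intercept-only fit.
  Cross-checked against `nlme::gls` with `ape::corPagel`.
* **Ecology x mass models** on discriminant-axis coordinates: coordinates
  are shifted by $\lvert\min\rvert + 1$ and log10-transformed — the literal
  "add the lowest coordinate" rule maps the minimum to zero and breaks the
  log, so the unit offset keeps order and finite values. The model is
  `log10(coord) ~ ecology * log10(mass)` with the interaction dropped when
  its type-II F test exceeds 0.05, and BH-corrected pairwise ecology
  contrasts (via `emmeans`) when the main effect is significant.

## The synthetic-data generators

`make_section()` draws sections with controllable outline eccentricity,
normalised inner radius, sinusoidal angular cortical-thickness modulation,
logistic transition width and salt-and-pepper noise, and returns the analytic
compactness and the per-direction inner-radius function as ground truth.
`make_tree()` gives seeded unit-depth pure-birth trees; `make_trait_dataset()`
evolves variables as class shift + $\lambda$-transformed Brownian deviation +
iid noise, with clade-based or random labels. Default raster size is 512 x
512, at which all closed-form geometry checks hold to better than 1%.

The planted-subset recovery fixture deserves a note. Its two signal variables
share a strong Brownian trend with the class shift in their *contrast*, so
the pair is jointly necessary for discrimination. With independent shifts on
each variable, single-variable subsets saturate LOO PCC at 100% and the
"top-ranked subset contains both" property is decided by ties among dozens of
perfect subsets — a fixture identifiability artifact that no selection rule
can beat reliably. The contrast design makes recovery a property of the
machinery again.

What the passing tests show: the measurement layer matches closed forms and
pixel oracles; the discriminant layer reduces to LDA where it must and
recovers planted structure; the statistics are calibrated (type-I near 5% at
$\alpha = 0.05$) and match independent implementations. What they do not
show: real bone has trabecular texture, resorption cavities, taphonomic
deformation and segmentation error that no annulus-family generator
emulates; eccentricity in particular is fragile to crushing, which is why a
variable-subset preset excluding it exists. Conclusions about real specimens
still require the usual scrutiny of the input masks.

## Problem sizes and determinism

Every stochastic routine takes a seed and is bit-reproducible under it; the
pipeline writes its seed and configuration hash into the run report, and
caches stage outputs keyed by that hash. The shipped test battery uses
32-200-tip trees, 2-3-tree populations for selection, 200 null replicates
for calibration and 20 seeds for recovery rates — sizes at which every
property is stable while the whole suite stays comfortably interactive;
larger runs only tighten the Monte-Carlo error around the same values.

## Known limitations

* The per-sector fit inherits the 100-ring discretisation; sections thinner
  than a few rings per sector give noisy per-sector $S$.
* $\hat\lambda$ in the discriminant reflects phylogenetic structure of the
  class indicators given the predictors, not of the predictors themselves;
  the two are often conflated in casual reading.
* LOO folds keep $\lambda$ at the full-data optimum; with very small samples
  this slightly flatters PCC for subsets whose $\hat\lambda$ is unstable.
* The delta statistic's absolute scale is implementation-specific (moment
  form); only comparisons and shuffle p-values are meaningful.
* Classes reduced to one member cannot be cross-validated and their folds
  are skipped with a warning.
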