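---
title: "Modelling captive–wild shape differences with morphmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling captive-wild shape differences with morphmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphmix)
```

## The problem

Captive and wild animals develop under different mechanical, nutritional
and social conditions, and skeletal shape can respond plastically to those
conditions. `morphmix` implements a complete analysis chain for asking
whether, and in which direction, captivity (or any other specimen-level
factor) shifts the shape of a bilaterally symmetric structure such as the
macaque mandible, while controlling for size, sex, age class and unknown
population-level differences.

The chain is: landmark I/O and validation → generalized Procrustes
superimposition with object-symmetry decomposition → Smirnov–Grubbs outlier
screening → PCA of the symmetric shape components → Bayesian multivariate
linear mixed models with population random intercepts → WAIC model
comparison → posterior geometry of effect directions (angles, correlations,
shape scores). A synthetic-data generator with planted effects makes every
step testable end to end.

## Shape extraction

**Superimposition.** `gpa()` removes translation, scale and rotation by
partial Procrustes superimposition: every configuration is centred, fixed at
unit centroid size, and rotated (proper rotations only; reflections are
excluded through a determinant correction of the SVD solution) to a
consensus that is iterated until its root-mean-square change falls below
`1e-10` (at most 100 iterations). Centroid size — the square root of the
summed squared distances of landmarks from their centroid — is recorded
before scaling, and its natural log is the `size` variable used downstream.

**Object symmetry.** For structures with a midline and paired landmarks,
each specimen enters the superimposition twice: as digitized and as its
reflected-and-relabelled copy (x-axis negated, left/right labels swapped).
The symmetric component of a specimen is the average of its two aligned
copies, the asymmetric component half their difference; their sum
reconstructs the aligned original exactly. Only the symmetric components
are analysed further, the asymmetric ones are retained for inspection.

**Orientation and tangent projection.** The converged consensus is rotated
into a canonical frame (symmetry-plane normal on axis 1, in-plane principal
axes on axes 2–3, deterministic sign rule) so results do not depend on how
specimens were digitized in space. Aligned shapes are then orthogonally
projected onto the tangent space at the consensus before PCA. Shape
variation in these data is small relative to the curvature of shape space,
so the projection changes coordinates only minutely; it is switchable
(`tangent = FALSE`) for comparison.

**Screening.** Aberrant specimens (mislabelled landmarks, damaged bone)
show up as unusually large Procrustes distances from the mean shape.
`grubbs_screen()` applies a one-sided upper Smirnov–Grubbs test at
`alpha = 0.05`. One-sidedness is a deliberate choice: distances to the mean
are non-negative and only the upper tail signals aberrance. The default is
a single removal pass; an iterative mode with a re-superimposition hook is
available. After screening the pipeline re-runs the GPA on the retained
specimens, so the analysed superimposition never includes the outliers.

## Dimension reduction

`shape_pca()` eigendecomposes the covariance of the symmetric components;
`retain_pcs(pca, m)` keeps the first `m` scores (default `m = 10` in the
pipeline, a configuration value rather than a constant) and reports two
diagnostics: the cumulative variance fraction, and the Pearson correlation
between pairwise Euclidean distances in the reduced score space and the
full Procrustes distances. Shape coordinates are highly redundant, so a
correlation near 1 at modest `m` is the expected justification for the
reduction. PC signs follow a deterministic convention (largest-magnitude
loading element positive), since the sign of a principal axis is otherwise
arbitrary and would make runs irreproducible.

`size_adjust()` regresses all shape coordinates on log centroid size,
reports a pooled R² with a permutation p-value (default 9999 permutations,
seeded), and returns the residuals; feeding those residuals back into
`shape_pca()` gives the size-adjusted variant of the analysis — a pipeline
configuration (`size_adjusted = TRUE`), not separate code.

## The Bayesian mixed model

For responses \(y_{ir}\) (log centroid size, or PC1..PCm jointly) with
fixed effects \(x_i\) and population \(g(i)\):

\[
y_{ir} = \alpha_r + x_i'\beta_r + u_{g(i),r} + \epsilon_{ir},\qquad
u_{jr}\sim N(0,\tau_r^2),\quad \epsilon_{ir}\sim N(0,\sigma_r^2)
\]

All responses and predictors are z-scored first, so coefficients are
comparable across variables; captivity (0 wild, 1 founder, 2 captive-born)
enters as a single scaled numeric predictor. Priors are improper flat on
\(\alpha,\beta\) and half-Student-t with 3 degrees of freedom and scale 2.5
on \(\tau\) and \(\sigma\) — weakly informative for unit-sd responses.

**Sampler.** The model is fitted by a Gibbs scheme: coefficients and group
levels have exact Gaussian conditionals; the half-t scale priors are
handled through their inverse-gamma mixture representation, which keeps
every update conjugate. This is a contract, not a mechanism: the sampler's
correctness is pinned by a closed-form conjugate special case (known
residual scale, no random effect, where the posterior is exactly
\(N(\hat\beta,\sigma^2(X'X)^{-1})\)) and by interval-calibration simulations.
Convergence is monitored by split-chain Rhat; values at or above 1.1 are
flagged, not fatal. With a fixed seed and fixed row order, fits are
bit-reproducible.

**Multivariate responses.** PCs are fitted jointly with independent
residuals across responses, each response carrying its own population
intercepts and scales. PC scores are mutually orthogonal by construction,
so freely estimated residual correlations would concentrate near zero
while inflating the parameter count; the package therefore does not
estimate them. Pointwise log-likelihoods are summed across responses per
specimen, so WAIC compares models at the level of whole specimens.

**Model assessment.** `waic()` computes
\(\mathrm{WAIC} = -2\sum_i(\mathrm{lppd}_i - p_i)\) from the pointwise
log-likelihood draws, with \(\sqrt{n}\,\mathrm{sd}\) standard errors;
`compare_models()` adds the difference to the best model with the paired
standard error of the pointwise differences. `bayes_r2()` reports, per
draw, the variance of fitted values (including population levels) over
that variance plus residual variance, averaged over responses.

## Effect geometry

The direction a factor pushes shape is its coefficient vector across the
shape responses. `compare_effects()` propagates posterior uncertainty into
the angle and the element-wise Pearson correlation between two such
vectors. Within one model, draw *t* of one effect is paired with draw *t*
of the other (they share a posterior); between models, each draw of one
effect is compared with the other's posterior mean, in both directions,
and the two sets concatenated. Independence is read off the 95% interval:
an angle interval containing 90° (or a correlation interval containing 0)
means the data do not resolve the two directions as related. Angles are
reported in degrees; the correlation is the plain Pearson correlation of
the coefficient vectors' elements, following the convention of trajectory
comparisons in morphometrics.

The shape score \(s = y\beta'(\beta\beta')^{-1/2}\) projects each
specimen's shape variables onto the unit vector along a chosen effect
(the posterior mean coefficient vector, computed on the standardized scale
the model was fitted on). It is invariant to positive rescaling of
\(\beta\) and gives a univariate axis — e.g. of captivity-related shape —
that can be correlated with PCs, age or captive generation, and folded
back into landmark space by `score_shape_change()` (with a conventional
exaggeration factor for display).

## The synthetic-data generator

Real specimen data for this design are rarely shareable, so the package
ships a generator that emulates the statistical structure the analysis
assumes, with a ground-truth manifest for recovery testing:

* **Design.** By default the packaged 23-population table (uneven sizes,
  93 captive / 84 wild specimens across latitudes 30.3–41.5, captivity
  confounded with a subset of populations, sexes and age classes as
  tabulated). A balanced design
  (`n_populations` × `n_per_population`) is used for scaled-down
  simulations.
* **Geometry.** A hand-built, exactly symmetric 28-landmark mandible-like
  template (mm scale). Effects act along fixed orthonormal symmetric
  deformation fields orthogonal to the similarity-transform subspace at
  the template, so planted shape change cannot leak into translation,
  rotation or scale.
* **Variation.** Individual biological variation is low-rank: 15
  orthogonal symmetric axes with harmonically decaying sds (leading axis
  1.4 mm), reproducing the dominant-PC structure of real samples; the
  five covariate effects act along the five leading axes. On top of this
  sit population-level symmetric deviations (0.12 mm), isotropic
  symmetric digitizing noise (0.3 mm per coordinate), and optional
  fluctuating asymmetry (0.15 mm). Log centroid size follows a linear
  model in sex and age class with population intercepts (sd 0.03) and
  residual sd 0.05.
* **Effect scaling.** Effect sizes are slopes per covariate sd in units
  of the background sd of the trait they act on, so a planted 0.4 reads
  approximately as a standardized regression coefficient of 0.4. Defaults
  (sex→size 0.7, age→size 0.2, allometry 0.5, sex→shape 0.5, age→shape
  0.2, captivity→shape 0.4, temperature→shape 0) sit near the magnitudes
  reported for macaque mandibles.
* **Ecogeography.** Population temperature and precipitation are linear
  in latitude with noise chosen to give |r| ≈ 0.7–0.8 with latitude,
  matching the collinearity that motivates excluding latitude itself
  from the models.
* **Ground truth.** `truth_in_pc_space()` rotates the planted directions
  into the superimposition frame (Procrustes alignment of the template to
  the PCA consensus), projects them through the loadings, and standardizes
  by the realized score sds — the exact scale of the fitted coefficients.

What the generator does *not* emulate: biomechanically realistic
deformation, growth, measurement error correlated along the bone, or
genetic relatedness between populations. Passing recovery tests therefore
demonstrate that the *pipeline* is correct under its own assumptions, not
that those assumptions hold for any particular real sample.

## Numerical choices and edge cases

* GPA convergence: RMS consensus change `< 1e-10`, max 100 iterations;
  non-convergence is an error carrying the residual trace.
* Degenerate inputs error early and by name: coincident landmarks (zero
  centroid size), rank-deficient configurations in OPA, constant columns
  in standardization, zero-variance distances in screening (reported, no
  outlier), zero draws variance in Rhat (returns 1, flagged).
* Half-t scale parameters are initialized overdispersed across chains;
  the burn-in default (half the chain) absorbs initialization.
* Ties in Grubbs screening resolve to the first maximum; removal order is
  recorded in the report.
* All simulation sizes in the test-suite are scaled down (e.g. 8
  populations × 12 specimens, 4 retained PCs, 4 chains × 1500 iterations)
  — large enough for the statistical properties under test, small enough
  to keep the suite fast; the calibration and selection-rate checks state
  their replicate counts explicitly.

## Design decisions that were genuinely open

* **Sidedness of the Grubbs test**: one-sided upper (distances are
  non-negative); switchable by screening on transformed distances if a
  two-sided variant is ever needed.
* **Point estimate for the shape score's β**: the posterior mean, matching
  how coefficients are reported elsewhere in the package.
* **Within- vs between-model vector comparison**: both are provided;
  "within" pairs draws, "between" compares draws against the other
  effect's mean in both directions and pools.
* **Residual correlations across PCs**: not estimated (see above); the
  model-comparison machinery would accommodate a correlated-residual
  variant, but orthogonal responses give it no signal to work with.
* **Age filter semantics**: `exclude_captive_age_over` drops only captive
  specimens — wild ages are unknown by design, and dropping unknowns would
  empty the wild sample.

## A worked example

```{r example, eval = FALSE}
library(morphmix)

cfg <- pipeline_config(
  simulate = synth_config(seed = 7),   # 23-population design, 177 specimens
  m = 10, chains = 4, iter = 1500, burn = 500, seed = 7,
  outdir = "report")
rep <- run_pipeline(cfg)
print(rep)
rep$effect_comparisons
```

The report bundle contains the screening JSON, PCA summary, coefficient
tables, the WAIC comparison table, effect-direction comparisons and the
shape scores; re-running with the same seed reproduces every file
byte-for-byte.

## Known limitations

* Landmarks must be complete; there is no missing-landmark estimation.
* Only object symmetry (one structure with an internal symmetry plane) is
  supported, not matching symmetry (paired structures).
* The mixed model is Gaussian with random intercepts only; random slopes,
  non-Gaussian families and spatial covariance between populations are out
  of scope.
* WAIC standard errors at small specimen counts are themselves noisy; the
  comparison table reports them, but decisions at |ΔWAIC| ≲ se should be
  treated as ties.
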