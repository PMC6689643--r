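# morphmix

Geometric morphometrics with Bayesian mixed models, built for
captive–wild comparisons of bilaterally symmetric skeletal structures —
the motivating case is the mandible of Japanese macaques sampled from
many populations, some wild and some held in captivity.

## The scientific problem

Does captivity change the shape of the mandible, and if so, in which
direction — for example, does captivity-related shape change resemble the
male direction of sexual dimorphism ("masculinization")? Answering this
from museum samples requires a chain of standard but exacting steps, each
of which this package implements and tests:

1. **Shape extraction.** 3D landmark configurations (28 named mandibular
   landmarks: 4 midline, 12 bilateral pairs) are superimposed by
   generalized Procrustes analysis (GPA): translation, scale and rotation
   are removed, leaving pure shape. Because the mandible has object
   symmetry, each specimen and its reflected-relabelled copy enter the
   superimposition; the *symmetric component* (average of the two aligned
   copies) carries the biological signal and the asymmetric remainder is
   set aside. Centroid size `CS = sqrt(sum ||x_i - centroid||^2)` is the
   size measure; its natural log is "size".
2. **Screening.** A one-sided Smirnov–Grubbs test
   (`G = (max d - mean d) / sd d` against a t-based critical value) flags
   specimens whose Procrustes distance from the mean shape is aberrant;
   the retained set is re-superimposed.
3. **Dimension reduction.** PCA of the symmetric components; the first
   *m* PCs (default 10) serve as shape variables, justified by the
   correlation between reduced-space and full Procrustes distances.
4. **Modelling.** Bayesian Gaussian linear mixed models, fitted by a
   conjugate Gibbs sampler:
   `y_ir = alpha_r + x_i' beta_r + u_{g(i),r} + e_ir`, with population
   random intercepts `u ~ N(0, tau_r^2)`, flat priors on fixed effects
   and half-Student-t(3, 2.5) priors on scales, all variables z-scored.
   Shape PCs are fitted jointly (multivariate response); size is fitted
   univariately. Models with and without the focal factor (captivity, or
   temperature + precipitation) are compared by WAIC with paired standard
   errors; Bayes R² and split-chain Rhat are reported.
5. **Effect geometry.** Directions of shape change are coefficient
   vectors over the PCs. Posterior angles and element-wise correlations
   between pairs of effects (within or between models) quantify, e.g.,
   whether captivity-related change parallels sexual dimorphism. The
   shape score `s = y beta' (beta beta')^{-1/2}` projects specimens onto
   an effect's direction.

Because specimen landmark data of this kind are generally not shareable,
the package also ships a first-class synthetic-data generator
(`synth_config()` / `generate_dataset()`) that emulates the
multi-population sampling design (a packaged 23-population table),
bilateral symmetry, low-rank biological shape variation, allometry, sex /
age / captivity effects, population heterogeneity and digitizing noise —
with a ground-truth manifest (`truth_in_pc_space()`) so the whole
pipeline's recovery of planted effects is testable.

## A worked example

```r
library(morphmix)

cfg <- pipeline_config(
  simulate = synth_config(n_populations = 12, n_per_population = 15,
                          captive_fraction = 0.5, seed = 7),
  m = 6, chains = 4, iter = 2000, burn = 800, seed = 7)
rep <- run_pipeline(cfg)
print(rep)
```

```
pipeline report: 179 specimens analysed, 1 outlier(s), 6 PCs retained
                   model      waic       se delta_waic  delta_se  bayes_r2
     captivity_size_full  401.0668 20.97456  1.0693322 0.7522193 0.4997414
  captivity_size_reduced  399.9974 20.95621         NA        NA 0.4969733
    captivity_shape_full 2997.0456 44.76068         NA        NA 0.1390865
 captivity_shape_reduced 3003.5246 45.34780  6.4790317 6.5736313 0.1261679
        ecogeo_size_full  214.3852 12.04756  0.4999727 1.0905664 0.4411964
     ecogeo_size_reduced  213.8853 11.81686         NA        NA 0.4269572
       ecogeo_shape_full 1538.7965 33.22967 15.7929738 4.1446305 0.1606285
    ecogeo_shape_reduced 1523.0035 33.14597         NA        NA 0.1371290
```

The generator planted a captivity effect on shape (standardized 0.4) and
no ecogeographic effect, and the comparison table recovers exactly that
structure: for shape, the full captivity model has the smaller WAIC
(reduced is worse by 6.5), while adding temperature + precipitation
*worsens* the ecogeographic shape model by 15.8; for size, captivity and
ecogeography models are ties within error (a blank ΔWAIC marks the best
model of each pair). The captivity effect concentrates on two shape axes:

```r
summary(rep$fits$captivity_shape$full)$parameters   # excerpt
#        parameter   mean    sd  lower  upper
#  b_PC3_captivity -0.259 0.095 -0.454 -0.076
#  b_PC4_captivity -0.254 0.085 -0.419 -0.081
round(rep$score_pc_correlations, 2)
#   PC1   PC2   PC3   PC4   PC5   PC6
# -0.12 -0.16 -0.64 -0.63  0.33 -0.22
```

i.e. PC3/PC4 carry the captivity-related contrast, and the captivity
shape score is correspondingly correlated with those axes. The direction
comparison shows that this planted captivity change is *independent* of
sexual dimorphism (the 95% angle interval straddles 90°), as it should be
for orthogonally planted effects:

```r
subset(rep$effect_comparisons, grepl("captivity.sex", pair))
#                   pair     measure     mean lower  upper independent
#   captivity.sex.within       angle 109.2908 81.03 135.55        TRUE
#   captivity.sex.within correlation  -0.0232 -0.58   0.58        TRUE
```

`vignettes/captive-wild-shape-analysis.Rmd` documents the model, its
assumptions, the generator's design and the package's numerical choices.

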