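# semspace

Statistical machinery for asking how emotional experience — and its
expression in the face — is shared across groups of raters speaking
different languages or living in different cultures. Given per-rater
emotion-category ratings of a common set of stimuli from two groups, and
per-response facial-expression feature annotations, the package answers:

* How many **distinct dimensions of reported experience are preserved**
  across the two groups, and what are they?
* How strongly does each **category of experience correlate across
  groups**, once rater noise is accounted for?
* How well do **facial expressions predict experience** within a group, and
  does a model trained in one group **transfer** to the other — before and
  after removing group differences in expression *intensity* (display
  tendencies)?
* How much of the expression-explained variance in experience is
  **individual, cultural, or universal**?

## The core method

**Principal preserved components analysis (PPCA).** For two commensurate
matrices `X` and `Y` (same stimuli in rows, same rating categories in
columns — e.g. mean ratings from two cultures), PPCA finds orthonormal
directions `α` maximizing the covariance *preserved across datasets*,
`Cov(Xα, Yα)`, rather than the variance within one dataset. The solution is
the eigendecomposition of the symmetrized cross-covariance

```
R = [Cov(X, Y) + Cov(Y, X)] / 2,       R αᵢ = λᵢ αᵢ
```

with the identity `λᵢ = Cov(Xαᵢ, Yαᵢ)`: eigenvalues are signed preserved
covariances, and negative eigenvalues flag directions on which the two
datasets covary in opposite directions. When `X = Y`, PPCA is exactly PCA.

**How many dimensions are real?** A leave-one-rater-out scheme: for each
held-out rater, PPCA is refit without them (on a held-out-stimulus design —
see the methods vignette for why), their own ratings and the other group's
mean are projected onto each component, and the partial Spearman
correlation between the projections (controlling for both series'
projections on all previous components) is tested across raters with a
one-tailed Wilcoxon signed-rank test. The ordered p-values pass through the
**ForwardStop** sequential FDR rule

```
k̂ = max { k : (1/k) Σᵢ₌₁..k −log(1 − pᵢ) ≤ α }
```

Significant components are varimax-rotated into interpretable dimensions,
each labelled by its dominant category.

**Noise ceilings.** Raw cross-group correlations of noisy ratings are
bounded by the measurement reliability. The interrater reliability `r₁²` of
single responses is estimated by repeatedly correlating randomly paired
responses across stimuli; the maximum attainable correlation is
`√(r₁²_X) · √(r₁²_Y)`, and dividing by it recovers the latent cross-group
correlation. The explainable variance of an average of N responses follows

```
r_N² = ((1 − r₁²) / (N·r₁²) + 1)⁻¹
```

**Prediction and transfer.** Leave-one-stimulus-out linear regression maps
expression features to experience dimensions. Cross-group transfer applies
one group's model to the other's features, after a leave-one-out
calibration regression aligning the two groups' rating spaces; z-scoring
features within group isolates differences in expression *meaning* from
differences in *intensity*.

A synthetic two-culture generator (`simulate_emotion_study()`) with planted
latent dimensions, rater noise, per-individual deviations shared between
the rating and expression channels, and per-culture feature gains provides
ground truth for validating every stage.

## Worked example

```r
library(semspace)

cfg <- generator_config(n_stimuli = 200, n_categories = 16, n_latent = 4,
                        n_expressible = 3, n_features = 24,
                        n_raters = c(10, 6), seed = 7)
study <- simulate_emotion_study(cfg)

dims <- preserved_dims(study$ratings$a, study$ratings$b, n_components = 10)
dims
#> Preserved dimensionality (leave-one-rater-out)
#>   16 participants, 10 components tested, criterion: dual
#>   significant dimensions: 4
#>   joint p-values:
#>   1.53e-05 1.53e-05 1.53e-05 1.53e-05 0.9036 0.7359 0.9036 0.0583 0.4699 0.2166

report <- run_pipeline(study, config = run_config(seed = 1, n_components = 10,
                                                  n_bootstrap = 50,
                                                  n_reliability_reps = 50))
report
#> Cross-group experience/expression analysis
#>   200 shared stimuli, 16 categories
#>   significant preserved dimensions: 4
#>   labels: cat08, cat02, cat11, cat13
#>   mean adjusted category correlation: 0.994
#>   within-group prediction r: 0.774 / 0.778
#>   cross-group r raw: 0.503 / 0.519; normalized: 0.757 / 0.780
#>   shared variance fraction raw 0.43 -> normalized 0.98
```

Reading the output: the study planted 4 shared latent dimensions, and the
leave-one-rater-out test finds exactly 4 (the first four p-values are at
the signed-rank floor; the rest are null). Category correlations adjusted
for the noise ceiling sit at ~1.0, as they should when the two groups share
their latent signal. Group B's expression features carry per-feature
intensity gains, so the raw cross-group transfer correlation (≈0.51) falls
well below the within-group fit (≈0.77); within-group z-scoring of the
features removes the intensity differences and restores transfer (≈0.76–
0.78), lifting the cross-culturally shared fraction of explained variance
from 43% to 98%.

`write_report(report, "report.json")` serializes the full result;
`write_bundle(study, "data/")` writes the synthetic study as CSV + JSON.

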