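---
title: "Texture radiomics with mrtexture: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture radiomics with mrtexture: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mrtexture` implements a magnetic-resonance texture-analysis (MRTA)
pipeline for small rectangular ROIs: gray-level normalization and
quantization, a MaZda-compatible feature vector, Wilks-lambda stepwise
discriminant analysis with Fisher classification functions, LASSO
logistic radiomics signatures, and ROC / calibration / reproducibility
evaluation. This vignette explains the underlying models, the
conventions the implementation fixes where the field's software leaves
them ambiguous, and the reasoning behind the design choices. It states
no empirical claims beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## Normalization and quantization

Texture matrices are computed on integer gray levels `1..Ng` with
`Ng = 2^k`. `normalize_quantize()` first computes μ and SD over the ROI
pixels and saturates intensities outside μ ± 3·SD to the nearest bound
(the common MRTA "±3σ" normalization). Saturation — rather than removal
— is deliberate: removing pixels would change the ROI geometry and
invalidate co-occurrence offsets and run decompositions. The number of
saturated pixels is reported as `n_discarded`. The remaining range
`[low, high]` maps affinely onto levels via
`level = 1 + floor((x − low)/(high − low) · (2^k − 1))`; a constant
patch maps everywhere to level 1.

Conventions fixed here:

* **Bit depth** defaults to `k = 6` (64 levels), standard practice for
  matrix-based texture features on small ROIs; it is configurable
  (1–12 bits). All families — including histogram, gradient and
  autoregressive — are computed on the same quantized grid for internal
  consistency.
* **Statistics scope** is ROI-local (μ and SD from the ROI itself, not
  the slice), because the features are ROI-local quantities.
* **Coordinates** are 0-based, row-major, `y` increasing downward; ROIs
  are half-open rectangles, 8 × 9 pixels by default.

Quantization is monotone and equivariant under positive affine
transformations of the raw intensities; both properties are enforced by
property tests.

## The feature families

`extract_features()` returns 261 named features. The names follow the
MaZda convention so that externally published coefficient tables (the
packaged fixtures) resolve directly.

**Histogram (11).** Mean, population variance, skewness, excess
kurtosis of levels; nearest-rank percentiles at 1/10/50/90/99%
(deterministic for integer data); MinNorm/MaxNorm, the extreme observed
levels.

**Co-occurrence, `S(dx,dy)` (11 × 20).** `compute_glcm()` counts level
pairs at offset `(dx, dy)` for distances 1–5 in four directions —
`(d,0)` horizontal, `(0,d)` vertical, `(d,d)` down-right, `(d,−d)`
up-right. Accumulation is symmetric (each pair counted in both
directions), making features independent of scan direction. Features
use level-valued marginal indices (`i + j ∈ 2..2Ng`), natural
logarithms with `0·log 0 := 0`, and `Correlat := 0` for degenerate
(zero-variance) marginals so feature tables never contain `NaN`. The
absolute magnitude of SumAverg therefore depends on the level-value
convention; it is stated here because any external comparison must use
the same convention.

**Gradient (5).** Scaled central differences,
`g(i,j) = sqrt((x(i+1,j)−x(i−1,j))² + (x(i,j+1)−x(i,j−1))²)/4`, over
interior pixels; moments of the gradient map plus the nonzero fraction.
This kernel normalization is declared and oracle-tested rather than
claimed bit-identical to any external binary, whose exact scaling is
unpublished.

**Run length (5 × 4).** Maximal runs of identical level along rows,
columns, up-right anti-diagonals and down-right diagonals; the five
standard emphases with the run count `N_r` as denominator and
`Fraction = N_r / n_pixels`.

**Autoregressive (5).** Least-squares fit of the causal neighborhood
`x(i,j) ≈ θ₁x(i,j−1) + θ₂x(i−1,j−1) + θ₃x(i−1,j) + θ₄x(i−1,j+1)` on
mean-centered levels, with `Sigma` the residual SD. Rank-deficient
systems (e.g. constant ROIs) return zero coefficients with a degeneracy
flag.

The canonical set counts 261 features. External reports of this
workflow commonly cite "262 features per ROI" without itemizing the
set; the difference of one is documented rather than guessed at, and
every feature name appearing in the packaged published models is
producible (a test audits this). `extract_features()` accepts distance
configuration if a different offset set is needed.

## Stepwise discriminant analysis

`stepwise_select()` is the classic Wilks-lambda stepwise procedure: at
each step the candidate minimizing the partial Wilks' Λ =
det(W)/det(T) enters if its partial
`F = ((Λ_p/Λ_{p+1}) − 1)·(n − g − p)/(g − 1)` reaches the F-to-enter
threshold; any included feature whose F-to-remove falls below the exit
threshold then leaves. Defaults are 3.84 / 2.71, the long-standing
defaults of the major statistical packages. Candidates that would make
the within-group scatter numerically singular (reciprocal condition
below 1e−10) are skipped with a warning — this is both a collinearity
guard (a duplicated column can never co-enter) and an overfitting
brake on small tables.

`fit_canonical()` eigen-decomposes `W⁻¹B` and reports the dimension
chain: percent variance `100·λᵢ/Σλ`, residual Wilks lambdas
`Λ_k = Π_{i≥k} 1/(1+λᵢ)`, and Bartlett chi-squares
`χ²_k = −(n − 1 − (p+g)/2)·ln Λ_k` with `(p−k+1)(g−k)` degrees of
freedom. The multiplier was validated against an externally published
chi-square chain (reproduced by `canonical_chain()` in the acceptance
suite). One quirk found during that validation: the external report
prints a second Wilks value of "1.141", which is impossible (Λ ≤ 1 by
construction); the arithmetic from its own eigenvalues gives 0.141,
and the package documents this as a presumed misprint rather than
silently correcting anything.

`fit_fisher()` produces the per-group linear classification functions
`Y_g(x) = −½ μ_gᵀ W_c⁻¹ μ_g + ln(π_g) + (W_c⁻¹ μ_g)ᵀ x` with pooled
within-group covariance `W_c`; classification is argmax with
declaration-order tie-breaking (warned). Priors default to equal:
the five groups are nearly balanced and equal priors match the
canonical nearest-centroid rule exactly (a test cross-checks the
classification against an independent LDA implementation).
"Cross-validated" accuracy means leave-one-ROI-out; a grouped
leave-one-rat-out variant (`mode = "logo"`) is provided because ROIs
within a rat are correlated, and both can be reported. Folds whose
refit becomes singular or empties a group are skipped with a warning
rather than aborting the evaluation.

## LASSO radiomics signatures

`fit_lasso_cv()` delegates the penalized path to glmnet (binomial
family): 100 log-spaced penalties from the analytic null penalty
λ_max down to 1e−4·λ_max, features standardized internally with
coefficients reported on the original scale, and 10-fold
cross-validation on binomial deviance with stratified, seeded fold
assignment (the seed is a required, logged parameter; identical seed
and fold count give a bit-identical λ_min and signature). The signature
(`build_signature()`) is the intercept plus the nonzero coefficients at
λ_min, the deviance-minimizing rule; λ_1se is also computed. In
simulation, λ_min reliably captures every informative feature but — as
is well known for deviance-minimizing selection — admits more noise
features than the sparser 1-SE rule; the test suite checks signal
recovery at λ_min and support sparsity at λ_1se.

**Honest evaluation.** Scoring the training ROIs with a CV-tuned
signature (resubstitution) is optimistically biased, most visibly on
data with no group signal. `fit_lasso_cv()` therefore keeps glmnet's
prevalidated (out-of-fold) linear predictors, and
`pairwise_signature_auc()` reports both `auc_cv` (out-of-fold, the
honest estimate) and `auc_resub` (the in-sample convention of the
published workflow this package follows). On null cohorts only the
out-of-fold AUC sits at chance; the acceptance suite uses it for the
null check and the resubstitution AUC for the published-methodology
effect check, reporting both.

## Evaluation statistics

* **ROC/AUC** via the Mann–Whitney identity (ties ½), with DeLong 95%
  intervals by default (the usual choice when no method is named) and
  a seeded stratified bootstrap as an alternative. An all-pairs
  counting oracle bounds the implementation error at 1e−12 in tests.
* **Hosmer–Lemeshow** uses rank-based equal-count "deciles of risk"
  (tied probabilities share a rank and stay together). The rank rule
  makes bin assignment exactly mirror-symmetric under probability
  complementation, so relabeling the positive class cannot change the
  statistic. Bins with vanishing expected counts are merged with a
  warning; degrees of freedom are `bins − 2`.
* **ICC** is fixed to ICC(2,1) — two-way random effects, absolute
  agreement, single measurement — the standard form for inter- and
  intra-observer feature reproducibility; zero between-subject variance
  returns 0 with a degeneracy flag.
* **Cluster maps** z-score each feature, drop zero-variance features
  with a warning, and cluster ROIs and features with correlation
  distance (1 − Pearson r) and average linkage; dendrograms export to
  Newick via `dendrogram_newick()`.

## The synthetic cohort generator

`generate_cohort()` emulates the study layout this pipeline targets:
five groups (control and four post-stress time points) of 10/10/10/9/10
rats, five slices per rat, one pooled 8 × 9 ROI per slice — 245 ROIs in
total, matching the arithmetic of the published cohort table. A
left/right two-ROI variant is available. Group texture is the same
causal AR process the feature extractor fits — a deliberate closed
loop, so AR parameter recovery is directly checkable and co-occurrence
and run-length differences arise implicitly from the induced
correlation structure. Patches are generated on an enlarged grid (20
extra rows/columns) and cropped, so edge initialization never reaches
the output; the background outside the ROIs is a low-frequency Gaussian
blob field, which makes accidental ROI misplacement detectable (a
misplaced rectangle would show smooth, not textured, statistics).

Preset conditions, fixed once:

* `"effect"`: groups differ in the horizontal coefficient a₁ over
  {−0.5, −0.2, 0.1, 0.4, 0.7} (adjacent gap 0.3) with a₃ = 0.1, noise
  SD 1, equal means — a strong pure-texture group effect. Quantization
  is scale/shift-equivariant, so the effect survives normalization by
  construction; mean-level differences are deliberately absent.
* `"null"`: all groups share a = (0.1, 0, 0.1, 0) — no signal, used to
  verify that out-of-fold signature AUC stays within the Mann–Whitney
  95% chance band and that label-permuted leave-one-out accuracy sits
  at the 1/g chance level.

What the generator does *not* emulate: MR acquisition physics
(relaxometry, partial volume, coil bias fields), inter-rat anatomical
variability, or manual ROI placement error. Passing tests therefore
demonstrate the correctness and statistical behavior of the pipeline,
not the biological effect size of any real cohort.

## Numerical choices and degenerate inputs

* Wilks lambdas are computed from Cholesky log-determinants; non
  positive-definite submatrices yield `NA` and skip the candidate.
* Constant ROIs: all levels 1, zero entropies, InvDfMom 1,
  `Correlat = 0` (flagged), zero AR coefficients, zero gradient.
* Classification ties break to the earliest-declared group, with a
  warning.
* Model JSON round-trips use 17 significant digits, which reproduces
  IEEE doubles exactly.
* Problem sizes in the test and acceptance suites (one 245-ROI cohort
  per preset, 50-ROI oracle batches, 10-replicate recovery and
  permutation checks, 300-seed calibration nulls at n = 3000) were
  chosen to make Monte-Carlo noise small relative to each asserted
  tolerance while keeping a full run in the low minutes on one CPU.

## Known limitations

* The gradient and quantization conventions are declared, tested
  implementations of common MRTA practice, not bit-exact replicas of
  any specific closed-source tool.
* Stepwise discriminant selection inherits the known optimism of
  sequential F-tests; the package mitigates but does not eliminate it
  (LOO and leave-one-rat-out accuracy are first-class outputs for this
  reason).
* Pairwise signatures are binary only; no multinomial LASSO over all
  five groups is provided.
* 2D features only — no wavelet, Gabor, fractal or 3D texture.
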