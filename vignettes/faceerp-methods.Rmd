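---
title: "Individual-level analysis of infant face-processing ERPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual-level analysis of infant face-processing ERPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceerp)
```

# The scientific problem

Infants with an older sibling diagnosed with autism spectrum disorder (ASD)
are at elevated likelihood (EL) of a later ASD diagnosis themselves.
Event-related potentials (ERPs) recorded while 8-month-old infants view
faces and control stimuli index successive stages of face processing: the
early sensory P1 (positive, ~100-130 ms), and the face-sensitive N290
(negative, ~290 ms) and P400 (positive, ~400-500 ms), the latter two
regarded as developmental precursors of the adult N170. `faceerp`
implements an individual-level analysis pipeline over these features:

1. **erp** — peak amplitude (µV) and latency (ms) extraction from averaged
   epochs, per stimulus condition and contrast;
2. **impute** — eligibility filtering and expectation-maximization (EM)
   imputation of missing features under a multivariate Gaussian;
3. **groupstats** — split-plot (condition × outcome-group) ANOVAs with
   covariate adjustment, Sidak-corrected post-hocs and Cohen's d;
4. **select** — genetic-algorithm (GA) wrapper feature selection around a
   10-fold cross-validated linear support-vector machine (SVM), with
   holdout validation, bootstrap CIs and permutation ("shuffle") tests;
5. **enet** — elastic-net regression of a continuous social-functioning
   outcome under nested leave-one-out / repeated 10-fold cross-validation;
6. **bhc** — Bayesian hierarchical clustering (BHC) with a
   Dirichlet-process prior for stratification into subgroups;
7. **synth** — a synthetic cohort generator that plants all of the above
   structure so each stage is testable end to end.

The six stimulus conditions are FD (direct gaze), FA (averted gaze), F
(static face), N (visual noise), SD (gaze shifting toward the viewer) and
SA (gaze shifting away); the three contrasts are face−noise (`FvN`),
direct−averted (`DvA`) and toward−away (`TvA`). The feature inventory is
fixed at 56 columns: 3 components × {amplitude, latency} × 6 conditions
(36), × 3 contrasts (18), plus gender (0 female / 1 male) and standardized
age. The exact predictor count of the original analyses is not public; 56
is the smallest inventory consistent with all analysis arms, and the
package treats it as the canonical layout throughout.

# The synthetic cohort generator

The generator defines the study conditions under which every later claim is
tested. Its defaults are fixed once:

- **Cohort sizes.** 68 TL (typical likelihood), 115 EL-no-ASD, 33 EL-ASD —
  so 33/148 = 22.3% of EL infants carry the later diagnosis.
- **Feature model.** For each of the six component-measures, a
  subject-level random effect shared across the six conditions (within-
  subject correlation `within_subject_rho = 0.5`) plus condition noise,
  unit marginal variance. The shared effect mirrors the waveform
  generator, where a subject's component latency/amplitude is drawn once
  and reused across conditions; it is also what makes conditional-mean
  imputation meaningful, exactly as in real ERP data where a subject's
  responses correlate across conditions.
- **Planted group effects** (standardized shifts, Cohen's d): P1 latency
  TvA +0.74 in TL and +0.43 in EL-no-ASD with the reversed sign in EL-ASD
  (−0.40); N290 latency FvN +0.61 in TL and +0.52 in EL-no-ASD with no
  differentiation in EL-ASD; P400 latency TvA +0.50 in EL-ASD against
  −0.55 / −0.47 in TL / EL-no-ASD; P400 amplitude TvA +0.46 / +0.41 in the
  EL groups against −0.40 in TL. Magnitudes that are only qualitatively
  reported (a direction without a d) default to 0.4-0.5, the range of the
  reported effects; they were chosen once and not revisited. An effect on
  a contrast feature is planted by shifting the two parent conditions
  symmetrically by `±d·sqrt(2(1−ρ))/2`, so the contrast itself carries
  exactly the requested d and the identity *contrast = parent difference*
  holds subject by subject.
- **Outcome model.** A social-functioning score `100 + 15·(Xβ + ε)` with
  the dominant negative weight on N290 latency FvN, a negative gender
  weight (females higher), a negative age weight, and ε ~ N(0, 1): a
  modest signal-to-noise ratio in line with "significant but not strong"
  dimensional prediction.
- **Missingness.** MCAR by default (5%); a MAR-on-age mechanism makes the
  per-subject masking probability a logistic function of standardized age
  only, with the intercept solved numerically so the expected overall rate
  is as requested. Masking operates on the 36 averaged features — losing
  a peak loses its contrasts — and the differential columns are recomputed
  with `NA` propagation.
- **Clusters.** `make_cluster_spec(K, separation)` places centroids at the
  vertices of a regular simplex scaled so that every pair of centroids is
  `separation` within-cluster-SD units apart *per feature dimension* (RMS
  over dimensions; pairwise Euclidean distance `separation·sqrt(p)`), then
  rotates the simplex by a seeded random orthonormal basis so between-
  cluster differences are spread diffusely over all 36 averaged features.
  The diffuse layout matches subgroups that differ on broad response
  profiles rather than single features. The per-dimension convention is
  deliberate: with a *total* Euclidean separation of a few SD in 36
  dimensions, mixture components overlap so heavily that no clustering
  method (k-means given the true K included) can recover them, so the
  planted structure would be untestable.

What the generator does **not** emulate: 1/f EEG noise spectra, real
electrode montages and volume conduction, eye-movement or motion
artifacts beyond simple amplitude outliers, non-Gaussian feature
distributions, and outcome heteroscedasticity. Passing recovery tests on
this cohort therefore demonstrates correctness of the estimators under
their own assumptions, not robustness to everything real infant EEG does.

## Waveform mode

`generate_waveforms()` builds each epoch as baseline Gaussian noise plus
three Gaussian bumps (P1 positive, N290 negative, P400 positive) with
subject-level latencies/amplitudes, full gain on 6 designated
occipito-temporal channels of a generic 20-channel layout and 0.2 gain
elsewhere. Component centers must be at least one combined width apart or
the configuration errors out. With zero noise the extraction round-trips:
peak latency within half a sample (2 ms at 250 Hz) and amplitude within
0.05 µV of the planted values.

# Feature extraction choices

Peak search windows default to P1 [70, 170] ms (positive), N290 [200, 350]
ms (negative), P400 [350, 600] ms (positive) — standard infant face-ERP
windows; the publication's exact windows are supplement-only, so these are
configurable defaults. The peak is the extremum of the *channel-group
mean* over the designated occipito-temporal channels (not averaged
per-channel peaks). A candidate peak must be a local extremum of the
signal; a monotone run through the window is flagged `no-peak`, and ties go
to the earliest sample. Baselines use the full prestimulus segment
(time ≤ 0). Artifact rejection is a deliberately simple absolute-amplitude
rule (default 200 µV on the designated channels) with a minimum-epochs
requirement (default 10): the original artifact protocol is out of scope,
and this simplified rule is documented as such. Flags propagate: a flagged
condition leaves its features and every contrast touching them missing.

# EM imputation

Subjects with at least 70% of their ERP features observed (inclusive
boundary) are eligible. The imputation model is a single multivariate
Gaussian over the **36 averaged features only**: the 18 differential
features are exact linear combinations of them, so a joint Gaussian over
all 54 would be degenerate; contrasts are recomputed from the imputed
parents, which also preserves the contrast identity exactly. Gender and
age are not in the imputation model; they appear only in the
missing-at-random diagnostics (Welch t-tests and chi-square tests
comparing complete against incomplete subjects).

Estimation is MAP-EM under a weak inverse-Wishart prior with mode at the
diagonal of the available-case covariance (strength `nu = 2`). The
unpenalized Gaussian likelihood is *unbounded* when n is not large
relative to p = 36 — iterating exact EM on such data drifts toward a
singular covariance — whereas the MAP objective is bounded and its EM
ascent provably monotone; the reported `loglik` trace is this penalized
objective, and a material decrease raises an error as an
implementation-bug signal. Convergence is declared at a relative objective
change below `1e-6` (at most 500 iterations); singular observed blocks
fall back to a ridge-regularized inverse with a warning. A final E-step at
the converged parameters produces the imputed values.

To avoid leakage, the classification arm fits the imputation model on the
main (training) split only and applies the fitted parameters to the
holdout via `em_apply()`; whether the original analysis imputed before or
after splitting is not stated, and split-first is the package default.

# Group-level inference

With a two-level within-subject factor, the split-plot ANOVA decomposes
exactly into two orthogonal strata: subject means (between: group, and
optionally cohort) and condition differences (within: condition, condition
× group). The package computes both strata from this decomposition, which
reproduces the classical repeated-measures sums of squares, and the
interaction F is *identically* the one-way ANOVA F on difference scores —
an algebraic identity used as a test oracle. Sphericity is moot with two
within levels, so no Greenhouse-Geisser correction exists or is needed.
Covariate adjustment residualizes the stratum projections on the
covariates (dropping constants and collinear columns with a warning) and
reduces the error degrees of freedom accordingly. Post-hoc comparisons use
Welch t-tests (robust to unequal variances) but pooled-SD Cohen's d for
comparability with conventional effect-size reporting, Sidak-adjusted over
the family of the three pairwise group contrasts.

# The classification arm

The fitness of a feature mask is the pooled 10-fold cross-validated AUC of
a soft-margin linear SVM (fixed C = 1, no internal tuning) on standardized
masked features, standardization parameters always from the training folds
only. AUC uses the Mann-Whitney formulation with ties counted one half.
The SVM is solved by dual coordinate descent with shrinking (the standard
algorithm for linear SVMs) with the bias as an augmented constant feature;
a reference implementation agrees with its decision values to correlation
> 0.999 in tests.

The GA uses binary chromosomes over the 56-feature inventory: tournament
selection (size 3), single-point crossover (p = 0.8), per-bit mutation
(1/p), elitism of one, and a *sparse* initial population
(`init_density = 0.1`). Sparse initialization is the usual choice for
wrapper selection — candidate sets stay small and informative features are
assembled by crossover — and it keeps the per-feature incidence of
uninformative features among best masks low, which is what makes the
incidence aggregation discriminating. The fold assignment is fixed within
an evolution (so elitism guarantees monotone best fitness against a fixed
fitness function) and redrawn across evolutions (so fold-specific
overfitting decorrelates across the archive). The study-scale
configuration is 100 evolutions, population 50, 100 generations; the
analysis scripts and tests run 20 evolutions of population 18 over 12
generations, which the recovery experiments show is sufficient to rank 4
planted d = 1 features above all 52 noise features in ≥ 90% of seeded
experiments at n = 300.

The "optimal" set is the single best-fitness mask across evolutions (ties
broken toward fewer features, then lexicographically). The "highest
incidence" set keeps features whose incidence *strictly* exceeds 80% among
best masks whose fitness *strictly* exceeds 0.85 — both inequalities
strict, matching the > symbols of the selection rule. Gender and age are
always candidate features and their selection frequency is reported.

Holdout evaluation trains on the full main split, scores the holdout, and
thresholds at the Youden-J-optimal point *of the main sample* (the
original thresholding rule is unstated; Youden on training data is the
conventional choice). Sensitivity, specificity, accuracy, PPV and NPV get
percentile bootstrap CIs over holdout resamples; AUC significance against
chance uses label permutation with `p = (1 + #{AUC_perm ≥ AUC_obs}) /
(n_perm + 1)`, and classifier pairs are compared by a paired permutation
that swaps the two score vectors within subjects.

# The dimensional arm

Predictors are checked for skewness (|skew| ≥ 0.7 flags a `log1p`
transform after shifting to positive support) and standardized — both
fitted inside each outer training fold and applied to the held-out subject
with training parameters, a leakage-free refinement of the global
preprocessing description. The elastic net minimizes

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
\lambda\left(\alpha\|\beta\|_1 + \frac{1-\alpha}{2}\|\beta\|_2^2\right)$$

by cyclic coordinate descent with soft-threshold updates and glmnet-style
active-set cycling (the kernel is compiled; the per-sweep objective trace
is returned so monotone descent is assertable). Tests pin the fit to
ordinary least squares at λ = 0, to exact soft-thresholding under a
centered orthonormal design, and to an independent implementation of the
same objective. The λ-grid holds 50 log-spaced values spanning 4 decades
below λ_max = max|X'y|/(nα) (inflated by 1e-6 so the top of the grid is
strictly all-zero); the α-grid is {0.1, 0.3, 0.5, 0.7, 0.9, 1} at study
scale and {0.5, 1} in the desk-scale profile. α is tuned on the inner grid
(the original mixing setting is unstated). Outer validation is
leave-one-out; inner selection is repeated k-fold CV minimizing RMSE
(10 × 10 at study scale, 10 × 2 at desk scale). Reported: RMSE with a
1000-resample bootstrap CI, relative error = RMSE / range(y), Pearson r
with a slope test, Shapiro-Wilk and Breusch-Pagan residual checks, a
shuffle test permuting the outcome (counting permutations with RMSE at or
below the observed, since better-than-chance means *smaller* error), and
the strict stability rule: a feature is "always selected" only if its
coefficient is nonzero in 100% of outer fits.

# The stratification arm

BHC greedily merges the pair of clusters with the highest posterior merge
probability r, combining the marginal likelihood of the merged block under
a conjugate model with the Dirichlet-process weight recursion
(d_k = α·Γ(n_k) + d_i·d_j, π_k = α·Γ(n_k)/d_k), all in log space. The
likelihood is an independent per-dimension Normal-Gamma (diagonal
covariance): with p = 36 features and n ≈ 144 subjects a full
Normal-inverse-Wishart would be poorly determined, and the diagonal model
keeps the marginal a closed-form product. The n = 1 marginal equals the
prior-predictive Student-t density (tested), and small-n trees match an
exhaustive independent reimplementation exactly.

Hyperparameter defaults are calibrated to standardized features:
`kappa0 = 1, a0 = 2, b0 = 1` give a unit-variance prior predictive with 4
degrees of freedom, under which a standardized observation is typical. A
much weaker mean prior (e.g. kappa0 of order 0.01) makes the prior
predictive so heavy-tailed (a near-Cauchy with variance ~100 on
standardized data) that merge posteriors are driven by the DP terms alone
and the greedy tree mixes planted clusters from the very first merges,
which is why the package does not default to it. The DP concentration is
α = 1. All are configurable.

The flat partition cuts the tree from the root: nodes with r > 0.5 root
clusters, nodes with r ≤ 0.5 are split (ties at exactly 0.5 split);
cluster count is thus automatic. Stability is leave-one-out: rebuild on
n−1, cut, compare to the full partition restricted to the same subjects by
the adjusted Rand index (the stability metric of the original analysis is
unnamed; ARI is the standard chance-corrected choice). Characterization
runs one-way ANOVAs per feature and per outcome variable across clusters
(singletons excluded with a warning), Holm-Bonferroni within each family
separately, and Tukey HSD for survivors.

# Numerical and reproducibility choices

- One root seed; every stage derives its own stream via
  `derive_seed(root, label)`, so stages are independently reproducible and
  any stage re-run with the same config and seed is bit-identical.
- All DP/likelihood recursions in log space with `logaddexp`; the mixture
  bound `log p(D|T) ≥` both components is asserted at every merge.
- Tie-breaks are deterministic and documented: earliest sample for peak
  ties, smallest combined node index for merge ties, fewest features then
  lexicographic for GA fitness ties.
- Degenerate inputs are guarded, not silently absorbed: all-equal ANOVA
  strata report F = 0 / p = 1; zero-variance predictors are dropped with
  warnings; empty masks, single-class folds and missing-class holdouts
  raise errors or flags.

## Problem sizes

Simulations in the test-suite and analysis scripts are sized for a desk:
recovery experiments use n = 144-300 subjects, 20 GA evolutions
(population 18, 12 generations), 200-500 permutations/replications, inner
CV 10 × 2, and 1000-2000 bootstrap resamples. The study-scale profile
(10000 permutations, 10000 bootstrap resamples, 100 evolutions, 10
repeated inner folds) is available via `pipeline_config(profile =
"study")`; these counts change precision, not methodology.

# Known limitations

- The diagonal BHC likelihood ignores feature correlations; strongly
  correlated blocks can fragment or fuse clusters. A full-covariance
  plug-in would be the natural extension.
- The GA's wrapper fitness overfits the fixed fold assignment within an
  evolution; the archive-level incidence aggregation is the intended
  counter, and single-evolution masks should not be over-interpreted.
- EM imputation assumes joint Gaussianity and MAR; under MNAR mechanisms
  conditional means are biased.
- LOO stability rebuilds the tree n times (O(n³) overall); for large
  cohorts use a subsample, as the analysis script does.
- Holdout metrics at n = 43 carry wide bootstrap intervals; the synthetic
  experiments reproduce that imprecision faithfully rather than hiding it.
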