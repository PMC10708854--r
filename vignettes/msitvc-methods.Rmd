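---
title: "Methods: neuro-fuzzy TVC prediction from multispectral signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neuro-fuzzy TVC prediction from multispectral signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Meat spoilage is driven by microbial growth on the product surface, and
the standard quality index is the total viable count (TVC), expressed in
log10 cfu cm^-2. Plate counting takes days; multispectral imaging (MSI)
is fast and non-destructive. An 18-waveband instrument (405-970 nm)
yields, per specimen, two first-order-statistics features per band: the
mean reflectance over the region of interest and the standard deviation
of pixel intensity. `msitvc` regresses TVC on these 36 features.

The pipeline has four stages, run in parallel for the mean and sd
feature blocks: (1) wavelength selection by fusing seven ranking
methods with a majority vote; (2) a clustering-initialised
Takagi-Sugeno (TSK) neuro-fuzzy regressor with asymmetric Gaussian
membership functions (referred to as CAGFINN) per block; (3) stacking
the two base predictions through a meta-model; (4) validation with the
metrics conventional in predictive food microbiology and chemometrics.

## Synthetic data: what it emulates and what it does not

Instrument datasets of this kind are rarely deposited, so
`generate_dataset()` simulates a complete storage trial and every
downstream stage is developed and tested against it.

**Growth kinetics.** TVC trajectories follow the Baranyi-Roberts model

$$y(t) = y_0 + \mu A(t) - \log_{10}\!\left(1 + \frac{10^{\mu A(t)} - 1}{10^{y_{max}-y_0}}\right),
\qquad
A(t) = t + \frac{1}{\hat\mu}\ln\!\left(e^{-\hat\mu t} + e^{-h_0} - e^{-\hat\mu t - h_0}\right),$$

with $\hat\mu = \mu \ln 10$ and a Ratkowsky square-root secondary model
for temperature, expressed as
$\mu(T) = \mu_{ref}\,((T - T_{min})/(T_{ref} - T_{min}))^2$. Defaults
($y_0 = 3.06$, $y_{max} = 9.89$ log10 cfu cm^-2, $\mu_{ref} = 0.085$
log10 h^-1 at $T_{ref} = 16$ °C, $T_{min} = -10$ °C, $h_0 = 1$) were
chosen once so that the default design — 17 specimens at each of 0, 4,
8, 12 and 16 °C, sampled on an even schedule up to at most 434 h —
reproduces the qualitative shape of a chill-to-abuse beef storage
trial: spoilage within ~80 h at 16 °C, a plateau barely reached after
400+ h at 0 °C, and a half-span time strictly decreasing with
temperature (property-tested).

**Spectral coupling.** Each feature is affine in TVC plus Gaussian
noise: `baseline[j] + slope[j]*tvc + N(0, noise_sd)`, with an optional
quadratic term for deliberately nonlinear scenarios. The default slope
patterns give the visible mean-reflectance bands {1,2,5,7,8,9,11,12}
and the mid-visible sd bands {4,5,6,7,8,12} genuine signal and leave
the remaining bands flat, so that feature selection has both true
positives and true nulls to find. This is a deliberate simplification:
real reflectance spectra carry band-to-band correlation structure,
scattering effects and heteroscedastic noise that the generator does
not model. Passing tests therefore demonstrate algorithmic
correctness, not field performance on real meat.

`generate_tsk_dataset()` is a separate generator: it samples inputs
uniformly and evaluates a fully specified TSK system with a plain-loop
forward pass. It exists to give the network trainer a ground truth
whose functional form the network can represent exactly, enabling
parameter-recovery tests.

## Wavelength selection and fusion

Seven rankers are exposed behind one interface (`rank_features()`):
a shadow-feature random-forest test (the Boruta idea: a band is
confirmed when its permutation importance beats the best permuted copy
in a majority of repeated forests), backward recursive feature
elimination over random-forest importance, a compact generational
genetic algorithm (crossover 0.8, mutation 0.1, AIC fitness), AIC
stepwise regression, the cross-validated lasso, LMG relative-importance
decomposition (exact Shapley over subsets for up to 12 bands, seeded
permutation sampling beyond), and a partial-least-squares coefficient
filter built on the package's own NIPALS routine. Rankings are
per-method permutations 1..m with no gaps; an all-shrunk lasso returns
an empty, flagged ranking rather than an error.

`fuse_rankings()` is the decision core: a band is selected when at
least `threshold` methods retained it, with `"majority"` resolving to
`floor(K/2) + 1`. Ordering of the selected set is by votes (desc), then
mean rank among selectors (asc), then band index — the tie-break is
recorded in the result so downstream users can see exactly how order
was decided. The fusion is tested against exhaustive vote counting on
random tables and is permutation-invariant and monotone in the
threshold. On the published ranking tables shipped in
`inst/extdata/`, the strict majority rule reproduces the published
8-band mean selection and 6-band sd selection exactly.

`pca_baseline()` (covariance PCA) is provided as the conventional
unsupervised alternative for comparison runs.

## The neuro-fuzzy regressor

**Architecture.** One fuzzy rule per cluster. Rule $i$ holds one
asymmetric Gaussian membership per input $j$: a shared centre $c_{ij}$
with separate left/right spreads. The forward pass evaluates
$A_{ij}(x) = \exp(-(x_j - c_{ij})^2 / (2 b_{ij}^2))$ with the *total*
spread $b_{ij} = \sigma^{left}_{ij} + \sigma^{right}_{ij}$, recording
which side of the centre the input fell on. Rule strength is the
product over inputs; strengths are normalised to sum to one; the output
is the normalised-strength-weighted sum of affine consequents
$f_i = w_i \cdot x + w_{i,q+1}$. If all strengths underflow, the
normalisation falls back to uniform weights (counted, not fatal).

**Initialisation.** A supervised LVQ-like stage allocates prototypes
incrementally in the z-scored joint (input, target) space: a point
farther than `radius_frac` x the cloud's bounding-box diagonal from
every prototype spawns a new one, otherwise the nearest prototype moves
toward it by `lvq_rate` (defaults 0.3 and 0.05). The cluster count —
hence the rule count — is therefore emergent. Fuzzy c-means (fuzzifier
2, the standard choice) then refines the centres; the prototype stage
standardises internally because the radius criterion needs scale
invariance, while FCM runs in the original units so the resulting
centres and spreads need no back-mapping (the trainer z-scores
everything consistently afterwards). Initial spreads are the
membership-weighted second moments about the centres, floored at 1e-3
of the coordinate range; each side spread starts at half the initial
value.

**Hybrid learning.** Per epoch, samples are processed sequentially:
recursive least squares (forgetting factor 1, covariance $10^4 I$,
reset per epoch — so consequents converge to the batch least-squares
solution of the linearised system, which is verified to 1e-6 in tests)
updates the consequents on the regressor
$(\bar R_1 [x, 1], \dots, \bar R_c [x, 1])$; then gradient descent
(rate 0.01 in standardised input space) updates the premise. The
centre gradient follows the chain rule; the spread step is taken on the
total spread, and only the recorded side is set to $\sigma_{new}/2$,
which is what makes the membership functions grow asymmetric. The side
indicator is treated as locally constant (its derivative vanishes
almost everywhere), and both gradients are verified against central
finite differences to 1e-4 relative error. Because online updates
cannot guarantee monotone epoch RMSE, the trainer returns the
best-epoch parameters by default (`keep_best = TRUE`); training stops
on an improvement tolerance of 1e-6 or at 500 epochs.

**Numerical safeguards.** Spreads are floored; a divergence guard
raises an error on non-finite RMSE (in practice the bounded membership
and the underflow fallback make this hard to reach, which is itself
property-tested); rule count never changes after initialisation.

## Stacking

The mean-block and sd-block models are base learners. Their
out-of-fold predictions (5-fold by default in the pipeline) form the
meta-training set — in-sample base fits would bias the meta-model
optimistically. Three combiners are computed: the plain average; a
linear PLS meta-model on $(X_{mean}, X_{sd})$; and the nonlinear
meta-model, a NIPALS PLS fit on the degree-4 polynomial basis
$\{X_{mean}^d, X_{sd}^d : d = 1..4\}$ plus intercept (9 coefficients,
reported in raw units). The basis is standardised before component
extraction to tame the collinearity of powers; the component count is
chosen by inner cross-validation, capped at 4. Meta-models in the
pipeline are themselves evaluated leave-one-out over the stacked rows.

## Validation metrics

`compute_metrics()` reports RMSE, MAE, MAPE%, the un-averaged APE sum,
SEP% (= 100 RMSE / mean(y), bias-uncorrected), the bias factor
$B_f = 10^{\sum \log_{10}(\hat y_i / y_i)/n}$, the accuracy factor
$A_f = 10^{\sum |\log_{10}(\hat y_i / y_i)|/n}$, RPD, RER, RPIQ
(type-7 quartiles, recorded in the report), the standardised mean
difference, Cohen's d with the pooled SD, and R² (squared Pearson
correlation by default; the coefficient-of-determination convention is
available via `r2 = "determination"`). Note $A_f$ uses the absolute
log ratio — without it the "accuracy" factor would degenerate into the
bias factor and lose its scatter semantics. Non-positive observations
flag the log-ratio metrics as undefined instead of failing the report;
zero RMSE flags the ratio metrics and reports them as infinite.

`loocv()` is model-agnostic (fit/predict closures) and its predictions
are verified against the hat-matrix closed form for linear models.
`holdout_split()` stratifies by storage temperature with
largest-remainder quotas, so 84 samples at a 10% fraction give exactly
8 test samples.

## Problem sizes and reproducibility

The shipped tests and the pipeline default run on an 85-sample
simulated trial (17 specimens x 5 temperatures), TSK-recovery sets of
100-200 samples, and 1000-instance random suites for the metric and
fusion oracles — sizes at which every oracle comparison is exact and
the full pipeline completes in well under a minute per stage. A single
master seed fans out to per-stage seeds by stable hashing of stage
names, so any stage can be re-run in isolation and two runs with the
same configuration produce identical artifacts.

## Known limitations

- The synthetic generator's affine coupling cannot show real-data
  advantages of the asymmetric memberships over symmetric ones; it
  shows correctness, not superiority.
- The published per-method ranking tables are reproduced as fusion
  *inputs*; re-deriving them from data requires the original trial.
- The LMG decomposition falls back to permutation sampling above 12
  candidate bands and is then stochastic (seeded).
- The regressor is single-output (MISO); no rule pruning or structure
  learning occurs after initialisation.
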