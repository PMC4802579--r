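---
title: "ampliBench: models, assessments and design choices"
author: "ampliBench authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ampliBench: models, assessments and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliBench)
```

## The problem

Quantitative PCR measures gene (here, microRNA) abundance indirectly: the
instrument records a baseline-corrected fluorescence value (ΔRn) at the end
of every amplification cycle, and an algorithm converts each amplification
curve into a *threshold cycle* — the fractional cycle at which amplification
is considered detected. Higher threshold cycles mean fewer starting copies;
one cycle corresponds to a two-fold change in abundance. Different
algorithms (vendor software, open-source curve fitters) produce different
estimates and different quality scores from the same raw curves, and their
relative merits are not obvious without a benchmark in which the *relative*
truth is known.

`ampliBench` provides (i) an open curve-fitting estimator (sigmoidal model
families with the second-derivative-maximum rule), (ii) a suite of seven
assessment statistics that score any expression/quality matrix pair against
a two-pool mixture/dilution design, and (iii) a ground-truthed synthetic
generator of that design, so the entire pipeline can be exercised and
validated end to end without external data.

## The mixture/dilution design

Two RNA pools, A and B (emulating blends of two tissues each), are combined
into ten sample types measured in quadruplicate (40 samples):

* types 1 and 5: pure A and pure B (relative weight 1);
* types 2–4: A held constant at weight 1 while B is titrated through
  0.2, 0.4, 0.8 (doubling twice — the 16/80, 32/80, 64/80 volume ratios);
* types 6–8: the mirror series titrating A;
* types 9 and 10: equal-weight low-input dilutions (0.1/0.1 and 0.01/0.01).

Because mixing is physical, it is linear on the abundance scale. With
threshold-cycle expression $E$ and abundance $\propto 2^{-E}$, a mixture
with weights $(w_A, w_B)$ has expected expression

$$E_{mix} = -\log_2\!\left(w_A 2^{-E_A} + w_B 2^{-E_B}\right),$$

which is the package's central modelling identity (`expectedExpression()`).
It implies, for example, that a ten-fold dilution of both pools shifts
expected expression by exactly $\log_2 10 \approx 3.3219$ cycles. The
published design states only that expectations derive from the pure
samples; the abundance-scale form above is our explicit construction and
everything downstream (limit of detection, accuracy) relies on it.

## Curve models and the cpD2 rule

Five model families are registered (`listModels()`), with $x$ the cycle:

| id | formula | parameters |
|----|---------|-----------|
| b4 | $c + (d-c)/(1+e^{b(x-e)})$ | 4 |
| l4 | $c + (d-c)/(1+e^{b(\ln x-\ln e)})$ | 4 |
| b5 | $c + (d-c)/(1+e^{b(x-e)})^{f}$ | 5 |
| l5 | $c + (d-c)/(1+e^{b(\ln x-\ln e)})^{f}$ | 5 |
| linexp | $a e^{kx} + mx + o$ | 4 |

$c$ and $d$ are baseline and plateau fluorescence, $e$ locates the rise
(cycles), $b < 0$ is the slope parameter of an increasing curve and $f$ an
asymmetry exponent. Fitting is bounded Levenberg–Marquardt least squares
(`minpack.lm`), with starting values taken from the data: $c_0 = \min y$,
$d_0 = \max y$, $e_0$ at the steepest observed rise, $b_0$ from the slope
there, $f_0 = 1$. Convergence uses a relative residual-sum-of-squares
tolerance of $10^{-10}$ with at most 500 iterations. A fit is flagged
non-converged — never an exception — when the optimizer fails, the input is
flat (residual variance undefined), the fitted plateau does not exceed the
baseline, or the fitted curve is non-increasing over the cycle range;
non-converged curves yield a missing expression estimate with quality 0.

The expression estimate is **cpD2**: the cycle at which the second
derivative of the fitted curve is maximal, i.e. the point of maximal
acceleration at the start of the exponential phase. Second derivatives are
analytic for every family; the maximum is located on a 0.01-cycle grid and
refined by root-finding on the (numerically differentiated) analytic second
derivative, falling back to golden-section refinement when no sign change
brackets the grid argmax. For the symmetric logistic
$c + (d-c)/(1+e^{-(x-e)/s})$ the maximum has the closed form
$e - s\ln(2+\sqrt 3)$, which the tests use as an independent oracle. For
l4/l5 we compute the second derivative on the raw-cycle axis (not the
log-cycle axis); implementations that differentiate in $\ln x$ will differ
slightly. The linexp family has a monotone second derivative, so its cpD2
is a boundary argmax; it is retained for completeness but is expected to
perform worst, consistent with its published reputation.

The quality score of a fit is $R^2 = 1 - SS_{res}/SS_{tot}$ on the fitted
cycles, clamped to $[0,1]$; higher is always better. The default
good-quality cut is $R^2 \ge 0.99$ (inclusive); imported vendor quality
scores (AmpScore-style) conventionally use a cut of 1.25, also inclusive.

## The seven assessments

All assessments consume a `CqSet` (features × samples expression and
quality matrices) plus the `MixtureDesign`; "observed" expression for a
feature in a sample type is the mean over its good-quality replicates, and
two-method comparisons restrict by default to entries good in both.

1. **Quality** (`qualitySummary`): expression/quality pairs for present
   estimates, the quality distribution of missing estimates, 2-D binned
   counts.
2. **Expression comparison** (`expressionComparison`): paired estimates with
   a flag list where $|e_1 - e_2|$ exceeds a threshold (default 2 cycles =
   4-fold abundance; deliberately conservative).
3. **Complete features** (`classifyFeatures`, `completeFeaturesTable`):
   complete = detected with good quality in all samples; absent = in none;
   partial otherwise; the two-method 3×3 cross-table sums to the feature
   count.
4. **Limit of detection** (`limitOfDetection`): for the three comparisons
   (type 9 vs pure prediction, type 10 vs pure, type 10 vs type 9 shifted
   by $\log_2 10$), the reported limit at tolerance $t$ is the smallest
   observed expected value $t^*$ such that the median absolute
   observed-minus-expected difference among features with expected
   $\ge t^*$ reaches $t$; candidates are the observed expected values
   themselves (no interpolation), which makes the scan deterministic and
   forces thresholds to be non-decreasing in the tolerance. Default
   tolerances are 0.5, 0.75 and 1.00 cycles.
5. **Titration response** (`titrationResponse`): a feature responds when
   its replicate-mean expression is *strictly* decreasing along a series
   (abundance strictly increasing); ties count as non-response, a strict
   and deterministic convention. Results are stratified by
   $d$ = constant-pool pure expression − titrated-pool pure expression, so
   $d > 0$ means the titrated component is the more abundant one.
6. **Accuracy** (`signalDetectSlopes`): per feature × series, ordinary
   least squares of observed on expected expression using replicate-level
   points (up to 12) rather than 3 means, to give the slope test usable
   degrees of freedom; ideal slope 1; slopes with $p \ge 0.05$ for the
   slope-zero test are flagged non-significant (no multiplicity
   correction, matching the raw 0.05 convention); median/MAD summaries in
   tertile bins of $d$. Both series are stratified by $d$; published
   summaries whose binning variable is ambiguous may therefore not be
   numerically identical.
7. **Precision** (`precisionSummary`): per feature × sample type whose
   present replicates are all good quality and number ≥ 2, the
   within-replicate SD (denominator $n-1$) and CV = SD/mean, in three
   equal-count bins of group mean expression.

## The synthetic generator

`generateTruth()` draws, per feature, pure-pool threshold cycles from
Uniform(14, 30) with fractions 0.15/0.15/0.15 of pool-A-only, pool-B-only
and absent-in-both features (the remaining 55% shared), emulating
tissue-specific microRNAs and the sizeable absent fraction seen in real
two-tissue benchmarks; pool A and B cycles are drawn independently. Curve
shape parameters are uniform per feature: plateau 1.5–3.5, baseline 0–0.15
(arbitrary fluorescence units), logistic scale 1.3–1.9 cycles — typical of
baseline-corrected ΔRn curves that complete their rise within a 46-cycle
run for the expression range above.

`simulateBenchmark()` computes each feature × sample-type mixture threshold
cycle with the abundance-mixing identity, then per replicate:

* **failure**: with probability `failureRate` (default 0.02) the curve is
  flat regardless of abundance, emulating reaction failure;
* **dropout / detection ceiling**: template molecules are Poisson with
  mean $\lambda = 2^{M - Ct}$, where $M$ (default 30 cycles) is the
  single-molecule ceiling. Zero molecules give a flat curve, so dropout
  probability $e^{-2^{M-Ct}}$ rises sigmoidally past $M$; detected curves
  measure $M - \log_2 n$, which reproduces both the Poisson jitter of low
  template counts and the saturation of observed expression near the
  detection limit — the very effect the limit-of-detection assessment
  quantifies. The default $M = 30$ was chosen once to place the simulated
  detection limit near cycle 30, a realistic value for this assay class;
  setting $M = \infty$ disables the mechanism entirely;
* **replicate noise**: Gaussian, `ctNoiseSd` (default 0.25 cycles);
* **curve synthesis**: a symmetric logistic with midpoint
  $x_{mid} = Ct + s\ln(2+\sqrt 3)$, so the curve's analytic cpD2 equals
  the noisy threshold cycle — truth is directly comparable to cpD2
  estimates — plus i.i.d. per-cycle fluorescence noise with SD equal to
  `fluorNoiseSd` (default 0.02) times the curve amplitude.

All randomness flows from one seed through a single fixed, vectorized draw
order keyed by (feature, sample type, replicate), so results are
reproducible and independent of any iteration order.

What the generator does *not* emulate: amplification-efficiency drift,
primer cross-hybridization, pre-amplification bias, or the exact marginal
distributions of any real dataset. Passing tests on synthetic data
therefore demonstrate the correctness and internal consistency of the
estimators and assessments under the stated model, not the field
performance of any algorithm on real chemistry.

## Numerical choices and degenerate inputs

* Flat curves (zero residual variance) are non-converged by definition;
  noisy flat curves may converge to junk fits with very low $R^2$, which
  the quality threshold then filters — mirroring how real estimators
  behave on template-free wells.
* cpD2 is reported unrounded; the grid step (0.01 cycles) plus
  root-refinement give ~$10^{-9}$-cycle reproducibility, which matters for
  the noise-free end-to-end identities below.
* The LOD scan uses suffix medians over candidates equal to observed
  expected values; because a larger tolerance can only be reached at or
  after a smaller one, thresholds are provably non-decreasing in the
  tolerance.
* Features absent from a pool are encoded as `Inf` pure expression (zero
  abundance); `expectedExpression` propagates `NA` (unknown) but treats
  `Inf` (known absent) as a zero contribution, and a both-pools-absent
  mixture is itself `Inf`, i.e. never detected.
* Quality is never missing where expression is present (class invariant);
  failed fits carry quality 0 so that "poor quality" and "missing" are
  distinguishable.

## Verification strategy and problem sizes

The test suite checks, among others: model predictions against directly
restated formulas ($10^{-12}$); analytic second derivatives against central
differences; cpD2 against the logistic closed form and against brute-force
0.001-cycle grid argmaxes for all five families; l4 parameter recovery
within $10^{-4}$ relative on clean curves; and the end-to-end noise-free
identities — fitted threshold cycles within 0.05 cycles of truth, every
signal-detect slope within $10^{-6}$ of 1, every CV exactly 0, and 100%
titration response among titratable features (present in the titrated pool
and evaluable). The noise-free end-to-end checks fit the b4 family, which
matches the generator's symmetric-logistic curves, so deviations measure
numerical error rather than model mismatch. The dropout/LOD property is
checked on the type-9-versus-pure comparison at tolerance 0.75, where the
pure-based expectation is unbiased and expected values straddle the
ceiling; the type-10 comparisons push expectations several cycles past the
ceiling and legitimately diverge earlier.

Routine tests run the generator at 8–40 features (full design: 40 samples
× 46 cycles each) and assessment-level property tests at up to 600
features; the acceptance script additionally runs one full-scale
simulation (754 features, 30,160 curve fits) under the default noise
conditions. These sizes were chosen as the smallest that exercise every
code path with stable statistics.

## Known limitations

* The vendor Crt/AmpScore algorithm is consumed as imported data only
  (`readCqSet`); it is proprietary and never recomputed here.
* l4/l5 cpD2 on the raw-cycle axis may differ slightly from
  implementations differentiating on the log-cycle axis.
* The noise magnitudes are plausible defaults, not calibrated against any
  published dataset; absolute values of simulated summaries (e.g. the
  complete-feature count) depend on them, while the structural identities
  (slopes, CVs, LOD location) do not.
* Binned summaries use equal-count (quantile) bins computed on the data at
  hand; published bin edges from other datasets are not reproduced.
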