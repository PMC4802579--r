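# ampliBench

Benchmarking of qPCR amplification-curve expression estimators.

## What problem this solves

High-throughput qPCR arrays (e.g. microRNA panels) record a
baseline-corrected fluorescence value (ΔRn) at the end of every
amplification cycle. An expression-estimation algorithm turns each curve
into a *threshold cycle* (Cq/Crt) — the fractional cycle at which
amplification is detected — plus a quality score. Competing algorithms
disagree, and their accuracy cannot be judged without data in which the
relative truth is known. `ampliBench` is for method developers and
platform users who want to (1) estimate expression from raw curves with an
open, reproducible algorithm, and (2) score *any* algorithm's output
against a mixture/dilution benchmark design in which relative expression
is known by construction.

The package provides:

* **Curve fitting / estimation** — five model families (`b4`, `l4`, `b5`,
  `l5`, `linexp`; e.g. l4: `f(x) = c + (d−c)/(1+exp(b(ln x − ln e)))`)
  fitted by bounded Levenberg–Marquardt least squares. The expression
  estimate is **cpD2**, the cycle maximizing the second derivative of the
  fitted curve (for a symmetric logistic with midpoint `e` and scale `s`,
  cpD2 = `e − s·ln(2+√3)`); the quality score is the fit R², cut at 0.99.
* **Assessments** — quality diagnostics, two-method expression comparison,
  complete/partial/absent feature counts, limit of detection (suffix-median
  scan at tolerances 0.5/0.75/1.0 cycles), titration response (strict
  monotone decrease of Cq along a doubling series), signal-detect slopes
  (OLS of observed on expected expression; ideal slope 1) and
  within-replicate precision (SD, CV), all against a ten-sample-type
  two-pool mixture/dilution design. Expected mixture expression uses
  abundance-scale mixing: `E = −log2(wA·2^−EA + wB·2^−EB)`.
* **Synthetic benchmark** — a ground-truthed generator of the full design
  (default 754 features × 10 sample types × 4 replicates × 46 cycles) with
  tissue-specific/absent features, replicate noise, outright failures and a
  Poisson single-molecule detection ceiling that produces realistic
  dropout and saturation near the limit of detection.

External algorithms' exports (expression + quality CSV matrices, e.g.
vendor Crt/AmpScore tables) are imported with `readCqSet()` and scored by
the same assessments; the vendor algorithm itself is never recomputed.

## Worked example

```r
library(ampliBench)

tr  <- generateTruth(120, seed = 42)          # per-feature pure-pool truth
sim <- simulateBenchmark(tr, seed = 42)       # full 10x4 design, 46 cycles
sim$dataset
#> AmplificationSet: 120 features x 40 samples, 46 cycles ( 4800 curves )

cq <- estimateExpression(sim$dataset, "l4")   # fit + cpD2 + R^2 quality
cq
#> CqSet [l4]: 120 features x 40 samples; 651 missing estimates; quality threshold 0.99

design <- defaultDesign()
table(classifyFeatures(cq))
#> complete  partial   absent
#>       25       80       15

round(limitOfDetection(cq, design)$thresholds, 2)
#>                   0.5  0.75     1
#> type9_vs_pure   28.92    NA    NA
#> type10_vs_pure  26.82 27.88 27.96
#> type10_vs_type9 26.35 27.68 28.54

print(signalDetectSlopes(cq, design)$bins, digits = 3)
#>            bin  n median    mad
#> 1  [-14,-3.07] 49  2.390 21.162
#> 2 (-3.07,3.07] 48  0.990  0.521
#> 3    (3.07,14] 49  0.975  0.119

titrationResponse(cq, design)$counts
#>   series responders nonResponders
#> 1      A         60            45
#> 2      B         62            43

print(precisionSummary(cq)$bins, digits = 3)
#>           bin   n medianSD medianCV
#> 1   [13.4,18] 324    0.257   0.0161
#> 2   (18,22.2] 324    0.265   0.0133
#> 3 (22.2,30.1] 324    0.375   0.0149
```

Reading the output: 15 of 120 features are absent (never detected with
R² ≥ 0.99), matching the generator's absent-in-both fraction. The limit of
detection sits in the 27–29 cycle range — observed expression diverges from
the dilution-predicted value as features approach the simulated
single-molecule ceiling at cycle 30 (an `NA` means the median divergence
never reaches that tolerance among evaluable features). Signal-detect
slopes are near the ideal 1 when the titrated component is at least as
abundant as the constant one (middle/high bins) and wild when it is far
less abundant (low bin, huge MAD) — exactly the behaviour this stratification
is designed to expose. Median within-replicate CVs of ~1.5% correspond to
the 0.25-cycle replicate noise.

A one-shot pipeline (`simulate → fit → all seven assessments → CSV/JSON
bundle + run log`) is available as `runBenchmark(benchmarkConfig(...))`, or
from a shell via `Rscript scripts/ampliBench.R {simulate|fit|assess|benchmark} …`.

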