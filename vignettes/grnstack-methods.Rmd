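---
title: "Stacked ensemble GRN inference: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble GRN inference: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(grnstack)
```

# The inference problem and the stacking model

A gene regulatory network (GRN) is a directed graph whose edges run from
transcription factors (TFs) to the genes they regulate. Given a genes ×
samples expression matrix, a TF list, and a gold standard of experimentally
validated (or simulated ground-truth) edges, the task is to rank all
candidate TF → gene edges so that true edges concentrate at the top.

`grnstack` is built on one observation: individual inference algorithms
disagree, and which one is best varies by dataset, so their outputs are
best treated as *features*, not verdicts. The pipeline has three stages:

1. **Level 1.** Each method scores every candidate edge in the universe
   (gold-standard regulators × all genes, minus self-edges). Built-in
   representatives of the three main algorithm families are provided:
   absolute Pearson correlation; shrunk partial correlation (precision
   matrix of `R* = (1−s)R + sI`); time-lagged correlation (maximum |r| over
   lags 0..L, pairs never crossing trajectory boundaries); pairwise mutual
   information (plug-in estimate with equal-frequency binning, emitted
   symmetrically to both directions); random-forest importance of TFs for
   each target; and ODE ridge regression of each target's finite-difference
   derivative on TF levels plus the target's own level (the decay term,
   which is never emitted as an edge). Externally produced ranked-edge
   files plug in as additional columns.
2. **Level 2.** A classifier is trained on the candidate edges of the
   *training* TFs, with gold-standard labels under a closed-world
   assumption (unlisted edges among covered regulators are negatives), and
   scores the edges of held-out TFs. Gaussian Naive Bayes is the default;
   voting, logistic regression (plain and SGD), SVM, k-NN, random forest,
   AdaBoost, and gradient-boosted trees are available alternatives.
3. **Evaluation.** AUPRC ratio versus a random predictor over repeated
   TF-disjoint 2:1 splits, with a paired sign-flip resampling test for
   method comparisons and the average-rank "community" aggregation as a
   reference baseline.

The TF-disjoint split mirrors deployment: laboratories validate edges for
particular TFs (over-expression/knockdown assays), and the useful question
is whether edges of *untested* TFs can be predicted. Splitting edges at
random instead would leak per-TF information and overstate performance.

# Why Naive Bayes, and why a kurtosis filter

With only a handful of feature columns and very sparse positive labels
(tens of positives among hundreds or thousands of candidate edges on the
training side), low-variance models are favored. Gaussian Naive Bayes
estimates per class only a mean and a variance per feature plus a prior —
and its strong independence bias is an asset at this sample size.

Its weak point is the Gaussian class-conditional assumption. Methods whose
score distribution is flatter than a Gaussian (negative excess kurtosis
`g₂ = m₄/m₂² − 3`, population-moment form; a uniform distribution has
`g₂ = −1.2`) fit that assumption poorly, so the filter retains only methods
with `g₂ > 0`, computed on the *full* score column — all candidate edges,
never the labels, so no information leaks from the test side. Zero-variance
columns are dropped (kurtosis undefined); if nothing survives, all
non-degenerate columns are retained with a warning rather than failing.

Class priors affect only the scale of the posterior, not the ranking, so
AUPRC is unaffected by the label imbalance; models are therefore fitted on
the natural imbalanced labels by default, with an optional
`class_weight = "balanced"` flag. The Naive Bayes variance floor is
`1e-9 ×` the largest feature variance, guarding against degenerate
zero-variance class conditionals.

# Feature normalization

Level-1 methods emit scores on wildly different scales (correlations in
[0,1], MI in nats, unbounded regression coefficients). Features are
rank-normalized over the full candidate universe — average ranks for ties,
divided by the edge count, giving values in (0, 1] — before level-2
fitting. This makes columns commensurable for distance- and
density-based models and makes every downstream ranking invariant to
strictly monotone transforms of any method's raw scores. The filter,
by contrast, is deliberately computed on the *raw* scores, because the
shape of the raw output distribution is what it screens.

# The simulator

`simulation_config()` + `generate_network()` + `simulate_expression()`
emulate DREAM-style in silico benchmarks: networks where only TFs have
outgoing edges, time-series responses to perturbations, and the exact
ground truth for evaluation.

* **Network.** Each TF's out-degree is Poisson(`mean_out_degree`, default
  3); targets are drawn uniformly without replacement; each edge is an
  activator with probability 0.7 or a repressor with 0.3, with strength
  uniform in [0.5, 2].
* **Kinetics.** `dx_g/dt = α·f_g(x) − λ·x_g`, where `f_g` is the
  strength-weighted mean of Hill terms `h(x_r) = x_rⁿ/(Kⁿ + x_rⁿ)` for
  activators and `1 − h(x_r)` for repressors (`f_g ≡ 1` for unregulated
  genes). Defaults: `α = 1`/min, `λ = 0.02`/min (≈ 50-minute mRNA
  relaxation time), Hill exponent `n = 2`.
* **Half-saturation.** `K` defaults to *half the unregulated steady-state
  level* `0.5·α/λ` (= 25 expression units at the defaults). An absolute
  constant much smaller than the steady state would leave every Hill term
  saturated near 1, so knockdowns would not propagate to targets and the
  data would carry no regulatory signal; tying `K` to the expression scale
  keeps regulators on the responsive part of the curve.
* **Perturbations.** Each trajectory starts at the unperturbed fixed point
  and knocks one randomly chosen TF down to a uniform [0, 0.2] fraction of
  its transcription rate — the in silico analogue of the knockdown
  experiments behind DREAM time series. All knockdown draws are made
  before any noise draws, so noisy and noiseless runs of the same seed
  share the same perturbation schedule.
* **Sampling and noise.** Samples at `t = 0, Δ, 2Δ, … ≤ horizon` (default
  Δ = 50 min, horizon = 1000 min, 10 trajectories), then multiplicative
  lognormal noise with log-scale sd `noise_sd` (default 0.05).
* **Integration.** Fixed-step classical Runge–Kutta 4 with step
  `Δ / max(20, ⌈Δ/0.5⌉)` — at most 0.5 min and always an exact divisor of
  the sampling interval, so sample times fall on step boundaries for any
  positive Δ. The kinetics are smooth and non-stiff at these parameters;
  a non-finite state aborts with the offending gene named. The unperturbed
  fixed point is obtained by relaxing the system for 60 decay
  time-constants.

**What the simulator does and does not show.** It reproduces the
*structure* of the benchmark problem — directed TF-sourced networks,
perturbation time series, calibrated noise, known ground truth — but real
single-cell or bulk RNA-seq data add dropout, batch effects, unmodeled
regulators, post-transcriptional control, and gold standards that are
themselves incomplete. Passing tests on simulated data therefore validate
the machinery and the protocol, not field performance on any particular
organism.

# Evaluation choices

* **AUPRC** is computed in average-precision (step) form: each positive
  contributes the precision at its threshold; tied scores form one
  threshold group whose end-of-group precision is assigned to all its
  positives. This avoids the optimism of trapezoidal interpolation, makes
  a constant predictor score exactly the prevalence, and is pinned in the
  tests by a brute-force threshold-enumeration oracle (agreement to
  1e-12). The **AUPRC ratio** divides by the test side's own prevalence,
  so a random predictor calibrates to ≈ 1 and results are comparable
  across splits with different prevalence.
* **Paired sign-flip test.** Per-split AUPRC gains are paired by split
  seed; the null distribution of the mean difference is generated by
  random sign flips, with the `(1 + k)/(1 + n)` correction making the
  Monte-Carlo p-value conservative (for ≤ 20 pairs an exhaustive
  enumeration of all 2ⁿ patterns is available). The sign-flip construction
  is this package's explicit choice of non-parametric paired resampling
  test and is labeled as such in reports. One-sided by default, because
  the hypothesis of interest is improvement.
* **Degenerate splits.** A split whose test side has no positive edge
  leaves AUPRC undefined; such splits are redrawn with a fresh seed and
  logged, and a benchmark aborts if redraws exceed half the requested
  splits (the gold standard is then too sparse for the protocol).
* **Reference conventions.** "Best level-1 method" is reported both as the
  post-hoc per-split maximum on the test side (optimistic for level 1,
  since it re-selects the winner every split) and as the single method
  with the best mean training-side ratio evaluated on test. The
  average-rank baseline aggregates the retained methods' rank-normalized
  scores by their mean — the classic community method — and the `voting`
  level-2 kind is its thresholded cousin (fraction of methods ranking an
  edge in their global top fraction, default 0.1); both are provided
  because the two interpretations of a "voting ensemble" differ.

# Problem sizes and numerical details

The test suite exercises the full pipeline at desk scale: 50-gene /
10-TF networks with 10 trajectories of 21 time points (490 candidate
edges), 20-split benchmarks, and 100-repetition property checks for the
stochastic claims; the oracle-fixture stacking property uses 60 TFs × 40
targets (2400 edges). These sizes give stable Monte-Carlo estimates for
every property while keeping a full run of the suite in minutes.

Other numerical conventions: partial correlation advises `shrinkage > 0`
when the correlation matrix is singular; constant genes receive
correlation scores of 0 with a warning; per-target tree importances are
normalized to sum to 1 (uniform if identically zero); ridge coefficients
are computed on standardized predictors and reported on the original
scale; rank normalization uses average ranks for ties; `round(ratio · n)`
sets the training-side size of a split, clamped so both sides are
non-empty; ties in hyper-parameter tuning resolve in grid order.

# Known limitations

* The built-in level-1 methods are deliberately simplified family
  representatives, not reimplementations of GENIE3, PPCOR, LEAP, PIDC or
  Inferelator; external tools can contribute through ranked-edge files.
* Level-1 scores are computed once on the full expression matrix; only
  labels are split by TF. Edges of test TFs therefore influence level-1
  score distributions (and the kurtosis filter), which mirrors the
  deployment setting where expression data for all genes is available but
  validated edges exist only for some TFs — it is not out-of-fold
  stacking.
* The simulator's kinetics are deterministic ODEs with lognormal
  measurement noise; no intrinsic (stochastic) transcription noise, no
  separate mRNA/protein layers.
* Pseudotime is consumed as if it were time; the package does not estimate
  it.
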