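---
title: "Models and methods: sample-based probability estimation and set-point decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sampleBDT)
```

## The scientific problem

In many visuo-motor tasks a decision maker never sees the probability
distribution governing outcomes — only a small sample drawn from it. This
package implements, end to end, an analysis pipeline for two such tasks:

1. **Interval estimation.** The observer sees N = 5 or 30 points from an
   anisotropic bivariate Gaussian (vertical variance σ², horizontal variance
   σ²/2, σ² drawn uniformly from [100, 400] mm² each trial) and judges the
   probability that one more draw lands in a marked vertical interval. The
   interval is the symmetric band ±wσ, its upper half, or its lower half,
   with nine widths spanning symmetric probabilities 0.1–0.9. This probes
   *accuracy* (is the estimate the true Gaussian integral?) and *additivity*
   (do the two half-interval estimates sum to the full-interval estimate?).
2. **Set-point decision.** The observer rigidly translates the sample (and
   the invisible pdf underneath) vertically by a set point S. One more point
   is then drawn from the shifted pdf: it earns `y·100/180` points for
   0 < y ≤ 180 mm, the penalty (0 or −500) above 180 mm, and nothing below
   zero. This probes how the sample is *used*: does each sample point get
   the weight an ideal observer would give it?

## Models

### Accuracy: linear-in-log-odds (LLO) distortion

Estimated probabilities are modelled as a linear transformation on the
log-odds scale,
`Lo(p̂) = γ·Lo(p) + (1−γ)·Lo(p₀)`, `Lo(q) = log(q/(1−q))`,
with slope γ and crossover p₀ (the probability mapped to itself). γ < 1
means overestimation below p₀ and underestimation above it.

**Likelihood choice (ours, not given by the source task).** The fitting
noise model is Gaussian on the *logit* of the estimate with constant
variance, fitted as one extra parameter. On this scale the MLE of (γ, p₀)
is ordinary least squares of `logit(estimate)` on `logit(truth)`, which
makes the fit deterministic, convex and exactly recoverable from noiseless
data. Estimates of exactly 0 or 1 are clipped to [0.005, 0.995] — the
response device quantises anyway. The null model (no distortion, γ = 1) is
fitted alongside; models are compared by AICc with evidence ratio
`exp(ΔAICc/2)`. When γ ≈ 1 the crossover is unidentifiable and is reported
as 0.5 by convention.

### Additivity

For triples (p̂\[SU\], p̂\[SL\], p̂\[S\]) the model is
`p̂[SU] + p̂[SL] = p̂[S] + b` with Gaussian residuals. H0 fixes b = 0, H1
constrains b > 0 (super-additive), H2 constrains b < 0. The
sign-constrained MLE of b is the clamped residual mean; AICc ranks the
three hypotheses and ties at b̂ ≈ 0 go to H0 by parsimony.

### The normative set-point model

The ideal observer knows the population mean (it is fixed at the start
position in the task), so the sample enters only through (s², N):

- **Prior**: uniform on σ² ∈ [100, 400] mm² — the generating distribution.
- **Likelihood**: the task's source model describes the likelihood of the
  estimated variance by exchanging the roles of s² and σ̂² in the sampling
  density of s² (a scaled χ² with N−1 df). We implement that "flipped" form
  literally: a gamma-form density in σ̂² with shape (N−1)/2 and scale
  2s²/(N−1), whose mode is s²(N−3)/(N−1). The orthodox likelihood
  (density of s² given σ²) is available via `mode = "orthodox"` for
  sensitivity analysis; after renormalisation over the truncated support
  the two differ only mildly.
- **Posterior**: likelihood × prior on a grid of 601 equally spaced σ̂²
  values with trapezoidal end-weights, renormalised to masses summing to 1.
  The grid is a numerical choice (the source gives none); doubling it moves
  set points by far less than the 0.05 mm refinement tolerance.
- **Expected gain**: `EG(S) = Σ w(σ̂²) ∫ G(y) N(y; S, σ̂²) dy`, with the
  inner integral in closed form via truncated-Gaussian first moments (the
  reward is piecewise linear). The closed form is verified against
  piecewise adaptive quadrature to 1e−6 in the test suite.
- **Optimum**: `S* = argmax EG(S)` by a 1-mm grid on [−20, 280] followed by
  local refinement with `optimize()` (tolerance 1e−4 mm). The landscape is
  unimodal for both penalty levels across the prior support. A batched
  implementation shares the per-σ̂² gain matrix across many s² values (one
  matrix product), which is what makes the Monte-Carlo influence loop and
  the model-recovery suites cheap.

### Influence

*Empirical influence* is the vector of ridge-regression weights of the
sorted sample (order statistics, mm) on the set point, with unpenalised
intercept, centred predictors and response, and no variance scaling (all
predictors share units). The penalty λ is chosen by 10-fold
cross-validation with the one-standard-error rule over 60 log-spaced values
on [1e−2, 1e5]; grid, centring and fold seeding are our choices — the
source reports none.

*Normative influence* is the Monte-Carlo average of the change in S* per mm
change of the i-th order statistic, over freshly drawn populations and
samples. **Differencing choice.** We change each point by 1 mm *in total*
but split it symmetrically (±0.5 mm). The one-sided alternative (+1 mm)
carries a first-order bias: s² is quadratic in each coordinate, so the
one-sided perturbations inflate variance by δ²/N on average and the
influence profile then sums to `dS*/ds²·δ ≈ −0.02` instead of zero,
breaking the zero-sum and skew-symmetry properties the normative model
provably has (a uniform shift of the sample leaves s², hence S*,
unchanged). The central scheme cancels the bias; `difference = "forward"`
reproduces the literal one-sided scheme and the test suite demonstrates
its bias. Perturbations are attributed to the original order index even if
1 mm would swap adjacent order statistics (swaps are rare and second-order).

*Influence ratios* divide empirical by normative weights; entries whose
normative influence is below 5% of the profile's maximum magnitude are
masked as unreliable (the exact masking rule in the source is unstated;
5%-of-max is our choice and is exposed as a parameter).

### The Max-Point heuristic and model comparison

The heuristic sets `S = B − P_MAX`: the sample's highest point is placed at
an internal reference boundary B, one B per penalty condition, shared
across sample sizes. The least-squares/Gaussian-MLE boundary is
`B̂ = mean(S + P_MAX)`. For model comparison both models produce per-trial
predictions; residuals are Gaussian with one MLE noise parameter per
condition (penalty × N). This residual convention is the largest assumption
in the comparison — the source states AICc values but not the residual
model — and it is applied identically to both models, so the AICc
difference is insensitive to how the shared noise parameters are counted.
K = #conditions for the normative model (no structural free parameters) and
#penalty levels + #conditions for Max-Point.

*Efficiency* is realized total score divided by the total expected score of
the normative model at its optimal set points, given the same samples.

### Cost scenarios

Two classic stimuli quantify what the measured estimation failures would
cost:

- **Disc scenario**: reward and penalty discs of radius 8.97 mm, centres
  1.5 radii apart (read as centre-to-centre; the overlap scores 0),
  endpoint SD 3.89 mm. Disc hit probabilities are exact (noncentral χ²);
  the lens-shaped overlap is adaptive quadrature; the aim-point search runs
  along the inter-centre axis (sufficient by symmetry). Note that with
  overlapping discs the optimum is *not* at the reward centre even when the
  penalty is 0, because the overlap scores 0 rather than +100.
  With the fitted LLO distortion (γ = 0.88, p₀ = 0.76) the *distorted*
  expected gain `100·w(P[green-only]) − 100·w(P[red-only])` drops from
  87.26 to 85.60 (−1.9%), while the objective gain at the shifted aim is
  essentially unchanged (87.23): misestimating probabilities costs the
  observer's expectations, not their realized performance.
- **Double-bar scenario**: bars of width 1.5 × 3.05 mm separated by 0.75 of
  the width, endpoint SD 3.05 mm, aim at the gap midpoint; closed-form CDF
  differences give the double-target probability 0.535, the matched single
  width 4.453 mm, and — given the super-additivity-inflated double estimate
  0.597, which we treat as an input because its derivation from the fitted
  b is not specified by the source — the indifference-restoring width
  5.101 mm (+14.6%).

## The synthetic-data generators

Generators emulate the two sessions exactly as stated: 270 estimation
trials (2 × 3 × 9 × 5) and 200 decision trials (2 × 2 × 50), population
variance uniform on [100, 400] mm², horizontal variance σ²/2. Artificial
observers: the LLO estimator (optionally super-additive: each half-interval
estimate inflated by b/2), the counting estimator (fraction of sample
points inside the interval — estimates are multiples of 1/N), the normative
BDT observer, the Max-Point observer, a mean-tracker and a constant
responder. Response noise is additive Gaussian — on the logit for
estimation (default sd 0.2 logits) and on the set point for decisions
(default sd 5 mm); the source models no response noise explicitly, and
these defaults are chosen once to be comparable to the inter-trial scatter
a human observer shows. Everything is deterministic given (seed, config,
agent); the pipeline derives per-stage seeds from a master seed by hashing
the stage name.

What a green test does *not* establish: the generators contain no learning
across trials, no kinematics or reaction times, no sequential effects, and
Gaussian response noise by construction — so recovery results certify the
estimators, not the realism of human noise.

## Numerical choices and degenerate inputs

- Probabilities entering a logit are clipped to [0.005, 0.995].
- `fit_llo` needs ≥ 3 distinct true probabilities and errors on constant
  estimates; a non-positive OLS slope is pinned just above zero.
- Region unions declared disjoint are validated numerically (cross-section
  overlap on a 201-point grid) and refuse overlapping constituents.
- Quadrature tolerances: 1e−7 absolute for region probabilities, 1e−10 for
  the disc-overlap integral.
- The optimal-aim search uses `optimize()` on the symmetry axis with 1e−4 mm
  tolerance.
- Zero-width intervals, empty regions, σ → 0 double bars, and prior
  supports shrunk toward zero variance all take well-defined limits and are
  covered by tests.

## Scaled-down test sizes

The packaged test suite reduces some Monte-Carlo sizes to keep a full run
within a CI budget: normative-influence properties run at 400 simulations
(the headline analyses use 1000), model recovery at 40 replicates per
generating agent, and parameter recovery at 60 replicates. The assertions
are unchanged; the seeds are fixed; none of the generator parameters,
thresholds or tolerances were adjusted after seeing test outcomes.

## Known limitations

- The flipped-likelihood form is implemented for fidelity; it is not the
  orthodox inverse-gamma posterior for a Gaussian variance.
- The comparison of AICc values across packages depends on the Gaussian
  residual convention described above.
- The influence regression assumes a shared N within a condition and does
  not model heteroskedastic response noise.
- Human-data quantities (per-participant fits, the 82.7% efficiency, the
  fitted boundaries 179.0/168.7 mm) require the behavioural dataset and are
  covered only by parameter-recovery analogues on synthetic observers.
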