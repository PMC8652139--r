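---
title: "Methods: signature T-scores, the three-node path model, and the elimination bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature T-scores, the three-node path model, and the elimination bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbsem)
```

## The problem

A regulator's perturbation experiment in a model system yields a directional
gene signature: the downstream targets whose expression rises or falls with
the regulator's activity. In a human cohort where the regulator cannot be
perturbed, that signature can still act as an in-silico reporter: a specimen
in which the up-regulated arm sits high and the down-regulated arm sits low
behaves as if the regulator were active. `perturbsem` quantifies this with a
per-sample T-score, relates two such activities to a downstream reporter
with a three-node path model, and asks which parts of a signature carry the
signal with an elimination bootstrap.

## Preprocessing

Expression input is a normalized genes-by-samples matrix; normalization
itself (RMA, TPM, quantile, ...) is upstream of this package. Two steps
prepare it:

* **Probe collapse.** When several probes measure one gene, the probe with
  the highest sample standard deviation (denominator n − 1) represents the
  gene. Ties are broken by the lexicographically first probe id so results
  are deterministic. Collapse happens *before* median centering so that the
  centering describes the gene-level values actually tested; the opposite
  order would center rows that are later discarded.
* **Median centering.** Each gene's values are centered to the row median
  (even sample counts use the mean of the two middle order statistics, the
  standard convention). Centering makes the two signature arms comparable
  within a single sample column and absorbs per-gene baseline differences;
  consequently a T-score measures activity *relative to the cohort median
  sample*, not on an absolute scale.

Signatures cross species through an ortholog table (many-to-many allowed).
A homolog reachable from both the up and the down arm is a direction
conflict; it is excluded from both arms rather than raising an error,
because many-to-many maps make such collisions routine. Symbols match
case-sensitively after whitespace trimming by default; `fold_case = TRUE`
covers mouse-to-human symbol case conventions. Genes lost in mapping or
absent from the matrix are counted and reported, not silently ignored.

## The T-score

For one sample, with centered values of the up-arm and down-arm homolog
sets, the score is `d * TINV(p, df)`: `p` the two-tailed equal-variance
pooled two-sample t-test p-value, `df = n_up + n_down - 2`, `d` the sign of
the arm-mean difference. This equals the signed pooled *t* statistic
exactly, and the test suite checks the identity to 1e-10 on random inputs.
Conventions worth noting:

* The pooled (Student) test is used, never Welch — the score is defined
  through the equal-variance test.
* At an exact arm-mean tie the statistic is 0 regardless of `d`;
  `classify_activity()` calls a sample active only for scores strictly
  greater than 0, so a tie is inactive.
* Each direction needs at least 2 genes and the pooled variance must be
  positive; degenerate inputs raise errors rather than returning infinities.
* Raw per-sample p-values are reported alongside; no multiple-testing
  correction is applied, since the scores are typically consumed as a
  continuous activity variable rather than as per-sample hypothesis tests.

## The three-node path model

The model is `endpoint = γ11·fac1 + γ21·fac2 + ζ` with freely correlated
exogenous regulators and residual ζ independent of both. Fitting is
covariance-only maximum likelihood: minimise
`F = log|Σ(θ)| + tr(S Σ(θ)⁻¹) − log|S| − 3` with S the sample covariance
(divisor n − 1), and report `T = (n − 1)·F_min`. No mean structure is
modelled — the three-node question concerns relationships, not intercepts.
The Wishart n − 1 convention is stated here explicitly so external
cross-checks can rescale if they use n.

Either path and the exogenous covariance can be fixed to 0. For every such
specification the joint-normal likelihood factorises into the marginal
exogenous block and the conditional regression of the endpoint on the
*free* regressors, so the exact ML solution is available in closed form:
the exogenous block is `S_xx` (diagonalised when the covariance is fixed),
the free paths are the regression coefficients of the endpoint on the free
regressors computed from S, and the residual variance is the corresponding
residual moment. The implementation therefore uses no iterative optimizer;
a test cross-checks the closed form against direct numerical minimisation
of F. Standard errors come from the inverse expected information
`I_jk = (n−1)/2 · tr(Σ⁻¹ ∂Σ/∂θj Σ⁻¹ ∂Σ/∂θk)` with analytic derivative
matrices, and coefficient p-values are two-sided Wald normal — standard SEM
practice.

Fit indices follow their usual definitions; the deliberate choices are:

* RMSEA `= sqrt(max(T − df, 0)/(df (n−1)))`, 0 for a saturated model. Its
  90% interval inverts the noncentral chi-square CDF in the noncentrality
  parameter by bisection (absolute tolerance 1e-8, truncated at 0); df = 0
  yields (0, 0).
* CFI truncates at [0, 1] through `max` terms against the independence
  baseline (diagonal Σ, df = 3).
* TLI is reported as 1 at df = 0, where the ratio form is undefined but
  "perfect fit" is the right semantics.
* SRMR averages the squared standardized residuals over all 6 unique
  elements of `S − Σ̂` including the diagonal — one of several published
  variants, fixed and documented here so it is testable.
* The saturated model reproduces S analytically, so its T is set to exactly
  0 rather than evaluating F and reporting float noise.

The model's γ coefficients are unstandardized path coefficients
(endpoint units per regressor unit); because they are sometimes discussed
on a correlation scale, `tidy()` also reports fully standardized estimates.
A saturated three-node model has df = 0 and trivially perfect global
indices, so scientific conclusions should rest on the coefficient tests;
global indices become informative only for constrained specifications.
Degenerate inputs (n < 4, singular S, all paths fixed) are rejected with
explicit errors.

## The elimination bootstrap

The question: does a designated subset of signature genes (for instance the
signature of a downstream effector) matter to a path-model quantity? The
observed statistic removes exactly that subset, recomputes T-scores and
refits the saturated model. Null replicates are generated per mode:

* *without replacement*: remove an equally sized random subset of the
  non-target signature genes;
* *with replacement*: remove the target subset and refill to the original
  size with uniform draws (no repetition) from the background pool minus
  the current signature, each refill inheriting the direction of the
  removed gene it replaces, matched by removal order.

The empirical p-value is `max(count, 1)/B` with `count` the number of
replicates at least as extreme as the observed value under the chosen tail,
flooring at `1/B`. The default statistic is the perturbed regulator's own
path coefficient with a two-sided tail; the tested quantity is genuinely a
user choice (chi-square or any fit index can be selected), and defaulting
to γ11 makes the test directly about the modelled relation. A master seed
spawns one substream per replicate index, so results are reproducible and
independent of execution order. Replicates whose model fit fails are
excluded from the p-value denominator; more than 5% failures aborts the run.
The two modes are reported separately; combining them into a single test is
out of scope.

## What the synthetic generators emulate

`simulate_expression()` draws standard-normal per-sample activities and
shifts up-arm genes by `+effect_size · activity` and down-arm genes by the
negative, on Gaussian noise with SD `noise_sd`; with unit-variance
activities, `effect_size/noise_sd` is the single signal-to-noise knob.
`simulate_sem_dataset()` draws the regulators bivariate normal with unit
variances and the requested correlation, and builds the endpoint from the
path equation. `make_chained_truth()` chains the two so the embedded
signatures' latent activities are the path model's regressors and a
reporter row equals the endpoint vector, exercising the whole workflow
against known truth.

Gaussian noise everywhere matches the normality assumptions of both the
pooled t-test and ML covariance fitting. The generators deliberately do
*not* emulate microarray platform artifacts, batch effects, count-based
RNA-seq noise, correlated background genes, or partially overlapping
signatures. Passing tests therefore demonstrate correctness of the
statistical machinery under its own assumptions — not robustness of the
method on real cohort data.

## Test and calibration conditions

Problem sizes in the test suite are chosen to make sampling distributions
well behaved at desk scale: parameter recovery uses 200 replicates of
n = 500; the constrained-model close-fit check uses 25 replicates of
n = 500; the chi-square(1) calibration of a correctly specified constrained
model uses 500 replicates of n = 200; the bootstrap p-value floor check
runs B = 1,000 on a 50-gene signature whose 10-gene informative core is the
eliminated target.

The bootstrap null calibration (uniform p-values when the target is itself
a random draw) runs 200 experiments at B = 199 on a 634-gene signature with
a 30-gene target — the scale of a realistic direct signature. The scale
matters: because null replicates avoid the target genes, every replicate
keeps the full target subset and replicates are slightly more correlated
with each other than with the observed statistic. For small signatures
(tens of genes) with a large target fraction this biases the observed rank
and the empirical p-value becomes visibly non-uniform; at realistic
signature sizes the effect is negligible. Users applying the bootstrap to
very small signatures should interpret borderline p-values with this
finite-size artifact in mind.

## Known limitations

* The model is fixed at three observed variables; latent measurement
  models, more nodes, and multi-group fits are out of scope.
* T-scores inherit the signature's quality: contaminated or direction-mixed
  signatures dilute the score, and the method offers no internal check of
  signature validity beyond the drop/conflict counts.
* The equal-variance t-test and ML normal theory are assumed, not tested,
  per sample; heavy-tailed expression data will distort both the scores'
  p-values and the SEM chi-square.
* Empirical p-values are resolution-limited at 1/B; claims below 0.001
  need more than 1,000 iterations.
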