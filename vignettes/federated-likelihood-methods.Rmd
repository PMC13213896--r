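---
title: "Federated likelihood inference: model, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federated likelihood inference: model, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedlik)
```

## The problem

Health jurisdictions often cannot share patient-level records, yet the
scientific question -- here, the association between hypertension and
incident chronic kidney disease among adults with diabetes -- is about a
parameter assumed common across jurisdictions. `fedlik` implements a
federated estimation protocol in which sites exchange only aggregate
artifacts, plus the standard comparator (common-effect meta-analysis)
and the accuracy metric used to judge both against the pooled-data
benchmark.

The model at every site is the same logistic regression

$$\mathrm{logit}\,\Pr(Y_i = 1) = \beta_0 + \beta_1\,\mathrm{exposure}_i +
\beta_2\,\mathrm{sex}_i + \beta_3\,\mathrm{age}_i,$$

with log-likelihood $\ell(\beta) = \sum_i [y_i\eta_i -
\log(1+e^{\eta_i})]$, $\eta_i = x_i^\top\beta$. Because sites hold
independent records, the network-wide log-likelihood at any $\beta$ is
the *sum* of the site log-likelihoods at that same $\beta$. The protocol
exploits exactly this additivity:

1. **Round 1.** Each site fits its local model by IRLS and shares only
   estimates, standard errors and 95% Wald intervals. For each
   parameter the coordinator takes the most conservative bounds -- the
   smallest lower and largest upper endpoint across the site intervals
   -- and segments the range at a uniform increment, producing one axis
   per parameter. The Cartesian product of the axes is the shared
   lattice; no value any site considers plausible is excluded.
2. **Round 2.** Each site evaluates $\ell(\beta)$ at every lattice cell
   and shares the resulting tensor. The coordinator sums the tensors
   cellwise and takes the argmax as the federated estimate; the region
   where the relative likelihood exceeds 14.7% of the maximum yields
   per-parameter likelihood intervals by projection.

No step transmits anything finer-grained than likelihood values at
pre-agreed parameter points.

## Assumptions, enforced as validation

The protocol's validity rests on assumptions the package enforces
rather than documents away:

* **Identical model structure.** `build_grid_spec()` refuses fits whose
  parameter sets differ; `combine_tensors()` refuses tensors whose grid
  fingerprints differ. Alignment is checked by fingerprint (a SHA-256
  digest of axis names, full-precision bounds and increment), never by
  float-comparing axis vectors.
* **No overlapping records.** Duplicate site ids are rejected when
  combining: summing a site twice double-counts its likelihood.
* **Complete cases, binary 0/1 outcome.** `fit_local()` and
  `evaluate_tensor()` error on missing values or non-binary outcomes.
* **A common effect.** Not checkable from one dataset; the
  meta-analysis side (Cochran's Q, I-squared) is the diagnostic. The
  bundled case-study estimates themselves show I-squared = 80% for the
  exposure, a caution the package reproduces rather than hides.

## Numerical choices

* **Likelihood evaluation.** The softplus term is computed piecewise as
  $\max(\eta,0) + \log(1+e^{-|\eta|})$, finite for $|\eta|$ up to
  around 700. Records are summed in dataset order; tensor chunks
  partition cells, never observations, so results are bitwise
  independent of the chunk size (a tested contract).
* **Axes by integer indexing.** Axis values are
  $\mathrm{lower} + k\cdot\mathrm{increment}$, generated from the
  exact, unrounded lower anchor -- never by repeated addition -- so
  lattices are bit-reproducible across platforms. When the range is
  not an increment multiple the axis stops at the last value at or
  below the upper bound (1e-9 slack): undershooting keeps all values
  inside the declared plausible range. Ranges narrower than one
  increment give a single-value axis, which is legitimate: a very
  precisely estimated parameter (age here) can resolve to one lattice
  value and a degenerate likelihood interval.
* **Local fits.** IRLS via `stats::glm.fit` with a relative-deviance
  tolerance of 1e-8 and at most 50 iterations -- deterministic and
  standard for this model class. Standard errors come from the inverse
  observed information (equal to the expected information under the
  logit link). Wald intervals use the exact normal quantile
  (1.959964..., not 1.96). Separation is detected through
  non-convergence, divergent coefficients, or a singular information
  matrix, and reported as an explicit error; likewise a single-class
  outcome, which in the case study forced the exclusion of an entire
  jurisdiction.
* **Ties and thresholds.** The argmax tie-break is the lowest row-major
  cell index (last axis fastest). The 14.7% relative-likelihood cutoff
  is used literally as published and is configurable; the analytically
  calibrated value $\exp(-\chi^2_{1,0.95}/2) = 0.1465$ differs by less
  than 0.001. Likelihood intervals are projections of the joint region
  onto each axis (the published description derives them "from the
  region"); for unimodal surfaces this coincides with profile
  intervals, which are not separately implemented.
* **Memory.** A tensor of $c$ cells costs $8c$ bytes; evaluation
  refuses lattices above a 2 GiB default ceiling with advice to coarsen
  the increment or narrow the bounds. The case study's finest grid
  (~61M cells) fits; its runtime there was reported in hours per
  region, which is why the demonstration configurations below are
  smaller.

## The synthetic-data generator

Real multi-jurisdiction records are not shippable, so the package
generates networks with the case study's published structure: five
sites of 1,700 / 8,002 / 6,089 / 23,946 / 2,604 patients; site-specific
exposure prevalences 0.59, 0.62, 0.52, 0.44, 0.67; male proportions
0.51--0.55; ages truncated-normal per site (means 62.7--64.7, SDs
~12.1--12.6) on 18--104 years, rounded to whole years since ages in
the emulated registry are visit year minus birth year. Outcomes are
Bernoulli under the logistic model with the published global
coefficients (-7.046, 0.2542, -0.0737, 0.077) as the default truth,
which yields an overall outcome prevalence near 15% (Monte-Carlo value
~0.143). Sex is coded male = 1; the source tables do not state the
reference level, so this is a package convention.

Covariates are drawn independently within site: the published tables
give marginals only, no joint distribution, so no hypertension-age
correlation is modelled. Each site draws from a substream seeded by a
hash of (master seed, site id), making site data invariant to site
order and to the addition of other sites. `heterogeneous_network()`
varies only the exposure coefficient by site, emulating the published
regional spread (0.566 down to 0.163) to exercise the common-effect
diagnostics.

What passing tests on these networks show: correct arithmetic,
additivity, discretisation behaviour, and calibration of the
heterogeneity statistics under a known truth. What they cannot show:
robustness to covariate dependence, informative missingness,
measurement differences between registries, or model misspecification
-- none of which the generator emulates.

## Scaled-down benchmark design

The published full-scale experiment (42,341 records, lattices of 4.4M
and 61M cells) demonstrated that the combined-tensor argmax tracks the
pooled-data MLE to within about one lattice increment, with a maximum
log-likelihood gap under one unit. The package's tests reproduce this
*pattern* at a tenth of the site sizes, where a subtlety appears:
confidence intervals widen by $\sqrt{10}$, so the round-1
conservative-bounds lattice at increment 0.01 would have ~5e8 cells.
Two configurations are therefore used:

* The full two-round protocol (CI-union bounds) runs end to end on a
  five-site network of 400 patients each at increment 0.05, where the
  lattice stays below ~4e5 cells.
* The tenth-scale benchmark (sizes / 10, true coefficients = the
  published global model) uses a demonstration lattice centred on the
  pooled-fit estimates with per-axis half-width $\max(SE, 2 \times
  0.04)$, evaluated at increments 0.04, 0.02 and 0.01. Sharing one set
  of bounds makes the three lattices nested, so the grid maximum is
  monotone in refinement and the axis error shrinks with the
  increment, the mechanism behind the published accuracy improvement
  from the 0.01 to the 0.005 grid. The floor $2 \times 0.04$ keeps the
  age axis -- whose information dwarfs the others -- resolvable at the
  coarsest spacing.

Benchmark problem sizes (tenth-scale network, ~4e5 cells at 0.01; 100
replicates for the heterogeneity study; 200 for the pooling-bias study)
were chosen so the whole suite runs in minutes on a single CPU.

## The comparator and the accuracy metric

Common-effect inverse-variance pooling is implemented directly ($w_i =
1/SE_i^2$; pooled $= \sum w_i\theta_i / \sum w_i$; $SE = 1/\sqrt{\sum
w_i}$), with Cochran's $Q = \sum w_i(\theta_i - \bar\theta)^2$,
chi-square p-value on $k-1$ degrees of freedom, and $I^2 = \max(0,
(Q-(k-1))/Q)$ -- the clamp at zero follows the standard definition.
Random-effects models are deliberately out of scope. The test suite
cross-checks the implementation against an independent meta-analysis
package.

Accuracy against the pooled-data benchmark is the relative percent
absolute bias, $\mathrm{RPAB} = 100\,|\hat\theta_{\text{pooled}} -
\hat\theta_{\text{global}}| / |\hat\theta_{\text{global}}|$. The
denominator takes the absolute value: the published definition divides
by "the global estimate", which is sign-ambiguous for negative
coefficients; for the positive exposure coefficient the two readings
coincide.

One bundled value deserves a flag: the published common-effect
intercept (-7.0131) is not reproducible by inverse-variance pooling of
the published regional rows (which give about -7.0447) and is not
centred in its own printed interval; the fixture carries it verbatim
with a note, and arithmetic checks use the exposure and age rows.

## Known limitations

* Grid search scales exponentially in the parameter count; the method
  as implemented is practical for a handful of coefficients.
* Likelihood intervals inherit the lattice resolution: endpoints move
  in increment steps, and near-degenerate axes produce degenerate
  intervals.
* The common-effect assumption is diagnosed, not relaxed; heterogeneous
  networks need mixed- or random-effects extensions outside this
  package's scope.
* The protocol is realised as file exchange between directories; no
  transport security or multi-host execution is provided.
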