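---
title: "Estimating risk perception from certainty equivalents: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating risk perception from certainty equivalents: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The decision problem

cptrisk models how healthcare managers — in the motivating application,
administrators of long-term care facilities deciding on infection
prevention and control (IPC) spending — evaluate binary loss prospects.
A scenario offers a loss of $X$ dollars with probability $p$ and
nothing otherwise; the respondent states the sure investment they
consider equivalent to facing that prospect, the certainty equivalent
(CE). Under cumulative prospect theory the stated CE satisfies

$$v(CE) = w(p)\,v(-X) + (1 - w(p))\,v(0),$$

with a power value function on losses and the one-parameter inverse-S
weighting function

$$v(x) = -\lambda(-x)^\alpha \;(x \le 0), \qquad
  w(p) = \frac{p^\beta}{\left(p^\beta + (1-p)^\beta\right)^{1/\beta}}.$$

$\alpha$ governs curvature of the valuation of losses ($\alpha > 1$:
risk aversion for the sizes on offer), $\beta$ governs probability
distortion ($\beta < 1$: small probabilities overweighted, large ones
underweighted), and $\lambda$ scales losses. Because both sides of the
CE identity scale with $\lambda$, the noiseless CE solution
$CE = w(p)^{1/\alpha} X$ does not involve $\lambda$ at all — a fact
that shapes the estimation design below.

The package covers the full pipeline: the two decision-task grids as a
validated data model (`default_tasks`, `read_observations`), the CPT
mathematics (`cpt_value`, `cpt_weight`, `ce_predict`), a synthetic
cohort generator (`simulate_cohort`), a pooled Bayesian fit
(`fit_cpt`), a hierarchical covariate model (`fit_hierarchical`,
`two_stage_fit`), and reporting drivers.

# The observation model and its likelihood

Elicited CEs are noisy. The observation model places Gaussian error on
the *value* scale: for respondent $i$ and scenario $(j, k)$,

$$v(CE_{ijk}) = w(p_j)\,v(-X_k) + \epsilon_{ijk}, \qquad
  \epsilon_{ijk} \sim N(0, \sigma_\epsilon^2).$$

All money is first divided by the task's `money_scale` (default
100,000 USD). Some normalization is required for a power value
function — the error variance and $\lambda$ are only interpretable
relative to it — and $\alpha$ and $\beta$ are invariant to the choice.
$\lambda$ and $\sigma_\epsilon$ are not, and are always reported on
the normalized scale with the scale echoed in the output.

Writing the residual in normalized units shows the identification
structure: with $c = CE/s$ and $x = X/s$,

$$v(CE) - w(p)v(-X) = -\lambda\left(c^\alpha - w(p)\,x^\alpha\right),$$

so the likelihood depends on $(\alpha, \beta)$ and the *ratio*
$\tau = \sigma_\epsilon / \lambda$ only. $\lambda$ is not identified
by CE data from pure-loss prospects; its posterior is its prior up to
a mild, sample-size-independent tilt from marginalizing over the
$(\lambda, \sigma_\epsilon)$ ridge. The package makes this explicit
rather than hiding it: the sampler is parameterized in
$(\log\lambda, \log\alpha, \beta, \log\tau)$, where $\log\lambda$
moves freely along the ridge, and the test suite asserts that the
$\lambda$ posterior stays broad and data-independent while $\alpha$
and $\beta$ sharpen with sample size.

# Sampler, priors, and diagnostics

`fit_cpt` runs adaptive random-walk Metropolis within Gibbs on the
four transformed coordinates. Proposal scales adapt toward roughly
44% acceptance during burn-in and are frozen afterwards, so the
retained chain is a fixed Markov kernel. The chain starts from a
least-squares fit of the CE identity; the least-squares objective has
a secondary basin (small $\alpha$ traded against large $\beta$), so
the starting point is chosen by a coarse grid scan before local
refinement. The same scan protects the per-respondent stage-1 fits in
`two_stage_fit`.

Priors are weakly informative and centered near 1:
$\lambda \sim \mathrm{LogNormal}(0, 0.5)$,
$\alpha \sim \mathrm{LogNormal}(0, 0.5)$,
$\beta \sim \mathrm{Uniform}(0.3, 2)$, and
$\sigma_\epsilon \sim \mathrm{HalfNormal}(0.5)$ on the normalized
value scale.

The $\beta$ support deserves a note: the one-parameter weighting
function loses monotonicity for $\beta$ below about 0.28. The default
support $[0.3, 2]$ excludes the non-monotone region, and any
reconfigured support is checked numerically (on a $10^{-3}$
probability grid) at construction, so a non-monotone configuration is
rejected before any sampling happens.

The reference iteration budget is 320,000 draws with 6,000 burn-in
(the `mcmc_config` default). All fits in the test and acceptance
suites use the desk-scale budget of 20,000 draws with 2,000 burn-in,
which the recovery results show is ample for this posterior: with
8,175 observations the $(\alpha, \beta)$ posterior is extremely sharp
and mixes within a few hundred iterations. Both budgets are recorded
in the output metadata.

Diagnostics per parameter: split-chain $\hat R$ (threshold 1.05),
Geweke z between the first 10% and last 50% of the retained chain
(threshold $\pm 3$, with batch-means standard errors), Monte Carlo
standard error by batch means with $\lfloor\sqrt n\rfloor$ batches,
and the posterior mass within 2% of a $\beta$ support edge (flagged
above 25%). Failures warn and are recorded in the result; they never
abort, because a flagged fit is information.

Degenerate data deserve honest behavior rather than a forced answer.
Two cases are characterized in the tests: data generated at the
$\beta$ support edge pile posterior mass against the edge and raise
the boundary flag; and pathological response patterns that no
weighting curve can produce (e.g. paying the full loss in every
scenario) are absorbed into the noise scale — the fitted
$\sigma_\epsilon/\lambda$ blows up by orders of magnitude relative to
elicitation-scale noise, which is the diagnostic signal to look for.

# The covariate model

Per-respondent curvatures are linked to six coded factors — gender,
job title, funding status, facility type, scale, and strategy type —
by

$$\alpha_i = \gamma_0 + \textstyle\sum_m \gamma_m \theta_{im} + \eta_i,
\qquad
\beta_i = \xi_0 + \textstyle\sum_m \xi_m \theta_{im} + \zeta_i,$$

with Gaussian residuals. The factors enter as numeric codes (1/2/3),
one slope each, not dummy-expanded: the coefficient table this
reproduces reports exactly one coefficient per factor, which is only
consistent with numeric coding. A recoding test verifies the affine
contract (shifting a binary code moves the intercept, never the
slope).

The primary route, `fit_hierarchical`, samples everything jointly:
vectorized random-walk updates for the 2×327 respondent curvatures,
conjugate Gibbs draws for the coefficient vectors (flat priors) and
residual variances (vague inverse-gamma, $a_0 = b_0 = 0.01$), and the
same ridge treatment for the global $\lambda$ and noise. The default
budget is 12,000 iterations with 4,000 burn-in; the residual-SD
chains start from two-stage estimates whose stage-1 measurement error
inflates them slightly, and the longer burn-in lets them settle
before retention (the Geweke diagnostic was the arbiter here).
Respondent curvatures are constrained to their supports
($\alpha_i > 0.05$, $\beta_i \in [0.3, 2]$); respondents whose
posterior sits against an edge are flagged in the output.

The cross-check route, `two_stage_fit`, estimates each respondent by
nonlinear least squares on the CE scale and regresses the estimates
on the codes by OLS — the classical "estimate then regress"
construction, with classical standard errors. The two routes agree
within their uncertainty on well-behaved fixtures (a tested
property), but they are not the same estimator: stage 1 weights
residuals on the CE scale while the likelihood weights them on the
value scale, and with per-respondent noise the difference is visible.
Significance flags mirror the reported convention: `*` when the 90%
central interval excludes zero (classical route: $p < 0.1$), `**` for
the 99% interval ($p < 0.01$). Both tasks are pooled by default; a
`task_offset` option adds additive task-2 offsets to both curvatures
when systematic task differences are of interest.

# The synthetic cohort generator

No survey microdata are deposited, so every downstream stage is
validated against synthetic cohorts whose generating values are the
published estimates. The generator is first-class, tested code, and
its defaults are the study conditions — they are not tuning knobs.

`generate_profiles` reproduces the surveyed composition exactly at
n = 327: gender 204/123, job title 102/225, funding 61/266, facility
type 61/102/164, scale 82/164/81, and strategy 82/143/102 (the
published 25% / 43.8% / 31.2% shares). Factors are assigned by
independent seeded permutation, so marginals are exact and the joint
distribution is exchangeable — real cohorts correlate their factors
(large facilities are more often public, say), which is one of the
documented gaps between fixture and reality.

`generate_ce` draws the noisy value
$v^* = w(p)v(-X) + \epsilon$ and restricts it to the physical range
$[v(-X), 0]$ by truncated-normal sampling, then maps back through
$v^{-1}$. Truncation (rather than clipping) keeps CEs strictly
positive without a point mass at zero, at the cost of a small mean
shift in cells where $|w(p)v(-X)|$ is comparable to
$\sigma_\epsilon$ — the Task-1 cell (p = 0.01, X = 10,000) is the
extreme case. The shift is measured against the analytic
truncated-normal mean in the tests, and the recovery results bound
its practical effect (posterior means land within ~0.4% of the
generating $\alpha, \beta$). The average truncated probability mass
is reported in the simulation manifest.

Per-respondent curvatures from the coefficient presets are clamped to
their supports, with clamping counted and reported; under the
published coefficient preset the clamp rate is ~3%, and a test guards
that it stays below 10%. When menu discretization is enabled, CEs
snap to the nearest offered amount *not exceeding the scenario loss*
(so discretized data still satisfy $0 < CE \le X$), with ties broken
toward the smaller investment. The elicitation menus are coarse —
five amounts per task — so discretized responses carry far less
information than continuous ones; the recovery presets default to
continuous CEs, which matches reading the elicited investment as a
point on a continuous scale.

Four presets bundle the study conditions: `table2_task1` and
`table2_task2` (homogeneous cohorts at the published pooled
estimates, value noise 0.01), `table3` (heterogeneous cohort at the
published coefficient rows, residual SDs 0.1 and 0.05), and `null`
(all slopes zero, for calibration). The residual SDs are the
package's choice — the source reports none — selected once so that
coefficient effects of the published magnitude are recoverable at
n = 327, and validated in the recovery suite. The two preset families
are deliberately inconsistent with each other: the published
coefficient rows imply a cohort-mean curvature near 0.58 while the
pooled estimates sit near 1.2–1.4, and the package treats them as
separate fixtures rather than reconciling them.

# Decision-task grids

Task 1 uses entrance probabilities {1%, 3%, 10%, 30%, 90%} against
losses of USD 10,000–130,000 with an investment menu of USD
1,000–100,000. Task 2's published description fixes only the
probability range (0.1% to 9%) and the losses (USD 0.2M–1.4M, menu
USD 10,000–1M); the package adopts {0.1%, 0.3%, 1%, 3%, 9%} — Task
1's ×3 ladder scaled by one tenth — as the default grid. The grid is
configurable through `decision_task`, and every output manifest
records the grid actually used. Observation files are validated
row-by-row against their grid (off-grid cells, unknown tasks, and
CEs outside $(0, X]$ each raise a distinct named condition
identifying the row).

# Numerical choices

* Money normalization: 100,000 USD per model unit, shared by both
  tasks; chosen so the normalized losses bracket 1 and the reported
  error scale is plausible. $\alpha, \beta$ are invariant to it.
* Inverse value function: closed form; round trips are exact to
  relative $10^{-10}$ (tested).
* Quantiles: linear interpolation (type 7), the `stats::quantile`
  default.
* Grid matching on file input: relative tolerance $10^{-9}$, so
  file-printed probabilities match their grid cells exactly without
  being bit-fragile.
* CSV output: 17 significant digits, so write-then-read round trips
  are bit-exact (tested).
* Random-walk proposals outside a support are rejected through the
  prior, never clamped — clamping proposals would bias the invariant
  distribution.
* Seeds: every stochastic stage takes one integer seed; simulation
  sub-stages derive fixed offsets from it. Identical seeds give
  byte-identical output files.

# What passing tests do and do not show

The test and acceptance suites demonstrate that the estimation
machinery recovers known generating values under the study
conditions: correct model, Gaussian value-scale noise, exact grid
compliance, no item nonresponse, exchangeable covariates. They cannot
certify behavior on real surveys, where respondents pick from coarse
menus (information loss the generator can emulate but the recovery
presets do not assume), errors need not be Gaussian or homoscedastic,
reference points may drift across scenarios, and a single $(\alpha,
\beta)$ per respondent may be misspecified. The $\lambda$ estimate in
particular should never be read as data-driven from pure-loss CE
designs: identifying loss aversion requires mixed gain–loss
prospects, which this instrument does not contain.
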