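---
title: "Adaptive enrichment designs: model, decision rule and operating characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive enrichment designs: model, decision rule and operating characteristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(adaptenrich)
```

## The design problem

A confirmatory Phase III trial compares a new treatment with control in a
population containing a pre-specified biomarker subpopulation S1 (a fraction
$\lambda$ of all patients) thought to respond particularly well. Two one-sided
hypotheses are of interest: $H_{01}: \theta_1 \le 0$ for the effect in S1, and
$H_{03}: \theta_3 \le 0$ for the full-population effect
$\theta_3 = \lambda\theta_1 + (1-\lambda)\theta_2$, where $\theta_2$ is the
effect in the complement S2. ($H_{02}$ is not tested.)

After a fraction $\tau$ of the planned sample, an interim analysis chooses
between two sampling plans for the remainder:

* **continue** recruiting from the full population (both hypotheses stay
  testable), or
* **enrich** — recruit only from S1, doubling the information flowing to
  $\theta_1$ but forgoing the test of $H_{03}$.

The package works at the summary-statistic level. With total Fisher
information $\tilde I = n/(4\sigma^2)$ for $\theta_3$ (equal randomization,
response SD $\sigma$), the stage-wise effect estimates are independent
normals: the interim estimates carry informations $\lambda\tau\tilde I$ and
$(1-\lambda)\tau\tilde I$, a non-enriched stage 2 carries
$\lambda(1-\tau)\tilde I$ and $(1-\lambda)(1-\tau)\tilde I$, and an enriched
stage 2 carries $(1-\tau)\tilde I$ for $\theta_1$ alone. Patient-level
simulation is deliberately avoided: every downstream quantity depends on the
data only through these sufficient statistics, and large-sample theory gives
the same estimator distributions for a wide range of endpoint types. This is
also the main idealization of the generator — real interim data involve
accrual lag, dropout, and nuisance-parameter estimation that the
summary-statistic model does not represent, so passing tests certify the
design calculus, not those operational aspects.

```{r}
design <- design_config(lambda = 0.5, tau = 0.5, alpha = 0.025,
                        n = 264, sigma = 25)
design
```

## Familywise error control

Both hypotheses are tested by a closed testing procedure at one-sided level
$\alpha$: $H_{01}$ is rejected overall only if level-$\alpha$ tests reject
both $H_{01}$ and the intersection $H_{0,13}$, and similarly for $H_{03}$.
The intersection is tested with the Simes combination
$p_{13} = \min\{2\min(p_1,p_3), \max(p_1,p_3)\}$, valid under the positive
association of the nested test statistics. Stages are merged with the
weighted inverse-normal combination
$W(p^{(1)}, p^{(2)}) = 1-\Phi\{w_1\Phi^{-1}(1-p^{(1)}) +
w_2\Phi^{-1}(1-p^{(2)})\}$, $w_1^2+w_2^2=1$. Because the weights are fixed in
advance, the combined statistic is standard normal under the null *whatever*
interim rule decides the stage-2 sampling plan — this is the property that
makes it safe to optimize the enrichment decision freely. After enrichment
there is no stage-2 estimate of $\theta_3$; the stage-2 intersection p-value
is then the S1 p-value itself and $H_{03}$ is no longer testable.

Default weights are $w_1 = \sqrt{\tau}$, $w_2 = \sqrt{1-\tau}$. These are
the only $\tau$-proportioned weights satisfying the constraint, and they make
the combined z-statistics equal, when no enrichment occurs, to the
z-statistics of the pooled full-data estimates (the `w1 = tau` convention
sometimes quoted fails the constraint $w_1^2+w_2^2=1$). Rejection uses the
closed interval $p \le \alpha$; p-values numerically at 0 or 1 are clamped to
`[1e-300, 1 - 1e-16]` before $\Phi^{-1}$.

## The Bayes-optimal interim decision

A prior $\pi(\theta)$ — a point mass or a bivariate normal — and the gain
function
$$G(\theta, X) = \lambda\theta_1\mathcal{R}_1 + \theta_3\mathcal{R}_3$$
(reward proportional to the size of the population for which efficacy is
claimed and the true effect there; $\mathcal{R}_1$ = only $H_{01}$ rejected,
$\mathcal{R}_3$ = $H_{03}$ rejected) define the optimality criterion. At the
interim, the posterior given the stage-1 estimates is available in closed
form (normal-normal conjugacy; the likelihood is exactly bivariate normal, so
the update is exact, with zero-variance components held fixed). The optimal
decision maximizes the conditional expected gain, estimated from one shared
posterior sample of size $M$ (common random numbers for the two options):

* **enrich**: after enrichment the closed test rejects $H_{01}$ exactly when
  the stage-2 estimate exceeds a threshold $\kappa(x_1)$ available in closed
  form, so the conditional gain is the average of
  $\lambda\theta_{i,1}\{1-\Phi((\kappa-\theta_{i,1})\sqrt{(1-\tau)\tilde I})\}$
  — analytic in stage 2, no simulation. (An MC version is kept as a test
  oracle; the analytic form has the same expectation and strictly lower
  variance.)
* **continue**: one stage-2 dataset is simulated per posterior draw and the
  closed test applied; replicating stage 2 within a draw is less efficient
  than adding draws.

Exact ties go to continuing (which keeps $H_{03}$ testable); they have
probability zero in the exact problem and the tolerance is configurable.
The decision machinery is specific to the default gain; the evaluators
accept a replacement gain function for sensitivity analyses of completed
rules.

```{r}
set.seed(1)
decide_enrichment(design, prior_point(10, 2), est1 = 8, est2 = -1, m = 1e4)
```

## Mapping the decision boundary

Simulating the optimized design requires the decision at every possible
interim observation. `build_boundary()` maps it over a square region $A$
centered at the prior-predictive mean of the interim estimates with
half-width 5.2 prior-predictive SDs — the smallest round figure for which the
rectangle provably holds at least $1-10^{-6}$ of the predictive mass (at 5
SDs the two-axis union bound already exceeds $10^{-6}$). The region is split
into four squares; vertices are evaluated with `decide_enrichment()` (cached,
so shared vertices cost one evaluation; each vertex gets a seed derived from
the root seed and its grid position, making the build order-independent and
reproducible); squares whose four vertices agree unambiguously inherit the
decision; others are quartered, down to a smallest cell (default: region
side / 128). A vertex is *ambiguous* — treated like a disagreement — when its
two estimated gains differ by less than two combined Monte Carlo standard
errors; this operationalizes "both decisions optimal at a vertex" with an
explicit statistical criterion. Leaf cells still split at the finest size
take the majority vertex decision, ties to continue. Because the enrich and
continue regions are geometrically simple, the expensive Monte Carlo work
concentrates along a one-dimensional strip around the boundary instead of a
full grid — typically a few thousand vertex evaluations for a 128-cell map.

Lookups are half-open (lower-left inclusive); points outside $A$ take the
nearest boundary cell, which on the uniform fine raster is exact
nearest-center extrapolation. Rules serialize to JSON and round-trip
losslessly; `autoplot()` rasterizes them.

```{r, eval = FALSE}
rule <- build_boundary(design, prior_normal(12, 2, 25, 25, 0.75),
                       m = 1e5, cells_per_side = 128, seed = 1)
autoplot(rule)
```

## Operating characteristics and the two fixed comparators

`evaluate_adaptive()` simulates the full pipeline per replicate: draw
$\theta$ from the prior, simulate stage 1, look up the decision, simulate
stage 2 accordingly, run the closed test, record the gain (one stage-2
dataset per replicate). Two non-adaptive references share the same total
sample size:

* **FF** (fixed full-population): recruit everyone, test both hypotheses
  once with a single-stage Simes closed test. Simulated by drawing the two
  subpopulation estimates independently, which induces the exact joint law
  of $(\hat\theta_1, \hat\theta_3)$ (correlation $\sqrt\lambda$).
* **FS** (fixed subpopulation): recruit only S1, test only $H_{01}$ —
  fully analytic, with normal priors handled by adaptive 1-D quadrature
  (`rel.tol 1e-10`) over the $\theta_1$ marginal.

`compare_designs()`, `oc_sweep()` (over $\tau$, $\lambda$ or the prior
variance, re-optimizing the rule per value) and `best_design_map()` (winner
per one-point prior on a grid, with statistical ties at two combined SEs
labeled jointly rather than forced to a single winner) assemble the standard
comparison tables and region maps as tidy tibbles.

```{r}
fs <- evaluate_fs(prior_point(10, 2), design_config(info = 0.105))
fs[, c("design", "p_r1", "e_gain")]
```

## Numerical choices and problem sizes

* Posterior sampling uses the lower Cholesky factor in a fixed order, so a
  seed pins the draws exactly; boundary builds and evaluations are
  bit-reproducible given their seeds.
* Tail z-statistics use upper-tail `qnorm`/`pnorm` directly, avoiding
  catastrophic cancellation in `1 - p`.
* Defaults follow the decision-accuracy levels at which the Monte Carlo
  error of a vertex decision is negligible relative to the gain surface:
  $M = 10^5$ posterior draws per vertex, 128 fine cells per region side,
  and $N \ge 10^5$ replicates for operating characteristics (the
  reproduction script uses $10^5$–$2\times10^5$; standard errors are always
  reported so users can scale $N$ to their needs). The test suite exercises
  the same code paths at reduced sizes ($M \approx 2\times10^4$, 64 cells)
  with correspondingly wider tolerances that include a boundary-resolution
  allowance.

## Known limitations

* One subpopulation, one interim analysis; nested or multiple subpopulations
  and futility stopping are out of scope (a futility option would require a
  sampling-cost term in the gain).
* The Bayes decision optimizes the default gain only; custom gains enter
  evaluation, not rule construction.
* Near the decision boundary the mapped rule is uncertain at the scale of a
  fine cell plus the vertex Monte Carlo error; quantities that integrate over
  the interim distribution (expected gain, rejection probabilities) are
  insensitive to this, but pointwise decisions adjacent to the boundary can
  differ between builds.
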