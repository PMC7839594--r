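# adaptenrich

Design and evaluation of **two-stage adaptive enrichment Phase III trials**
with a pre-specified biomarker subpopulation.

When a subset S1 of patients (a fraction λ of the population) is expected to
respond particularly well to a new treatment, an adaptive enrichment design
recruits from the full population until an interim analysis (after a fraction
τ of the planned sample) and then either **continues** in the full population
or **enriches** — restricts the rest of recruitment to S1. Two one-sided
hypotheses are of interest: H01: θ₁ ≤ 0 for the subpopulation effect, and
H03: θ₃ ≤ 0 for the full-population effect θ₃ = λθ₁ + (1−λ)θ₂. The package is
for trial statisticians who need to construct such designs, prove their error
control, and quantify what the adaptivity is worth against fixed alternatives.

Three components make up the core:

1. **FWER-controlling closed testing.** Each hypothesis and their
   intersection is tested at level α; the intersection uses the Simes
   p-value `min{2·min(p₁,p₃), max(p₁,p₃)}`, and stages are merged with the
   weighted inverse-normal combination
   `1 − Φ{w₁Φ⁻¹(1−p⁽¹⁾) + w₂Φ⁻¹(1−p⁽²⁾)}` (w₁²+w₂²=1, defaults
   √τ, √(1−τ)). The familywise error rate is controlled strongly *whatever*
   interim rule is used — which is what makes it safe to optimize the rule.
2. **Bayes-optimal interim decision.** Given a prior for (θ₁, θ₂) — point
   mass or bivariate normal — and the gain function
   `G(θ, X) = λθ₁·R1 + θ₃·R3` (R1 = only H01 rejected, R3 = H03 rejected),
   the decision maximizes the conditional expected gain given the interim
   data, estimated by Monte Carlo over the (conjugate, closed-form)
   posterior with an analytic stage-2 rejection probability on the
   enrichment arm.
3. **Boundary mapping and operating characteristics.** An adaptive
   square-subdivision algorithm precomputes the optimal decision over the
   plane of interim estimates (Monte Carlo effort concentrates along the
   decision boundary), and simulators reproduce the expected gain, rejection
   and enrichment probabilities of the adaptive (AE), fixed full-population
   (FF) and fixed subpopulation (FS) designs.

## Worked example

Half the population is biomarker-positive (λ = 0.5), the interim sits at
τ = 0.5, and n = 264 patients with response SD 25 give the information that
powers a single test of H03 at 90% for an effect of 10:

```r
library(adaptenrich)
design <- design_config(lambda = 0.5, tau = 0.5, alpha = 0.025,
                        n = 264, sigma = 25)
design
#> <enrich_design>
#>   lambda = 0.5, tau = 0.5, alpha = 0.025
#>   information = 0.1056  (n = 264, sigma = 25)
#>   weights w1 = 0.707107, w2 = 0.707107

set.seed(7)
interim <- simulate_stage1(design, theta1 = 10, theta2 = 2, n_rep = 1)
interim
#>   theta1 theta2 est1  est2 est3
#> 1     10      2 24.1 -5.37 9.36

set.seed(8)
decide_enrichment(design, prior_normal(10, 2, 25, 25, 0.75),
                  est1 = interim$est1, est2 = interim$est2, m = 1e5)
#>   gain_enrich se_enrich gain_continue se_continue decision ambiguous      m
#> 1        6.66   0.00569           7.8     0.00979        2     FALSE 100000
```

Despite the negative interim estimate in S2, the optimal decision here is to
**continue** (decision 2): the S1 signal is so strong (est1 = 24.1) that H01
is nearly certain to be rejected either way, and continuing keeps the chance
of also rejecting H03 — worth 7.8 in expected gain against 6.66 for
enriching. The gains are conditional expected values of `G`, in effect units.

The fixed subpopulation comparator is analytic; at θ₁ = 10 it rejects H01
with probability 0.90 and earns λ·θ₁·0.90 = 4.5:

```r
evaluate_fs(prior_point(10, 2), design_config(info = 0.105))[, c("design", "p_r1", "e_gain")]
#>   design p_r1 e_gain
#> 1     FS  0.9    4.5
```

A full design workflow precomputes the decision boundary once, then
simulates the design at scale:

```r
prior <- prior_normal(10, 2, 25, 25, 0.75)
rule  <- build_boundary(design, prior, m = 1e5, cells_per_side = 128, seed = 1)
autoplot(rule)                      # enrich / continue regions
evaluate_adaptive(rule, prior, design, n_rep = 1e5)   # AE operating characteristics
compare_designs(prior, design, rule = rule)           # AE vs FF vs FS
```

A thin command-line front end over the same functions lives at
`inst/cli/aetrial.R` (subcommands `calibrate`, `boundary`, `compare`,
`sweep`, `simulate`; every run writes a manifest sufficient to reproduce its
outputs).

## Scope

One biomarker subpopulation, one interim look, equal randomization,
normal-theory summary statistics (which large-sample theory extends to other
endpoint types). No futility stopping (that would need a sampling-cost term
in the gain), no nested/multiple subpopulations. See the methods vignette
(`vignettes/adaptive-enrichment-methods.Rmd`) for the model, the decision
theory, the boundary algorithm and the package's numerical choices.
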