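#' Critical stage-2 threshold for rejection after enrichment
#'
#' After enrichment, both combined p-values that govern rejection of
#' \eqn{H_{01}} — \eqn{P_1^{(c)}} and \eqn{P_{13}^{(c)}} — are strictly
#' decreasing in the stage-2 estimate \eqn{\hat\theta_1^{(2)}}, so there is an
#' exact threshold \eqn{\kappa(x_1)} with
#' \eqn{\hat\theta_1^{(2)} \ge \kappa(x_1) \iff H_{01}} rejected by the closed
#' test. In closed form, with \eqn{Z_1^{(1)}} and
#' \eqn{Z_{13}^{(1)} = \Phi^{-1}(1 - P_{13}^{(1)})} from the interim data,
#' \deqn{\kappa(x_1) = \frac{\max_j\,(\Phi^{-1}(1-\alpha) - w_1 Z_j^{(1)})/w_2}
#' {\sqrt{(1-\tau)\tilde I}}, \quad j \in \{1, 13\}.}
#'
#' @param design An [design_config()] object (requires `w2 > 0`).
#' @param est1,est2 Interim estimates (vectorized).
#' @return The threshold(s) \eqn{\kappa(x_1)} in effect units.
#' @export
critical_value <- function(design, est1, est2) {
  stopifnot(inherits(design, "enrich_design"))
  if (design$w2 == 0)
    stop("w2 = 0: stage 2 cannot influence the combined test, kappa is undefined")
  s1 <- stage_pvalues(design, est1, est2, stage = 1)
  z13 <- stats::qnorm(clamp_p(s1$p13, warn = FALSE), lower.tail = FALSE)
  z_alpha <- stats::qnorm(1 - design$alpha)
  c1 <- (z_alpha - design$w1 * s1$z1) / design$w2
  c13 <- (z_alpha - design$w1 * z13) / design$w2
  pmax(c1, c13) / sqrt((1 - design$tau) * design$info)
}

#' Conditional expected gain of enriching
#'
#' Given interim data \eqn{x_1} and a sample \eqn{\{\theta_i\}} from the
#' posterior of the effects, the conditional expected gain of enrichment is
#' estimated as
#' \deqn{\frac{1}{M}\sum_i \lambda\theta_{i,1}\,
#'   P(\hat\theta_1^{(2)} \ge \kappa(x_1) \mid \theta_1 = \theta_{i,1}),}
#' with the stage-2 rejection probability evaluated analytically as
#' \eqn{1 - \Phi\{(\kappa - \theta_{i,1})\sqrt{(1-\tau)\tilde I}\}} (no
#' stage-2 simulation; strictly lower variance than simulating, same
#' expectation).
#'
#' @param design An [design_config()] object.
#' @param est1,est2 Interim estimates (scalars).
#' @param theta_sample A data frame of posterior draws with columns `theta1`,
#'   `theta2` (see [sample_effects()]).
#' @return A list with elements `gain` (the Monte Carlo mean) and `se` (its
#'   standard error over the posterior draws; 0 for a point posterior).
#' @export
expected_gain_enrich <- function(design, est1, est2, theta_sample) {
  stopifnot(nrow(theta_sample) >= 1)
  kappa <- critical_value(design, est1, est2)
  s2_scale <- sqrt((1 - design$tau) * design$info)
  p_rej <- stats::pnorm((kappa - theta_sample$theta1) * s2_scale,
                        lower.tail = FALSE)
  g <- design$lambda * theta_sample$theta1 * p_rej
  list(gain = mean(g), se = mc_se(g))
}

# sample SE of a mean; 0 for a single draw (degenerate point posteriors)
mc_se <- function(g) {
  if (length(g) < 2L) return(0)
  stats::sd(g) / sqrt(length(g))
}

#' Conditional expected gain of continuing in the full population
#'
#' For each posterior draw \eqn{\theta_i}, one stage-2 dataset
#' \eqn{(\hat\theta_{i,1}^{(2)}, \hat\theta_{i,2}^{(2)})} is simulated without
#' enrichment, the closed testing procedure is applied to the combined trial,
#' and the gain \eqn{\lambda\theta_{i,1}\mathcal{R}_1 +
#' \theta_{i,3}\mathcal{R}_3} is recorded; the estimate is the average over
#' the \eqn{M} draws. One stage-2 replicate per draw is used: replicating
#' stage 2 within a draw is less efficient than spending the effort on more
#' posterior draws.
#'
#' @inheritParams expected_gain_enrich
#' @return A list with elements `gain` and `se`.
#' @export
expected_gain_continue <- function(design, est1, est2, theta_sample) {
  stopifnot(nrow(theta_sample) >= 1)
  s1 <- stage_pvalues(design, est1, est2, stage = 1)
  continue_gain_core(design, s1, theta_sample$theta1, theta_sample$theta2)
}

# Fast kernel shared with the boundary builder: stage-1 p-values fixed
# (scalars), stage-2 simulated once per theta draw, closed test in z-space.
continue_gain_core <- function(design, s1, theta1, theta2) {
  la <- design$lambda; ta <- design$tau; I <- design$info
  w1 <- design$w1; w2 <- design$w2
  z_alpha <- stats::qnorm(1 - design$alpha)
  m <- length(theta1)

  sd1 <- 1 / sqrt(la * (1 - ta) * I)
  sd2 <- 1 / sqrt((1 - la) * (1 - ta) * I)
  e1 <- stats::rnorm(m, theta1, sd1)
  e2 <- stats::rnorm(m, theta2, sd2)
  e3 <- la * e1 + (1 - la) * e2
  z1_2 <- e1 * sqrt(la * (1 - ta) * I)
  z3_2 <- e3 * sqrt((1 - ta) * I)
  p1_2 <- stats::pnorm(z1_2, lower.tail = FALSE)
  p3_2 <- stats::pnorm(z3_2, lower.tail = FALSE)
  z13_2 <- stats::qnorm(clamp_p(simes_pvalue(p1_2, p3_2), warn = FALSE),
                        lower.tail = FALSE)

  z1_1 <- s1$z1; z3_1 <- s1$z3
  z13_1 <- stats::qnorm(clamp_p(s1$p13, warn = FALSE), lower.tail = FALSE)

  rej1 <- (w1 * z1_1 + w2 * z1_2) >= z_alpha
  rej3 <- (w1 * z3_1 + w2 * z3_2) >= z_alpha
  rej13 <- (w1 * z13_1 + w2 * z13_2) >= z_alpha
  h01 <- rej1 & rej13
  h03 <- rej3 & rej13
  theta3 <- la * theta1 + (1 - la) * theta2
  g <- la * theta1 * (h01 & !h03) + theta3 * h03
  list(gain = mean(g), se = mc_se(g))
}

#' Bayes-optimal enrichment decision at the interim
#'
#' Updates the prior with the interim estimates, draws one shared sample of
#' `m` effect pairs from the posterior (common random numbers for the two
#' options), estimates the conditional expected gain of enriching
#' ([expected_gain_enrich()]) and of continuing
#' ([expected_gain_continue()]), and picks the larger. Ties — gains within
#' `tie_z` combined standard errors of each other, with the strict default
#' `tie_z = 0` meaning exact equality — go to continuing, which preserves the
#' ability to test \eqn{H_{03}}.
#'
#' @param design An [design_config()] object.
#' @param prior An `enrich_prior`.
#' @param est1,est2 Interim estimates (scalars).
#' @param m Posterior sample size \eqn{M}.
#' @param tie_z Tie tolerance in units of the combined standard error.
#' @return A one-row tibble with `gain_enrich`, `se_enrich`, `gain_continue`,
#'   `se_continue`, `decision` (1 enrich / 2 continue), `ambiguous` (gains
#'   within two combined standard errors), and `m`.
#' @examples
#' d <- design_config(info = 0.105)
#' set.seed(1)
#' decide_enrichment(d, prior_point(10, 2), est1 = 8, est2 = -1, m = 1e4)
#' @export
decide_enrichment <- function(design, prior, est1, est2, m = 1e5, tie_z = 0) {
  stopifnot(m >= 1)
  post <- posterior_update(prior, est1, est2, design)
  ts <- sample_effects(post, m)
  ge <- expected_gain_enrich(design, est1, est2, ts)
  gc <- expected_gain_continue(design, est1, est2, ts)
  se_comb <- sqrt(ge$se^2 + gc$se^2)
  diff <- ge$gain - gc$gain
  decision <- if (diff > tie_z * max(ge$se, gc$se)) 1L else 2L
  tibble::tibble(
    gain_enrich = ge$gain, se_enrich = ge$se,
    gain_continue = gc$gain, se_continue = gc$se,
    decision = decision,
    ambiguous = abs(diff) < 2 * se_comb,
    m = as.integer(m)
  )
}
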