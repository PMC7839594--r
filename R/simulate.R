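#' Simulate stage-1 effect estimates
#'
#' Draws interim (stage-1) treatment-effect estimates under the normal
#' sampling model: \eqn{\hat\theta_1^{(1)} \sim N(\theta_1,
#' \{\lambda\tau\tilde{I}\}^{-1})} and \eqn{\hat\theta_2^{(1)} \sim
#' N(\theta_2, \{(1-\lambda)\tau\tilde{I}\}^{-1})}, independent given
#' \eqn{\theta}. The full-population estimate
#' \eqn{\hat\theta_3^{(1)} = \lambda\hat\theta_1^{(1)} +
#' (1-\lambda)\hat\theta_2^{(1)}} is returned as well; the pair
#' \eqn{(\hat\theta_1^{(1)}, \hat\theta_3^{(1)})} is bivariate normal with
#' correlation \eqn{\sqrt{\lambda}} by construction.
#'
#' `theta1`/`theta2` are recycled against `n_rep`, so a vector of true effects
#' (for example posterior or prior draws) yields one stage-1 dataset per draw.
#'
#' @param design An [design_config()] object.
#' @param theta1,theta2 True effects in S1 and S2.
#' @param n_rep Number of replicate trials to simulate.
#' @return A tibble with columns `theta1`, `theta2`, `est1`, `est2`, `est3`.
#' @examples
#' d <- design_config(n = 264, sigma = 25)
#' set.seed(1)
#' simulate_stage1(d, theta1 = 10, theta2 = 2, n_rep = 3)
#' @export
simulate_stage1 <- function(design, theta1, theta2, n_rep = 1) {
  stopifnot(inherits(design, "enrich_design"))
  info <- stage_information(design, 1L)
  k <- max(n_rep, length(theta1), length(theta2))
  theta1 <- rep_len(theta1, k)
  theta2 <- rep_len(theta2, k)
  est1 <- stats::rnorm(k, theta1, 1 / sqrt(info[["i1"]]))
  est2 <- stats::rnorm(k, theta2, sd_est2(design, 1L))
  tibble::tibble(
    theta1 = theta1, theta2 = theta2,
    est1 = est1, est2 = est2,
    est3 = theta_full(est1, est2, design$lambda)
  )
}

#' Simulate stage-2 effect estimates
#'
#' Draws the post-interim estimates given the enrichment decision. Without
#' enrichment, \eqn{\hat\theta_1^{(2)} \sim N(\theta_1,
#' \{\lambda(1-\tau)\tilde{I}\}^{-1})} and \eqn{\hat\theta_2^{(2)} \sim
#' N(\theta_2, \{(1-\lambda)(1-\tau)\tilde{I}\}^{-1})}. With enrichment the
#' whole stage-2 sample comes from S1, giving \eqn{\hat\theta_1^{(2)} \sim
#' N(\theta_1, \{(1-\tau)\tilde{I}\}^{-1})} and no estimate of \eqn{\theta_2}
#' or \eqn{\theta_3} (`est2`, `est3` are `NA`).
#'
#' @inheritParams simulate_stage1
#' @param enrich Logical (recycled): was recruitment restricted to S1?
#' @return A tibble with columns `theta1`, `theta2`, `enrich`, `est1`, `est2`,
#'   `est3`.
#' @export
simulate_stage2 <- function(design, theta1, theta2, enrich = FALSE, n_rep = 1) {
  stopifnot(inherits(design, "enrich_design"))
  k <- max(n_rep, length(theta1), length(theta2), length(enrich))
  theta1 <- rep_len(theta1, k)
  theta2 <- rep_len(theta2, k)
  enrich <- rep_len(as.logical(enrich), k)
  sd1 <- ifelse(enrich,
                1 / sqrt(stage_information(design, 2L, TRUE)[["i1"]]),
                1 / sqrt(stage_information(design, 2L, FALSE)[["i1"]]))
  est1 <- stats::rnorm(k, theta1, sd1)
  est2 <- rep(NA_real_, k)
  if (any(!enrich)) {
    est2[!enrich] <- stats::rnorm(sum(!enrich), theta2[!enrich],
                                  sd_est2(design, 2L))
  }
  tibble::tibble(
    theta1 = theta1, theta2 = theta2, enrich = enrich,
    est1 = est1, est2 = est2,
    est3 = ifelse(enrich, NA_real_,
                  theta_full(est1, est2, design$lambda))
  )
}

#' Simulate whole trials under a decision rule
#'
#' Runs the full two-stage pipeline: stage-1 estimates, enrichment decision via
#' `rule`, then stage-2 estimates under that decision. `rule` may be a built
#' decision boundary (see [build_boundary()]), the strings `"always"`,
#' `"never"`, `"random"` (fair coin, useful for error-rate stress tests), or a
#' function `(est1, est2) -> decision vector` returning 1 (enrich) or 2
#' (continue).
#'
#' @inheritParams simulate_stage1
#' @param rule Decision rule (see Details).
#' @return A tibble with one row per trial: true effects, stage-1 estimates
#'   (`s1_*`), `decision` (1 enrich / 2 continue), and stage-2 estimates
#'   (`s2_*`, `NA` where unavailable after enrichment).
#' @export
simulate_trials <- function(design, theta1, theta2, rule, n_rep = 1) {
  s1 <- simulate_stage1(design, theta1, theta2, n_rep)
  decision <- apply_rule(rule, s1$est1, s1$est2)
  s2 <- simulate_stage2(design, s1$theta1, s1$theta2, enrich = decision == 1L)
  tibble::tibble(
    theta1 = s1$theta1, theta2 = s1$theta2,
    theta3 = theta_full(s1$theta1, s1$theta2, design$lambda),
    s1_est1 = s1$est1, s1_est2 = s1$est2, s1_est3 = s1$est3,
    decision = decision,
    s2_est1 = s2$est1, s2_est2 = s2$est2, s2_est3 = s2$est3
  )
}

# Resolve the various rule representations to a decision vector in {1, 2}.
apply_rule <- function(rule, est1, est2) {
  if (inherits(rule, "enrich_rule")) {
    lookup_decision(rule, est1, est2)
  } else if (is.function(rule)) {
    d <- rule(est1, est2)
    stopifnot(all(d %in% c(1L, 2L)))
    as.integer(d)
  } else if (identical(rule, "always")) {
    rep(1L, length(est1))
  } else if (identical(rule, "never")) {
    rep(2L, length(est1))
  } else if (identical(rule, "random")) {
    sample(c(1L, 2L), length(est1), replace = TRUE)
  } else {
    stop("unrecognized decision rule")
  }
}

sd_est2 <- function(design, stage) {
  I <- design$info; la <- design$lambda; ta <- design$tau
  f <- if (stage == 1L) ta else 1 - ta
  1 / sqrt((1 - la) * f * I)
}
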