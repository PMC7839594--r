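#' Specify a two-stage adaptive enrichment design
#'
#' Collects the fixed constants of a two-stage trial in which a biomarker
#' subpopulation S1 forms a fraction `lambda` of the full population, a single
#' interim analysis takes place after a fraction `tau` of the planned sample,
#' and the familywise error rate for the one-sided hypotheses
#' \eqn{H_{01}: \theta_1 \le 0} and \eqn{H_{03}: \theta_3 \le 0} is controlled
#' at level `alpha`. The full-population effect is
#' \eqn{\theta_3 = \lambda\theta_1 + (1-\lambda)\theta_2}.
#'
#' Total Fisher information for \eqn{\theta_3} in a fixed trial of `n` equally
#' randomized patients with response standard deviation `sigma` is
#' \eqn{\tilde{I} = n / (4\sigma^2)}. Either `info` or the pair (`n`, `sigma`)
#' may be given; when all are given they must agree.
#'
#' The stage-wise inverse-normal combination weights default to
#' \eqn{w_1 = \sqrt{\tau}}, \eqn{w_2 = \sqrt{1-\tau}}, which satisfy the
#' required constraint \eqn{w_1^2 + w_2^2 = 1} and make the combined
#' z-statistics for \eqn{H_{01}} and \eqn{H_{03}} equal, in the absence of
#' enrichment, to the z-statistics of the pooled full-data estimates.
#'
#' @param lambda Fraction of the population in subpopulation S1, in (0, 1).
#' @param tau Fraction of the total sample observed at the interim, in (0, 1).
#' @param alpha One-sided familywise error level, in (0, 1).
#' @param info Total information \eqn{\tilde{I}} (units 1/effect^2), or `NULL`
#'   to derive it from `n` and `sigma`.
#' @param n Optional total sample size (patients).
#' @param sigma Optional response standard deviation (effect units).
#' @param w1,w2 Combination-test weights; must satisfy `w1^2 + w2^2 == 1`.
#'   Default `sqrt(tau)`, `sqrt(1 - tau)`.
#' @return An object of class `enrich_design`: a list with the validated
#'   constants and the derived information.
#' @examples
#' design_config(lambda = 0.5, tau = 0.5, alpha = 0.025, n = 264, sigma = 25)
#' @export
design_config <- function(lambda = 0.5, tau = 0.5, alpha = 0.025,
                          info = NULL, n = NULL, sigma = NULL,
                          w1 = NULL, w2 = NULL) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L,
            is.numeric(tau), length(tau) == 1L,
            is.numeric(alpha), length(alpha) == 1L)
  if (lambda <= 0 || lambda >= 1) stop("`lambda` must be strictly inside (0, 1)")
  if (tau <= 0 || tau >= 1) stop("`tau` must be strictly inside (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be strictly inside (0, 1)")

  info_ns <- if (!is.null(n) && !is.null(sigma)) information_from_n(n, sigma)
  if (is.null(info)) {
    if (is.null(info_ns))
      stop("supply either `info` or both `n` and `sigma`")
    info <- info_ns
  } else {
    if (!is.numeric(info) || length(info) != 1L || info <= 0)
      stop("`info` must be a positive number")
    if (!is.null(info_ns) && abs(info - info_ns) > 1e-9)
      stop("`info` and n/(4*sigma^2) disagree (|diff| > 1e-9); supply one or ",
           "make them consistent")
  }

  if (is.null(w1) != is.null(w2))
    stop("supply both `w1` and `w2`, or neither")
  if (is.null(w1)) {
    w1 <- sqrt(tau)
    w2 <- sqrt(1 - tau)
  }
  if (abs(w1^2 + w2^2 - 1) > 1e-12)
    stop("combination weights must satisfy w1^2 + w2^2 = 1")

  structure(
    list(lambda = lambda, tau = tau, alpha = alpha, info = info,
         n = n, sigma = sigma, w1 = w1, w2 = w2),
    class = "enrich_design"
  )
}

#' Total information from sample size and response standard deviation
#'
#' \eqn{\tilde{I} = n / (4\sigma^2)}: the Fisher information for the
#' full-population effect \eqn{\theta_3} from `n` patients randomized equally
#' between the two treatment arms.
#'
#' @param n Total sample size (> 0).
#' @param sigma Response standard deviation (> 0).
#' @return Information in units 1/effect^2.
#' @examples
#' information_from_n(264, 25)
#' @export
information_from_n <- function(n, sigma) {
  if (!is.numeric(n) || any(n <= 0)) stop("`n` must be positive")
  if (!is.numeric(sigma) || any(sigma <= 0)) stop("`sigma` must be positive")
  n / (4 * sigma^2)
}

#' Calibrate total information for a target power
#'
#' Returns the information \eqn{\tilde{I}} for which a single one-sided
#' level-`alpha` test of \eqn{H_{03}} has the stated power at effect `delta`:
#' \eqn{\tilde{I} = \{(\Phi^{-1}(\mathrm{power}) +
#' \Phi^{-1}(1-\alpha))/\delta\}^2}.
#'
#' @param delta Effect size at which the power is required (> 0).
#' @param power Target power, in (0, 1).
#' @param alpha One-sided significance level, in (0, 0.5).
#' @return Information in units 1/effect^2.
#' @examples
#' calibrate_information(10, 0.9, 0.025) # about 0.105
#' @export
calibrate_information <- function(delta, power, alpha = 0.025) {
  if (!is.numeric(delta) || any(delta <= 0)) stop("`delta` must be positive")
  if (!is.numeric(power) || any(power <= 0) || any(power >= 1))
    stop("`power` must be in (0, 1)")
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 0.5))
    stop("`alpha` must be in (0, 0.5)")
  ((stats::qnorm(power) + stats::qnorm(1 - alpha)) / delta)^2
}

#' Per-arm sample sizes implied by a design
#'
#' Requires the design to carry `n`. Counts are per treatment arm:
#' stage-1 S1 arms hold \eqn{\lambda\tau n/2} patients each, stage-1 S2 arms
#' \eqn{(1-\lambda)\tau n/2}; without enrichment stage 2 adds
#' \eqn{\lambda(1-\tau)n/2} and \eqn{(1-\lambda)(1-\tau)n/2}, and with
#' enrichment \eqn{(1-\tau)n/2} from S1 alone.
#'
#' @param design An `enrich_design`.
#' @return A tibble with columns `stage`, `subpopulation`, `enriched`,
#'   `per_arm`.
#' @export
arm_sizes <- function(design) {
  stopifnot(inherits(design, "enrich_design"))
  if (is.null(design$n)) stop("design was specified by information only; no `n`")
  n <- design$n; la <- design$lambda; ta <- design$tau
  tibble::tibble(
    stage = c(1L, 1L, 2L, 2L, 2L),
    subpopulation = c("S1", "S2", "S1", "S2", "S1"),
    enriched = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    per_arm = c(la * ta * n / 2, (1 - la) * ta * n / 2,
                la * (1 - ta) * n / 2, (1 - la) * (1 - ta) * n / 2,
                (1 - ta) * n / 2)
  )
}

#' Full-population effect from subpopulation effects
#'
#' @param theta1,theta2 Treatment effects in S1 and S2 (vectorized).
#' @param lambda Fraction of the population in S1.
#' @return \eqn{\theta_3 = \lambda\theta_1 + (1-\lambda)\theta_2}.
#' @export
theta_full <- function(theta1, theta2, lambda) {
  lambda * theta1 + (1 - lambda) * theta2
}

#' @export
print.enrich_design <- function(x, ...) {
  cat("<enrich_design>\n")
  cat(sprintf("  lambda = %g, tau = %g, alpha = %g\n", x$lambda, x$tau, x$alpha))
  cat(sprintf("  information = %.6g", x$info))
  if (!is.null(x$n)) cat(sprintf("  (n = %g, sigma = %g)", x$n, x$sigma))
  cat("\n")
  cat(sprintf("  weights w1 = %.6g, w2 = %.6g\n", x$w1, x$w2))
  invisible(x)
}

# Stage/enrichment-specific information for the theta1 and theta3 estimates.
# Stage 1: (lambda*tau*I, tau*I); stage 2 without enrichment:
# (lambda*(1-tau)*I, (1-tau)*I); stage 2 enriched: ((1-tau)*I, NA).
stage_information <- function(design, stage, enriched = FALSE) {
  I <- design$info; la <- design$lambda; ta <- design$tau
  if (stage == 1L) {
    c(i1 = la * ta * I, i3 = ta * I)
  } else if (enriched) {
    c(i1 = (1 - ta) * I, i3 = NA_real_)
  } else {
    c(i1 = la * (1 - ta) * I, i3 = (1 - ta) * I)
  }
}
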