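#' Simes p-value for the intersection hypothesis
#'
#' Combines one-sided p-values for \eqn{H_{01}} and \eqn{H_{03}} into a
#' p-value for the intersection \eqn{H_{0,13}}:
#' \deqn{p_{13} = \min\{2\min(p_1, p_3),\ \max(p_1, p_3)\}.}
#' Valid (conservative) under the positive association induced by the nested
#' patient groups behind the two statistics.
#'
#' @param p1,p3 One-sided p-values in \[0, 1\] (vectorized).
#' @return The Simes intersection p-value, in \[0, 1\].
#' @examples
#' simes_pvalue(0.01, 0.04) # 0.02
#' @export
simes_pvalue <- function(p1, p3) {
  if (any(p1 < 0 | p1 > 1, na.rm = TRUE) || any(p3 < 0 | p3 > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  pmin(2 * pmin(p1, p3), pmax(p1, p3))
}

#' Weighted inverse-normal combination of stage-wise p-values
#'
#' \deqn{W(p^{(1)}, p^{(2)}) = 1 - \Phi\{w_1\Phi^{-1}(1-p^{(1)}) +
#' w_2\Phi^{-1}(1-p^{(2)})\}} with pre-specified weights satisfying
#' \eqn{w_1^2 + w_2^2 = 1}. Because the weights are fixed before the interim,
#' the combined statistic is standard normal under the null whatever
#' data-dependent choice governs stage 2, which is what lets the enrichment
#' decision be optimized freely without inflating the error rate.
#'
#' p-values numerically equal to 0 or 1 are clamped to the machine-open
#' interval (with a warning) before applying \eqn{\Phi^{-1}}.
#'
#' @param p_stage1,p_stage2 Stage-wise p-values (vectorized).
#' @param w1,w2 Weights with `w1^2 + w2^2 == 1`.
#' @return The combined p-value.
#' @examples
#' combine_pvalues(0.025, 0.025, sqrt(0.5), sqrt(0.5))
#' @export
combine_pvalues <- function(p_stage1, p_stage2, w1, w2) {
  if (abs(w1^2 + w2^2 - 1) > 1e-12)
    stop("combination weights must satisfy w1^2 + w2^2 = 1")
  p1 <- clamp_p(p_stage1)
  p2 <- clamp_p(p_stage2)
  stats::pnorm(w1 * stats::qnorm(p1, lower.tail = FALSE) +
                 w2 * stats::qnorm(p2, lower.tail = FALSE),
               lower.tail = FALSE)
}

# Clamp p-values away from {0, 1} so qnorm stays finite; warns when it bites
# unless `warn = FALSE` (internal Monte Carlo kernels, where extreme tails are
# an expected numerical event and the clamped value is inconsequential).
clamp_p <- function(p, lo = 1e-300, hi = 1 - 1e-16, warn = TRUE) {
  bad <- !is.na(p) & (p < lo | p > hi)
  if (warn && any(bad))
    warning(sum(bad), " p-value(s) at or beyond {0, 1} clamped to the open unit interval")
  pmin(pmax(p, lo), hi)
}

#' Stage-wise z-statistics and p-values
#'
#' Converts stage-wise effect estimates into the z-statistics and one-sided
#' p-values entering the closed testing procedure. Stage 1 uses informations
#' \eqn{\lambda\tau\tilde I} (for \eqn{\theta_1}) and \eqn{\tau\tilde I} (for
#' \eqn{\theta_3}); stage 2 without enrichment uses
#' \eqn{\lambda(1-\tau)\tilde I} and \eqn{(1-\tau)\tilde I}; an enriched
#' stage 2 carries only \eqn{\hat\theta_1^{(2)}} at information
#' \eqn{(1-\tau)\tilde I}, and the intersection p-value is then
#' \eqn{p_{13} = p_1} (no estimate of \eqn{\theta_3} exists, and
#' \eqn{H_{0,13}} implies \eqn{\theta_1 \le 0}).
#'
#' @param design An [design_config()] object.
#' @param est1 Estimate(s) of the S1 effect at this stage.
#' @param est2 Estimate(s) of the S2 effect; must be `NULL` exactly when
#'   `stage = 2` and `enriched = TRUE`.
#' @param stage 1 or 2.
#' @param enriched For stage 2: was the stage enriched?
#' @return A tibble with columns `z1`, `z3`, `p1`, `p3`, `p13` (`z3`, `p3`
#'   are `NA` for an enriched stage 2).
#' @export
stage_pvalues <- function(design, est1, est2 = NULL, stage = 1, enriched = FALSE) {
  stopifnot(inherits(design, "enrich_design"), stage %in% c(1, 2))
  if (stage == 1) enriched <- FALSE
  if (enriched && !is.null(est2))
    stop("an enriched stage 2 has no S2 estimate; leave `est2` NULL")
  if (!enriched && is.null(est2))
    stop("`est2` is required unless stage 2 was enriched")
  info <- stage_information(design, stage, enriched)
  z1 <- est1 * sqrt(info[["i1"]])
  p1 <- stats::pnorm(z1, lower.tail = FALSE)
  if (enriched) {
    return(tibble::tibble(z1 = z1, z3 = NA_real_, p1 = p1, p3 = NA_real_,
                          p13 = p1))
  }
  est3 <- theta_full(est1, est2, design$lambda)
  z3 <- est3 * sqrt(info[["i3"]])
  p3 <- stats::pnorm(z3, lower.tail = FALSE)
  tibble::tibble(z1 = z1, z3 = z3, p1 = p1, p3 = p3,
                 p13 = simes_pvalue(p1, p3))
}
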