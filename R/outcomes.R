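#' Closed-test outcome of an adaptive two-stage trial
#'
#' Applies the full closed testing procedure to simulated (or observed)
#' two-stage trials. Stage-wise p-values for \eqn{H_{01}}, \eqn{H_{03}} and
#' the intersection \eqn{H_{0,13}} are merged across stages with the weighted
#' inverse-normal combination; then
#' \itemize{
#'   \item \eqn{H_{01}} is rejected overall iff \eqn{P_1^{(c)} \le \alpha}
#'     and \eqn{P_{13}^{(c)} \le \alpha};
#'   \item \eqn{H_{03}} is rejected overall iff \eqn{P_3^{(c)} \le \alpha}
#'     and \eqn{P_{13}^{(c)} \le \alpha} — and only in trials that did not
#'     enrich, since enrichment forgoes the test of \eqn{H_{03}}.
#' }
#' The indicator `r1` flags trials where \eqn{H_{01}} is rejected but
#' \eqn{H_{03}} is not; `r3` flags rejection of \eqn{H_{03}}. These are the
#' events entering the gain function, so `r1` and `r3` are mutually exclusive.
#'
#' @param data A data frame of trials as produced by [simulate_trials()]:
#'   columns `s1_est1`, `s1_est2`, `decision` (1 enrich / 2 continue),
#'   `s2_est1`, and `s2_est2` (`NA` allowed where `decision == 1`).
#' @param design An [design_config()] object.
#' @return The input tibble with appended columns `p1_c`, `p3_c`, `p13_c`,
#'   `reject_h01`, `reject_h03`, `r1`, `r3`.
#' @export
adaptive_outcome <- function(data, design) {
  stopifnot(inherits(design, "enrich_design"))
  need <- c("s1_est1", "s1_est2", "decision", "s2_est1")
  if (!all(need %in% names(data)))
    stop("`data` must have columns ", paste(need, collapse = ", "))
  enr <- data$decision == 1L
  if (any(!enr) && !("s2_est2" %in% names(data)))
    stop("`s2_est2` required for trials that continued in the full population")
  if (any(!enr & is.na(data$s2_est2 %||% NA_real_)))
    stop("missing `s2_est2` in a trial whose decision was to continue")

  s1 <- stage_pvalues(design, data$s1_est1, data$s1_est2, stage = 1)

  n <- nrow(data)
  p1_2 <- p3_2 <- p13_2 <- rep(NA_real_, n)
  if (any(enr)) {
    e <- stage_pvalues(design, data$s2_est1[enr], NULL, stage = 2,
                       enriched = TRUE)
    p1_2[enr] <- e$p1; p13_2[enr] <- e$p13
  }
  if (any(!enr)) {
    f <- stage_pvalues(design, data$s2_est1[!enr], data$s2_est2[!enr],
                       stage = 2, enriched = FALSE)
    p1_2[!enr] <- f$p1; p3_2[!enr] <- f$p3; p13_2[!enr] <- f$p13
  }

  w1 <- design$w1; w2 <- design$w2; alpha <- design$alpha
  p1_c <- combine_pvalues(s1$p1, p1_2, w1, w2)
  p13_c <- combine_pvalues(s1$p13, p13_2, w1, w2)
  p3_c <- rep(NA_real_, n)
  if (any(!enr))
    p3_c[!enr] <- combine_pvalues(s1$p3[!enr], p3_2[!enr], w1, w2)

  reject_h01 <- p1_c <= alpha & p13_c <= alpha
  reject_h03 <- !enr & !is.na(p3_c) & p3_c <= alpha & p13_c <= alpha
  dplyr::mutate(tibble::as_tibble(data),
                p1_c = p1_c, p3_c = p3_c, p13_c = p13_c,
                reject_h01 = reject_h01, reject_h03 = reject_h03,
                r1 = reject_h01 & !reject_h03, r3 = reject_h03)
}

#' Closed-test outcome of the fixed full-population (FF) design
#'
#' The FF design recruits from the full population throughout and tests both
#' hypotheses once at the end: \eqn{P_1 = 1 - \Phi(\hat\theta_1
#' \sqrt{\lambda\tilde I})}, \eqn{P_3 = 1 - \Phi(\hat\theta_3\sqrt{\tilde I})},
#' \eqn{P_{13}} by Simes, and the same closed-test rejection rules as the
#' adaptive design but with no combination step.
#'
#' @param data A data frame with columns `est1` and `est3` (full-data
#'   estimates, variances \eqn{(\lambda\tilde I)^{-1}} and
#'   \eqn{\tilde I^{-1}}).
#' @param design An [design_config()] object.
#' @return The input tibble with appended `p1`, `p3`, `p13`, `reject_h01`,
#'   `reject_h03`, `r1`, `r3`.
#' @export
ff_outcome <- function(data, design) {
  stopifnot(inherits(design, "enrich_design"),
            all(c("est1", "est3") %in% names(data)))
  I <- design$info; alpha <- design$alpha
  p1 <- stats::pnorm(data$est1 * sqrt(design$lambda * I), lower.tail = FALSE)
  p3 <- stats::pnorm(data$est3 * sqrt(I), lower.tail = FALSE)
  p13 <- simes_pvalue(p1, p3)
  reject_h01 <- p1 <= alpha & p13 <= alpha
  reject_h03 <- p3 <= alpha & p13 <= alpha
  dplyr::mutate(tibble::as_tibble(data),
                p1 = p1, p3 = p3, p13 = p13,
                reject_h01 = reject_h01, reject_h03 = reject_h03,
                r1 = reject_h01 & !reject_h03, r3 = reject_h03)
}

#' Outcome of the fixed subpopulation (FS) design
#'
#' The FS design recruits all `n` patients from S1 and tests only
#' \eqn{H_{01}}: \eqn{P_1 = 1 - \Phi(\hat\theta_1\sqrt{\tilde I})}, rejected
#' iff \eqn{P_1 \le \alpha}. \eqn{H_{03}} is never tested.
#'
#' @param data A data frame with column `est1` (variance
#'   \eqn{\tilde I^{-1}}).
#' @param design An [design_config()] object.
#' @return The input tibble with appended `p1`, `reject_h01`, `reject_h03`
#'   (always `FALSE`), `r1`, `r3`.
#' @export
fs_outcome <- function(data, design) {
  stopifnot(inherits(design, "enrich_design"), "est1" %in% names(data))
  p1 <- stats::pnorm(data$est1 * sqrt(design$info), lower.tail = FALSE)
  reject_h01 <- p1 <= design$alpha
  dplyr::mutate(tibble::as_tibble(data),
                p1 = p1,
                reject_h01 = reject_h01, reject_h03 = FALSE,
                r1 = reject_h01, r3 = FALSE)
}

#' Gain of a completed trial
#'
#' The default gain rewards a positive finding in proportion to the size of
#' the population for which it is made and the true effect there:
#' \deqn{G(\theta, X) = \lambda\theta_1\mathcal{R}_1 + \theta_3\mathcal{R}_3,}
#' where \eqn{\mathcal{R}_1} indicates rejection of \eqn{H_{01}} only and
#' \eqn{\mathcal{R}_3} rejection of \eqn{H_{03}}. A different utility can be
#' supplied through `gain_fn`, a function
#' `(theta1, theta3, r1, r3, lambda) -> numeric` evaluated vectorized.
#'
#' @param theta1,theta3 True effects (vectorized).
#' @param r1,r3 Outcome indicators (logical or 0/1, vectorized).
#' @param design An [design_config()] object (supplies `lambda`).
#' @param gain_fn Optional replacement gain function.
#' @return Numeric gains.
#' @examples
#' d <- design_config(info = 0.105)
#' evaluate_gain(10, 6, r1 = 1, r3 = 0, design = d) # lambda * theta1 = 5
#' @export
evaluate_gain <- function(theta1, theta3, r1, r3, design, gain_fn = NULL) {
  if (!is.null(gain_fn))
    return(gain_fn(theta1, theta3, r1, r3, design$lambda))
  design$lambda * theta1 * as.numeric(r1) + theta3 * as.numeric(r3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
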