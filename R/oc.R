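#' Operating characteristics of an optimized adaptive enrichment design
#'
#' Simulates the full design `n_rep` times: draw \eqn{\theta} from the prior,
#' simulate stage-1 estimates, take the enrichment decision from the
#' precomputed `rule`, simulate stage 2 under that decision, apply the closed
#' testing procedure, and evaluate the gain. One stage-2 dataset is generated
#' per replicate.
#'
#' @param rule An `enrich_rule` from [build_boundary()] (or any rule accepted
#'   by [simulate_trials()], e.g. `"never"` for stress tests).
#' @param prior An `enrich_prior` from which the true effects are drawn each
#'   replicate (a point prior fixes them).
#' @param design An [design_config()] object.
#' @param n_rep Number of simulated trials \eqn{N}.
#' @param gain_fn Optional custom gain function (see [evaluate_gain()]).
#' @return A one-row tibble with columns `design` (`"AE"`), `p_r1`
#'   (probability that only \eqn{H_{01}} is rejected), `p_r3` (probability
#'   that \eqn{H_{03}} is rejected), `p_enrich`, `e_gain`, their standard
#'   errors, and `n_reps`.
#' @export
evaluate_adaptive <- function(rule, prior, design, n_rep = 1e5, gain_fn = NULL) {
  stopifnot(inherits(prior, "enrich_prior"), inherits(design, "enrich_design"),
            n_rep >= 1)
  th <- sample_effects(prior, n_rep)
  trials <- simulate_trials(design, th$theta1, th$theta2, rule)
  out <- adaptive_outcome(trials, design)
  g <- evaluate_gain(out$theta1, out$theta3, out$r1, out$r3, design, gain_fn)
  oc_row("AE", out$r1, out$r3, g, n_rep, p_enrich = mean(out$decision == 1L))
}

#' Operating characteristics of the fixed full-population (FF) design
#'
#' Draws \eqn{\theta} from the prior each replicate, then the full-data
#' estimates \eqn{\hat\theta_1 \sim N(\theta_1, (\lambda\tilde I)^{-1})} and
#' \eqn{\hat\theta_2 \sim N(\theta_2, ((1-\lambda)\tilde I)^{-1})}
#' independently, forming \eqn{\hat\theta_3} as the \eqn{\lambda}-weighted
#' sum (which yields the exact joint law of \eqn{(\hat\theta_1, \hat\theta_3)},
#' correlation \eqn{\sqrt{\lambda}}, by construction), and applies
#' [ff_outcome()].
#'
#' @inheritParams evaluate_adaptive
#' @return A one-row tibble as for [evaluate_adaptive()]; `p_enrich` is `NA`.
#' @export
evaluate_ff <- function(prior, design, n_rep = 1e5, gain_fn = NULL) {
  stopifnot(inherits(prior, "enrich_prior"), inherits(design, "enrich_design"),
            n_rep >= 1)
  th <- sample_effects(prior, n_rep)
  I <- design$info; la <- design$lambda
  est1 <- stats::rnorm(n_rep, th$theta1, 1 / sqrt(la * I))
  est2 <- stats::rnorm(n_rep, th$theta2, 1 / sqrt((1 - la) * I))
  dat <- tibble::tibble(est1 = est1, est3 = theta_full(est1, est2, la))
  out <- ff_outcome(dat, design)
  theta3 <- theta_full(th$theta1, th$theta2, la)
  g <- evaluate_gain(th$theta1, theta3, out$r1, out$r3, design, gain_fn)
  oc_row("FF", out$r1, out$r3, g, n_rep)
}

#' Operating characteristics of the fixed subpopulation (FS) design
#'
#' Fully analytic: \eqn{P(\mathcal{R}_1 \mid \theta_1) =
#' \Phi(\theta_1\sqrt{\tilde I} - \Phi^{-1}(1-\alpha))}. For a point prior
#' this is plugged in directly; for a normal prior both
#' \eqn{P(\mathcal{R}_1)} and \eqn{E\{G\} = \lambda E[\theta_1
#' P(\mathcal{R}_1 \mid \theta_1)]} are obtained by adaptive 1-D quadrature
#' over the \eqn{\theta_1} marginal. \eqn{H_{03}} is never tested, so
#' `p_r3 = 0` and all standard errors are zero.
#'
#' @inheritParams evaluate_adaptive
#' @return A one-row tibble as for [evaluate_adaptive()] with `design =
#'   "FS"`, zero standard errors, and `n_reps = NA`.
#' @export
evaluate_fs <- function(prior, design) {
  stopifnot(inherits(prior, "enrich_prior"), inherits(design, "enrich_design"))
  I <- design$info; la <- design$lambda
  z_alpha <- stats::qnorm(1 - design$alpha)
  p_rej <- function(t1) stats::pnorm(t1 * sqrt(I) - z_alpha)
  if (prior$kind == "point" || prior$cov[1, 1] == 0) {
    t1 <- prior$mu[1]
    p_r1 <- p_rej(t1)
    e_gain <- la * t1 * p_r1
  } else {
    mu <- prior$mu[1]; sd <- sqrt(prior$cov[1, 1])
    q1 <- stats::integrate(function(t) p_rej(t) * stats::dnorm(t, mu, sd),
                           -Inf, Inf, rel.tol = 1e-10)
    q2 <- stats::integrate(function(t) t * p_rej(t) * stats::dnorm(t, mu, sd),
                           -Inf, Inf, rel.tol = 1e-10)
    if (q1$message != "OK" || q2$message != "OK")
      stop("FS quadrature did not converge: ", q1$message, " / ", q2$message)
    p_r1 <- q1$value
    e_gain <- la * q2$value
  }
  tibble::tibble(design = "FS", p_r1 = p_r1, p_r3 = 0, p_enrich = NA_real_,
                 e_gain = e_gain, se_r1 = 0, se_r3 = 0, se_enrich = NA_real_,
                 se_gain = 0, n_reps = NA_integer_)
}

oc_row <- function(label, r1, r3, g, n_rep, p_enrich = NA_real_) {
  tibble::tibble(
    design = label,
    p_r1 = mean(r1), p_r3 = mean(r3), p_enrich = p_enrich,
    e_gain = mean(g),
    se_r1 = sqrt(mean(r1) * (1 - mean(r1)) / n_rep),
    se_r3 = sqrt(mean(r3) * (1 - mean(r3)) / n_rep),
    se_enrich = if (is.na(p_enrich)) NA_real_ else
      sqrt(p_enrich * (1 - p_enrich) / n_rep),
    se_gain = stats::sd(g) / sqrt(n_rep),
    n_reps = as.integer(n_rep)
  )
}

#' Compare the three designs under one prior
#'
#' Convenience wrapper running [evaluate_fs()], [evaluate_ff()] and — when a
#' rule is supplied or `build = TRUE` — [evaluate_adaptive()], returning one
#' tidy table.
#'
#' @inheritParams evaluate_adaptive
#' @param rule Optional prebuilt `enrich_rule`; built on the fly when `NULL`
#'   and `build = TRUE`.
#' @param build Build the AE rule if missing.
#' @param m,cells_per_side,seed Passed to [build_boundary()] when building.
#' @return A tibble with one row per evaluated design.
#' @export
compare_designs <- function(prior, design, n_rep = 1e5, rule = NULL,
                            build = TRUE, m = 1e5, cells_per_side = 128,
                            seed = NULL) {
  rows <- list(evaluate_fs(prior, design), evaluate_ff(prior, design, n_rep))
  if (is.null(rule) && build)
    rule <- build_boundary(design, prior, m = m,
                           cells_per_side = cells_per_side, seed = seed)
  if (!is.null(rule))
    rows <- c(rows, list(evaluate_adaptive(rule, prior, design, n_rep)))
  dplyr::bind_rows(rows)
}

#' Which design wins at each true effect pair?
#'
#' For every point \eqn{\theta_0} of a grid, evaluates the FS design
#' analytically, the FF design by Monte Carlo, and the adaptive design
#' optimized for the one-point prior at \eqn{\theta_0} (boundary built per
#' point), and labels the point with the design of highest estimated expected
#' gain. Designs whose gains are within two combined standard errors of the
#' best are flagged as statistical ties and included in the label
#' (slash-separated).
#'
#' @param theta1,theta2 Vectors defining the grid points (paired, not
#'   crossed).
#' @param design An [design_config()] object.
#' @param n_rep Replicates for the FF and AE evaluations.
#' @param m,cells_per_side Boundary-build controls.
#' @param seed Root seed; per-point seeds are derived from it.
#' @return A tibble with `theta1`, `theta2`, `gain_fs`, `gain_ff`, `gain_ae`,
#'   `winner`.
#' @export
best_design_map <- function(theta1, theta2, design, n_rep = 1e5, m = 1e5,
                            cells_per_side = 64, seed = NULL) {
  stopifnot(length(theta1) == length(theta2))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  dplyr::bind_rows(purrr::map2(theta1, theta2, function(t1, t2) {
    pr <- prior_point(t1, t2)
    pt_seed <- vertex_seed(seed, round(1e3 * t1), round(1e3 * t2))
    set.seed(pt_seed)
    fs <- evaluate_fs(pr, design)
    ff <- evaluate_ff(pr, design, n_rep)
    rule <- build_boundary(design, pr, m = m, cells_per_side = cells_per_side,
                           seed = pt_seed)
    set.seed(pt_seed + 1)
    ae <- evaluate_adaptive(rule, pr, design, n_rep)
    all <- dplyr::bind_rows(fs, ff, ae)
    best <- which.max(all$e_gain)
    tied <- abs(all$e_gain - all$e_gain[best]) <=
      2 * sqrt(all$se_gain^2 + all$se_gain[best]^2)
    tibble::tibble(theta1 = t1, theta2 = t2,
                   gain_fs = fs$e_gain, gain_ff = ff$e_gain,
                   gain_ae = ae$e_gain,
                   winner = paste(all$design[tied], collapse = "/"))
  }))
}

#' Sweep a design or prior parameter across the three designs
#'
#' Re-optimizes the adaptive rule and re-evaluates all requested designs for
#' each value of the swept parameter: `"tau"` (interim timing), `"lambda"`
#' (subpopulation fraction), or `"prior_var"` (common prior variance of both
#' effects, keeping the prior correlation).
#'
#' @param design Baseline [design_config()].
#' @param prior Baseline `enrich_prior`.
#' @param param One of `"tau"`, `"lambda"`, `"prior_var"`.
#' @param values Values to sweep over; invalid values are skipped with a
#'   warning.
#' @param designs Subset of `c("FS", "FF", "AE")` to evaluate.
#' @param n_rep Replicates for MC evaluations.
#' @param m,cells_per_side Boundary-build controls for AE.
#' @param seed Root seed; per-value seeds are derived from it.
#' @return A tibble with one row per value per design, columns `param`,
#'   `value` plus the [evaluate_adaptive()] columns.
#' @export
oc_sweep <- function(design, prior, param = c("tau", "lambda", "prior_var"),
                     values, designs = c("FS", "FF", "AE"), n_rep = 1e5,
                     m = 1e5, cells_per_side = 64, seed = NULL) {
  param <- match.arg(param)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  dplyr::bind_rows(purrr::imap(values, function(v, idx) {
    scen <- tryCatch(sweep_scenario(design, prior, param, v),
                     error = function(e) {
                       warning("skipping ", param, " = ", v, ": ",
                               conditionMessage(e))
                       NULL
                     })
    if (is.null(scen)) return(NULL)
    set.seed(vertex_seed(seed, idx, 0L))
    rows <- list()
    if ("FS" %in% designs) rows <- c(rows, list(evaluate_fs(scen$prior, scen$design)))
    if ("FF" %in% designs) rows <- c(rows, list(evaluate_ff(scen$prior, scen$design, n_rep)))
    if ("AE" %in% designs) {
      rule <- build_boundary(scen$design, scen$prior, m = m,
                             cells_per_side = cells_per_side,
                             seed = vertex_seed(seed, idx, 1L))
      set.seed(vertex_seed(seed, idx, 2L))
      rows <- c(rows, list(evaluate_adaptive(rule, scen$prior, scen$design, n_rep)))
    }
    dplyr::mutate(dplyr::bind_rows(rows), param = param, value = v,
                  .before = 1)
  }))
}

sweep_scenario <- function(design, prior, param, value) {
  if (param == "tau") {
    design <- design_config(lambda = design$lambda, tau = value,
                            alpha = design$alpha, info = design$info)
  } else if (param == "lambda") {
    design <- design_config(lambda = value, tau = design$tau,
                            alpha = design$alpha, info = design$info)
  } else {
    rho <- if (prior$kind == "point" || any(diag(prior$cov) == 0)) 0 else
      prior$cov[1, 2] / sqrt(prior$cov[1, 1] * prior$cov[2, 2])
    prior <- if (value == 0) prior_point(prior$mu[1], prior$mu[2]) else
      prior_normal(prior$mu[1], prior$mu[2], value, value, rho)
  }
  list(design = design, prior = prior)
}
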