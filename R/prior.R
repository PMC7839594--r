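#' Prior distributions for the treatment-effect pair
#'
#' `prior_point()` places probability 1 on a single effect pair
#' \eqn{\theta_0 = (\theta_{0,1}, \theta_{0,2})}; the Bayes rule then adapts
#' only to sampling variability, not parameter uncertainty. `prior_normal()`
#' is the bivariate normal prior
#' \deqn{(\theta_1, \theta_2) \sim N_2\!\left((\mu_1, \mu_2),
#'   \begin{pmatrix}\sigma_1^2 & \rho\sigma_1\sigma_2\\
#'   \rho\sigma_1\sigma_2 & \sigma_2^2\end{pmatrix}\right).}
#' Variances may be zero (that component is then treated as known, and the
#' correlation must be zero); `var1 = var2 = 0` is equivalent to a point
#' prior.
#'
#' @param theta1,theta2 Point-prior effects.
#' @param mu1,mu2 Prior means.
#' @param var1,var2 Prior variances (>= 0).
#' @param rho Prior correlation, |rho| < 1 (ignored with a warning if either
#'   variance is zero and `rho != 0`).
#' @return An object of class `enrich_prior`.
#' @examples
#' prior_point(10, 2)
#' prior_normal(10, 2, 25, 25, 0.75)
#' @export
prior_point <- function(theta1, theta2) {
  stopifnot(is.numeric(theta1), length(theta1) == 1L,
            is.numeric(theta2), length(theta2) == 1L,
            is.finite(theta1), is.finite(theta2))
  structure(list(kind = "point", mu = c(theta1, theta2),
                 cov = matrix(0, 2, 2)),
            class = "enrich_prior")
}

#' @rdname prior_point
#' @export
prior_normal <- function(mu1, mu2, var1, var2, rho = 0) {
  stopifnot(is.numeric(var1), var1 >= 0, is.numeric(var2), var2 >= 0,
            is.numeric(rho), abs(rho) < 1)
  if ((var1 == 0 || var2 == 0) && rho != 0) {
    warning("`rho` ignored: a zero-variance component cannot be correlated")
    rho <- 0
  }
  if (var1 == 0 && var2 == 0) return(prior_point(mu1, mu2))
  cv <- rho * sqrt(var1 * var2)
  structure(list(kind = "bvn", mu = c(mu1, mu2),
                 cov = matrix(c(var1, cv, cv, var2), 2, 2)),
            class = "enrich_prior")
}

#' @export
print.enrich_prior <- function(x, ...) {
  if (x$kind == "point") {
    cat(sprintf("<enrich_prior> point mass at (%g, %g)\n", x$mu[1], x$mu[2]))
  } else {
    cat(sprintf("<enrich_prior> bivariate normal, mu = (%g, %g), var = (%g, %g), rho = %.3g\n",
                x$mu[1], x$mu[2], x$cov[1, 1], x$cov[2, 2],
                x$cov[1, 2] / sqrt(x$cov[1, 1] * x$cov[2, 2])))
  }
  invisible(x)
}

#' Conjugate posterior of the effects given the interim estimates
#'
#' The stage-1 estimates are, given \eqn{\theta}, independent normals with
#' precisions \eqn{\lambda\tau\tilde I} and \eqn{(1-\lambda)\tau\tilde I}, so
#' for a bivariate normal prior the posterior is again bivariate normal with
#' precision = prior precision + data precision and mean = posterior
#' covariance x (prior precision x prior mean + data precision x estimates).
#' This update is exact (the likelihood itself is bivariate normal). A point
#' prior is returned unchanged, and a component with zero prior variance
#' stays fixed while the other is updated by the corresponding 1-D conjugate
#' formula.
#'
#' @param prior An [prior_point()] or [prior_normal()] object.
#' @param est1,est2 Interim effect estimates \eqn{\hat\theta_1^{(1)}},
#'   \eqn{\hat\theta_2^{(1)}} (scalars).
#' @param design An [design_config()] object.
#' @return An `enrich_prior` (the posterior; bivariate-normal form, or point).
#' @examples
#' d <- design_config(n = 264, sigma = 25)
#' posterior_update(prior_normal(10, 2, 25, 25, 0.75), 8, 3, d)
#' @export
posterior_update <- function(prior, est1, est2, design) {
  stopifnot(inherits(prior, "enrich_prior"), inherits(design, "enrich_design"))
  if (prior$kind == "point") return(prior)
  info <- stage_information(design, 1L)
  prec_data <- diag(c(info[["i1"]], (1 - design$lambda) * design$tau * design$info))
  v1 <- prior$cov[1, 1]; v2 <- prior$cov[2, 2]
  if (v1 == 0 || v2 == 0) {
    # one component known: 1-D conjugate update of the other
    mu <- prior$mu; cov <- prior$cov
    j <- if (v1 == 0) 2L else 1L
    x <- c(est1, est2)[j]
    post_prec <- 1 / cov[j, j] + prec_data[j, j]
    mu[j] <- (mu[j] / cov[j, j] + prec_data[j, j] * x) / post_prec
    cov[j, j] <- 1 / post_prec
    return(structure(list(kind = "bvn", mu = mu, cov = cov),
                     class = "enrich_prior"))
  }
  prec_prior <- solve(prior$cov)
  post_cov <- solve(prec_prior + prec_data)
  post_mu <- drop(post_cov %*% (prec_prior %*% prior$mu +
                                  prec_data %*% c(est1, est2)))
  structure(list(kind = "bvn", mu = post_mu, cov = (post_cov + t(post_cov)) / 2),
            class = "enrich_prior")
}

#' Sample effect pairs from a prior or posterior
#'
#' For a point distribution this is `m` copies of the point. For the
#' bivariate-normal form draws use the lower Cholesky factor of the
#' covariance (fixed factorization order, so a given seed reproduces draws
#' exactly); a zero-variance component is held constant.
#'
#' @param dist An `enrich_prior` (prior or posterior).
#' @param m Number of draws (>= 1).
#' @return A tibble with `m` rows and columns `theta1`, `theta2`.
#' @export
sample_effects <- function(dist, m) {
  stopifnot(inherits(dist, "enrich_prior"), m >= 1)
  if (dist$kind == "point") {
    return(tibble::tibble(theta1 = rep(dist$mu[1], m),
                          theta2 = rep(dist$mu[2], m)))
  }
  L <- chol_lower(dist$cov)
  z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
  tibble::tibble(
    theta1 = dist$mu[1] + L[1, 1] * z1,
    theta2 = dist$mu[2] + L[2, 1] * z1 + L[2, 2] * z2
  )
}

# Lower Cholesky of a 2x2 PSD matrix, tolerating zero diagonal entries.
chol_lower <- function(S) {
  l11 <- sqrt(S[1, 1])
  l21 <- if (l11 > 0) S[2, 1] / l11 else 0
  l22 <- sqrt(max(S[2, 2] - l21^2, 0))
  matrix(c(l11, l21, 0, l22), 2, 2)
}

# Marginal mean / SD helpers used for boundary-region sizing.
prior_predictive_stage1 <- function(prior, design) {
  info <- stage_information(design, 1L)
  v1 <- prior$cov[1, 1] + 1 / info[["i1"]]
  v2 <- prior$cov[2, 2] + 1 / ((1 - design$lambda) * design$tau * design$info)
  list(mean = prior$mu, sd = c(sqrt(v1), sqrt(v2)))
}
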