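# Shared designs, priors and oracles for the test suite.

design_105 <- function(...) design_config(info = 0.105, ...)
design_264 <- function(...) design_config(n = 264, sigma = 25, ...)

# Memoised cache for expensive decision-rule builds so several test blocks
# can share one rule. Builds use reduced (but still informative) sizes:
# M posterior draws per vertex and a 64-cell fine grid.
.rule_cache <- new.env(parent = emptyenv())

cached_rule <- function(key, design, prior, m = 2e4, cells_per_side = 64,
                        seed = 20260922) {
  hit <- .rule_cache[[key]]
  if (!is.null(hit)) return(hit)
  rule <- build_boundary(design, prior, m = m, cells_per_side = cells_per_side,
                         seed = seed)
  .rule_cache[[key]] <- rule
  rule
}

# Bivariate normal density (closed form) for the grid-posterior oracle.
dbvn <- function(x, y, mu, S) {
  rho <- S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  sx <- sqrt(S[1, 1]); sy <- sqrt(S[2, 2])
  zx <- (x - mu[1]) / sx; zy <- (y - mu[2]) / sy
  q <- (zx^2 - 2 * rho * zx * zy + zy^2) / (1 - rho^2)
  exp(-q / 2) / (2 * pi * sx * sy * sqrt(1 - rho^2))
}

# Semi-analytic quadrature oracles for expected gains over a pair of
# independent normal estimates (e1, e2). Conditional on e1, every rejection
# event is a monotone step function of e2 (p3 falls and the Simes p-value is
# non-increasing in e2), so the inner expectation over e2 is exact given the
# step locations, which a bisection on the outcome function finds to ~1e-9.
# Only the outer integral over e1 is numeric, split at the discontinuity
# where rejection of H01 switches on.

# vectorized bisection: for each row, the smallest e2 at which pred flips to
# TRUE (pred takes an e2 vector, one entry per row); -Inf/Inf when constant
e2_threshold_vec <- function(pred, n, lo = -1e4, hi = 1e4, iter = 40) {
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  at_lo <- pred(lo); at_hi <- pred(hi)
  for (k in seq_len(iter)) {
    mid <- (lo + hi) / 2
    r <- pred(mid)
    hi[r] <- mid[r]
    lo[!r] <- mid[!r]
  }
  out <- (lo + hi) / 2
  out[at_lo] <- -Inf
  out[!at_hi] <- Inf
  out
}

# shared outer integration: E[gain] with e1 ~ N(mu1, sd1), e2 ~ N(mu2, sd2),
# `cond(e1_vec)` returning list(rej1, t13, t3) vectors of the e2 step
# locations, and `split1` the discontinuity of rej1 in e1.
gain_threshold_oracle <- function(cond, split1, mu1, sd1, mu2, sd2,
                                  lambda, theta1, theta3) {
  f <- function(v) {
    th <- cond(v)
    # th$t13: step of reject_h01 (defined only where rej1 can occur);
    # th$t3: step of reject_h03 (includes the intersection requirement and
    # therefore is >= th$t13 whenever both are finite)
    p13 <- pnorm(th$t13, mu2, sd2, lower.tail = FALSE)
    p_r3 <- pnorm(th$t3, mu2, sd2, lower.tail = FALSE)
    g <- ifelse(th$rej1, lambda * theta1 * (p13 - p_r3) + theta3 * p_r3,
                theta3 * p_r3)
    g * dnorm(v, mu1, sd1)
  }
  lims <- unique(sort(c(mu1 - 9 * sd1,
                        pmin(pmax(split1, mu1 - 9 * sd1), mu1 + 9 * sd1),
                        mu1 + 9 * sd1)))
  total <- 0
  for (k in seq_len(length(lims) - 1)) {
    total <- total + integrate(f, lims[k], lims[k + 1], rel.tol = 2e-5,
                               subdivisions = 200L)$value
  }
  total
}

# Oracle for the expected gain of the FF design at a point theta.
ff_gain_quadrature <- function(design, theta1, theta2) {
  la <- design$lambda; I <- design$info
  sd1 <- 1 / sqrt(la * I); sd2 <- 1 / sqrt((1 - la) * I)
  cond <- function(e1) {
    n <- length(e1)
    out_at <- function(e2) suppressWarnings(
      ff_outcome(tibble::tibble(est1 = e1,
                                est3 = theta_full(e1, e2, la)), design))
    rej1 <- out_at(rep(-1e4, n))$p1 <= design$alpha
    t13 <- e2_threshold_vec(function(e2) out_at(e2)$reject_h01, n)
    t13[!rej1] <- Inf
    t3 <- e2_threshold_vec(function(e2) out_at(e2)$reject_h03, n)
    list(rej1 = rej1, t13 = t13, t3 = t3)
  }
  split1 <- qnorm(1 - design$alpha) / sqrt(la * I)
  gain_threshold_oracle(cond, split1, theta1, sd1, theta2, sd2,
                        la, theta1, theta_full(theta1, theta2, la))
}

# Oracle for the conditional expected gain of continuing, at a fixed interim
# observation and point posterior.
continue_gain_quadrature <- function(design, est1, est2, theta1, theta2) {
  la <- design$lambda; ta <- design$tau; I <- design$info
  sd1 <- 1 / sqrt(la * (1 - ta) * I); sd2 <- 1 / sqrt((1 - la) * (1 - ta) * I)
  cond <- function(e1) {
    n <- length(e1)
    out_at <- function(e2) suppressWarnings(adaptive_outcome(
      tibble::tibble(s1_est1 = est1, s1_est2 = est2, decision = 2L,
                     s2_est1 = e1, s2_est2 = e2), design))
    rej1 <- out_at(rep(-1e4, n))$p1_c <= design$alpha
    t13 <- e2_threshold_vec(function(e2) out_at(e2)$reject_h01, n)
    t13[!rej1] <- Inf
    t3 <- e2_threshold_vec(function(e2) out_at(e2)$reject_h03, n)
    list(rej1 = rej1, t13 = t13, t3 = t3)
  }
  # e1 value where the combined z for H01 crosses its critical value
  s1 <- stage_pvalues(design, est1, est2, stage = 1)
  split1 <- (qnorm(1 - design$alpha) - design$w1 * s1$z1) / design$w2 /
    sqrt(la * (1 - ta) * I)
  gain_threshold_oracle(cond, split1, theta1, sd1, theta2, sd2,
                        la, theta1, theta_full(theta1, theta2, la))
}

# Bisection oracle for the post-enrichment rejection threshold kappa(x1):
# smallest stage-2 estimate for which the closed test rejects H01.
# Vectorized over interim observations.
kappa_bisection <- function(design, est1, est2, lo = -200, hi = 500,
                            iter = 50) {
  rejects <- function(x) {
    # extreme probes drive stage-2 p-values to the clamped tails by design
    suppressWarnings(adaptive_outcome(
      tibble::tibble(s1_est1 = est1, s1_est2 = est2, decision = 1L,
                     s2_est1 = x, s2_est2 = NA_real_),
      design))$reject_h01
  }
  lo <- rep_len(lo, length(est1))
  hi <- rep_len(hi, length(est1))
  stopifnot(!any(rejects(lo)), all(rejects(hi)))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    r <- rejects(mid)
    hi[r] <- mid[r]
    lo[!r] <- mid[!r]
  }
  (lo + hi) / 2
}
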