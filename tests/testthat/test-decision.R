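test_that("kappa matches its closed form and is monotone in the interim data", {
  d <- design_105()
  # neutral interim data: z1 = z13 = 0
  expect_equal(critical_value(d, 0, 0), qnorm(0.975) * sqrt(2) / sqrt(0.0525),
               tolerance = 1e-10)
  # more promising interim data never raise the threshold
  ks <- critical_value(d, seq(-10, 20, by = 0.5), 3)
  expect_true(all(diff(ks) <= 1e-10))
  expect_error(critical_value(design_config(info = 0.105, w1 = 1, w2 = 0),
                              0, 0),
               "w2 = 0")
})

test_that("kappa agrees with a bisection search over the closed test", {
  d <- design_105()
  set.seed(14)
  e1 <- rnorm(100, 5, 8); e2 <- rnorm(100, 2, 8)
  kappa <- critical_value(d, e1, e2)
  oracle <- kappa_bisection(d, e1, e2)
  expect_equal(kappa, oracle, tolerance = 1e-6)
  # and the threshold is sharp: reject at kappa, not just below
  out_at <- adaptive_outcome(
    tibble::tibble(s1_est1 = e1, s1_est2 = e2, decision = 1L,
                   s2_est1 = kappa + 1e-9, s2_est2 = NA_real_), d)
  out_below <- adaptive_outcome(
    tibble::tibble(s1_est1 = e1, s1_est2 = e2, decision = 1L,
                   s2_est1 = kappa - 1e-6, s2_est2 = NA_real_), d)
  expect_true(all(out_at$reject_h01))
  expect_true(!any(out_below$reject_h01))
})

test_that("kappa holds under varied weights, tau and alpha", {
  set.seed(15)
  for (i in 1:10) {
    ta <- runif(1, 0.2, 0.8)
    d <- design_config(lambda = runif(1, 0.3, 0.7), tau = ta,
                       alpha = runif(1, 0.01, 0.1), info = runif(1, 0.05, 0.3))
    e1 <- rnorm(1, 5, 8); e2 <- rnorm(1, 2, 8)
    expect_equal(critical_value(d, e1, e2), kappa_bisection(d, e1, e2),
                 tolerance = 1e-6)
  }
})

test_that("expected enrichment gain matches hand values and the MC oracle", {
  d <- design_105()
  # theta1 = 0 kills the gain regardless of the data
  expect_equal(expected_gain_enrich(d, 3, -4,
                                    tibble::tibble(theta1 = 0, theta2 = 7))$gain,
               0)
  # single-point sample at (10, 2) with neutral interim data
  g <- expected_gain_enrich(d, 0, 0, tibble::tibble(theta1 = 10, theta2 = 2))
  kappa <- critical_value(d, 0, 0)
  expect_equal(g$gain, 5 * (1 - pnorm((kappa - 10) * sqrt(0.0525))),
               tolerance = 1e-10)
  expect_equal(g$se, 0)

  # analytic stage-2 probability vs brute-force stage-2 simulation
  set.seed(41)
  for (i in 1:10) {
    e1 <- rnorm(1, 6, 6); e2 <- rnorm(1, 2, 6)
    th <- sample_effects(
      posterior_update(prior_normal(10, 2, 25, 25, 0.75), e1, e2, d), 200)
    analytic <- expected_gain_enrich(d, e1, e2, th)
    n2 <- 1e5
    idx <- sample.int(nrow(th), n2, replace = TRUE)
    s2 <- simulate_stage2(d, th$theta1[idx], th$theta2[idx], enrich = TRUE)
    out <- adaptive_outcome(
      tibble::tibble(s1_est1 = e1, s1_est2 = e2, decision = 1L,
                     s2_est1 = s2$est1, s2_est2 = NA_real_), d)
    g_mc <- evaluate_gain(th$theta1[idx], 0, out$r1, FALSE, d)
    se_mc <- sd(g_mc) / sqrt(n2)
    expect_lt(abs(analytic$gain - mean(g_mc)), 3 * (se_mc + analytic$se))
  }
})

test_that("expected continuation gain matches limits and the quadrature oracle", {
  d <- design_105()
  set.seed(51)
  # hopeless effects: nothing is ever rejected
  th_neg <- tibble::tibble(theta1 = rep(-50, 500), theta2 = rep(-50, 500))
  expect_equal(expected_gain_continue(d, 0, 0, th_neg)$gain, 0)
  # decisive stage-1 data with theta = (10, 10): H03 essentially certain,
  # gain converges to theta3 = 10
  th_pos <- tibble::tibble(theta1 = rep(10, 2000), theta2 = rep(10, 2000))
  g <- expected_gain_continue(d, 60, 60, th_pos)
  expect_equal(g$gain, 10, tolerance = 0.05)

  # point-posterior MC vs a semi-analytic quadrature of the exact
  # rejection-region gain
  for (i in 1:3) {
    e1 <- rnorm(1, 8, 5); e2 <- rnorm(1, 2, 5)
    t1 <- rnorm(1, 10, 3); t2 <- rnorm(1, 3, 3)
    m <- 4e4
    th <- tibble::tibble(theta1 = rep(t1, m), theta2 = rep(t2, m))
    mc <- expected_gain_continue(d, e1, e2, th)
    quad <- continue_gain_quadrature(d, e1, e2, t1, t2)
    expect_lt(abs(mc$gain - quad), 3 * mc$se + 1e-3)
  }
})

test_that("the Bayes decision maximizes the conditional expected gain", {
  d <- design_105()
  # very strong interim data with a positive prior: continuing dominates
  # (H03 almost surely rejected, worth theta3 > lambda*theta1)
  set.seed(61)
  dec <- decide_enrichment(d, prior_point(10, 10), 40, 40, m = 5000)
  expect_identical(dec$decision, 2L)
  expect_gt(dec$gain_continue, dec$gain_enrich)
  # subpopulation-only signal: enrichment wins
  dec <- decide_enrichment(d, prior_point(10, 2), 10, -8, m = 5000)
  expect_identical(dec$decision, 1L)
  # exact tie goes to continuing
  dec0 <- decide_enrichment(d, prior_point(-50, -50), 0, 0, m = 100)
  expect_identical(dec0$decision, 2L)
  expect_equal(dec0$gain_enrich, dec0$gain_continue)
})

test_that("the decision is bit-reproducible for a fixed seed", {
  d <- design_105()
  pr <- prior_normal(10, 2, 25, 25, 0.75)
  set.seed(77)
  a <- decide_enrichment(d, pr, 6, 1, m = 2000)
  set.seed(77)
  b <- decide_enrichment(d, pr, 6, 1, m = 2000)
  expect_identical(a, b)
})

test_that("negative gains require a negative effect with a rejection", {
  d <- design_105()
  set.seed(71)
  # adversarial: true effects straddle zero
  trials <- simulate_trials(d, rnorm(5000, 0, 6), rnorm(5000, 0, 6), "random")
  out <- adaptive_outcome(trials, d)
  g <- evaluate_gain(out$theta1, out$theta3, out$r1, out$r3, d)
  neg <- g < 0
  expect_true(all((out$theta1[neg] < 0 & out$r1[neg]) |
                    (out$theta3[neg] < 0 & out$r3[neg])))
})
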