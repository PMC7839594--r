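test_that("a constant-decision prior yields exactly four cells", {
  d <- design_105()
  # far-positive point prior: continuing is optimal everywhere in A
  rule <- build_boundary(d, prior_point(50, 50), m = 500,
                         cells_per_side = 16, seed = 7)
  expect_identical(nrow(rule$cells), 4L)
  expect_true(all(rule$cells$decision == 2L))
  expect_true(all(rule$cells$unanimous))
})

test_that("cells tile the region exactly and respect the dyadic geometry", {
  d <- design_105()
  rule <- cached_rule("pt-10-2", d, prior_point(10, 2))
  expect_equal(sum(rule$cells$size^2), rule$n_fine^2)   # exact tiling
  expect_true(all(rule$cells$size >= 1))
  expect_true(all(bitwAnd(rule$cells$size, rule$cells$size - 1L) == 0L))
  # no overlap: the raster was filled once per fine cell
  expect_false(anyNA(rule$raster))
  # unanimous cells carry the decision their four cached vertices agreed on
  expect_gt(mean(rule$cells$unanimous), 0.5)
})

test_that("region A holds at least 1 - 1e-6 of the predictive mass", {
  d <- design_105()
  pr <- prior_normal(10, 2, 25, 25, 0.75)
  pp <- adaptenrich:::prior_predictive_stage1(pr, d)
  rule <- cached_rule("bvn-10-2", d, pr)
  cover <- adaptenrich:::region_coverage(
    pp, c(rule$x0, rule$x0 + rule$side), c(rule$y0, rule$y0 + rule$side))
  expect_gte(cover, 1 - 1e-6)
  # a deliberately undersized region warns with the achieved coverage
  expect_warning(
    build_boundary(d, prior_point(50, 50), m = 200, cells_per_side = 4,
                   half_width_sd = 2, seed = 1),
    "prior-predictive mass")
})

test_that("lookup uses half-open cells and nearest-cell extrapolation", {
  d <- design_105()
  rule <- cached_rule("pt-10-2", d, prior_point(10, 2))
  # a cell's lower-left corner belongs to that cell
  cell <- rule$cells[5, ]
  x <- rule$x0 + cell$i0 * rule$min_cell
  y <- rule$y0 + cell$j0 * rule$min_cell
  expect_identical(lookup_decision(rule, x, y), cell$decision)
  # deep inside a recorded cell the lookup returns its decision
  xc <- x + cell$size * rule$min_cell / 2
  yc <- y + cell$size * rule$min_cell / 2
  expect_identical(lookup_decision(rule, xc, yc), cell$decision)
  # far outside A: decision of the nearest boundary cell
  far <- lookup_decision(rule, rule$x0 + rule$side / 2, rule$y0 + 1e6)
  top_mid <- lookup_decision(rule, rule$x0 + rule$side / 2,
                             rule$y0 + rule$side - rule$min_cell / 2)
  expect_identical(far, top_mid)
  # the far-positive corner of this prior's plane is continue territory
  expect_identical(lookup_decision(rule, 1e4, 1e4), 2L)
})

test_that("the mapped rule agrees with fresh high-precision decisions", {
  d <- design_105()
  pr <- prior_point(10, 2)
  rule <- cached_rule("pt-10-2", d, pr)
  set.seed(123)
  # random interim points drawn over the central region of A
  n_pt <- 60
  x <- runif(n_pt, rule$x0 + 0.25 * rule$side, rule$x0 + 0.75 * rule$side)
  y <- runif(n_pt, rule$y0 + 0.25 * rule$side, rule$y0 + 0.75 * rule$side)
  mapped <- lookup_decision(rule, x, y)
  fresh <- vapply(seq_len(n_pt), function(i) {
    decide_enrichment(d, pr, x[i], y[i], m = 2e5)$decision
  }, integer(1))
  agree <- mean(mapped == fresh)
  expect_gte(agree, 0.9)
  # disagreements are confined to cells near the decision boundary: within
  # two fine cells there is a cell of the opposite decision
  near_boundary <- function(x1, y1, dec) {
    i <- floor((x1 - rule$x0) / rule$min_cell)
    j <- floor((y1 - rule$y0) / rule$min_cell)
    ii <- pmin(pmax((i - 2):(i + 2), 0), rule$n_fine - 1L) + 1L
    jj <- pmin(pmax((j - 2):(j + 2), 0), rule$n_fine - 1L) + 1L
    any(rule$raster[ii, jj] != dec)
  }
  for (i in which(mapped != fresh)) {
    expect_true(near_boundary(x[i], y[i], mapped[i]))
  }
})

test_that("serialization round-trips losslessly and rasters consistently", {
  d <- design_105()
  rule <- cached_rule("pt-10-2", d, prior_point(10, 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_rule(rule, path)
  back <- read_rule(path)
  expect_equal(back$cells, rule$cells)
  expect_identical(back$raster, rule$raster)
  expect_equal(back$x0, rule$x0)
  expect_equal(back$min_cell, rule$min_cell)

  # a 200 x 200 raster reproduces the area-based enrichment fraction
  ras <- rule_raster(rule, 200)
  frac_ras <- mean(ras$decision == 1L)
  expect_equal(frac_ras, glance(rule)$frac_area_enrich, tolerance = 0.005)

  expect_error(read_rule(withr::local_tempfile(lines = "{}",
                                               fileext = ".json")),
               "malformed")
  empty <- rule; empty$cells <- rule$cells[0, ]
  expect_error(write_rule(empty, path), "empty")
})

test_that("the boundary has the expected qualitative shape", {
  d <- design_105()
  rule <- cached_rule("bvn-10-2", d, prior_normal(10, 2, 25, 25, 0.75))
  # for interim S1 estimates in the central range, the decision as a function
  # of the S2 estimate switches enrich -> continue a small number of times
  ys <- seq(rule$y0, rule$y0 + rule$side, length.out = 200)
  for (x in quantile(c(rule$x0, rule$x0 + rule$side), c(0.45, 0.55, 0.65))) {
    dec <- lookup_decision(rule, rep(x, 200), ys)
    expect_lte(sum(diff(dec) != 0), 3)
    # low theta2-hat favors enrichment, high favors continuing
    expect_gte(mean(dec[1:20] == 1L), mean(dec[181:200] == 1L))
  }
})

test_that("rule construction is reproducible for a fixed seed", {
  d <- design_105()
  a <- build_boundary(d, prior_point(10, 2), m = 1000, cells_per_side = 8,
                      seed = 99)
  b <- build_boundary(d, prior_point(10, 2), m = 1000, cells_per_side = 8,
                      seed = 99)
  expect_equal(a$cells, b$cells)
  expect_identical(a$raster, b$raster)
})
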