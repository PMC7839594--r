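#' Map the Bayes-optimal enrichment decision over the interim-estimate plane
#'
#' Large-scale simulation of an optimized adaptive design needs the optimal
#' decision for every possible interim observation
#' \eqn{x_1 = (\hat\theta_1^{(1)}, \hat\theta_2^{(1)})}. This routine
#' precomputes it over a square region \eqn{A} holding essentially all the
#' prior-predictive mass of \eqn{X_1}, by adaptive square subdivision:
#' \eqn{A} is split into four subsquares, [decide_enrichment()] is evaluated
#' at the (cached, shared) vertices, a square whose four vertices agree
#' unambiguously inherits that decision, and any other square is split into
#' four again, down to a smallest cell size. Because the enrich/continue
#' regions are geometrically simple, the expensive Monte Carlo decision is
#' only evaluated along a one-dimensional strip around the boundary rather
#' than on a full two-dimensional grid.
#'
#' A vertex is treated as ambiguous — forcing subdivision exactly like
#' disagreeing vertices — when its two estimated gains differ by less than
#' two combined Monte Carlo standard errors. Smallest-size cells whose
#' vertices still disagree take the majority decision (ties go to continue,
#' matching the tie rule of [decide_enrichment()]).
#'
#' Every vertex evaluation uses its own seed derived deterministically from
#' `seed` and the vertex position, so the rule is reproducible and
#' independent of evaluation order.
#'
#' @param design An [design_config()] object.
#' @param prior An `enrich_prior`.
#' @param m Posterior draws per vertex evaluation.
#' @param cells_per_side Fine-grid resolution of \eqn{A} (a power of two);
#'   the smallest cell side is `side / cells_per_side`.
#' @param half_width_sd Half-width of \eqn{A} in prior-predictive standard
#'   deviations of the interim estimates (the default 5.2 leaves less than
#'   1e-6 predictive mass outside the square).
#' @param seed Root seed for the per-vertex streams (drawn if `NULL`).
#' @param tie_z Tie tolerance passed to [decide_enrichment()].
#' @param verbose Print per-level progress (square and vertex counts).
#' @return An object of class `enrich_rule`: region geometry, the recorded
#'   cells, a fine-grid decision raster, and build metadata.
#' @examples
#' \donttest{
#' d <- design_config(info = 0.105)
#' rule <- build_boundary(d, prior_point(10, 2), m = 2000,
#'                        cells_per_side = 16, seed = 1)
#' }
#' @export
build_boundary <- function(design, prior, m = 1e5, cells_per_side = 128,
                           half_width_sd = 5.2, seed = NULL, tie_z = 0,
                           verbose = FALSE) {
  stopifnot(inherits(design, "enrich_design"), inherits(prior, "enrich_prior"))
  n_fine <- as.integer(cells_per_side)
  if (n_fine < 2 || bitwAnd(n_fine, n_fine - 1L) != 0L)
    stop("`cells_per_side` must be a power of two >= 2")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)

  pp <- prior_predictive_stage1(prior, design)
  half <- half_width_sd * max(pp$sd)
  x0 <- pp$mean[1] - half
  y0 <- pp$mean[2] - half
  side <- 2 * half
  cell <- side / n_fine
  cover <- region_coverage(pp, c(x0, x0 + side), c(y0, y0 + side))
  if (cover < 1 - 1e-6)
    warning(sprintf(
      "region A covers only %.8f of the prior-predictive mass of X1; enlarge `half_width_sd`",
      cover))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  # vertex cache keyed by fine-grid integer coordinates
  cache <- new.env(parent = emptyenv())
  eval_vertex <- function(i, j) {
    key <- paste(i, j)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    set.seed(vertex_seed(seed, i, j))
    d <- decide_enrichment(design, prior, x0 + i * cell, y0 + j * cell,
                           m = m, tie_z = tie_z)
    out <- c(decision = d$decision, ambiguous = as.integer(d$ambiguous))
    cache[[key]] <- out
    out
  }

  cells_i0 <- integer(); cells_j0 <- integer(); cells_size <- integer()
  cells_dec <- integer(); cells_unanimous <- logical()
  half_n <- n_fine %/% 2L
  active <- list(c(0L, 0L, half_n), c(half_n, 0L, half_n),
                 c(0L, half_n, half_n), c(half_n, half_n, half_n))
  level <- 1L
  while (length(active)) {
    nxt <- list()
    for (sq in active) {
      i0 <- sq[1]; j0 <- sq[2]; sz <- sq[3]
      v <- rbind(eval_vertex(i0, j0), eval_vertex(i0 + sz, j0),
                 eval_vertex(i0, j0 + sz), eval_vertex(i0 + sz, j0 + sz))
      agree <- length(unique(v[, "decision"])) == 1L && !any(v[, "ambiguous"] == 1L)
      if (agree || sz == 1L) {
        dec <- if (agree) v[1, "decision"] else {
          if (sum(v[, "decision"] == 1L) > 2L) 1L else 2L  # tie -> continue
        }
        cells_i0 <- c(cells_i0, i0); cells_j0 <- c(cells_j0, j0)
        cells_size <- c(cells_size, sz); cells_dec <- c(cells_dec, as.integer(dec))
        cells_unanimous <- c(cells_unanimous, agree)
      } else {
        h <- sz %/% 2L
        nxt <- c(nxt, list(c(i0, j0, h), c(i0 + h, j0, h),
                           c(i0, j0 + h, h), c(i0 + h, j0 + h, h)))
      }
    }
    if (verbose)
      message(sprintf("level %d: %d squares resolved or leaf, %d subdivided, %d vertices evaluated",
                      level, length(active) - length(nxt) %/% 4L * 0L,
                      length(nxt) %/% 4L, length(ls(cache))))
    active <- nxt
    level <- level + 1L
  }

  cells <- tibble::tibble(i0 = cells_i0, j0 = cells_j0, size = cells_size,
                          decision = cells_dec, unanimous = cells_unanimous)
  raster <- matrix(NA_integer_, n_fine, n_fine)
  for (r in seq_len(nrow(cells))) {
    ii <- cells$i0[r] + seq_len(cells$size[r])
    jj <- cells$j0[r] + seq_len(cells$size[r])
    raster[ii, jj] <- cells$decision[r]
  }
  stopifnot(!anyNA(raster))  # cells tile A exactly

  structure(
    list(x0 = x0, y0 = y0, side = side, n_fine = n_fine, min_cell = cell,
         cells = cells, raster = raster,
         meta = list(m = m, seed = seed, tie_z = tie_z,
                     half_width_sd = half_width_sd,
                     n_vertices = length(ls(cache)),
                     prior = unclass(prior),
                     design = unclass(design))),
    class = "enrich_rule"
  )
}

vertex_seed <- function(seed, i, j) {
  (as.double(seed) + 1000003 * i + 10007 * j) %% 2147483629
}

# Lower bound (union over the four tails) on P(X1 in the rectangle).
region_coverage <- function(pp, xr, yr) {
  out <- stats::pnorm(xr[1], pp$mean[1], pp$sd[1]) +
    stats::pnorm(xr[2], pp$mean[1], pp$sd[1], lower.tail = FALSE) +
    stats::pnorm(yr[1], pp$mean[2], pp$sd[2]) +
    stats::pnorm(yr[2], pp$mean[2], pp$sd[2], lower.tail = FALSE)
  1 - out
}

#' Look up the enrichment decision for interim observations
#'
#' Cell membership is half-open with the lower-left edge inclusive. Points
#' outside the mapped region take the decision of the nearest boundary cell
#' (index clamping; on the uniform fine grid this is the cell whose center is
#' nearest in Euclidean distance).
#'
#' @param rule An `enrich_rule` from [build_boundary()].
#' @param est1,est2 Interim estimates (vectorized).
#' @return Integer decisions, 1 (enrich) or 2 (continue).
#' @export
lookup_decision <- function(rule, est1, est2) {
  stopifnot(inherits(rule, "enrich_rule"))
  i <- pmin(pmax(floor((est1 - rule$x0) / rule$min_cell), 0), rule$n_fine - 1L)
  j <- pmin(pmax(floor((est2 - rule$y0) / rule$min_cell), 0), rule$n_fine - 1L)
  rule$raster[cbind(i + 1L, j + 1L)]
}

#' Serialize and restore a decision rule
#'
#' `write_rule()` stores the region geometry, cell list and build metadata as
#' JSON; `read_rule()` reconstructs the rule (including the raster) from it.
#' The round trip is lossless.
#'
#' @param rule An `enrich_rule`.
#' @param path File path.
#' @return `write_rule()` returns `path` invisibly; `read_rule()` returns the
#'   restored `enrich_rule`.
#' @export
write_rule <- function(rule, path) {
  stopifnot(inherits(rule, "enrich_rule"))
  if (nrow(rule$cells) == 0) stop("refusing to serialize an empty rule")
  obj <- list(
    format = "enrich_rule/1",
    region = list(x0 = rule$x0, y0 = rule$y0, side = rule$side,
                  n_fine = rule$n_fine, min_cell = rule$min_cell),
    cells = rule$cells,
    meta = rule$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rule
#' @export
read_rule <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop("malformed rule file: ", conditionMessage(e)))
  if (!identical(obj$format, "enrich_rule/1"))
    stop("malformed rule file: missing or unknown format marker")
  cells <- tibble::as_tibble(obj$cells)
  cells$i0 <- as.integer(cells$i0); cells$j0 <- as.integer(cells$j0)
  cells$size <- as.integer(cells$size); cells$decision <- as.integer(cells$decision)
  n_fine <- as.integer(obj$region$n_fine)
  raster <- matrix(NA_integer_, n_fine, n_fine)
  for (r in seq_len(nrow(cells))) {
    ii <- cells$i0[r] + seq_len(cells$size[r])
    jj <- cells$j0[r] + seq_len(cells$size[r])
    raster[ii, jj] <- cells$decision[r]
  }
  structure(
    list(x0 = obj$region$x0, y0 = obj$region$y0, side = obj$region$side,
         n_fine = n_fine, min_cell = obj$region$min_cell,
         cells = cells, raster = raster, meta = obj$meta),
    class = "enrich_rule"
  )
}

#' Rasterize a decision rule for plotting
#'
#' @param rule An `enrich_rule`.
#' @param n Grid resolution per axis.
#' @return A tibble of cell centers with columns `est1`, `est2`, `decision`.
#' @export
rule_raster <- function(rule, n = 200) {
  stopifnot(inherits(rule, "enrich_rule"))
  xs <- rule$x0 + (seq_len(n) - 0.5) / n * rule$side
  ys <- rule$y0 + (seq_len(n) - 0.5) / n * rule$side
  grid <- tidyr::expand_grid(est1 = xs, est2 = ys)
  grid$decision <- lookup_decision(rule, grid$est1, grid$est2)
  grid
}

#' @export
print.enrich_rule <- function(x, ...) {
  cat("<enrich_rule>\n")
  cat(sprintf("  region A: [%.3g, %.3g] x [%.3g, %.3g], %d x %d fine grid (cell %.3g)\n",
              x$x0, x$x0 + x$side, x$y0, x$y0 + x$side,
              x$n_fine, x$n_fine, x$min_cell))
  cat(sprintf("  %d cells (%d enrich, %d continue), %d vertex evaluations at M = %g\n",
              nrow(x$cells), sum(x$cells$decision == 1L),
              sum(x$cells$decision == 2L), x$meta$n_vertices, x$meta$m))
  invisible(x)
}
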