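#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a decision rule into its cells
#'
#' One row per recorded cell, with bounds in effect units.
#'
#' @param x An `enrich_rule`.
#' @param ... Unused.
#' @return A tibble with columns `x0`, `y0`, `side`, `decision`,
#'   `unanimous`.
#' @method tidy enrich_rule
#' @export
tidy.enrich_rule <- function(x, ...) {
  dplyr::transmute(x$cells,
                   x0 = x$x0 + .data$i0 * x$min_cell,
                   y0 = x$y0 + .data$j0 * x$min_cell,
                   side = .data$size * x$min_cell,
                   decision = .data$decision,
                   unanimous = .data$unanimous)
}

#' One-row summary of a decision rule
#'
#' @param x An `enrich_rule`.
#' @param ... Unused.
#' @return A tibble with the region geometry, cell counts, the fraction of
#'   the region area assigned to enrichment, and the build's Monte Carlo
#'   size.
#' @method glance enrich_rule
#' @export
glance.enrich_rule <- function(x, ...) {
  area <- x$cells$size^2
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_vertices = x$meta$n_vertices,
    min_cell = x$min_cell,
    side = x$side,
    frac_area_enrich = sum(area[x$cells$decision == 1L]) / sum(area),
    m_per_vertex = x$meta$m,
    seed = x$meta$seed
  )
}

#' Tidy a design configuration
#'
#' @param x An `enrich_design`.
#' @param ... Unused.
#' @return A one-row tibble of the design constants.
#' @method tidy enrich_design
#' @export
tidy.enrich_design <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, tau = x$tau, alpha = x$alpha,
                 info = x$info, n = x$n %||% NA_real_,
                 sigma = x$sigma %||% NA_real_, w1 = x$w1, w2 = x$w2)
}

#' Tidy a prior or posterior
#'
#' @param x An `enrich_prior`.
#' @param ... Unused.
#' @return A one-row tibble with the kind, means, variances and correlation.
#' @method tidy enrich_prior
#' @export
tidy.enrich_prior <- function(x, ...) {
  v1 <- x$cov[1, 1]; v2 <- x$cov[2, 2]
  tibble::tibble(kind = x$kind, mu1 = x$mu[1], mu2 = x$mu[2],
                 var1 = v1, var2 = v2,
                 rho = if (v1 > 0 && v2 > 0) x$cov[1, 2] / sqrt(v1 * v2) else 0)
}

#' Plot a decision boundary
#'
#' Raster view of the enrich / continue regions over the interim-estimate
#' plane.
#'
#' @param object An `enrich_rule`.
#' @param n Raster resolution per axis.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enrich_rule
#' @export
autoplot.enrich_rule <- function(object, n = 200, ...) {
  df <- rule_raster(object, n)
  df$region <- factor(ifelse(df$decision == 1L, "enrich", "continue"),
                      levels = c("enrich", "continue"))
  ggplot2::ggplot(df, ggplot2::aes(.data$est1, .data$est2,
                                   fill = .data$region)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(enrich = "#d95f02",
                                          continue = "#1b9e77")) +
    ggplot2::labs(x = expression(hat(theta)[1]^{(1)}),
                  y = expression(hat(theta)[2]^{(1)}),
                  fill = "interim decision") +
    ggplot2::coord_fixed()
}

#' Plot a best-design region map
#'
#' Tile map of [best_design_map()] output: which design achieves the highest
#' expected gain at each true effect pair.
#'
#' @param map A tibble from [best_design_map()].
#' @return A ggplot.
#' @export
plot_design_map <- function(map) {
  stopifnot(all(c("theta1", "theta2", "winner") %in% names(map)))
  ggplot2::ggplot(map, ggplot2::aes(.data$theta1, .data$theta2,
                                    fill = .data$winner)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = expression(theta[1]), y = expression(theta[2]),
                  fill = "best design")
}
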