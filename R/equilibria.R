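#' Beta shape parameters of a stationary opinion marginal
#'
#' The mean-field opinion dynamics admits stationary marginals of Beta form
#' `g(w) = C w^(a-1) (1-w)^(b-1)` whose shape is determined by the mean
#' location `m` and the compromise-to-diffusion ratio `mu = lambda / sigma^2`
#' through `a = m / mu`, `b = (1 - m) / mu`. Small `mu` (compromise
#' dominating) concentrates the marginal around `m`; `mu > min(m, 1 - m)`
#' produces boundary-singular, extreme-polarization shapes.
#'
#' @param m Mean opinion, in (0, 1).
#' @param mu Ratio `lambda / sigma^2`, positive.
#' @return Named numeric vector `c(a = , b = )`.
#' @examples
#' beta_shape(4 / 25, 1 / 5)  # a = 0.8, b = 4.2 (boundary-singular at 0)
#' beta_shape(1 / 3, 1 / 6)   # a = 2,   b = 4   (unimodal)
#' @export
beta_shape <- function(m, mu) {
  if (!is.numeric(m) || !is.numeric(mu) || length(m) != length(mu))
    stop("m and mu must be numeric of equal length")
  if (any(m <= 0 | m >= 1)) stop("m must lie in (0, 1)")
  if (any(mu <= 0)) stop("mu must be positive")
  if (length(m) == 1L) c(a = m / mu, b = (1 - m) / mu)
  else cbind(a = m / mu, b = (1 - m) / mu)
}

#' Specification of a stationary Beta marginal
#'
#' Holds the mean location `m` and ratio `mu = lambda / sigma^2` of a
#' stationary opinion marginal together with the derived shape `(a, b)` and
#' the exact normalization constant `C = 1 / B(a, b)` (computed from the
#' Beta function, never by numerical renormalization, so that integrable
#' boundary singularities `a < 1` or `b < 1` keep exact mass).
#'
#' @param m Mean in (0, 1).
#' @param mu Ratio `lambda / sigma^2 > 0`.
#' @return Object of class `beta_spec` with fields `m`, `mu`, `a`, `b`, `C`.
#' @seealso [beta_spec_from_rates()] to build from `(m, lambda, sigma)`.
#' @export
beta_spec <- function(m, mu) {
  ab <- beta_shape(m, mu)
  structure(list(m = m, mu = mu, a = ab[["a"]], b = ab[["b"]],
                 C = 1 / beta(ab[["a"]], ab[["b"]])),
            class = "beta_spec")
}

#' @rdname beta_spec
#' @param lambda Compromise rate (per day), positive.
#' @param sigma Diffusion coefficient, positive. Only the combination
#'   `mu = lambda / sigma^2` enters the stationary shape; separately
#'   reported `(lambda, sigma)` pairs with equal `mu` describe the same
#'   marginal.
#' @export
beta_spec_from_rates <- function(m, lambda, sigma) {
  if (lambda <= 0 || sigma <= 0) stop("lambda and sigma must be positive")
  beta_spec(m, lambda / sigma^2)
}

#' @export
print.beta_spec <- function(x, ...) {
  cat(sprintf("<beta_spec> m = %.4g, mu = %.4g  (a = %.4g, b = %.4g)\n",
              x$m, x$mu, x$a, x$b))
  invisible(x)
}

#' Two-component Beta mixture (susceptible- and recovered-origin marginals)
#'
#' The stationary marginal of the opinion density once a fake-news outbreak
#' has run its course is a convex combination of two Beta components: one
#' carried by agents that were never reached (weight `weight_S`, the
#' equilibrium susceptible fraction) and one carried by removed spreaders.
#' Bimodality of this mixture is the model's signature of polarization.
#'
#' @param weight_S Mixture weight of the first component, in `[0, 1]`.
#' @param spec_S,spec_R [beta_spec()] components. By convention the
#'   components are stored as given; use [sort_mixture_components()] to fix
#'   label order by ascending mean.
#' @return Object of class `beta_mixture_spec`.
#' @export
beta_mixture_spec <- function(weight_S, spec_S, spec_R) {
  if (!is.numeric(weight_S) || weight_S < 0 || weight_S > 1)
    stop("weight_S must lie in [0, 1]")
  stopifnot(inherits(spec_S, "beta_spec"), inherits(spec_R, "beta_spec"))
  structure(list(weight_S = weight_S, spec_S = spec_S, spec_R = spec_R),
            class = "beta_mixture_spec")
}

#' @export
print.beta_mixture_spec <- function(x, ...) {
  cat(sprintf("<beta_mixture_spec> weight_S = %.4g\n", x$weight_S))
  cat("  S: "); print(x$spec_S)
  cat("  R: "); print(x$spec_R)
  invisible(x)
}

#' Reorder mixture components by ascending mean
#'
#' Resolves label switching after a fit: the component with the smaller
#' mean is reported first (as component S).
#'
#' @param mix A [beta_mixture_spec()].
#' @return A `beta_mixture_spec` with components ordered by ascending mean.
#' @export
sort_mixture_components <- function(mix) {
  stopifnot(inherits(mix, "beta_mixture_spec"))
  if (mix$spec_S$m <= mix$spec_R$m) return(mix)
  beta_mixture_spec(1 - mix$weight_S, mix$spec_R, mix$spec_S)
}

#' Pointwise mixture density and CDF
#'
#' @param mix A [beta_mixture_spec()] (a plain [beta_spec()] is accepted
#'   and treated as a one-component mixture).
#' @param w,q Evaluation points in `[0, 1]`.
#' @return Numeric vector of density (resp. CDF) values.
#' @export
mixture_density <- function(mix, w) {
  mix <- .as_mixture(mix)
  mix$weight_S * stats::dbeta(w, mix$spec_S$a, mix$spec_S$b) +
    (1 - mix$weight_S) * stats::dbeta(w, mix$spec_R$a, mix$spec_R$b)
}

#' @rdname mixture_density
#' @export
mixture_cdf <- function(mix, q) {
  mix <- .as_mixture(mix)
  mix$weight_S * stats::pbeta(q, mix$spec_S$a, mix$spec_S$b) +
    (1 - mix$weight_S) * stats::pbeta(q, mix$spec_R$a, mix$spec_R$b)
}

.as_mixture <- function(x) {
  if (inherits(x, "beta_mixture_spec")) return(x)
  if (inherits(x, "beta_spec")) return(beta_mixture_spec(1, x, x))
  stop("expected a beta_spec or beta_mixture_spec")
}

#' Cell-averaged stationary marginal on a 1-D grid
#'
#' Cell values are exact cell integrals divided by the cell width, computed
#' from differences of the regularized incomplete Beta function rather than
#' midpoint sampling, so that boundary-unbounded shapes (`a < 1` or
#' `b < 1`) retain their exact cell mass and total mass is 1 by telescoping.
#'
#' @param spec A [beta_spec()].
#' @param grid An [opinion_grid1d()].
#' @return Object of class `empirical_marginal` (fields `grid`, `values`),
#'   normalized so `sum(values) * dw == 1`.
#' @export
stationary_marginal <- function(spec, grid) {
  stopifnot(inherits(spec, "beta_spec"), inherits(grid, "opinion_grid1d"))
  cdf <- stats::pbeta(grid$edges, spec$a, spec$b)
  empirical_marginal(grid, diff(cdf) / grid$dw)
}

#' Cell-averaged stationary Beta mixture on a 1-D grid
#'
#' @param mix A [beta_mixture_spec()].
#' @param grid An [opinion_grid1d()].
#' @return An `empirical_marginal`, cell-averaged with unit mass.
#' @export
stationary_mixture <- function(mix, grid) {
  mix <- .as_mixture(mix)
  stopifnot(inherits(grid, "opinion_grid1d"))
  cdf <- mixture_cdf(mix, grid$edges)
  empirical_marginal(grid, diff(cdf) / grid$dw)
}

#' Count the modes of a cell-averaged marginal
#'
#' A mode is a strict local maximum of the cell values. Boundary cells
#' count as modes when strictly above their single neighbor; runs of tied
#' cells (plateaus) collapse to a single mode located at the plateau
#' center, so a uniform density has exactly one mode.
#'
#' @param marginal An `empirical_marginal`, or a numeric vector of cell
#'   values (then locations are reported as cell indices' midpoints on a
#'   unit grid).
#' @return List with `n_modes` and `locations` (cell-center coordinates).
#' @export
count_modes <- function(marginal) {
  if (inherits(marginal, "empirical_marginal")) {
    v <- marginal$values
    centers <- marginal$grid$centers
  } else {
    v <- as.numeric(marginal)
    centers <- (seq_along(v) - 0.5) / length(v)
  }
  n <- length(v)
  if (n < 3L) stop("need at least 3 cells to count modes")
  # collapse plateaus: runs of equal consecutive values
  r <- rle(v)
  k <- length(r$values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  locs <- numeric(0)
  for (j in seq_len(k)) {
    left_ok <- j == 1L || r$values[j] > r$values[j - 1L]
    right_ok <- j == k || r$values[j] > r$values[j + 1L]
    if (left_ok && right_ok) {
      mid <- (centers[starts[j]] + centers[ends[j]]) / 2
      locs <- c(locs, mid)
    }
  }
  list(n_modes = length(locs), locations = locs)
}

#' Analytic mode of an interior-peaked Beta component
#'
#' For shape `a, b > 1` the density peaks at `(a - 1) / (a + b - 2)`.
#' In a mixture whose other component decays across this point, the
#' mixture's own interior local maximum sits close to (slightly below)
#' this component mode.
#'
#' @param spec A [beta_spec()] with `a > 1` and `b > 1`.
#' @return The mode abscissa.
#' @export
beta_mode <- function(spec) {
  stopifnot(inherits(spec, "beta_spec"))
  if (spec$a <= 1 || spec$b <= 1)
    stop("mode formula requires a > 1 and b > 1 (interior-peaked shape)")
  (spec$a - 1) / (spec$a + spec$b - 2)
}

#' Interior mode of a Beta component or mixture on a fine grid
#'
#' Convenience diagnostic: evaluates the mixture density on an `n`-cell
#' grid and returns the abscissa of the largest strict local maximum that
#' is not a boundary cell. For a single interior-peaked Beta component
#' this converges to the analytic mode `(a - 1) / (a + b - 2)`.
#'
#' @param mix [beta_spec()] or [beta_mixture_spec()].
#' @param n Grid resolution (default 1000).
#' @return Abscissa of the interior mode, or `NA` if none exists.
#' @export
interior_mode <- function(mix, n = 1000) {
  g <- opinion_grid1d(n)
  marg <- stationary_mixture(.as_mixture(mix), g)
  md <- count_modes(marg)
  interior <- md$locations[md$locations > g$dw & md$locations < 1 - g$dw]
  if (length(interior) == 0L) return(NA_real_)
  dens <- mixture_density(mix, interior)
  interior[which.max(dens)]
}
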