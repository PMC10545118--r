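#' @name flux_scheme
#' @title Structure-preserving finite-volume scheme for opinion marginals
#'
#' @description
#' Both opinion directions of the mean-field model reduce to 1-D
#' Fokker-Planck problems in flux form
#' \deqn{\partial_t f = \partial_w F[f],\qquad
#'       F[f] = (B(w) + \hat D'(w))\,f + \hat D(w)\,\partial_w f,}
#' with compromise drift `B(w) = lambda (w - m)` and a degenerate diffusion
#' `\hat D` vanishing at `w = 0, 1`. The scheme discretizes the flux at the
#' interior cell faces as
#' \deqn{F_{i+1/2} = \tilde C_{i+1/2}\,\tilde f_{i+1/2}
#'       + D_{i+1/2}\,(f_{i+1}-f_i)/\Delta w,}
#' where `\tilde f` is the exponentially weighted average
#' `(1 - delta) f_{i+1} + delta f_i`,
#' `delta = 1/lambda_f + 1/(1 - exp(lambda_f))`,
#' `lambda_f = dw * Ctilde / D_face`, and `Ctilde` is built from the
#' *exact* integral of `(B + \hat D') / \hat D` across the face (closed
#' forms below). With these weights the numerical flux vanishes
#' identically on the analytic steady state evaluated at the cell centers
#' (the ratio `f_{i+1}/f_i` matched by the scheme is exactly
#' `exp(-integral)`), which is the defining structure-preservation
#' property; `delta` always lies in `(0, 1)` so the semi-implicit update
#' is positivity-preserving for any `dt`, and fluxes telescope so mass is
#' conserved to round-off. Boundary faces carry zero flux.
#'
#' Two diffusion closures are available:
#' \describe{
#'   \item{`"beta"`}{`\hat D(w) = lambda * mu * w (1 - w)` with
#'     `mu = lambda / sigma^2`. Its stationary density is exactly the
#'     `Beta(m/mu, (1-m)/mu)` marginal of the equilibrium theory, so this
#'     is the closure used for all equilibrium and calibration work.}
#'   \item{`"sde_product"`}{`\hat D(w) = (sigma^2/2) w^2 (1-w)^2`, the
#'     literal Fokker-Planck diffusion of the agent equation with noise
#'     amplitude `sigma w (1 - w)`; used to cross-check the particle
#'     simulation at finite `N`.}
#' }
NULL

# Exact antiderivative of (B + Dhat')/Dhat for each closure.
# "beta":       H(w) = (1/mu) [-m log w - (1-m) log(1-w)] + log(w(1-w))
# "sde_product":H(w) = 2(lambda/sigma^2) G(w) + 2 log(w(1-w)),
#   G(w) = (1-2m) log(w/(1-w)) + m/w + (1-m)/(1-w)   (partial fractions)
.flux_antiderivative <- function(w, lambda, m, mu, sigma, closure) {
  switch(closure,
    beta = {
      (1 / mu) * (-m * log(w) - (1 - m) * log1p(-w)) +
        log(w) + log1p(-w)
    },
    sde_product = {
      mu_t <- lambda / sigma^2
      G <- (1 - 2 * m) * (log(w) - log1p(-w)) + m / w + (1 - m) / (1 - w)
      2 * mu_t * G + 2 * (log(w) + log1p(-w))
    })
}

.flux_diffusion <- function(w, lambda, mu, sigma, closure) {
  switch(closure,
    beta = lambda * mu * w * (1 - w),
    sde_product = (sigma^2 / 2) * w^2 * (1 - w)^2)
}

# delta(x) = 1/x - 1/expm1(x), the Chang-Cooper weight; stable for all x.
.cc_delta <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-5
  out[small] <- 0.5 - x[small] / 12
  xb <- x[!small]
  out[!small] <- 1 / xb - 1 / expm1(xb)
  out
}

#' Face coefficients of the structure-preserving flux scheme
#'
#' Computes, for every interior face of a 1-D grid, the diffusion value
#' `D_face`, the integrated advection coefficient `Ctilde`, the Peclet-like
#' ratio `lambda_face = dw * Ctilde / D_face` (equal to the exact integral
#' of `(B + D')/D` across the face) and the weight `delta_face` in
#' `(0, 1)`. See [flux_scheme] for the scheme and the closures.
#'
#' @param grid An [opinion_grid1d()].
#' @param lambda Compromise rate, > 0.
#' @param m Drift target (current mean), in (0, 1).
#' @param mu Ratio `lambda / sigma^2` (required for `closure = "beta"` if
#'   `sigma` is not given).
#' @param sigma Diffusion coefficient (required for
#'   `closure = "sde_product"`; for `"beta"` it is converted to `mu`).
#' @param closure `"beta"` (default) or `"sde_product"`.
#' @return Object of class `flux_coefficients`: list with `D_face`,
#'   `Ctilde`, `lambda_face`, `delta_face` (length `n - 1`, interior faces
#'   only), plus `grid` and `closure`.
#' @export
scheme_coefficients <- function(grid, lambda, m, mu = NULL, sigma = NULL,
                                closure = c("beta", "sde_product")) {
  closure <- match.arg(closure)
  stopifnot(inherits(grid, "opinion_grid1d"))
  if (lambda <= 0) stop("lambda must be positive")
  if (m <= 0 || m >= 1) stop("m must lie in (0, 1)")
  if (closure == "beta") {
    if (is.null(mu)) {
      if (is.null(sigma)) stop("closure 'beta' needs mu or sigma")
      mu <- lambda / sigma^2
    }
    if (mu <= 0) stop("mu must be positive")
  } else {
    if (is.null(sigma) || sigma <= 0)
      stop("closure 'sde_product' needs sigma > 0")
  }
  faces <- grid$edges[2:grid$n]              # interior faces
  centers <- grid$centers
  D_face <- .flux_diffusion(faces, lambda, mu, sigma, closure)
  H <- .flux_antiderivative(centers, lambda, m, mu, sigma, closure)
  lambda_face <- diff(H)                      # exact integral across face
  Ctilde <- D_face * lambda_face / grid$dw
  delta_face <- .cc_delta(lambda_face)
  structure(list(D_face = D_face, Ctilde = Ctilde,
                 lambda_face = lambda_face, delta_face = delta_face,
                 grid = grid, closure = closure),
            class = "flux_coefficients")
}

#' Numerical fluxes at all faces for a given cell-value vector
#'
#' @param coeffs A [scheme_coefficients()] object.
#' @param f Cell values (length `n`).
#' @return Length `n + 1` vector of face fluxes; the boundary entries are
#'   identically zero (no-flux).
#' @export
face_fluxes <- function(coeffs, f) {
  stopifnot(inherits(coeffs, "flux_coefficients"))
  n <- coeffs$grid$n
  f <- as.numeric(f)
  if (length(f) != n) stop("f must have one value per cell")
  d <- coeffs$delta_face
  ftilde <- (1 - d) * f[-1] + d * f[-n]
  inner <- coeffs$Ctilde * ftilde +
    coeffs$D_face * (f[-1] - f[-n]) / coeffs$grid$dw
  c(0, inner, 0)
}

# Tridiagonal generator matrix A with df/dt = A f (columns sum to zero).
.fp_operator <- function(coeffs) {
  n <- coeffs$grid$n
  dw <- coeffs$grid$dw
  a <- coeffs$Ctilde * coeffs$delta_face - coeffs$D_face / dw       # on f_k
  b <- coeffs$Ctilde * (1 - coeffs$delta_face) + coeffs$D_face / dw # on f_k+1
  A <- matrix(0, n, n)
  for (k in seq_len(n - 1)) {
    A[k, k] <- A[k, k] + a[k] / dw
    A[k, k + 1] <- A[k, k + 1] + b[k] / dw
    A[k + 1, k] <- A[k + 1, k] - a[k] / dw
    A[k + 1, k + 1] <- A[k + 1, k + 1] - b[k] / dw
  }
  A
}

#' One time step of the 1-D marginal solver
#'
#' Semi-implicit (default): solves `(I - dt A) f_new = f_old` with the
#' flux coefficients frozen at the supplied state, an M-matrix system that
#' conserves mass exactly (telescoping fluxes) and preserves positivity
#' for any `dt`. Explicit Euler is available for step-restriction studies.
#'
#' @param f Cell values: a length-`n` vector, or an `n x k` matrix whose
#'   columns are independent lines (used by the 2-D sweeps).
#' @param coeffs A [scheme_coefficients()] object.
#' @param dt Time step, > 0.
#' @param method `"semi_implicit"` (default) or `"explicit"`.
#' @return Updated values, same shape as `f`.
#' @export
fp_sweep_1d <- function(f, coeffs, dt, method = c("semi_implicit",
                                                  "explicit")) {
  method <- match.arg(method)
  stopifnot(inherits(coeffs, "flux_coefficients"))
  if (dt <= 0) stop("dt must be positive")
  vec <- is.null(dim(f))
  fm <- if (vec) matrix(f, ncol = 1) else as.matrix(f)
  if (nrow(fm) != coeffs$grid$n) stop("f has wrong number of cells")
  A <- .fp_operator(coeffs)
  out <- if (method == "semi_implicit") {
    solve(diag(nrow(A)) - dt * A, fm)
  } else {
    fm + dt * (A %*% fm)
  }
  if (any(out < 0) && method == "explicit")
    warning("explicit step produced negative values; reduce dt")
  if (vec) as.numeric(out) else out
}

#' Evolve a single 1-D opinion marginal
#'
#' Driver for the nonlinear 1-D problem: at every step the mean of the
#' current marginal is recomputed and the flux coefficients rebuilt
#' (semi-implicit linearization), unless a fixed drift target `m` is
#' supplied, in which case the coefficients are frozen once.
#'
#' @param init An `empirical_marginal` or a vector of cell values.
#' @param grid An [opinion_grid1d()] (taken from `init` when omitted).
#' @param lambda,mu,sigma,closure Passed to [scheme_coefficients()].
#' @param m Optional fixed drift target; default `NULL` (self-consistent
#'   mean, recomputed every step).
#' @param n_steps Number of steps.
#' @param dt Step size; default `dw` (the mesh-scaled step used throughout).
#' @return List with `values` (final cell values), `marginal`
#'   (`empirical_marginal`), and `means` (mean after every step).
#' @export
evolve_marginal <- function(init, grid = NULL, lambda, mu = NULL,
                            sigma = NULL, closure = "beta", m = NULL,
                            n_steps, dt = NULL) {
  if (inherits(init, "empirical_marginal")) {
    grid <- init$grid
    f <- init$values
  } else {
    if (is.null(grid)) stop("grid required when init is a plain vector")
    f <- as.numeric(init)
  }
  if (is.null(dt)) dt <- grid$dw
  fixed <- !is.null(m)
  coeffs <- NULL
  means <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    target <- if (fixed) m else sum(grid$centers * f) * grid$dw / (sum(f) * grid$dw)
    if (is.null(coeffs) || !fixed)
      coeffs <- scheme_coefficients(grid, lambda, target, mu = mu,
                                    sigma = sigma, closure = closure)
    f <- fp_sweep_1d(f, coeffs, dt)
    means[s] <- sum(grid$centers * f) / sum(f)
  }
  list(values = f, marginal = empirical_marginal(grid, f), means = means)
}

#' Means, variances and mass of a 2-D opinion density field
#'
#' Cell-center quadrature of the first two moments per axis.
#'
#' @param field A [density_field2d()] with positive mass.
#' @return List `m_plus, m_minus, v_plus, v_minus, mass`.
#' @export
field_moments <- function(field) {
  stopifnot(inherits(field, "density_field2d"))
  if (field$mass <= 0) stop("field has zero mass")
  ca <- field$grid$cell_area
  wp <- field$grid$plus$centers
  wm <- field$grid$minus$centers
  mass <- sum(field$values) * ca
  gp <- rowSums(field$values) * field$grid$minus$dw   # marginal in w+
  gm <- colSums(field$values) * field$grid$plus$dw
  m_plus <- sum(wp * gp) * field$grid$plus$dw / mass
  m_minus <- sum(wm * gm) * field$grid$minus$dw / mass
  v_plus <- sum((wp - m_plus)^2 * gp) * field$grid$plus$dw / mass
  v_minus <- sum((wm - m_minus)^2 * gm) * field$grid$minus$dw / mass
  list(m_plus = m_plus, m_minus = m_minus,
       v_plus = v_plus, v_minus = v_minus, mass = mass)
}

# means of a (possibly non-normalized) values matrix on a 2-D grid
.field_means <- function(values, grid) {
  mass <- sum(values) * grid$cell_area
  gp <- rowSums(values) * grid$minus$dw
  gm <- colSums(values) * grid$plus$dw
  c(m_plus = sum(grid$plus$centers * gp) * grid$plus$dw / mass,
    m_minus = sum(grid$minus$centers * gm) * grid$minus$dw / mass)
}

#' Solve the single-population mean-field opinion equation on [0,1]^2
#'
#' First-order (Lie) dimensional splitting: per step, all lines are swept
#' semi-implicitly in the `w+` direction, the means are recomputed, then
#' all lines are swept in the `w-` direction. No-flux conditions hold on
#' all four edges, so mass is conserved to round-off and — with the
#' degenerate diffusion closures — the mean opinions are conserved up to
#' the quadrature error of the scheme.
#'
#' @param init A [density_field2d()] with unit mass (non-unit mass is
#'   renormalized with a warning, or rejected with
#'   `on_nonunit_mass = "error"`).
#' @param params An [opinion_params()]; `lambda_plus/minus` and
#'   `sigma_plus/minus` feed the per-direction flux coefficients.
#' @param t_final Final time (days).
#' @param dt Time step; default `dw+` (mesh-scaled).
#' @param closure Diffusion closure, see [flux_scheme].
#' @param record_times Times at which the field is stored (nearest step).
#' @param on_nonunit_mass `"renormalize"` or `"error"`.
#' @return List with `times`, `fields` (list of [density_field2d()]),
#'   and `moments` (data frame `time, mass, m_plus, m_minus, v_plus,
#'   v_minus`).
#' @export
solve_single_population <- function(init, params, t_final, dt = NULL,
                                    closure = "beta", record_times = NULL,
                                    on_nonunit_mass = c("renormalize",
                                                        "error")) {
  on_nonunit_mass <- match.arg(on_nonunit_mass)
  stopifnot(inherits(init, "density_field2d"),
            inherits(params, "opinion_params"))
  grid <- init$grid
  values <- init$values
  if (abs(init$mass - 1) > 1e-8) {
    if (on_nonunit_mass == "error") stop("initial field must have unit mass")
    warning("initial mass ", signif(init$mass, 6), " renormalized to 1")
    values <- values / init$mass
  }
  if (is.null(dt)) dt <- grid$plus$dw
  n_steps <- as.integer(round(t_final / dt))
  if (is.null(record_times)) record_times <- c(0, t_final)
  rec_steps <- unique(pmin(pmax(as.integer(round(record_times / dt)), 0L),
                           n_steps))
  fields <- vector("list", length(rec_steps))
  moments <- vector("list", length(rec_steps))
  k <- 1L
  store <- function(step) {
    while (k <= length(rec_steps) && rec_steps[k] == step) {
      fl <- density_field2d(grid, values)
      fields[[k]] <<- fl
      mo <- field_moments(fl)
      moments[[k]] <<- data.frame(time = step * dt, mass = mo$mass,
                                  m_plus = mo$m_plus, m_minus = mo$m_minus,
                                  v_plus = mo$v_plus, v_minus = mo$v_minus)
      k <<- k + 1L
    }
  }
  store(0L)
  for (s in seq_len(n_steps)) {
    m <- .field_means(values, grid)
    cp <- scheme_coefficients(grid$plus, params$lambda_plus, m[["m_plus"]],
                              sigma = params$sigma_plus, closure = closure)
    values <- fp_sweep_1d(values, cp, dt)
    m <- .field_means(values, grid)
    cm <- scheme_coefficients(grid$minus, params$lambda_minus,
                              m[["m_minus"]],
                              sigma = params$sigma_minus, closure = closure)
    values <- t(fp_sweep_1d(t(values), cm, dt))
    store(s)
  }
  list(times = rec_steps * dt, fields = fields,
       moments = do.call(rbind, moments))
}
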