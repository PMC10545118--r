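#' Contact function of the incidence operator
#'
#' The local incidence of fake-news transmission is
#' `K(w) = f_S(w) * integral kappa(w*) f_I(w*) dw*`; `kappa` measures how
#' strongly an opinion profile spreads misinformation. Either a constant
#' `kappa == beta`, or a separable product
#' `kappa(w) = beta * k_plus(w+) * k_minus(w-)`.
#'
#' @param beta Positive scale (the contact rate).
#' @param kind `"constant"` or `"separable"`.
#' @param k_plus,k_minus For the separable kind: nonnegative functions of
#'   one variable on `[0, 1]` (defaults: identically 1).
#' @return Object of class `contact_function`.
#' @export
contact_function <- function(beta, kind = c("constant", "separable"),
                             k_plus = NULL, k_minus = NULL) {
  kind <- match.arg(kind)
  if (beta <= 0) stop("beta must be positive")
  if (kind == "separable") {
    if (is.null(k_plus)) k_plus <- function(w) rep(1, length(w))
    if (is.null(k_minus)) k_minus <- function(w) rep(1, length(w))
  }
  structure(list(kind = kind, beta = beta,
                 k_plus = k_plus, k_minus = k_minus),
            class = "contact_function")
}

# kappa evaluated on the cell centers of a 2-D grid (matrix n+ x n-)
.contact_matrix <- function(contact, grid) {
  if (contact$kind == "constant") {
    matrix(contact$beta, grid$plus$n, grid$minus$n)
  } else {
    kp <- contact$k_plus(grid$plus$centers)
    km <- contact$k_minus(grid$minus$centers)
    if (any(kp < 0) || any(km < 0)) stop("contact factors must be >= 0")
    contact$beta * outer(kp, km)
  }
}

#' Local incidence rate between susceptible and infectious densities
#'
#' Cell-center quadrature of
#' `K(w) = f_S(w) * integral kappa(w*) f_I(w*) dw*`. For a constant
#' contact function this collapses exactly to `beta * rho_I * f_S`.
#'
#' @param f_S,f_I `n+ x n-` matrices of cell-averaged densities on a
#'   shared grid.
#' @param contact A [contact_function()].
#' @param grid The shared [opinion_grid2d()].
#' @return Matrix of the same shape as `f_S`.
#' @export
incidence_operator <- function(f_S, f_I, contact, grid) {
  stopifnot(inherits(contact, "contact_function"),
            inherits(grid, "opinion_grid2d"))
  f_S <- as.matrix(f_S); f_I <- as.matrix(f_I)
  dims <- c(grid$plus$n, grid$minus$n)
  if (!all(dim(f_S) == dims) || !all(dim(f_I) == dims))
    stop("field dimensions do not match the grid")
  kap <- .contact_matrix(contact, grid)
  f_S * (sum(kap * f_I) * grid$cell_area)
}

#' Bundle of per-compartment opinion densities
#'
#' @param grid Shared [opinion_grid2d()].
#' @param S,E,I,R Nonnegative `n+ x n-` matrices; total mass
#'   `sum over compartments of integral f_J` must be 1 within `1e-8`.
#' @return Object of class `compartment_fields` with `grid`, `values`
#'   (named list of matrices) and `masses`.
#' @export
compartment_fields <- function(grid, S, E, I, R) {
  stopifnot(inherits(grid, "opinion_grid2d"))
  vals <- list(S = as.matrix(S), E = as.matrix(E),
               I = as.matrix(I), R = as.matrix(R))
  dims <- c(grid$plus$n, grid$minus$n)
  for (J in names(vals)) {
    if (!all(dim(vals[[J]]) == dims)) stop("field ", J, " has wrong shape")
    if (any(vals[[J]] < 0)) stop("field ", J, " has negative values")
  }
  masses <- vapply(vals, function(v) sum(v) * grid$cell_area, numeric(1))
  if (abs(sum(masses) - 1) > 1e-8)
    stop("total mass must be 1 (got ", signif(sum(masses), 8), ")")
  structure(list(grid = grid, values = vals, masses = masses),
            class = "compartment_fields")
}

#' @export
print.compartment_fields <- function(x, ...) {
  cat("<compartment_fields> masses:",
      paste(sprintf("%s=%.4g", names(x$masses), x$masses), collapse = ", "),
      "\n")
  invisible(x)
}

#' Build compartment fields by scaling one shared opinion shape
#'
#' All four compartments receive the same normalized opinion density
#' (e.g. the first binned data snapshot, or an analytic product density),
#' scaled by the initial mass split — the natural initial condition when
#' only aggregate sentiment is observed.
#'
#' @param shape A [density_field2d()] with positive mass (renormalized).
#' @param masses Length-4 masses `(S, E, I, R)` summing to 1.
#' @return A [compartment_fields()].
#' @export
shared_shape_fields <- function(shape, masses) {
  stopifnot(inherits(shape, "density_field2d"))
  masses <- as.numeric(masses)
  if (length(masses) != 4L || any(masses < 0) ||
      abs(sum(masses) - 1) > 1e-10)
    stop("masses must be 4 nonnegative numbers summing to 1")
  v <- shape$values / shape$mass
  compartment_fields(shape$grid, masses[1] * v, masses[2] * v,
                     masses[3] * v, masses[4] * v)
}

# reaction right-hand side on fields (list S,E,I,R of matrices)
.exchange_rhs <- function(vals, eparams, kap_area) {
  K <- vals$S * sum(kap_area * vals$I)
  zE <- eparams$zeta * vals$E
  gI <- eparams$gamma * vals$I
  list(S = -K + (1 - eparams$alpha) * gI,
       E = K - zE,
       I = (1 - eparams$eta) * zE - gI,
       R = eparams$eta * zE + eparams$alpha * gI)
}

#' One explicit-Euler step of the compartment exchange terms
#'
#' Advances only the reaction part of the coupled system — incidence,
#' latency and removal — cellwise, leaving opinions untouched. The
#' reaction terms telescope, so total mass is conserved exactly.
#'
#' @param fields A [compartment_fields()].
#' @param eparams An [epidemic_params()].
#' @param contact A [contact_function()] (default: constant at
#'   `eparams$beta`).
#' @param dt Time step; a step large enough to drive any cell negative is
#'   rejected with advice to reduce `dt`.
#' @return Updated [compartment_fields()].
#' @export
epidemic_exchange_step <- function(fields, eparams,
                                   contact = NULL, dt) {
  stopifnot(inherits(fields, "compartment_fields"),
            inherits(eparams, "epidemic_params"))
  if (dt <= 0) stop("dt must be positive")
  if (is.null(contact)) contact <- contact_function(max(eparams$beta, 1e-300))
  kap_area <- .contact_matrix(contact, fields$grid) * fields$grid$cell_area
  rhs <- .exchange_rhs(fields$values, eparams, kap_area)
  new_vals <- Map(function(f, r) f + dt * r, fields$values, rhs)
  if (any(vapply(new_vals, function(v) any(v < 0), logical(1))))
    stop("exchange step produced negative densities; use a smaller dt")
  compartment_fields(fields$grid, new_vals$S, new_vals$E, new_vals$I,
                     new_vals$R)
}

# one RK4 step of the reaction terms (list-of-matrices arithmetic)
.exchange_rk4 <- function(vals, eparams, kap_area, dt) {
  axpy <- function(x, a, y) Map(function(u, v) u + a * v, x, y)
  k1 <- .exchange_rhs(vals, eparams, kap_area)
  k2 <- .exchange_rhs(axpy(vals, dt / 2, k1), eparams, kap_area)
  k3 <- .exchange_rhs(axpy(vals, dt / 2, k2), eparams, kap_area)
  k4 <- .exchange_rhs(axpy(vals, dt, k3), eparams, kap_area)
  Map(function(f, a, b, c, d) f + dt / 6 * (a + 2 * b + 2 * c + d),
      vals, k1, k2, k3, k4)
}

.global_means <- function(vals, grid) {
  total <- Reduce(`+`, vals)
  .field_means(total, grid)
}

#' Solve the coupled opinion--fake-news mean-field system
#'
#' First-order splitting per step: sweep every compartment in the `w+`
#' direction, recompute means, sweep in the `w-` direction, recompute
#' means, then integrate the epidemic exchange terms. All compartments
#' drift either toward the mass-weighted *global* means (the printed form
#' of the model; default) or toward fixed per-compartment targets — the
#' closure under which a calibrated two-component mixture with distinct
#' component means is an exact stationary state.
#'
#' @param init A [compartment_fields()].
#' @param opinion A single [opinion_params()] shared by all compartments,
#'   or a named list `list(S = , E = , I = , R = )` of them.
#' @param eparams An [epidemic_params()].
#' @param contact A [contact_function()]; default constant at
#'   `eparams$beta`.
#' @param t_final Final time (days).
#' @param dt Step; default `dw+`.
#' @param closure Diffusion closure, see [flux_scheme].
#' @param drift_target `"global"` or `"compartment"`.
#' @param target_means For `drift_target = "compartment"`: a 4 x 2 matrix
#'   (rows S, E, I, R; columns `w+`, `w-`) of fixed drift targets.
#' @param exchange_method `"euler"` (the simple explicit step; default) or
#'   `"rk4"` (cellwise classical Runge-Kutta on the reaction terms).
#' @param record_times Times at which fields/moments are stored.
#' @return List with `times`, `fields` (list of [compartment_fields()]),
#'   `moments` (tidy data frame `time, compartment, mass, m_plus,
#'   m_minus`) and `global` (data frame `time, mass, m_plus, m_minus`).
#' @export
solve_coupled <- function(init, opinion, eparams, contact = NULL,
                          t_final, dt = NULL, closure = "beta",
                          drift_target = c("global", "compartment"),
                          target_means = NULL,
                          exchange_method = c("euler", "rk4"),
                          record_times = NULL) {
  drift_target <- match.arg(drift_target)
  exchange_method <- match.arg(exchange_method)
  stopifnot(inherits(init, "compartment_fields"),
            inherits(eparams, "epidemic_params"))
  grid <- init$grid
  comps <- c("S", "E", "I", "R")
  if (inherits(opinion, "opinion_params"))
    opinion <- stats::setNames(rep(list(opinion), 4), comps)
  stopifnot(all(comps %in% names(opinion)))
  if (is.null(contact)) contact <- contact_function(max(eparams$beta, 1e-300))
  if (drift_target == "compartment") {
    if (is.null(target_means) || !all(dim(as.matrix(target_means)) == c(4, 2)))
      stop("drift_target = 'compartment' needs a 4 x 2 target_means matrix")
    target_means <- as.matrix(target_means)
    rownames(target_means) <- comps
  }
  if (is.null(dt)) dt <- grid$plus$dw
  n_steps <- as.integer(round(t_final / dt))
  if (is.null(record_times)) record_times <- c(0, t_final)
  rec_steps <- unique(pmin(pmax(as.integer(round(record_times / dt)), 0L),
                           n_steps))
  kap_area <- .contact_matrix(contact, grid) * grid$cell_area

  vals <- init$values
  # with fixed targets the sweep operators never change: prefactor them
  fixed_ops <- NULL
  if (drift_target == "compartment") {
    fixed_ops <- lapply(comps, function(J) {
      op <- opinion[[J]]
      cp <- scheme_coefficients(grid$plus, op$lambda_plus,
                                target_means[J, 1],
                                sigma = op$sigma_plus, closure = closure)
      cm <- scheme_coefficients(grid$minus, op$lambda_minus,
                                target_means[J, 2],
                                sigma = op$sigma_minus, closure = closure)
      list(plus = solve(diag(grid$plus$n) - dt * .fp_operator(cp)),
           minus = solve(diag(grid$minus$n) - dt * .fp_operator(cm)))
    })
    names(fixed_ops) <- comps
  }

  fields_out <- vector("list", length(rec_steps))
  mom_out <- vector("list", length(rec_steps))
  glob_out <- vector("list", length(rec_steps))
  k <- 1L
  store <- function(step) {
    while (k <= length(rec_steps) && rec_steps[k] == step) {
      cf <- compartment_fields(grid, vals$S, vals$E, vals$I, vals$R)
      fields_out[[k]] <<- cf
      rows <- lapply(comps, function(J) {
        mss <- cf$masses[[J]]
        mm <- if (mss > 1e-14) .field_means(vals[[J]], grid)
              else c(m_plus = NA_real_, m_minus = NA_real_)
        data.frame(time = step * dt, compartment = J, mass = mss,
                   m_plus = mm[["m_plus"]], m_minus = mm[["m_minus"]])
      })
      mom_out[[k]] <<- do.call(rbind, rows)
      gm <- .global_means(vals, grid)
      glob_out[[k]] <<- data.frame(time = step * dt,
                                   mass = sum(cf$masses),
                                   m_plus = gm[["m_plus"]],
                                   m_minus = gm[["m_minus"]])
      k <<- k + 1L
    }
  }
  store(0L)
  for (s in seq_len(n_steps)) {
    if (drift_target == "global") {
      gm <- .global_means(vals, grid)
      for (J in comps) {
        op <- opinion[[J]]
        cp <- scheme_coefficients(grid$plus, op$lambda_plus,
                                  gm[["m_plus"]],
                                  sigma = op$sigma_plus, closure = closure)
        vals[[J]] <- fp_sweep_1d(vals[[J]], cp, dt)
      }
      gm <- .global_means(vals, grid)
      for (J in comps) {
        op <- opinion[[J]]
        cm <- scheme_coefficients(grid$minus, op$lambda_minus,
                                  gm[["m_minus"]],
                                  sigma = op$sigma_minus, closure = closure)
        vals[[J]] <- t(fp_sweep_1d(t(vals[[J]]), cm, dt))
      }
    } else {
      for (J in comps) vals[[J]] <- fixed_ops[[J]]$plus %*% vals[[J]]
      for (J in comps) vals[[J]] <- t(fixed_ops[[J]]$minus %*% t(vals[[J]]))
    }
    vals <- if (exchange_method == "euler") {
      rhs <- .exchange_rhs(vals, eparams, kap_area)
      out <- Map(function(f, r) f + dt * r, vals, rhs)
      if (any(vapply(out, function(v) any(v < 0), logical(1))))
        stop("exchange step produced negative densities; use a smaller dt")
      out
    } else {
      .exchange_rk4(vals, eparams, kap_area, dt)
    }
    store(s)
  }
  list(times = rec_steps * dt, fields = fields_out,
       moments = do.call(rbind, mom_out),
       global = do.call(rbind, glob_out))
}

#' Exact moment-ODE companion of the coupled system
#'
#' For a constant contact function the compartment masses and first
#' moments of the coupled PDE close into an ODE system: the masses follow
#' the fake-news SEIR equations and the products `rho_J * m_J` evolve by
#' incidence/latency/removal transfer plus the compromise pull
#' `-lambda_J rho_J (m_J - m)` toward the global (mass-weighted) mean.
#' This closed system is integrated with a high-accuracy adaptive solver
#' and serves as the whole-system correctness oracle for the PDE solver.
#'
#' The latency loss in the exposed-mean equation is `-zeta rho_E m_E`
#' (the form required by dimensional consistency and by integrating the
#' PDE); `e_loss = "as-printed"` switches to the bare `-zeta rho_E`
#' variant for comparison.
#'
#' @param eparams An [epidemic_params()].
#' @param opinion Single [opinion_params()] or named list per compartment.
#' @param init_masses Length-4 masses `(S, E, I, R)` summing to 1.
#' @param init_means 4 x 2 matrix of initial means (rows S, E, I, R;
#'   columns `w+`, `w-`).
#' @param t_final Final time.
#' @param times Output times (default 201 points on `[0, t_final]`).
#' @param drift_target `"global"` or `"compartment"` (with
#'   `target_means` as in [solve_coupled()]).
#' @param target_means Optional 4 x 2 matrix of fixed targets.
#' @param e_loss `"with_mean"` (default) or `"as-printed"`.
#' @return Data frame with columns `time`, `rho_S..rho_R`,
#'   `m_plus_S..m_plus_R`, `m_minus_S..m_minus_R`, `m_plus`, `m_minus`.
#' @export
moment_ode_oracle <- function(eparams, opinion, init_masses, init_means,
                              t_final, times = NULL,
                              drift_target = c("global", "compartment"),
                              target_means = NULL,
                              e_loss = c("with_mean", "as-printed")) {
  drift_target <- match.arg(drift_target)
  e_loss <- match.arg(e_loss)
  stopifnot(inherits(eparams, "epidemic_params"))
  comps <- c("S", "E", "I", "R")
  if (inherits(opinion, "opinion_params"))
    opinion <- stats::setNames(rep(list(opinion), 4), comps)
  init_masses <- as.numeric(init_masses)
  init_means <- as.matrix(init_means)
  stopifnot(length(init_masses) == 4, all(dim(init_means) == c(4, 2)))
  lam <- vapply(comps, function(J)
    c(opinion[[J]]$lambda_plus, opinion[[J]]$lambda_minus), numeric(2))
  if (drift_target == "compartment") {
    stopifnot(!is.null(target_means), all(dim(as.matrix(target_means)) == c(4, 2)))
    target_means <- as.matrix(target_means)
  }
  if (is.null(times)) times <- seq(0, t_final, length.out = 201)
  y0 <- c(init_masses,
          init_masses * init_means[, 1],
          init_masses * init_means[, 2])
  rhs <- function(t, y, p) {
    rho <- y[1:4]
    qp <- y[5:8]    # q_J = rho_J * m_J, positive axis
    qm <- y[9:12]
    # global means: total mass is 1, so m = sum of the q_J
    tp <- if (drift_target == "global") rep(sum(qp), 4) else target_means[, 1]
    tm <- if (drift_target == "global") rep(sum(qm), 4) else target_means[, 2]
    drho <- seir_derivatives(rho, eparams)
    zeta <- eparams$zeta; gam <- eparams$gamma
    al <- eparams$alpha; et <- eparams$eta
    axis <- function(q, lamrow, tgt) {
      inc_m <- eparams$beta * q[1] * rho[3]          # beta rho_S m_S rho_I
      eloss <- if (e_loss == "with_mean") zeta * q[2] else zeta * rho[2]
      pull <- -lamrow * (q - rho * tgt)              # -lambda_J rho_J (m_J - m)
      c(-inc_m + (1 - al) * gam * q[3],
        inc_m - eloss,
        (1 - et) * eloss - gam * q[3],
        et * eloss + al * gam * q[3]) + pull
    }
    list(c(drho, axis(qp, lam[1, ], tp), axis(qm, lam[2, ], tm)))
  }
  out <- as.data.frame(deSolve::ode(y0, times, rhs, parms = NULL,
                                    method = "lsoda",
                                    rtol = 1e-10, atol = 1e-12))
  names(out) <- c("time", paste0("rho_", comps),
                  paste0("m_plus_", comps), paste0("m_minus_", comps))
  for (J in seq_along(comps)) {
    rho <- out[[1 + J]]
    out[[paste0("m_plus_", comps[J])]] <-
      ifelse(rho > 1e-13, out[[paste0("m_plus_", comps[J])]] / rho, NA)
    out[[paste0("m_minus_", comps[J])]] <-
      ifelse(rho > 1e-13, out[[paste0("m_minus_", comps[J])]] / rho, NA)
  }
  out$m_plus <- rowSums(sapply(seq_along(comps), function(J)
    ifelse(is.na(out[[paste0("m_plus_", comps[J])]]), 0,
           out[[1 + J]] * out[[paste0("m_plus_", comps[J])]])))
  out$m_minus <- rowSums(sapply(seq_along(comps), function(J)
    ifelse(is.na(out[[paste0("m_minus_", comps[J])]]), 0,
           out[[1 + J]] * out[[paste0("m_minus_", comps[J])]])))
  out
}
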