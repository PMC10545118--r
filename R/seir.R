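#' Parameters of the fake-news compartment dynamics
#'
#' Susceptible agents become exposed on contact with spreaders at rate
#' `beta`; exposed agents wait an average latency `1/zeta` and then start
#' spreading with probability `1 - eta` (skipping straight to removed with
#' probability `eta`); spreaders stop after an average time `1/gamma` and
#' are removed permanently with probability `alpha` (returning to the
#' susceptible pool otherwise). The defaults `alpha = 1`, `eta = 0`
#' correspond to a short-lived piece of fake news that every exposed agent
#' passes on once and then drops.
#'
#' @param beta Contact rate (per day), >= 0.
#' @param zeta Inverse latency (per day), >= 0. Default 1 (daily turnover,
#'   the average lifespan of a piece of fake news).
#' @param gamma Inverse spreading time (per day), >= 0. Default 1.
#' @param alpha Removal probability in `[0, 1]`, default 1.
#' @param eta Skip-spreading probability in `[0, 1]`, default 0.
#' @return Object of class `epidemic_params`.
#' @export
epidemic_params <- function(beta, zeta = 1, gamma = 1, alpha = 1, eta = 0) {
  if (beta < 0 || zeta < 0 || gamma < 0) stop("rates must be >= 0")
  if (alpha < 0 || alpha > 1 || eta < 0 || eta > 1)
    stop("alpha and eta must lie in [0, 1]")
  structure(list(beta = beta, zeta = zeta, gamma = gamma,
                 alpha = alpha, eta = eta),
            class = "epidemic_params")
}

#' Right-hand side of the fake-news SEIR system
#'
#' The four compartment-mass rates in full `alpha`/`eta` generality:
#' \deqn{\dot\rho_S = -\beta\rho_S\rho_I + (1-\alpha)\gamma\rho_I,\quad
#'       \dot\rho_E = \beta\rho_S\rho_I - \zeta\rho_E,}
#' \deqn{\dot\rho_I = (1-\eta)\zeta\rho_E - \gamma\rho_I,\quad
#'       \dot\rho_R = \eta\zeta\rho_E + \alpha\gamma\rho_I.}
#' The rates sum to zero identically (closed population).
#'
#' @param state Named or ordered numeric of length 4: `(S, E, I, R)`.
#' @param params An [epidemic_params()].
#' @return Numeric length-4 rate vector named `S, E, I, R`.
#' @export
seir_derivatives <- function(state, params) {
  stopifnot(inherits(params, "epidemic_params"))
  s <- as.numeric(state)
  with(params, c(
    S = -beta * s[1] * s[3] + (1 - alpha) * gamma * s[3],
    E = beta * s[1] * s[3] - zeta * s[2],
    I = (1 - eta) * zeta * s[2] - gamma * s[3],
    R = eta * zeta * s[2] + alpha * gamma * s[3]))
}

#' Integrate the fake-news SEIR system
#'
#' Classical fixed-step RK4 on the compartment masses (inlined: at the
#' default `dt = 1e-3` an integration to `t = 200` takes 200 000 steps,
#' which an adaptive wrapper would slow down considerably for no accuracy
#' gain on this smooth 4-state system).
#'
#' @param params An [epidemic_params()].
#' @param init Length-4 initial masses `(S, E, I, R)` summing to 1.
#' @param t_final Final time (days).
#' @param dt Step size (days), default `1e-3`.
#' @param record_every Store every `record_every`-th step (default chosen
#'   to keep about 2000 output rows).
#' @return Data frame `time, S, E, I, R` of class `mass_trajectory`.
#' @export
integrate_seir <- function(params, init, t_final, dt = 1e-3,
                           record_every = NULL) {
  stopifnot(inherits(params, "epidemic_params"))
  init <- as.numeric(init)
  if (length(init) != 4L || any(init < 0))
    stop("init must be 4 nonnegative masses")
  if (abs(sum(init) - 1) > 1e-10) stop("initial masses must sum to 1")
  if (dt <= 0) stop("dt must be positive")
  n_steps <- as.integer(round(t_final / dt))
  if (is.null(record_every))
    record_every <- max(1L, as.integer(n_steps / 2000))
  beta <- params$beta; zeta <- params$zeta; gamma <- params$gamma
  alpha <- params$alpha; eta <- params$eta
  f <- function(y) c(-beta * y[1] * y[3] + (1 - alpha) * gamma * y[3],
                     beta * y[1] * y[3] - zeta * y[2],
                     (1 - eta) * zeta * y[2] - gamma * y[3],
                     eta * zeta * y[2] + alpha * gamma * y[3])
  y <- init
  n_rec <- n_steps %/% record_every + 1L
  out <- matrix(NA_real_, n_rec + 1L, 5L)
  out[1L, ] <- c(0, y)
  r <- 1L
  for (s in seq_len(n_steps)) {
    k1 <- f(y); k2 <- f(y + dt / 2 * k1); k3 <- f(y + dt / 2 * k2)
    k4 <- f(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (s %% record_every == 0L || s == n_steps) {
      r <- r + 1L
      out[r, ] <- c(s * dt, y)
    }
  }
  out <- as.data.frame(out[seq_len(r), , drop = FALSE])
  names(out) <- c("time", "S", "E", "I", "R")
  if (any(out[, -1] < -1e-9))
    stop("negative masses produced; use a smaller dt")
  class(out) <- c("mass_trajectory", "data.frame")
  out
}

#' Final susceptible fraction of a fake-news outbreak
#'
#' In the `alpha = 1`, `eta = 0` regime the outbreak leaves behind only
#' susceptible and removed agents, and the equilibrium susceptible
#' fraction solves the transcendental final-size relation
#' \deqn{\log(\rho_S^\infty / \rho_S(0)) =
#'       -(\beta/\gamma)\,(\rho_R^\infty - \rho_R(0)),\qquad
#'       \rho_R^\infty = 1 - \rho_S^\infty,}
#' which follows from integrating \eqn{d\log\rho_S = -\beta \rho_I\,dt}
#' against \eqn{\dot\rho_R = \gamma\rho_I}. The root is bracketed on
#' `(0, rho_S(0))` and solved to `tol`.
#'
#' With `relation = "as-printed"` the simplified variant
#' \eqn{\log(\rho_S^\infty/\rho_S(0)) = (\beta/\gamma)(1-\rho_S^\infty)},
#' which drops the sign and the initially-removed correction, is used
#' instead (kept for comparison; it has no admissible root for
#' `beta > 0`, as its two sides have opposite signs on the bracket).
#'
#' @param beta,gamma Positive rates.
#' @param init Length-4 initial masses `(S, E, I, R)`.
#' @param relation `"corrected"` (default) or `"as-printed"`.
#' @param tol Root tolerance, default `1e-12`.
#' @return The equilibrium susceptible fraction `rho_S_infinity`.
#' @export
final_size <- function(beta, gamma, init, relation = c("corrected",
                                                       "as-printed"),
                       tol = 1e-12) {
  relation <- match.arg(relation)
  if (beta < 0 || gamma <= 0) stop("need beta >= 0 and gamma > 0")
  init <- as.numeric(init)
  s0 <- init[1]; r0 <- init[4]
  if (s0 <= 0) stop("initial susceptible mass must be positive")
  if (beta == 0) return(s0)
  fun <- if (relation == "corrected") {
    function(s) log(s / s0) + (beta / gamma) * (1 - s - r0)
  } else {
    function(s) log(s / s0) - (beta / gamma) * (1 - s)
  }
  lo <- s0 * 1e-14; hi <- s0 * (1 - 1e-14)
  if (fun(lo) * fun(hi) > 0)
    stop("final-size relation has no sign change on (0, rho_S(0))")
  stats::uniroot(fun, c(lo, hi), tol = tol)$root
}

#' Contact rate implied by an observed equilibrium susceptible fraction
#'
#' Closed-form inversion of the final-size relation:
#' \deqn{\beta = \gamma\,\log(\rho_S(0)/\rho_S^\infty) /
#'       (1 - \rho_S^\infty - \rho_R(0)).}
#' This is the calibration step that turns a fitted equilibrium mixture
#' weight into the contact rate of the compartment dynamics.
#'
#' @param rho_S_infinity Equilibrium susceptible fraction, in
#'   `(0, rho_S(0))`.
#' @param gamma Positive recovery rate.
#' @param init Length-4 initial masses `(S, E, I, R)`.
#' @return The contact rate `beta`.
#' @export
invert_final_size <- function(rho_S_infinity, gamma, init) {
  init <- as.numeric(init)
  s0 <- init[1]; r0 <- init[4]
  if (rho_S_infinity <= 0 || rho_S_infinity >= s0)
    stop("rho_S_infinity must lie in (0, rho_S(0))")
  denom <- 1 - rho_S_infinity - r0
  if (denom <= 0) stop("no positive outbreak: denominator <= 0")
  gamma * log(s0 / rho_S_infinity) / denom
}
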