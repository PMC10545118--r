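test_that("incidence collapses for constant contact and matches brute force", {
  g <- opinion_grid2d(8, 8)
  set.seed(21)
  f_S <- matrix(runif(64), 8, 8); f_I <- matrix(runif(64), 8, 8)
  beta <- 1.3
  K <- incidence_operator(f_S, f_I, contact_function(beta), g)
  rho_I <- sum(f_I) * g$cell_area
  expect_equal(K, beta * rho_I * f_S, tolerance = 1e-14)
  expect_equal(incidence_operator(f_S, 0 * f_I, contact_function(beta), g),
               0 * f_S)
  # separable kernel vs an O(n^4) double loop
  kp <- function(w) 1 + w; km <- function(w) exp(-w)
  ct <- contact_function(beta, "separable", kp, km)
  K2 <- incidence_operator(f_S, f_I, ct, g)
  ref <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8) {
    acc <- 0
    for (k in 1:8) for (l in 1:8)
      acc <- acc + beta * kp(g$plus$centers[k]) * km(g$minus$centers[l]) *
        f_I[k, l] * g$cell_area
    ref[i, j] <- f_S[i, j] * acc
  }
  expect_equal(K2, ref, tolerance = 1e-12)
  expect_error(incidence_operator(matrix(1, 4, 4), f_I,
                                  contact_function(beta), g), "dimensions")
})

test_that("the exchange step conserves mass and matches the mass ODE", {
  g <- opinion_grid2d(10, 10)
  shape <- product_field(g, stationary_marginal(beta_spec(0.3, 0.2), g$plus),
                         stationary_marginal(beta_spec(0.4, 0.2), g$minus))
  flds <- shared_shape_fields(shape, seir_init())
  ep <- epidemic_params(1.21, 1, 1)
  dt <- 0.01
  new <- epidemic_exchange_step(flds, ep, dt = dt)
  expect_equal(sum(unlist(new$masses)), 1, tolerance = 1e-13)
  # constant kappa: compartment masses take one explicit Euler step of the
  # mass ODE, exactly
  d <- seir_derivatives(seir_init(), ep)
  expect_equal(unname(unlist(new$masses)),
               seir_init() + dt * unname(d), tolerance = 1e-13)
  # beta = 0: susceptible field untouched, exposed decays at rate zeta
  ep0 <- epidemic_params(0, zeta = 2, gamma = 1)
  new0 <- epidemic_exchange_step(flds, ep0, dt = dt)
  expect_equal(new0$values$S, flds$values$S)
  expect_equal(new0$values$E, flds$values$E * (1 - 2 * dt), tolerance = 1e-14)
  expect_error(epidemic_exchange_step(flds, ep, dt = 5), "smaller dt")
})

test_that("with the epidemic off the coupled solver reduces to one population", {
  g <- opinion_grid2d(20, 20)
  shape <- product_field(g, stationary_marginal(beta_spec(0.35, 0.15), g$plus),
                         stationary_marginal(beta_spec(0.55, 0.2), g$minus))
  flds <- shared_shape_fields(shape, c(0.4, 0.3, 0.2, 0.1))
  p <- opinion_params(0.05, 0.06, 0.4, 0.5)
  ep_off <- epidemic_params(beta = 0, zeta = 0, gamma = 0)
  sol_c <- solve_coupled(flds, p, ep_off, t_final = 5, dt = 0.05,
                         record_times = c(0, 5))
  sol_1 <- solve_single_population(density_field2d(g, shape$values / shape$mass),
                                   p, t_final = 5, dt = 0.05,
                                   record_times = c(0, 5))
  total <- Reduce(`+`, sol_c$fields[[2]]$values)
  expect_equal(total, sol_1$fields[[2]]$values, tolerance = 1e-12)
  # compartment masses do not move
  expect_equal(unname(unlist(sol_c$fields[[2]]$masses)),
               c(0.4, 0.3, 0.2, 0.1), tolerance = 1e-12)
})

test_that("PDE masses and means track the closed moment ODE system", {
  g <- opinion_grid2d(20, 20)
  shape <- product_field(g, stationary_marginal(beta_spec(1 / 3, 1 / 6), g$plus),
                         stationary_marginal(beta_spec(1 / 3, 1 / 6), g$minus))
  flds <- shared_shape_fields(shape, seir_init())
  ep <- epidemic_params(1.21, 1, 1)
  op <- opinion_params(0.0475, 0.0475, 0.3871, 0.3871)
  tt <- seq(0, 10, by = 0.5)
  sol <- solve_coupled(flds, op, ep, t_final = 10, dt = 0.05,
                       record_times = tt)
  fm <- field_moments(density_field2d(g, shape$values / shape$mass))
  im <- matrix(c(rep(fm$m_plus, 4), rep(fm$m_minus, 4)), 4, 2)
  orc <- moment_ode_oracle(ep, op, seir_init(), im, 10, times = tt)
  wide <- stats::reshape(sol$moments, idvar = "time",
                         timevar = "compartment", direction = "wide")
  mass_err <- max(abs(cbind(wide$mass.S, wide$mass.E, wide$mass.I,
                            wide$mass.R) - as.matrix(orc[, 2:5])))
  mean_err <- max(abs(cbind(wide$m_plus.S, wide$m_plus.E, wide$m_plus.I,
                            wide$m_plus.R) - as.matrix(orc[, 6:9])),
                  na.rm = TRUE)
  expect_lt(mass_err, 1e-2)
  expect_lt(mean_err, 1e-2)
})

test_that("the moment oracle conserves the global mean for equal rates", {
  ep <- epidemic_params(1.21, 1, 1)
  op <- opinion_params(0.05, 0.05, 0.4, 0.4)
  im <- matrix(c(0.2, 0.3, 0.4, 0.5, 0.5, 0.4, 0.3, 0.2), 4, 2)
  orc <- moment_ode_oracle(ep, op, seir_init(), im, 400)
  expect_lt(max(abs(orc$m_plus - orc$m_plus[1])), 1e-10)
  expect_lt(max(abs(orc$m_minus - orc$m_minus[1])), 1e-10)
  # long time: susceptible and recovered means meet at the global mean
  last <- utils::tail(orc, 1)
  expect_equal(last$m_plus_S, last$m_plus_R, tolerance = 1e-6)
  expect_equal(last$m_plus_S, last$m_plus, tolerance = 1e-6)
})

test_that("the printed exposed-loss variant distorts the exposed mean", {
  ep <- epidemic_params(1.21, 1, 1)
  op <- opinion_params(0.05, 0.05, 0.4, 0.4)
  im <- matrix(0.4, 4, 2)
  tt <- seq(0, 5, by = 0.25)
  ref <- moment_ode_oracle(ep, op, seir_init(), im, 5, times = tt)
  alt <- moment_ode_oracle(ep, op, seir_init(), im, 5, times = tt,
                           e_loss = "as-printed")
  # dimensionally consistent form keeps the symmetric state at 0.4;
  # the bare -zeta*rho_E variant pushes the exposed mean off it
  expect_lt(max(abs(ref$m_plus_E - 0.4), na.rm = TRUE), 1e-8)
  expect_gt(max(abs(alt$m_plus_E - 0.4), na.rm = TRUE), 0.05)
})

test_that("the calibrated run polarizes into a bimodal negative marginal", {
  g <- opinion_grid2d(20, 20)
  spS_p <- beta_spec_from_rates(cal_fix$positive$S$m,
                                cal_fix$positive$S$lambda,
                                cal_fix$positive$S$sigma)
  spS_m <- beta_spec_from_rates(cal_fix$negative$S$m,
                                cal_fix$negative$S$lambda,
                                cal_fix$negative$S$sigma)
  shape <- product_field(g, stationary_marginal(spS_p, g$plus),
                         stationary_marginal(spS_m, g$minus))
  init <- shared_shape_fields(shape, seir_init())
  ep <- epidemic_params(cal_fix$epidemic$beta, 1, 1)
  sol <- solve_coupled(init, cal_opinion(), ep, t_final = 600, dt = 0.05,
                       drift_target = "compartment",
                       target_means = cal_targets(),
                       record_times = c(0, 600))
  last <- sol$fields[[2]]
  # outbreak is over; survivors match the final-size prediction
  expect_lt(last$masses[["E"]] + last$masses[["I"]], 1e-10)
  # within the O(dt) accuracy of the explicit exchange step
  expect_lt(abs(last$masses[["S"]] -
                  final_size(cal_fix$epidemic$beta, 1, seir_init())), 2e-3)
  total <- Reduce(`+`, last$values)
  marg <- empirical_marginals(density_field2d(g, total))$minus
  md <- count_modes(marg)
  expect_equal(md$n_modes, 2L)
  # terminal marginal approaches the predicted two-component mixture
  rsi <- last$masses[["S"]]
  spR_m <- beta_spec_from_rates(cal_fix$negative$R$m,
                                cal_fix$negative$R$lambda,
                                cal_fix$negative$R$sigma)
  pred <- rsi * nodal_marginal(spS_m, g$minus) +
    (1 - rsi) * nodal_marginal(spR_m, g$minus)
  expect_lt(sum(abs(marg$values - pred)) * g$minus$dw, 5e-2)
})
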