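test_that("face weights are well behaved across regimes", {
  g <- opinion_grid1d(20)
  co <- scheme_coefficients(g, lambda = 0.05, m = 0.5, mu = 0.2)
  # symmetric drift: the central face is exactly the centered scheme
  expect_equal(co$delta_face[10], 0.5, tolerance = 1e-13)
  expect_equal(co$lambda_face[10], 0, tolerance = 1e-12)
  # delta in (0, 1) over a wide scan, including strongly advective faces
  for (mu in c(0.01, 0.2, 5)) {
    for (m in c(0.05, 0.5, 0.95)) {
      cc <- scheme_coefficients(opinion_grid1d(40), 0.5, m, mu = mu)
      expect_true(all(cc$delta_face > 0 & cc$delta_face < 1))
    }
  }
  cc2 <- scheme_coefficients(g, 1, 0.3, sigma = 0.05, closure = "sde_product")
  expect_true(all(cc2$delta_face > 0 & cc2$delta_face < 1))
  expect_error(scheme_coefficients(g, -1, 0.5, mu = 1), "positive")
  expect_error(scheme_coefficients(g, 1, 1.5, mu = 1), "\\(0, 1\\)")
})

test_that("the numerical flux vanishes identically on the analytic steady state", {
  # beta closure: nodal Beta(m/mu, (1-m)/mu)
  for (case in list(c(0.3, 0.2), c(0.0793, 0.317), c(0.6, 0.05))) {
    g <- opinion_grid1d(20)
    sp <- beta_spec(case[1], case[2])
    co <- scheme_coefficients(g, 0.05, case[1], mu = case[2])
    f <- stats::dbeta(g$centers, sp$a, sp$b)
    expect_lt(max(abs(face_fluxes(co, f))), 1e-10 * max(f))
  }
  # sde closure: the machinery preserves *its* steady state exp(-H)
  g <- opinion_grid1d(30)
  lam <- 0.05; sig <- 0.3; m <- 0.4
  co <- scheme_coefficients(g, lam, m, sigma = sig, closure = "sde_product")
  H <- betapolar:::.flux_antiderivative(g$centers, lam, m, NULL, sig,
                                        "sde_product")
  f <- exp(-(H - min(H)))
  expect_lt(max(abs(face_fluxes(co, f))), 1e-10 * max(f))
})

test_that("the semi-implicit sweep conserves mass, positivity and equilibria", {
  g <- opinion_grid1d(20)
  co <- scheme_coefficients(g, 0.05, 0.3, mu = 0.2)
  set.seed(10)
  f <- runif(20)
  f1 <- fp_sweep_1d(f, co, dt = g$dw)
  expect_equal(sum(f1), sum(f), tolerance = 1e-13)
  expect_true(all(f1 >= 0))
  # a very large step is still positive (M-matrix property)
  f2 <- fp_sweep_1d(f, co, dt = 50)
  expect_true(all(f2 >= 0))
  # steady state untouched over 1000 steps
  sp <- beta_spec(0.3, 0.2)
  fb <- stats::dbeta(g$centers, sp$a, sp$b)
  fk <- fb
  for (i in 1:1000) fk <- fp_sweep_1d(fk, co, dt = g$dw)
  expect_lt(max(abs(fk - fb)), 1e-8)
  # explicit mode under a diffusive step restriction stays nonnegative
  dt_cfl <- g$dw^2 / (2 * max(co$D_face))
  f3 <- fp_sweep_1d(fb, co, dt = dt_cfl, method = "explicit")
  expect_true(all(f3 >= 0))
})

test_that("the nonlinear 1-D marginal relaxes onto the Beta manifold", {
  g <- opinion_grid1d(20)
  # symmetric start: the discrete mean 0.5 is an exact fixed point, so the
  # solution converges to the nodal Beta(2.5, 2.5) sharply
  init <- stationary_marginal(beta_spec(0.5, 0.05), g)
  ev <- evolve_marginal(init, lambda = 0.05, mu = 0.2, n_steps = 6000)
  f <- ev$values / (sum(ev$values) * g$dw)
  expect_lt(sum(abs(f - nodal_marginal(beta_spec(0.5, 0.2), g))) * g$dw,
            1e-8)
  # asymmetric start: the solution tracks the nodal Beta at its own current
  # mean while that mean creeps at the O(dw^2) quadrature-bias rate
  init2 <- stationary_marginal(beta_spec(0.6, 0.1), g)
  ev2 <- evolve_marginal(init2, lambda = 0.05, mu = 0.2, n_steps = 4000)
  m_t <- utils::tail(ev2$means, 1)
  f2 <- ev2$values / (sum(ev2$values) * g$dw)
  expect_lt(sum(abs(f2 - nodal_marginal(beta_spec(m_t, 0.2), g))) * g$dw,
            5e-3)
  expect_lt(abs(m_t - 0.6), 0.01)   # drift over t = 200 stays sub-cell
})

test_that("halving the mesh reduces the steady-state representation error", {
  # fixed drift target: the scheme converges to the nodal Beta(m/mu), and
  # its distance to the cell-averaged analytic density shrinks with dw
  err <- vapply(c(20, 40, 80), function(n) {
    g <- opinion_grid1d(n)
    sp <- beta_spec(0.3, 0.2)
    ev <- evolve_marginal(stationary_marginal(beta_spec(0.5, 0.3), g),
                          lambda = 0.05, mu = 0.2, m = 0.3,
                          n_steps = 8000, dt = 0.05)
    f <- ev$values / (sum(ev$values) * g$dw)
    sum(abs(f - stationary_marginal(sp, g)$values)) * g$dw
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[2], 0.5 * err[1])
})

test_that("field moments match analytic product-Beta moments", {
  g <- opinion_grid2d(20, 20)
  sp22 <- beta_spec(0.5, 0.25)  # Beta(2,2): mean 1/2, var 1/20
  f <- product_field(g, stationary_marginal(sp22, g$plus),
                     stationary_marginal(sp22, g$minus))
  fm <- field_moments(f)
  expect_equal(fm$m_plus, 0.5, tolerance = 1e-10)
  expect_lt(abs(fm$v_plus - 0.05), 1e-3)
  expect_equal(fm$mass, 1, tolerance = 1e-12)
  # single-cell mass: variance bounded by the cell width scale
  v <- matrix(0, 20, 20); v[11, 11] <- 1 / g$cell_area
  fm1 <- field_moments(density_field2d(g, v))
  expect_lt(fm1$v_plus, g$plus$dw^2)
})

test_that("the 2-D splitting solver conserves mass and approaches equilibrium", {
  g <- opinion_grid2d(20, 20)
  # symmetric means, off-equilibrium spread: sharp convergence per axis
  init <- product_field(g, stationary_marginal(beta_spec(0.5, 0.05), g$plus),
                        stationary_marginal(beta_spec(0.5, 0.4), g$minus))
  p <- opinion_params(0.05, 0.05, 0.5, 0.5)  # mu = 0.2 per axis
  sol <- solve_single_population(init, p, t_final = 200,
                                 record_times = c(0, 200))
  mo <- sol$moments
  expect_lt(max(abs(mo$mass - 1)), 1e-12)
  expect_lt(abs(mo$m_plus[2] - 0.5), 1e-12)
  marg <- empirical_marginals(sol$fields[[2]])
  nod <- nodal_marginal(beta_spec(0.5, 0.2), g$plus)
  expect_lt(sum(abs(marg$plus$values - nod)) * g$plus$dw, 1e-8)
  expect_lt(sum(abs(marg$minus$values - nod)) * g$minus$dw, 1e-8)

  # asymmetric means: mass still exact, mean drift bounded by the
  # O(dw^2) quadrature bias over the horizon
  init2 <- product_field(g, stationary_marginal(beta_spec(2 / 7, 1 / 7), g$plus),
                         stationary_marginal(beta_spec(2 / 3, 1 / 6), g$minus))
  sol2 <- solve_single_population(init2, p, t_final = 150,
                                  record_times = c(0, 150))
  expect_lt(max(abs(sol2$moments$mass - 1)), 1e-12)
  expect_lt(abs(sol2$moments$m_plus[2] - sol2$moments$m_plus[1]),
            g$plus$dw / 2)
})

test_that("a symmetric discrete equilibrium keeps its means to round-off", {
  g <- opinion_grid2d(20, 20)
  init <- product_field(g, stationary_marginal(beta_spec(0.5, 0.2), g$plus),
                        stationary_marginal(beta_spec(0.5, 0.15), g$minus))
  p <- opinion_params(0.05, 0.05, sqrt(0.05 / 0.2), sqrt(0.05 / 0.15))
  sol <- solve_single_population(init, p, t_final = 100,
                                 record_times = c(0, 100))
  expect_lt(abs(sol$moments$m_plus[2] - sol$moments$m_plus[1]), 1e-12)
  expect_lt(abs(sol$moments$m_minus[2] - sol$moments$m_minus[1]), 1e-12)
})
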