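# shared fixtures: the reference calibration and small analytic helpers

cal_fix <- hesitancy_calibration()

neg_mix <- function() calibration_mixture(cal_fix, "minus")
pos_mix <- function() calibration_mixture(cal_fix, "plus")

# nodal representation of a Beta spec: cell-center values, discretely
# normalized — the exact fixed point of the structure-preserving scheme
nodal_marginal <- function(spec, grid) {
  v <- stats::dbeta(grid$centers, spec$a, spec$b)
  v / (sum(v) * grid$dw)
}

nodal_mixture <- function(mix, grid) {
  mix$weight_S * nodal_marginal(mix$spec_S, grid) +
    (1 - mix$weight_S) * nodal_marginal(mix$spec_R, grid)
}

# analytic moments of a two-component Beta mixture
mixture_moments <- function(mix) {
  mom <- function(sp) {
    m1 <- sp$a / (sp$a + sp$b)
    m2 <- m1 * (sp$a + 1) / (sp$a + sp$b + 1)
    c(m1, m2)
  }
  w <- mix$weight_S
  m <- w * mom(mix$spec_S) + (1 - w) * mom(mix$spec_R)
  list(mean = m[1], var = m[2] - m[1]^2)
}

# product-density field from two 1-D cell-averaged marginals
product_field <- function(grid2d, marg_plus, marg_minus) {
  density_field2d(grid2d, outer(marg_plus$values, marg_minus$values))
}

seir_init <- function() unname(cal_fix$epidemic$init)

# per-compartment opinion parameters / targets of the reference calibration
cal_opinion <- function() {
  mk <- function(side) opinion_params(
    lambda_plus = cal_fix$positive[[side]]$lambda,
    lambda_minus = cal_fix$negative[[side]]$lambda,
    sigma_plus = cal_fix$positive[[side]]$sigma,
    sigma_minus = cal_fix$negative[[side]]$sigma)
  list(S = mk("S"), E = mk("S"), I = mk("S"), R = mk("R"))
}

cal_targets <- function() {
  rbind(S = c(cal_fix$positive$S$m, cal_fix$negative$S$m),
        E = c(cal_fix$positive$S$m, cal_fix$negative$S$m),
        I = c(cal_fix$positive$S$m, cal_fix$negative$S$m),
        R = c(cal_fix$positive$R$m, cal_fix$negative$R$m))
}
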