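#' Reference calibration for the Italian vaccine-hesitancy case study
#'
#' The parameter set obtained by fitting stationary two-component Beta
#' mixtures to the final-snapshot marginals of an aggregated corpus of
#' 4077 posts from six Italian vaccine-hesitant Telegram chats
#' (August 2021 - February 2022), and by inverting the final-size
#' relation for the contact rate. These point estimates are shipped as the
#' package's reference configuration: they reproduce the case study
#' without access to the (non-redistributable) raw corpus.
#'
#' The equilibrium susceptible fraction `rho_S = 0.5188` is the fitted
#' mixture weight; each mixture component carries a mean `m`, compromise
#' rate `lambda` and diffusion coefficient `sigma` (only
#' `mu = lambda / sigma^2` is identified by the marginal shape). The
#' compartment dynamics uses `zeta = gamma = 1` per day (fake news lives
#' about a day), initial masses `(0.9, 0.05, 0.025, 0.025)` and the
#' contact rate `beta = 1.21` implied by the fitted `rho_S`.
#'
#' @return A list with elements `rho_S`, `negative` and `positive`
#'   (each a list of `S` and `R` component parameter sets with
#'   `m`, `lambda`, `sigma`), and `epidemic`
#'   (`zeta`, `gamma`, `init`, `beta`).
#' @examples
#' cal <- hesitancy_calibration()
#' calibration_mixture(cal, "minus")   # the bimodal negative marginal
#' @export
hesitancy_calibration <- function() {
  list(
    rho_S = 0.5188,
    negative = list(
      S = list(m = 0.0793, lambda = 0.0475, sigma = 0.3871),
      R = list(m = 0.5574, lambda = 0.0063, sigma = 0.1756)),
    positive = list(
      S = list(m = 0.0400, lambda = 0.0412, sigma = 0.4658),
      R = list(m = 0.1375, lambda = 0.0126, sigma = 0.3228)),
    epidemic = list(zeta = 1, gamma = 1,
                    init = c(S = 0.9, E = 0.05, I = 0.025, R = 0.025),
                    beta = 1.21))
}

#' Stationary Beta mixture implied by a calibration
#'
#' @param cal A calibration list as returned by [hesitancy_calibration()].
#' @param axis `"minus"` (negative scores; the bimodal one) or `"plus"`.
#' @return A [beta_mixture_spec()] with weight `cal$rho_S`.
#' @export
calibration_mixture <- function(cal = hesitancy_calibration(),
                                axis = c("minus", "plus")) {
  axis <- match.arg(axis)
  side <- if (axis == "minus") cal$negative else cal$positive
  beta_mixture_spec(
    cal$rho_S,
    beta_spec_from_rates(side$S$m, side$S$lambda, side$S$sigma),
    beta_spec_from_rates(side$R$m, side$R$lambda, side$R$sigma))
}
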