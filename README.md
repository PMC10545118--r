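# betapolar

Opinion polarization dynamics in closed online communities, coupled with a
compartmental description of fake-news dissemination.

## The problem

Sentiment-analysis pipelines score every post of a community with a pair
`(w+, w-) ∈ [0,1]²` — how positive and how negative the expressed opinion
is. In vaccine-hesitant group chats and similar echo chambers, the
empirical distribution of these scores drifts over months from a unimodal
cloud into a *bimodal* shape: a spike of mildly negative users plus a
second peak of strongly negative ones. `betapolar` provides the modelling
chain that explains, simulates and calibrates this phenomenon:

* an N-agent compromise SDE with bounded confidence and degenerate
  diffusion `σ·w(1-w)` (committed agents are deaf to noise), simulated by
  Euler–Maruyama (`simulate_agents()`);
* its mean-field limit: a nonlinear Fokker–Planck equation on `[0,1]²`
  with no-flux boundaries, solved by dimensional splitting with a
  structure-preserving (Chang–Cooper type) finite-volume scheme whose
  discrete steady states coincide *exactly* with the analytic ones
  (`solve_single_population()`, `scheme_coefficients()`);
* a fake-news SEIR compartment system coupled to one opinion density per
  compartment through an incidence functional (`solve_coupled()`,
  `integrate_seir()`, `final_size()`);
* closed-form stationary marginals: Beta densities
  `g∞(w) ∝ w^(a-1)(1-w)^(b-1)` with `a = m/μ`, `b = (1-m)/μ`,
  `μ = λ/σ²`, and — after an outbreak — two-component Beta mixtures
  weighted by the equilibrium susceptible fraction `ρS∞`
  (`beta_spec()`, `stationary_mixture()`, `count_modes()`);
* nonlinear least-squares calibration of those mixtures to binned
  sentiment marginals, plus the final-size inversion
  `β = γ·log(ρS(0)/ρS∞) / (1 - ρS∞ - ρR(0))` that turns a fitted
  mixture weight into the contact rate (`fit_beta_mixture()`,
  `invert_final_size()`);
* a synthetic-corpus generator with known ground truth, so the whole
  pipeline is testable without any scraped data
  (`generate_synthetic_dataset()`).

Intended users: modellers of opinion dynamics/infodemics who want a
reproducible reference implementation, and data analysts who want to fit
the Beta-mixture equilibrium theory to their own binned sentiment scores.

## Worked example

The package ships the reference calibration of an Italian vaccine-hesitant
Telegram corpus (4077 posts, six chats, Aug 2021–Feb 2022) as
`hesitancy_calibration()`.

```r
library(betapolar)
cal <- hesitancy_calibration()

## 1. the calibrated stationary negative-opinion mixture
mix <- calibration_mixture(cal, "minus")
print(mix)
#> <beta_mixture_spec> weight_S = 0.5188
#>   S: <beta_spec> m = 0.0793, mu = 0.317  (a = 0.2502, b = 2.904)
#>   R: <beta_spec> m = 0.5574, mu = 0.2043  (a = 2.728, b = 2.166)
cat("interior peak at w- =", round(interior_mode(mix, n = 1000), 3), "\n")
#> interior peak at w- = 0.562

## 2. contact rate from the final-size inversion
beta_hat <- invert_final_size(cal$rho_S, gamma = 1, init = cal$epidemic$init)
cat("inverted contact rate beta =", round(beta_hat, 4), "\n")
#> inverted contact rate beta = 1.2075

## 3. forward check: integrate the outbreak and compare survivors
tr <- integrate_seir(epidemic_params(beta_hat), cal$epidemic$init,
                     t_final = 200, dt = 1e-3)
cat("terminal susceptible fraction =", round(tail(tr$S, 1), 4), "\n")
#> terminal susceptible fraction = 0.5188

## 4. recover the mixture from a synthetic corpus of 4077 posts
ds <- generate_synthetic_dataset(
  stationary_truth(calibration_mixture(cal, "plus"), mix),
  n_posts = 4077, seed = 1)
marg <- empirical_marginals(bin_to_density(ds, opinion_grid2d(20, 20)))$minus
fit <- fit_beta_mixture(marg, fit_options(seed = 1))
print(fit)
#> <beta_mixture_fit> residual = 0.00149368 (converged)
#>  weight     m_S    mu_S     m_R    mu_R
#> 0.49893 0.06504 0.26043 0.53818 0.22060
```

Reading the numbers: the fitted mixture says 51.9% of the community never
engaged with the fake news (component S: boundary-peaked at `w- ≈ 0`, shape
`a < 1`, i.e. a spike of mild negativity), while the removed 48.1%
(component R, unimodal with mode near `w- = 0.6`) polarized into strong
negativity. Inverting the final-size relation turns the surviving fraction
into a contact rate of 1.21/day, and forward integration closes the loop:
the outbreak with that rate indeed leaves 0.5188 of the population
untouched. The recovery fit on a synthetic corpus of the same size lands
within the sampling spread of the truth (the mixture weight carries
`sd ≈ 0.06` at n = 4077 — see the methods vignette on identifiability).

A command-line wrapper with the same functionality (subcommands
`make-synthetic`, `simulate-abm`, `solve-seir`, `solve-meanfield`,
`solve-coupled`, `steady-state`, `fit-marginals`,
`reproduce-calibration`, `calibrate-contact-rate`) is installed at
`inst/cli/betapolar`; every run writes its artifacts plus a
`manifest.json` with config hash, seed and package version.

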