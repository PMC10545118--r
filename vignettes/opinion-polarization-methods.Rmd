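---
title: "Modelling sentiment polarization under misinformation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sentiment polarization under misinformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betapolar)
```

## The model

`betapolar` describes a closed online community (for instance, a cluster of
topical group chats) in which every post carries a pair of sentiment
intensities $w = (w_+, w_-) \in [0,1]^2$: how positive and how negative the
expressed opinion is. Keeping both coordinates matters — a fierce rant and a
mild remark can have the same *difference* of scores but mean very different
things for polarization.

At the agent level, opinions follow a compromise-plus-noise stochastic
system: agent $i$'s sentiment on each axis is pulled toward the opinions of
the agents it interacts with at rate $\lambda_\pm$, restricted (bounded
confidence) to partners within a radius $\Delta_\pm$, and is perturbed by
independent Brownian noise with amplitude $\sigma_\pm D(w)$. The diffusion
shape $D(w) = w(1-w)$ encodes that both very moderate and very committed
agents are deaf to random influences. With $\Delta = 1$ (group chats, where
everyone sees everyone) the drift reduces to alignment with the population
mean and the large-$N$ limit is a McKean–Vlasov process: the density
$f(w,t)$ obeys a nonlinear Fokker–Planck equation on $[0,1]^2$ with no-flux
boundaries, whose drift targets the density's own mean $m_\pm(t)$. Mass is
conserved exactly, and — because the diffusion degenerates at the boundary —
so are the mean opinions.

Misinformation enters as a compartment structure: every agent is
susceptible (never met the fake news), exposed (incubating it), infectious
(spreading it) or removed (dropped it), with contact rate $\beta$, inverse
latency $\zeta$ and inverse spreading time $\gamma$ (all per day; the
defaults $\zeta = \gamma = 1$ encode a news item that lives about a day).
The coupled system evolves one opinion density per compartment, with an
incidence functional $K(f_S, f_I)(w) = f_S(w)\int \kappa(w_*) f_I(w_*)
\,\mathrm{d}w_*$ moving density from S to E. Integrating over $w$ with a
constant contact function recovers the classical SEIR mass equations and,
with it, the final-size relation
$$\log\frac{\rho_S^\infty}{\rho_S(0)} =
  -\frac{\beta}{\gamma}\bigl(\rho_R^\infty - \rho_R(0)\bigr), \qquad
  \rho_R^\infty = 1-\rho_S^\infty,$$
which `final_size()` solves by bracketed root finding and
`invert_final_size()` inverts in closed form. Note the sign and the
initially-removed correction $\rho_R(0)$: with the reference initial masses
$(0.9, 0.05, 0.025, 0.025)$ and the fitted equilibrium
$\rho_S^\infty = 0.5188$ this inversion gives $\beta = 1.21$ (two
decimals); a variant without the correction is kept behind
`relation = "as-printed"` for comparison but has no admissible root.

## Stationary marginals and the shape convention

The 1-D marginals of the opinion density admit Beta-form stationary states
$$g^\infty(w) = C\, w^{a-1}(1-w)^{b-1}, \qquad
  a = m/\mu,\quad b = (1-m)/\mu,\quad \mu = \lambda/\sigma^2 .$$
This $(m, \mu)$ parameterization — mean location plus a single
compromise-to-diffusion ratio — is the package's convention throughout, and
is the one under which the reference calibration below reproduces its
published diagnostics (the interior peak of the negative marginal at
$w_- \approx 0.6$). Two facts follow and are asserted by tests:

* only $\mu = \lambda/\sigma^2$ is identified by a stationary marginal;
  reported $(\lambda, \sigma)$ pairs with equal ratio describe the same
  density (`fit_beta_mixture()` therefore fits in the identifiable
  `shape` parameterization by default and only reports representative
  rates on request);
* $\mu > \min(m, 1-m)$ gives $a < 1$ or $b < 1$: an integrable boundary
  singularity, the signature of extreme polarization. All cell values are
  therefore computed as exact cell integrals of the regularized incomplete
  Beta function (`stationary_marginal()`), never by midpoint sampling, and
  normalization constants come from the Beta function, never from numeric
  renormalization.

After an outbreak has burnt out, the population is a mixture of
never-reached and removed agents, so the stationary marginal is a
two-component Beta mixture with weights $(\rho_S^\infty, 1-\rho_S^\infty)$.
Depending on the component shapes the mixture is unimodal or bimodal;
bimodality is the model's signature of polarization, and `count_modes()` /
`interior_mode()` implement the diagnostics (strict local maxima on cell
averages; plateaus collapse to one central mode; boundary cells count when
strictly above their neighbor). For the reference calibration the
interior-peaked component has mode $(a-1)/(a+b-2) = 0.597$; the mixture's
own interior maximum sits slightly left of it (at $0.5625$ on a 1000-cell
grid) because the boundary component's decaying tail tilts the stationary
point. Both are reported: `beta_mode()` for the component, and
`interior_mode()` for the literal mixture maximum.

## Diffusion closures

The package solves the 1-D marginal flux problem
$\partial_t f = \partial_w\bigl[(B + \hat D')f + \hat D\,\partial_w f\bigr]$
with drift $B(w) = \lambda (w - m)$ and a choice of degenerate diffusion
$\hat D$:

* **`beta` closure (default).** $\hat D(w) = \lambda\mu\, w(1-w)$. Its
  exact stationary density is the $\mathrm{Beta}(m/\mu, (1-m)/\mu)$
  marginal above, so every equilibrium statement of the theory holds
  *exactly* for the solver. This is the closure used for calibration,
  long-time and coupled runs.
* **`sde_product` closure.** $\hat D(w) = (\sigma^2/2)\,w^2(1-w)^2$, the
  literal Fokker–Planck diffusion of the agent equation with noise
  amplitude $\sigma\, w(1-w)$. It is the right object for validating the
  particle simulation: the acceptance test compares `simulate_agents()`
  moments at $N = 10^4$ against this closure and finds agreement within
  three Monte-Carlo standard errors.

The two closures have the same drift and both conserve mass and (at the
continuous level) the mean; they differ in their equilibrium families. The
package treats the choice as an explicit modelling option rather than
hiding one inside the other, because the $(m,\mu)$ Beta family is what the
data calibration identifies while the product-SDE form is what the agent
model simulates. The ABM's `distance` diffusion $D = |w - m|$ (consensus
formation, variance $V(t) = V(0)e^{(\sigma^2- 2\lambda)t}$ when
$2\lambda > \sigma^2$) is supported in the particle simulator only: its
diffusion vanishes in the interior, where the flux scheme's face integral
would be singular.

## The structure-preserving flux scheme

Each 1-D operator is discretized with an exponentially fitted (Chang–Cooper
type) finite-volume flux on a uniform mesh: at each interior face,
$$F_{i+1/2} = \tilde C_{i+1/2} \bigl[(1-\delta_{i+1/2}) f_{i+1} +
  \delta_{i+1/2} f_i \bigr] + D_{i+1/2}\frac{f_{i+1}-f_i}{\Delta w},
  \qquad
  \delta = \frac{1}{\lambda_f} + \frac{1}{1 - e^{\lambda_f}},$$
with $\lambda_f = \Delta w \tilde C / D_{i+1/2}$ and $\tilde C$ built from
the *exact* antiderivative of $(B + \hat D')/\hat D$ across the face
(closed-form partial fractions for both closures; the $\lambda_f \to 0$
limit $\delta = 1/2$ is handled by series). Three structural properties
follow and are asserted exactly in the tests:

* the discrete flux vanishes identically when $f$ equals the analytic
  steady state evaluated at the cell centers — the scheme's defining
  property (measured: $10^{-17}$ relative flux; $L^\infty$ change
  $3\times10^{-15}$ after 1000 steps);
* $\delta \in (0,1)$ always, so the semi-implicit update
  $(I - \Delta t\,A)f^{n+1} = f^n$ is an M-matrix system: positive for any
  step size;
* fluxes telescope, so mass is conserved to round-off; the no-flux
  boundary faces carry exactly zero flux (the domain faces sit where the
  diffusion degenerates, so nothing is lost by pinning them).

The 2-D solver applies first-order (Lie) splitting: all lines are swept
semi-implicitly along $w_+$, means are recomputed, all lines along $w_-$,
then (in the coupled system) the compartment-exchange reactions are
integrated cellwise with a simple explicit step. The nonlinearity is
handled by lagging the drift target one step (the "semi-implicit"
linearization). The default step is $\Delta t = \Delta w$ on a 20-cell
mesh — a deliberately coarse working resolution at which all structural
properties above still hold exactly; refinement tests confirm the expected
error decay when mesh and step are halved.

**A genuine limitation worth knowing about.** The *self-consistent* drift
target is the density's own discrete mean, computed by cell-center
quadrature. Every nodal Beta profile is an exact fixed point of the sweep
*for the mean its coefficients were built with*, but the recomputed
discrete mean of that profile differs from the coefficient mean by an
$O(\Delta w^2)$ quadrature bias. The result is a slow creep of the mean
along a manifold of quasi-equilibria (measured: $\lesssim 0.01$ over 200
days on 20 cells, vanishing under refinement and exactly zero for
symmetric states $m = 0.5$ or fixed drift targets). The conservation tests
therefore distinguish sharply between what holds to round-off (mass,
always; means, at symmetric or fixed-target equilibria) and what holds to
$O(\Delta w^2)$ (means through generic transients). The headline
conservation run — compartment-independent rates, shared equilibrium
shape, full outbreak to $t = 200$ — keeps the global means constant to
below $10^{-5}$.

## The coupled system and its moment oracle

With a constant contact function the compartment masses close into the
SEIR equations and the first moments $\rho_J m_J^\pm$ close into a 12-state
ODE system (incidence, latency and removal transfer moments between
compartments; compromise pulls each $m_J$ toward the global mass-weighted
mean). `moment_ode_oracle()` integrates this system with an adaptive
high-accuracy solver and is the package's strongest whole-system check: at
$20\times20$, $\Delta t = 0.05$, the PDE's masses and means track it to
better than $10^{-2}$ over 20 days, and the error shrinks by more than 30%
when mesh and step are halved (it is dominated by the explicit Euler
exchange step, whose error is $O(\Delta t)$). The exposed-compartment
moment loss is $-\zeta \rho_E m_E$, the form required by integrating the
density equations (a variant with the bare $-\zeta\rho_E$ is available for
comparison and demonstrably distorts the exposed mean).

Two drift-target regimes are supported, because they answer different
questions:

* `drift_target = "global"` (default): all compartments relax toward the
  common mass-weighted means — the form in which the coupled density
  equations are written, and the regime in which the global means are
  conserved when the compromise rates are compartment-independent;
* `drift_target = "compartment"`: each compartment relaxes toward a fixed
  target mean (its own calibrated equilibrium location). This is the
  regime in which a calibrated two-component mixture with *distinct*
  component means is an exact stationary state, i.e. the regime that the
  equilibrium mixture ansatz of the calibration actually describes; it is
  how the package reproduces the emergence of the bimodal negative
  marginal. Mechanistically it describes echo-chamber dynamics: members of
  each compartment align within their own subcommunity's climate rather
  than with the population average.

The reproduction run (reference calibration, susceptible-shape initial
condition scaled by $(0.9, 0.05, 0.025, 0.025)$, compartment targets)
ends, after the outbreak transfers $\approx 48\%$ of the mass to the
removed compartment, in a terminal negative marginal with exactly two
modes on the 20-cell mesh — a boundary spike of mildly negative
never-reached agents plus an interior bump of strongly negative removed
agents — within $L^1 = 0.023$ of the predicted two-component mixture at
$t = 600$ (and $5\times10^{-4}$ at $t = 1200$). The comparison uses the
nodal representation of the mixture (cell-center values, discretely
normalized), which is the scheme's own fixed-point representation; for a
boundary-singular component, nodal and cell-averaged representations
legitimately differ by $O(1)$ in the first cell of a coarse mesh.

## Calibration

`fit_beta_mixture()` solves the nonlinear least-squares problem of
matching a binned empirical marginal with a two-component mixture of
cell-averaged Beta densities, over $(\rho_S, m_S, \mu_S, m_R, \mu_R)$. The
optimizer is Levenberg–Marquardt on smoothly transformed variables
(logistic for the weight and the means, log for the ratios — box
constraints without clipping), restarted from 32 Latin-hypercube points;
components are reordered by ascending mean to resolve label switching, and
the returned optimum is the best over all starts. On noiseless input the
generating parameters are recovered to machine precision; about 70% of
random starts reach the global basin on the reference mixture.

On *sampled* input the mixture weight is weakly identified: at the corpus
scale of $n = 4077$ posts its sampling spread is $\mathrm{sd} \approx
0.06$ (the property tests measure this over 20 seeds, finding the
estimator unbiased to better than $0.05$ with per-seed deviations up to
$\approx 0.12$). This is an information bound of the mixture at this
sample size, not an optimizer artifact — a maximum-likelihood fit on the
raw scores started at the truth shows the same spread — and it should be
kept in mind when interpreting any single fitted weight at this corpus
scale.

The epidemic side is calibrated in two steps: the fitted equilibrium
weight is read as the never-reached fraction $\rho_S^\infty$, and the
final-size inversion turns it into the contact rate ($\beta = 1.21$ for
the reference data). Forward integration with that two-decimal rate
returns a terminal susceptible fraction of $0.5172$, i.e. within the
$\approx 0.003$ sensitivity band that two-decimal rounding of $\beta$
implies (the unrounded rate reproduces $0.5188$ to $10^{-6}$).

## The synthetic-data generator

Because the raw group-chat corpus is not redistributable, every test runs
on generated data. `generate_synthetic_dataset()` draws post times i.i.d.
uniformly over the observation window (default 190 days) and score pairs
independently per axis from either a fixed pair of Beta mixtures
(`stationary_truth()`) or a pair whose parameters interpolate linearly in
time between an initial and a final state (`drifting_truth()`, emulating a
community that polarizes over the window). Group labels are sampled
uniformly over six chat labels. What this emulates: the marginal score
distributions, their drift, the corpus size, and the binning pipeline
(20×20 half-open cells, scores of exactly 1 kept in the last cell, each
window normalized to a probability density). What it does not emulate:
within-axis/between-axis score correlation (axes are sampled
independently), per-chat heterogeneity, bursty posting times, and NLP
scoring error. Passing recovery tests therefore demonstrate correctness of
the estimation machinery under the model's own assumptions, not robustness
to the ways real sentiment pipelines violate them.

## Problem sizes used by the test-suite

Chosen as the package's working desk scale: 20-cell meshes (40 for
refinement checks), $\Delta t = 0.05$ day for field solves and $10^{-3}$
day for mass-ODE integrations, $N = 10^4$ agents for mean-field
consistency, $10^5$–$10^6$ samples for distributional checks, 20 seeds ×
4077 posts for the recovery study, and coupled horizons of 20–600 days.

## Known limitations

* The mean-quadrature creep described above: self-consistent means on
  coarse meshes drift at $O(\Delta w^2)$ through transients.
* The explicit exchange step limits coupled-run mass accuracy to
  $O(\Delta t)$ (about $10^{-3}$ at the default step over 20 days); the
  `rk4` exchange variant removes this at negligible cost.
* The mixture weight at corpus scale carries $\pm 0.1$-level sampling
  uncertainty (see Calibration); drawing epidemiological conclusions from
  a single fitted weight requires either more data or interval estimates.
* The coupled model with global drift targets cannot sustain distinct
  component means at exact stationarity; the compartment-target regime
  exists precisely to represent the calibrated mixture as a steady state,
  and which regime better describes a given community is a modelling
  judgement, not something the package decides.
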