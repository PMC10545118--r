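#' Parameters of the bivariate opinion-formation dynamics
#'
#' Each agent carries a pair of sentiment intensities `(W+, W-)` in
#' `[0, 1]^2`. Pairwise compromise acts at rate `lambda` per axis,
#' restricted to partners whose opinion on that axis differs by at most
#' the confidence radius `delta` (bounded confidence); `delta = 1` means
#' everyone interacts with everyone, and the drift collapses to alignment
#' with the population mean. Self-thinking noise enters with amplitude
#' `sigma * D(w)`, where the diffusion shape is either
#' `product` (`D(w) = w (1 - w)`, vanishing at both extremes so committed
#' agents are deaf to noise) or `distance` (`D(w) = |w - m|`, agents near
#' the consensus stop self-thinking; drives consensus when
#' `2 lambda > sigma^2`).
#'
#' @param lambda_plus,lambda_minus Compromise rates (per day), >= 0.
#' @param sigma_plus,sigma_minus Diffusion coefficients, >= 0.
#' @param delta_plus,delta_minus Confidence radii in `[0, 1]` (default 1).
#' @param diffusion `"product"` or `"distance"`.
#' @return Object of class `opinion_params`.
#' @export
opinion_params <- function(lambda_plus = 0.05, lambda_minus = 0.05,
                           sigma_plus = 0.05, sigma_minus = 0.05,
                           delta_plus = 1, delta_minus = 1,
                           diffusion = c("product", "distance")) {
  diffusion <- match.arg(diffusion)
  vals <- c(lambda_plus, lambda_minus, sigma_plus, sigma_minus)
  if (any(vals < 0)) stop("rates and diffusion coefficients must be >= 0")
  if (any(c(delta_plus, delta_minus) < 0 | c(delta_plus, delta_minus) > 1))
    stop("confidence radii must lie in [0, 1]")
  structure(list(lambda_plus = lambda_plus, lambda_minus = lambda_minus,
                 sigma_plus = sigma_plus, sigma_minus = sigma_minus,
                 delta_plus = delta_plus, delta_minus = delta_minus,
                 diffusion = diffusion),
            class = "opinion_params")
}

#' Population moments of an agent ensemble
#'
#' Arithmetic means and population variances (denominator `N`) of both
#' opinion components.
#'
#' @param w `N x 2` matrix of opinions in `[0, 1]^2`.
#' @return List with `m_plus`, `m_minus`, `v_plus`, `v_minus`.
#' @export
population_moments <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) < 1L || ncol(w) != 2L) stop("w must be an N x 2 matrix, N >= 1")
  m <- colMeans(w)
  v <- colMeans(w^2) - m^2
  list(m_plus = m[1], m_minus = m[2],
       v_plus = max(v[1], 0), v_minus = max(v[2], 0))
}

# One-axis drift: full O(N^2) bounded-confidence sum for delta < 1,
# algebraically identical O(N) mean shortcut for delta = 1.
.abm_drift <- function(x, lambda, delta) {
  if (lambda == 0) return(numeric(length(x)))
  if (delta >= 1) return(lambda * (mean(x) - x))
  n <- length(x)
  dif <- outer(x, x, "-")            # dif[i,j] = x_i - x_j
  mask <- abs(dif) <= delta
  lambda * rowSums(-dif * mask) / n  # (1/N) sum_j (x_j - x_i) over partners
}

.abm_diffusion <- function(x, kind, m) {
  switch(kind,
         product = x * (1 - x),
         distance = abs(x - m))
}

#' Euler-Maruyama simulation of the N-agent opinion system
#'
#' Per step and axis, each agent moves by the bounded-confidence
#' compromise drift plus independent Gaussian noise scaled by
#' `sigma * D(w) * sqrt(dt)`, and is then projected back onto `[0, 1]`
#' (the boundary rule that keeps opinion vectors admissible; with the
#' product diffusion the noise already vanishes at the boundary, so the
#' projection is rarely active).
#'
#' @param params An [opinion_params()].
#' @param init `N x 2` matrix of initial opinions in `[0, 1]^2`.
#' @param t_final Final time (days), >= 0.
#' @param dt Time step, > 0.
#' @param seed Integer seed.
#' @param record_times Times at which snapshots are stored (matched to the
#'   nearest step); default `c(0, t_final)`.
#' @return List with `times` (the matched record times), `snapshots`
#'   (list of `N x 2` matrices) and `moments` (data frame of
#'   `time, m_plus, m_minus, v_plus, v_minus` at every recorded time).
#' @export
simulate_agents <- function(params, init, t_final, dt, seed,
                            record_times = NULL) {
  stopifnot(inherits(params, "opinion_params"))
  w <- as.matrix(init)
  if (nrow(w) < 1L || ncol(w) != 2L) stop("init must be an N x 2 matrix")
  if (any(w < 0 | w > 1)) stop("initial opinions must lie in [0, 1]^2")
  if (dt <= 0) stop("dt must be positive")
  if (t_final < 0) stop("t_final must be >= 0")
  if (missing(seed)) stop("a seed is required")
  set.seed(as.integer(seed))
  n_steps <- if (t_final == 0) 0L else as.integer(round(t_final / dt))
  if (is.null(record_times)) record_times <- c(0, t_final)
  rec_steps <- unique(pmin(pmax(as.integer(round(record_times / dt)), 0L),
                           n_steps))
  N <- nrow(w)
  snapshots <- vector("list", length(rec_steps))
  times <- rec_steps * dt
  k <- 1L
  store <- function(step, w) {
    while (k <= length(rec_steps) && rec_steps[k] == step) {
      snapshots[[k]] <<- w
      k <<- k + 1L
    }
  }
  store(0L, w)
  sqdt <- sqrt(dt)
  for (s in seq_len(n_steps)) {
    mp <- mean(w[, 1]); mm <- mean(w[, 2])
    d1 <- .abm_drift(w[, 1], params$lambda_plus, params$delta_plus)
    d2 <- .abm_drift(w[, 2], params$lambda_minus, params$delta_minus)
    g1 <- .abm_diffusion(w[, 1], params$diffusion, mp)
    g2 <- .abm_diffusion(w[, 2], params$diffusion, mm)
    w[, 1] <- w[, 1] + d1 * dt + params$sigma_plus * g1 * sqdt * stats::rnorm(N)
    w[, 2] <- w[, 2] + d2 * dt + params$sigma_minus * g2 * sqdt * stats::rnorm(N)
    w[w < 0] <- 0; w[w > 1] <- 1
    store(s, w)
  }
  moments <- do.call(rbind, lapply(seq_along(snapshots), function(i) {
    mo <- population_moments(snapshots[[i]])
    data.frame(time = times[i], m_plus = mo$m_plus, m_minus = mo$m_minus,
               v_plus = mo$v_plus, v_minus = mo$v_minus)
  }))
  list(times = times, snapshots = snapshots, moments = moments)
}
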