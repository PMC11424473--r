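#' Parameters of the 1D margin contractility model
#'
#' The embryo margin is modelled as a closed tensile line of fixed total
#' length. Active tension `Ta` self-activates where the line contracts and is
#' inhibited by the (spatially uniform) passive tension, yielding a mechanical
#' analogue of an activator--inhibitor system in the limit of an infinitely
#' fast, infinitely long-ranged inhibitor.
#'
#' Default values are nondimensional (`T0 = 1`, `tau = 1`, `L = 2*pi`) and are
#' calibrated (see `scripts/calibrate.R`) so that the homogeneous state is
#' linearly unstable and the patterned steady state devotes about 37% of the
#' margin to the contracting domain, the proportion measured in control
#' embryos. Physical units are mm, hours and an arbitrary force unit.
#'
#' @param T0 baseline active-tension scale (force units).
#' @param zeta relative modulation amplitude of active tension, in `[0, 1)`.
#' @param alpha feedback offset (dimensionless); negative values bias the
#'   margin towards stretching, shrinking the contracting domain below 1/2.
#' @param beta mechanical feedback strength (dimensionless). The homogeneous
#'   state destabilizes when `beta * zeta * sech(alpha)^2 > 1`.
#' @param tau regulation timescale (h).
#' @param D contractility diffusivity (mm^2/h); sets the front width
#'   `sqrt(D * tau)`.
#' @param nu 1D margin viscosity (force * h).
#' @param L margin length (mm).
#' @param advection_on logical; advect `Ta` with the tangential velocity `u`.
#'   Off by default: regulation is faster than advection in the embryo.
#' @param n_grid number of grid points (>= 16).
#' @param dt time step (h); must satisfy `dt <= tau` (explicit reaction) and
#'   the advective CFL condition when advection is on.
#' @param seed integer seed used by stochastic initial conditions.
#' @param free_tension if non-`NULL`, models a margin whose tension has been
#'   released by cutting a free-floating piece: the long-range inhibitor
#'   (the self-consistent uniform tension) is replaced by this fixed external
#'   tension, length is no longer conserved, and the strain rate is
#'   `(free_tension - Ta) / nu`. With `free_tension` below the active
#'   tension everywhere, the contracting domain grows uninhibited to occupy
#'   the entire margin.
#' @return object of class `params_1d`.
#' @export
params_1d <- function(T0 = 1, zeta = 0.75, alpha = -1.2, beta = 6,
                      tau = 1, D = 0.00125, nu = 3, L = 2 * pi,
                      advection_on = FALSE, n_grid = 1024, dt = 0.02,
                      seed = 1L, free_tension = NULL) {
  stopifnot(tau > 0, nu > 0, D >= 0, zeta >= 0, zeta < 1,
            n_grid >= 16, T0 > 0, L > 0, dt > 0)
  if (dt > tau)
    stop("dt = ", dt, " violates the stability bound dt <= tau = ", tau)
  p <- list(T0 = T0, zeta = zeta, alpha = alpha, beta = beta, tau = tau,
            D = D, nu = nu, L = L, advection_on = isTRUE(advection_on),
            n_grid = as.integer(n_grid), dt = dt, seed = as.integer(seed),
            free_tension = free_tension)
  class(p) <- "params_1d"
  p
}

#' Homogeneous fixed point of the 1D model
#'
#' At spatial homogeneity the strain rate vanishes and the active tension
#' relaxes to `T* = T0 * (1 + zeta * tanh(alpha))`.
#'
#' @param params a [params_1d()] object.
#' @return the stationary uniform active tension (force units).
#' @export
homogeneous_fixed_point <- function(params) {
  stopifnot(inherits(params, "params_1d"))
  params$T0 * (1 + params$zeta * tanh(params$alpha))
}

#' Strain rate from an active-tension profile
#'
#' With the surrounding tissue neglected, force balance makes the total
#' tension `T = Ta + nu * strain_rate` uniform along the margin, and length
#' conservation forces the mean strain rate to zero, so
#' `strain_rate(s) = (mean(Ta) - Ta(s)) / nu`: regions of above-average active
#' tension contract (negative strain rate), the rest stretches.
#'
#' @param Ta numeric profile of active tension.
#' @param nu 1D viscosity (> 0).
#' @return strain-rate profile with exactly zero mean (enforced).
#' @export
strain_rate_from_Ta <- function(Ta, nu) {
  if (!all(is.finite(Ta))) stop("non-finite active tension")
  stopifnot(nu > 0)
  eps <- (mean(Ta) - Ta) / nu
  eps - mean(eps)  # kill residual roundoff in the mean
}

# tangential velocity from strain rate: du/ds = eps, zero spatial mean gauge
velocity_from_strain_rate <- function(eps, ds) {
  u <- cumsum(eps) * ds
  u - mean(u)
}

#' Construct a 1D margin state
#'
#' @param params a [params_1d()] object.
#' @param init either a numeric profile of length `n_grid`, or a preset name:
#'   `"fixed_point"` (uniform stationary state), `"posterior_bias"`
#'   (cosine modulation, high at the posterior `s = 0`), or `"noise"`
#'   (fixed point plus seeded Gaussian noise of amplitude `1e-3 * T0`).
#' @param t initial time (h).
#' @return object of class `margin_state_1d` with fields `s`, `Ta`, `T`
#'   (uniform total tension), `strain_rate`, `u`, `t`.
#' @export
margin_state_1d <- function(params, init = "posterior_bias", t = 0) {
  stopifnot(inherits(params, "params_1d"))
  n <- params$n_grid
  s <- seq(0, params$L, length.out = n + 1L)[-(n + 1L)]
  Tstar <- homogeneous_fixed_point(params)
  if (is.character(init)) {
    Ta <- switch(match.arg(init, c("fixed_point", "posterior_bias", "noise")),
      fixed_point = rep(Tstar, n),
      posterior_bias = Tstar + 0.2 * params$zeta * params$T0 *
        cos(2 * pi * s / params$L),
      noise = {
        set.seed(params$seed)
        Tstar + 1e-3 * params$T0 * stats::rnorm(n)
      })
  } else {
    stopifnot(is.numeric(init), length(init) == n, all(is.finite(init)))
    Ta <- as.numeric(init)
  }
  finish_state_1d(s, Ta, t, params)
}

finish_state_1d <- function(s, Ta, t, params) {
  ds <- params$L / length(s)
  if (is.null(params$free_tension)) {
    eps <- strain_rate_from_Ta(Ta, params$nu)
    Ttot <- mean(Ta)
  } else {
    eps <- (params$free_tension - Ta) / params$nu
    Ttot <- params$free_tension
  }
  st <- list(s = s, Ta = Ta, T = Ttot, strain_rate = eps,
             u = velocity_from_strain_rate(eps, ds), t = t)
  class(st) <- "margin_state_1d"
  st
}

# semi-implicit periodic diffusion via FFT: solves (I - dt*D*Lap) x_new = x
diffuse_periodic <- function(x, D, dt, ds) {
  if (D <= 0 || dt <= 0) return(x)
  n <- length(x)
  lam <- -(2 - 2 * cos(2 * pi * (seq_len(n) - 1L) / n)) / ds^2
  Re(stats::fft(stats::fft(x) / (1 - dt * D * lam), inverse = TRUE)) / n
}

#' Advance the 1D margin model by one time step
#'
#' Reaction (explicit Euler), diffusion (semi-implicit spectral solve,
#' unconditionally stable), and optional first-order upwind advection by the
#' tangential velocity. The explicit reaction update is a convex combination
#' for `dt <= tau`, so active tension started inside the band
#' `[T0(1-zeta), T0(1+zeta)]` remains there (discrete maximum principle).
#'
#' @param state a [margin_state_1d()] object.
#' @param params a [params_1d()] object.
#' @param dt step (h); defaults to `params$dt`.
#' @return the advanced `margin_state_1d`.
#' @export
step_1d <- function(state, params, dt = params$dt) {
  stopifnot(inherits(state, "margin_state_1d"), inherits(params, "params_1d"))
  if (dt > params$tau)
    stop("dt = ", dt, " violates the stability bound dt <= tau")
  n <- length(state$Ta)
  ds <- params$L / n
  Ta <- state$Ta
  inhibitor <- if (is.null(params$free_tension)) mean(Ta)
               else params$free_tension
  target <- params$T0 * (1 + params$zeta *
    tanh(params$alpha + params$beta * (Ta - inhibitor) / params$T0))
  Ta_new <- Ta + dt / params$tau * (target - Ta)
  if (params$advection_on) {
    u <- state$u
    cfl <- max(abs(u)) * dt / ds
    if (cfl > 1)
      stop("advective CFL violated: max|u|*dt/ds = ", signif(cfl, 3))
    fwd <- c(Ta[-1], Ta[1])
    bwd <- c(Ta[n], Ta[-n])
    dTa <- ifelse(u > 0, Ta - bwd, fwd - Ta)
    Ta_new <- Ta_new - dt * u * dTa / ds
  }
  Ta_new <- diffuse_periodic(Ta_new, params$D, dt, ds)
  if (!all(is.finite(Ta_new)))
    stop("NaN/Inf in active tension at t = ", state$t + dt,
         " (dt too large or parameters pathological)")
  finish_state_1d(state$s, Ta_new, state$t + dt, params)
}

#' Simulate the 1D margin model
#'
#' Driver around [step_1d()]: integrates from an initial condition to `t_end`
#' and collects a strain-rate kymograph plus sampled states. Deterministic
#' given `params$seed` (the seed only enters through the `"noise"` preset).
#'
#' @param params a [params_1d()] object.
#' @param initial initial condition, as in [margin_state_1d()].
#' @param t_end final time (h), > 0.
#' @param save_every save a state every this many steps (default: ~100 saved
#'   frames over the run).
#' @return a list with `kymograph` (a [kymograph()]), `states` (list of
#'   sampled `margin_state_1d`), `times`, and `params`.
#' @export
simulate_1d <- function(params, initial = "posterior_bias", t_end,
                        save_every = NULL) {
  stopifnot(t_end > 0)
  n_steps <- ceiling(t_end / params$dt)
  if (is.null(save_every)) save_every <- max(1L, floor(n_steps / 100))
  state <- if (inherits(initial, "margin_state_1d")) initial
           else margin_state_1d(params, initial)
  states <- list(state)
  times <- state$t
  eps_rows <- list(state$strain_rate)
  for (i in seq_len(n_steps)) {
    state <- step_1d(state, params)
    if (i %% save_every == 0L || i == n_steps) {
      states[[length(states) + 1L]] <- state
      times <- c(times, state$t)
      eps_rows[[length(eps_rows) + 1L]] <- state$strain_rate
    }
  }
  ky <- kymograph(times = times,
                  positions = state$s,
                  strain_rate = do.call(rbind, eps_rows),
                  margin_length = params$L)
  list(kymograph = ky, states = states, times = times, params = params)
}

#' Linear growth rate of a zero-mean mode about the homogeneous state
#'
#' Linearizing the model about the homogeneous fixed point for a zero-mean
#' perturbation of wavenumber `k` gives
#' `sigma(k) = (beta * zeta * sech(alpha)^2 - 1) / tau - D * k^2`.
#' The `k = 0` mode is excluded: length conservation removes it. The
#' homogeneous state is unstable (mechanical Turing instability) when
#' `beta * zeta * sech(alpha)^2 > 1` and `D` is small enough that some
#' admissible `k` still grows.
#'
#' @param params a [params_1d()] object.
#' @param k wavenumber (1/mm), nonzero; may be a vector.
#' @return growth rate(s) (1/h).
#' @export
dispersion_growth_rate <- function(params, k) {
  stopifnot(inherits(params, "params_1d"))
  if (any(k == 0)) stop("k = 0 excluded: the mean mode is removed by length conservation")
  sech2 <- 1 / cosh(params$alpha)^2
  (params$beta * params$zeta * sech2 - 1) / params$tau - params$D * k^2
}

#' Fraction of the margin that is actively contracting
#'
#' Arclength fraction of nodes with strictly negative strain rate; ties
#' (zero strain rate, within a small relative tolerance absorbing roundoff)
#' count as non-contracting, so a homogeneous state returns 0. In the
#' patterned regime this fraction is set by front homeostasis and is
#' independent of the margin length `L` at fixed other parameters.
#'
#' @param state a `margin_state_1d` object.
#' @return fraction in `[0, 1]`.
#' @export
domain_fraction <- function(state) {
  stopifnot(inherits(state, "margin_state_1d"))
  eps <- state$strain_rate
  tol <- 1e-9 * max(abs(eps), abs(state$T), 1e-300)
  mean(eps < -tol)
}

#' Diffusion-time estimate by quadratic scaling
#'
#' Time for diffusive transport over a distance `L`, scaled quadratically from
#' a reference: `t = t_ref * (L / L_ref)^2`. With the literature calibration
#' of about 2 h for a small protein over 1 mm, the ~2 mm posterior-to-anterior
#' span of the margin gives about 8 h -- too slow for the observed few-hour
#' redirection of gene expression, motivating a mechanical long-range signal.
#'
#' @param L distance (mm).
#' @param t_ref reference diffusion time (h), default 2.
#' @param L_ref reference distance (mm), default 1.
#' @return estimated time (h).
#' @export
diffusion_time_estimate <- function(L, t_ref = 2, L_ref = 1) {
  if (any(c(L, t_ref, L_ref) <= 0)) stop("all arguments must be positive")
  t_ref * (L / L_ref)^2
}

#' Write a 1D state history as a delimited-text table
#'
#' Long-format table with columns `time`, `s`, `Ta`, `strain_rate`, `u`
#' (schema stable; tab-separated).
#'
#' @param sim result of [simulate_1d()].
#' @param file output path.
#' @return the file path, invisibly.
#' @export
write_margin_history_1d <- function(sim, file) {
  rows <- lapply(sim$states, function(st)
    data.frame(time = st$t, s = st$s, Ta = st$Ta,
               strain_rate = st$strain_rate, u = st$u))
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
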