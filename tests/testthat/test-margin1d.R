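# 1D self-organized margin contractility model

test_that("homogeneous fixed point follows the closed form and is stationary", {
  expect_equal(homogeneous_fixed_point(params_1d(zeta = 0)), 1)
  expect_equal(homogeneous_fixed_point(params_1d(alpha = 0, zeta = 0.5)), 1)
  p <- params_1d(T0 = 1, zeta = 0.5, alpha = 1)
  expect_equal(homogeneous_fixed_point(p), 1 + 0.5 * tanh(1))
  # dynamics started exactly at the fixed point stay there
  p2 <- params_1d(n_grid = 64)
  st <- margin_state_1d(p2, "fixed_point")
  for (i in 1:50) st <- step_1d(st, p2)
  expect_equal(st$Ta, rep(homogeneous_fixed_point(p2), 64), tolerance = 1e-10)
  expect_equal(max(abs(st$u)), 0, tolerance = 1e-12)
})

test_that("strain rate from active tension: zero mean, cosine closed form, sign", {
  expect_equal(strain_rate_from_Ta(rep(2.3, 10), nu = 1.7), rep(0, 10))
  s <- seq(0, 2 * pi, length.out = 65)[-65]
  A <- 0.3; nu <- 1.4; k <- 2
  eps <- strain_rate_from_Ta(1.5 + A * cos(k * s), nu)
  expect_equal(eps, -(A / nu) * cos(k * s), tolerance = 1e-12)
  # high-Ta (posterior) region contracts
  expect_true(all(eps[cos(k * s) > 0.1] < 0))
  expect_error(strain_rate_from_Ta(c(1, NaN)), "non-finite")
})

test_that("dispersion relation matches a brute-force single-mode oracle", {
  # independent oracle: integrate step_1d from a tiny single-mode
  # perturbation and fit the exponential growth/decay rate
  measure_rate <- function(params, k_mode) {
    n <- params$n_grid
    s <- seq(0, params$L, length.out = n + 1L)[-(n + 1L)]
    k <- 2 * pi * k_mode / params$L
    Tstar <- homogeneous_fixed_point(params)
    st <- margin_state_1d(params, Tstar + 1e-6 * cos(k * s))
    amp <- function(st) 2 * mean((st$Ta - mean(st$Ta)) * cos(k * st$s))
    a0 <- amp(st)
    n_steps <- 100L
    for (i in seq_len(n_steps)) st <- step_1d(st, params)
    log(amp(st) / a0) / (n_steps * params$dt)
  }
  # (k_mode, beta, D) pairs spanning sub- and supercritical regimes
  cases <- list(c(1, 6, 0.00125), c(2, 6, 0.05), c(3, 6, 0.00125),
                c(1, 1, 0.00125), c(2, 8, 0.05))
  for (cs in cases) {
    p <- params_1d(beta = cs[2], D = cs[3], n_grid = 256, dt = 0.002)
    k <- 2 * pi * cs[1] / p$L
    sigma <- dispersion_growth_rate(p, k)
    measured <- measure_rate(p, cs[1])
    expect_equal(measured, sigma, tolerance = 0.02,
                 label = sprintf("rate at k_mode=%g beta=%g", cs[1], cs[2]))
  }
  # formula reductions and limits
  p0 <- params_1d(beta = 0, tau = 2, D = 0.1)
  expect_equal(dispersion_growth_rate(p0, 3), -1 / 2 - 0.1 * 9)
  psub <- params_1d(beta = 1)  # beta*zeta*sech(alpha)^2 < 1
  expect_true(all(dispersion_growth_rate(psub, c(0.5, 1, 2, 5, 20)) < 0))
  expect_lt(dispersion_growth_rate(params_1d(), 1e4), -100)
  expect_error(dispersion_growth_rate(params_1d(), 0), "k = 0")
})

test_that("subcritical cosine perturbations decay at the linearized rate", {
  p <- params_1d(beta = 1, n_grid = 256, dt = 0.002)
  n <- p$n_grid
  s <- seq(0, p$L, length.out = n + 1L)[-(n + 1L)]
  st <- margin_state_1d(p, homogeneous_fixed_point(p) + 1e-4 * cos(s))
  a0 <- 2 * mean((st$Ta - mean(st$Ta)) * cos(st$s))
  for (i in 1:200) st <- step_1d(st, p)
  a1 <- 2 * mean((st$Ta - mean(st$Ta)) * cos(st$s))
  rate <- log(a1 / a0) / (200 * p$dt)
  expect_equal(rate, dispersion_growth_rate(p, 2 * pi / p$L), tolerance = 0.02)
})

test_that("maximum principle and length conservation hold along trajectories", {
  p <- params_1d(n_grid = 128, dt = 0.05)
  lo <- p$T0 * (1 - p$zeta); hi <- p$T0 * (1 + p$zeta)
  set.seed(42)
  for (rep in 1:3) {
    Ta <- stats::runif(p$n_grid, lo, hi)
    st <- margin_state_1d(p, Ta)
    for (i in 1:200) {
      st <- step_1d(st, p)
      expect_true(all(st$Ta >= lo - 1e-12) && all(st$Ta <= hi + 1e-12))
      expect_lt(abs(mean(st$strain_rate)), 1e-10)
    }
  }
})

test_that("supercritical dynamics break symmetry spontaneously from noise", {
  # with D damping all modes beyond k = 1, noise selects a two-domain pattern
  p <- params_1d(n_grid = 512, seed = 7, D = 0.15)
  sim <- simulate_1d(p, "noise", t_end = 30)
  final <- sim$states[[length(sim$states)]]
  sgn <- sign(final$Ta - mean(final$Ta))
  flips <- sum(sgn != c(sgn[-1], sgn[1]))
  expect_identical(flips, 2L)
  # saturated pattern, orders of magnitude above the 1e-3 seeding noise
  expect_gt(diff(range(final$Ta)), 0.5 * p$zeta)
  # at the sharp-front defaults many modes grow: still patterns, never uniform
  pd <- params_1d(n_grid = 512, seed = 7)
  simd <- simulate_1d(pd, "noise", t_end = 30)
  fin2 <- simd$states[[length(simd$states)]]
  expect_gt(diff(range(fin2$Ta)), pd$zeta)
  # determinism: same seed, bitwise-identical kymographs
  sim2 <- simulate_1d(p, "noise", t_end = 30)
  expect_identical(sim$kymograph$strain_rate, sim2$kymograph$strain_rate)
})

test_that("patterned state persists without coarsening over 50 tau", {
  p <- params_1d(n_grid = 512)
  sim <- simulate_1d(p, "posterior_bias", t_end = 50, save_every = 250)
  fr <- vapply(sim$states, domain_fraction, numeric(1))
  late <- fr[sim$times >= 10]
  expect_true(all(late > 0.2 & late < 0.55))  # never homogeneous
  # in the patterned regime the fraction drifts < 2% over a 4-tau window
  last4 <- fr[sim$times >= 46]
  expect_lt(max(abs(last4 - last4[length(last4)])),
            0.02 * last4[length(last4)] + 1e-9)
})

test_that("zeta = 0 relaxes to uniform baseline with zero velocity", {
  p <- params_1d(zeta = 0, n_grid = 64)
  sim <- simulate_1d(p, "noise", t_end = 15)
  final <- sim$states[[length(sim$states)]]
  expect_equal(final$Ta, rep(1, 64), tolerance = 1e-5)
  expect_equal(max(abs(final$u)), 0, tolerance = 1e-5)
  expect_equal(domain_fraction(margin_state_1d(p, "fixed_point")), 0)
})

test_that("released-tension (free-boundary analogue) drives contraction everywhere", {
  p <- params_1d(n_grid = 256, free_tension = 0.2)
  sim <- simulate_1d(p, "posterior_bias", t_end = 10)
  final <- sim$states[[length(sim$states)]]
  expect_equal(domain_fraction(final), 1)
  expect_true(all(final$Ta > 0.2))
})

test_that("advection displaces fronts to a smaller stable contracting domain", {
  p <- params_1d(n_grid = 256, advection_on = TRUE, dt = 0.01)
  sim <- simulate_1d(p, "posterior_bias", t_end = 20, save_every = 200)
  fr <- vapply(sim$states, domain_fraction, numeric(1))
  n <- length(fr)
  expect_true(fr[n] > 0 && fr[n] < 0.37)  # persists, displaced inward
  expect_lt(abs(fr[n] - fr[n - 1L]), 0.02)  # settled
  expect_lt(abs(mean(sim$states[[n]]$strain_rate)), 1e-10)
})

test_that("diffusion time estimate scales quadratically", {
  expect_equal(diffusion_time_estimate(1, 2, 1), 2)
  expect_equal(diffusion_time_estimate(2, 2, 1), 8)
  expect_equal(diffusion_time_estimate(0.5, 2, 1), 0.5)
  expect_error(diffusion_time_estimate(-1), "positive")
})

test_that("state history round-trips through the delimited-text schema", {
  p <- params_1d(n_grid = 32)
  sim <- simulate_1d(p, "posterior_bias", t_end = 0.5, save_every = 10)
  f <- tempfile(fileext = ".tsv")
  write_margin_history_1d(sim, f)
  tab <- utils::read.delim(f)
  expect_identical(names(tab), c("time", "s", "Ta", "strain_rate", "u"))
  last <- tab[tab$time == max(tab$time), ]
  expect_equal(last$Ta, sim$states[[length(sim$states)]]$Ta)
  unlink(f)
})
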