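# Kinematic quantification pipeline

circle_tracks <- function(times, n = 64, R = 1, omega = 0) {
  th0 <- 2 * pi * (seq_len(n) - 1L) / n
  do.call(rbind, lapply(seq_along(times), function(k) {
    th <- th0 + omega * times[k]
    data.frame(time = times[k], node = seq_len(n),
               x = R * cos(th), y = R * sin(th))
  }))
}

test_that("rigid rotation gives a zero kymograph", {
  tr <- circle_tracks(seq(0, 1, by = 0.1), omega = 0.7)
  ky <- strain_rate_along_margin(tr)
  expect_lt(max(abs(ky$strain_rate)), 1e-10)
  expect_equal(attr(ky, "lengths"), rep(attr(ky, "lengths")[1], 11),
               tolerance = 1e-12)
})

test_that("kymograph recovers a prescribed piecewise strain rate", {
  truth <- synthetic_truth(noise_sigma = 0, fraction = 0.4, rate = 0.15,
                           duration = 2)
  g <- gen_margin_tracks(truth)
  ky <- strain_rate_along_margin(g$tracks)
  # posterior bins (margin coordinate near 0) contract at -rate
  post <- ky$strain_rate[, c(1:10, 119:128)]
  expect_equal(mean(post), -truth$rate, tolerance = 0.02 * truth$rate)
  # anterior bins stretch at rate * f/(1-f)
  ant <- ky$strain_rate[, 55:75]
  expect_equal(mean(ant), truth$rate * 0.4 / 0.6,
               tolerance = 0.02 * truth$rate)
  # posterior-at-zero convention: positions_deg near 0 in posterior columns
  expect_lt(abs(ky$positions_deg[1]), 3)
})

test_that("contracting domain size follows the extrema definition", {
  # triangular profile with extrema at +/- a around the posterior (s = 0)
  L <- 6; a <- 1.2
  s <- seq(0, L, length.out = 241)[-241]
  sc <- ((s + L / 2) %% L) - L / 2  # posterior-centred coordinate
  u <- ifelse(abs(sc) < a, -sc, (abs(sc) - L / 2) * sign(sc) * a / (L / 2 - a))
  cd <- contracting_domain_size(velocity_profile(s, u, L = L), smooth_bins = 1)
  expect_equal(cd$size, 2 * a, tolerance = 2 * L / 240)
  expect_equal(cd$fraction, 2 * a / L, tolerance = 2 / 240)
  # sinusoidal profile: extrema at L/4 and 3L/4, size L/2
  u2 <- sin(2 * pi * s / L)
  cd2 <- contracting_domain_size(velocity_profile(s, u2, L = L),
                                 smooth_bins = 1)
  expect_equal(cd2$size, L / 2, tolerance = 2 * L / 240)
  expect_error(contracting_domain_size(velocity_profile(s, rep(0, 240), L = L)),
               "flat")
})

test_that("velocity-profile size agrees with kymograph support on synthetic tracks", {
  truth <- synthetic_truth(noise_sigma = 0, fraction = 0.37, duration = 1)
  g <- gen_margin_tracks(truth)
  vp <- velocity_profile_from_tracks(g$tracks, t_index = 1L)
  cd <- contracting_domain_size(vp)
  expect_equal(cd$fraction, 0.37, tolerance = 1 / 128 + 1 / truth$n_nodes)
  ky <- strain_rate_along_margin(g$tracks)
  frac_ky <- kymograph_contracting_fraction(ky, t = ky$times[1])
  expect_equal(cd$fraction, frac_ky, tolerance = 3 / 128)
})

test_that("integrated contraction normalizes log fold change with the posterior sign", {
  expect_equal(integrated_contraction(c(1, 1), 0.5), 0)
  expect_equal(integrated_contraction(c(2, 1), 0.5), -1)
  expect_equal(integrated_contraction(c(1, 2), 0.5), 1)
  expect_equal(integrated_contraction(c(1, 0.4), 0.6), log(0.4) / abs(log(0.4)))
  expect_error(integrated_contraction(c(1, -1), 0.5))
})

test_that("deformation maps match closed-form flows", {
  fx <- gen_flow_fixture("rigid_rotation")
  dm <- deformation_map(fx$ref, fx$adv)
  expect_lt(max(abs(dm$log_area_ratio)), 1e-10)
  fx2 <- gen_flow_fixture("uniform_dilation", factor = 1.4)
  dm2 <- deformation_map(fx2$ref, fx2$adv)
  expect_equal(dm2$log_area_ratio, matrix(log(1.4^2), 20, 20),
               tolerance = 1e-10)
  expect_false(any(dm2$inverted))
  # ring contraction: inward displacement localized near the ring
  fx3 <- gen_flow_fixture("ring_contraction", n = 41)
  dm3 <- deformation_map(fx3$ref, fx3$adv)
  r_mid <- sqrt(((fx3$ref$x[-1, -1] + fx3$ref$x[-41, -41]) / 2)^2 +
                ((fx3$ref$y[-1, -1] + fx3$ref$y[-41, -41]) / 2)^2)
  near <- abs(r_mid - 1.3) < 0.2
  expect_lt(mean(dm3$log_area_ratio[near]), mean(dm3$log_area_ratio[r_mid < 0.5]))
})

test_that("staging by contraction inverts exponential shrinkage analytically", {
  times <- seq(0, 5, by = 0.05)
  r <- 0.3
  lengths <- 2 * exp(-r * times)
  # length reaches (1 - f) * L0 at t = -log(1 - f) / r
  for (f in c(0.2, 0.5, 0.6)) {
    expect_equal(stage_by_contraction(times, lengths, f), -log(1 - f) / r,
                 tolerance = 0.01)
  }
  expect_true(is.na(stage_by_contraction(times, 2 + times, 0.2)))
})
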