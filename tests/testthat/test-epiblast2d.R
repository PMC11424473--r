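# 2D epiblast model: solver oracles, margin dynamics, scenarios

disk_mesh <- function(R = 1, h = 0.05, pad = 0.2) {
  make_mesh(function(x, y) x^2 + y^2 <= R^2,
            c(-R - pad, R + pad, -R - pad, R + pad), h)
}

circle_curve <- function(n = 128, R = 1.3, c_val = 1, T_val = 1) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  margin_curve(cbind(R * cos(th), R * sin(th)),
               c = rep(c_val, n), T_elastic = rep(T_val, n))
}

test_that("walking kernel satisfies stall, saturation and linear limits", {
  expect_equal(walking_kernel(1, 0.3), 0)
  expect_equal(walking_kernel(1, 7), 0)
  # linear viscoelastic limit: W -> x - 1 as lam -> 0 (Taylor oracle)
  for (x in c(0.2, 0.8, 1.5)) {
    expect_equal(walking_kernel(x, 1e-6), x - 1, tolerance = 1e-5)
  }
  # saturation: unloaded cables contract at ~ -eps0, no faster
  lam <- 8; eps0 <- 0.25
  expect_equal(lam * eps0 * walking_kernel(0, lam), -eps0 * (1 - exp(-lam)))
  expect_gt(lam * eps0 * walking_kernel(0, lam), -eps0)
  # monotone increasing
  x <- seq(0, 2, by = 0.05)
  expect_true(all(diff(walking_kernel(x, 2)) > 0))
  expect_error(walking_kernel(1, 0), "lam")
})

test_that("flow solver passes its analytic oracles", {
  mesh <- disk_mesh()
  # attached boundary, no force -> identically zero
  op <- assemble_flow_operator(mesh, 1, 50, 1)
  sv <- flow_solver(op, mesh$boundary_nodes)
  ff <- solve_flow(sv)
  expect_equal(max(abs(ff$velocity)), 0)
  expect_lt(ff$bc_residual, 1e-8)
  # uniform divergence g, traction-free, friction floor -> u ~ g r / 2
  op2 <- assemble_flow_operator(mesh, mu = 0.01, lam_b = 50, friction = 0.001)
  sv2 <- flow_solver(op2, integer(0))
  g <- 0.2
  ff2 <- solve_flow(sv2, gamma_elem = rep(g, nrow(mesh$cells)))
  r <- sqrt(rowSums(mesh$nodes^2))
  ur <- rowSums(ff2$velocity * mesh$nodes) / pmax(r, 1e-9)
  sel <- r > 0.2 & r < 0.8
  expect_lt(max(abs(ur[sel] - g * r[sel] / 2) / (g * r[sel] / 2)), 0.01)
  # discrete divergence matches the prescribed field
  expect_lt(max(abs(ff2$divergence - g)), 1e-3 * g)
  # singular system reported: all-free boundary with zero friction
  op3 <- assemble_flow_operator(mesh, 1, 50, 0)
  expect_error(flow_solver(op3, integer(0)), "singular")
})

test_that("margin forces: centripetal ring, zero-T, zero net force/torque", {
  mesh <- make_mesh(function(x, y) x^2 + y^2 <= 4, c(-2.2, 2.2, -2.2, 2.2), 0.1)
  n <- 128
  cv <- circle_curve(n, R = 1.3, T_val = 2)
  mf <- margin_force_density(cv, mesh, 0.2)
  # uniform T on a circle: per-node force magnitude 2 T sin(pi/n), inward
  mag <- sqrt(rowSums(mf$node_force^2))
  expect_equal(mag, rep(2 * 2 * sin(pi / n), n), tolerance = 1e-10)
  expect_true(all(rowSums(mf$node_force * cv$nodes) < 0))
  # zero tension -> zero field
  cv0 <- circle_curve(n, T_val = 0)
  expect_equal(max(abs(margin_force_density(cv0, mesh, 0.2)$loads)), 0)
  # closed curve with arbitrary T: net force and torque vanish
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cvm <- circle_curve(n, R = 1.3)
  cvm$T <- 1 + 0.6 * cos(th) + 0.2 * sin(2 * th)
  mfm <- margin_force_density(cvm, mesh, 0.2)
  expect_lt(max(abs(colSums(mfm$loads))), 1e-10)
  torque <- sum(mesh$nodes[, 1] * mfm$loads[, 2] -
                mesh$nodes[, 2] * mfm$loads[, 1])
  expect_lt(abs(torque), 1e-5)  # quadrature tolerance of the Gaussian spread
})

test_that("posterior-biased ring tension entrains a counter-rotating vortex pair", {
  mesh <- make_mesh(function(x, y) x^2 + y^2 <= 4, c(-2.2, 2.2, -2.2, 2.2), 0.1)
  op <- assemble_flow_operator(mesh, 1, 50, 1)
  sv <- flow_solver(op, mesh$boundary_nodes)
  n <- 128
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cv <- circle_curve(n, R = 1.3)
  cv$T <- 1 + 0.5 * cos(th)
  ff <- solve_flow(sv, margin_force_density(cv, mesh, 0.2)$loads)
  expect_true(dominant_vortex_pair(ff))
  expect_identical(count_vortices(ff), 2L)
})

test_that("prescribed divergence: off -> zero; quadrature consistency", {
  p <- params_2d()
  gs_off <- default_gamma_spec(p, epiboly = FALSE, ingression = FALSE)
  pts <- cbind(runif(50, -2, 2), runif(50, -2, 2))
  expect_equal(prescribed_divergence(gs_off, pts), rep(0, 50))
  expect_error(prescribed_divergence(list(), pts), "malformed")
  # integral over the mesh matches the analytic flux budget
  mesh <- disk_mesh(R = 2, h = 0.05)
  gs <- default_gamma_spec(p, epiboly = TRUE, ingression = FALSE)
  tot <- sum(prescribed_divergence(gs, mesh$centres, t = 2)) * mesh$h^2
  analytic <- p$epiboly_accommodation * 2 * pi * p$disk_radius * p$v_epiboly
  expect_equal(tot, analytic, tolerance = 0.02)
  # ingression sink toggles by scenario: intact on, full obstacle off
  geo_i <- apply_scenario_geometry(scenario_spec("intact"), p)
  geo_f <- apply_scenario_geometry(scenario_spec("obstacle", obstacle = "full"), p)
  expect_true(geo_i$gamma_spec$ingression$on)
  expect_false(geo_f$gamma_spec$ingression$on)
})

test_that("margin advance: stall equilibrium and elastic loading oracle", {
  p <- params_2d()
  mesh <- disk_mesh(R = 2, h = 0.1)
  n <- 64
  cv <- circle_curve(n, R = 1.3, c_val = 1, T_val = 1 * p$Ts)  # at stall
  still <- list(velocity = matrix(0, nrow(mesh$nodes), 2), mesh = mesh)
  class(still) <- "flow_field"
  cv2 <- advance_margin(cv, still, p, 0.02)
  expect_equal(cv2$T, cv$T, tolerance = 1e-12)
  expect_equal(cv2$l0, cv$l0, tolerance = 1e-12)
  # elastic loading: uniform dilation flow at rate a with cables at stall;
  # oracle: fine-step integration of dT/dt = E (a - lam*eps0*W(T/(c Ts)))
  a <- 0.1
  dil <- list(velocity = a * mesh$nodes, mesh = mesh)
  class(dil) <- "flow_field"
  cvl <- circle_curve(n, R = 1.3, c_val = 1, T_val = 1 * p$Ts)
  n_steps <- 25L
  for (i in seq_len(n_steps)) {
    cvl <- advance_margin(cvl, dil, p, 0.02)
    # nodes moved outward: rebuild the dilation flow on current positions
  }
  t_end <- n_steps * 0.02
  Tor <- 1 * p$Ts
  dto <- 1e-4
  for (i in seq_len(round(t_end / dto)))
    Tor <- Tor + dto * p$E * (a - p$lam * p$eps0 *
                                walking_kernel(Tor / (1 * p$Ts), p$lam))
  expect_equal(mean(cvl$T), Tor, tolerance = 0.02 * Tor)
  # cutting: free ends clamp tension to zero within one step
  cvc <- margin_curve(cvl$nodes, cvl$c, cvl$T, free_ends = TRUE,
                      closed = FALSE)
  cvc <- advance_margin(cvc, still, p, 0.02)
  expect_identical(cvc$T[c(1L, n)], c(0, 0))
})

test_that("contractility update: homogeneous limit, sign response, bounds", {
  p <- params_2d(D = 0)
  n <- 64
  cv <- circle_curve(n)
  cv$c <- rep(0.9, n)
  cv$strain_rate <- rep(0, n)
  target <- p$c0 + p$delta_c * tanh(p$alpha)
  # exponential relaxation with timescale tau (discrete-Euler oracle)
  c_now <- 0.9
  for (i in 1:50) {
    cv <- update_contractility(cv, p, 0.02)
    c_now <- c_now + 0.02 / p$tau * (target - c_now)
  }
  expect_equal(cv$c, rep(c_now, n), tolerance = 1e-12)
  # contracting nodes are upregulated, stretched nodes downregulated
  cv$strain_rate <- c(rep(-0.2, 32), rep(0.2, 32))
  cv3 <- update_contractility(cv, p, 0.02)
  expect_true(all(cv3$c[1:32] > cv$c[1:32]))
  expect_true(all(cv3$c[33:64] < cv$c[33:64]))
  # maximum principle over many steps with random in-band data
  pd <- params_2d()
  set.seed(3)
  cvb <- circle_curve(64)
  cvb$c <- runif(64, pd$c0 - pd$delta_c, pd$c0 + pd$delta_c)
  cvb$strain_rate <- runif(64, -0.5, 0.5)
  for (i in 1:1000) cvb <- update_contractility(cvb, pd, 0.02)
  expect_true(all(cvb$c >= pd$c0 - pd$delta_c - 1e-9))
  expect_true(all(cvb$c <= pd$c0 + pd$delta_c + 1e-9))
})

test_that("scenario geometry realizes the experimental designs", {
  p <- params_2d()
  gi <- apply_scenario_geometry(scenario_spec("intact"), p)
  expect_true(gi$curve$closed)
  expect_false(gi$curve$free_ends)
  r_att <- sqrt(rowSums(gi$mesh$nodes[gi$dirichlet_nodes, ]^2))
  expect_true(all(r_att > p$disk_radius - 3 * p$h))
  # posterior half, free boundary: open margin, T = 0 ends, only rim attached
  gp <- apply_scenario_geometry(
    scenario_spec("posterior_half", boundary = "free", epiboly = FALSE), p)
  expect_false(gp$curve$closed)
  expect_true(gp$curve$free_ends)
  expect_identical(gp$curve$T[c(1L, nrow(gp$curve$nodes))], c(0, 0))
  expect_true(all(gp$mesh$nodes[, 1] >= -3 * p$h))  # posterior half only
  # full obstacle: friction band crossing the disk anterior of centre
  go <- apply_scenario_geometry(scenario_spec("obstacle", obstacle = "full"), p)
  band <- abs(go$mesh$centres[, 1] + 0.5) < 0.05
  expect_true(all(go$friction[band] > 100 * p$friction0))
  expect_true(go$curve$closed)  # margin intact, not a tight barrier
  # drug presets
  gh <- apply_scenario_geometry(scenario_spec("intact", drug = "h1152"), p)
  expect_equal(gh$params$c0, 0.3 * p$c0)
  gc <- apply_scenario_geometry(scenario_spec("intact", drug = "calyculin"), p)
  expect_equal(gc$params$c0, 1.6 * p$c0)
  expect_equal(gc$params$delta_c, p$delta_c)  # evener relative modulation
  gs <- apply_scenario_geometry(scenario_spec("intact", drug = "ski1"), p)
  expect_true(gs$expression_disabled)
  expect_equal(gs$params$c0, p$c0)  # mechanics unchanged
  expect_error(scenario_spec("intact", obstacle = "full"), "obstacle")
})

test_that("zero contractility and no prescribed growth give a static tissue", {
  p <- params_2d(c0 = 1e-6, delta_c = 0, v_epiboly = 0, gamma_ingression = 0,
                 n_margin = 64L, h = 0.125, w_margin = 0.25)
  traj <- simulate_scenario(scenario_spec("intact", t_end = 0.5), p,
                            record_every = 0.25, tracer_spacing = NA,
                            flow_snapshots = 1L)
  expect_lt(max(traj$summary$mean_speed), 1e-5)
})

test_that("scenario simulation is deterministic and remeshing preserves the curve", {
  p <- params_2d(n_margin = 64L, h = 0.125, w_margin = 0.25)
  sp <- scenario_spec("intact", t_end = 0.5)
  t1 <- simulate_scenario(sp, p, record_every = 0.25, tracer_spacing = NA,
                          flow_snapshots = 1L)
  t2 <- simulate_scenario(sp, p, record_every = 0.25, tracer_spacing = NA,
                          flow_snapshots = 1L)
  expect_identical(t1$tracks, t2$tracks)
  expect_identical(t1$summary, t2$summary)
  # remeshing conserves length and fields to interpolation accuracy
  cv <- t1$margin[[length(t1$margin)]]
  cv2 <- remesh_curve(cv)
  l1 <- curve_lengths(cv$nodes, cv$closed)$total
  l2 <- curve_lengths(cv2$nodes, cv2$closed)$total
  expect_equal(l2, l1, tolerance = 1e-3)
  expect_equal(mean(cv2$c), mean(cv$c), tolerance = 1e-2)
})

test_that("contraction foci are detected and classified", {
  n <- 128
  cv <- circle_curve(n, R = 1.3)
  th <- atan2(cv$nodes[, 2], cv$nodes[, 1])
  # posterior domain plus one ectopic focus near 135 degrees
  cv$strain_rate <- -0.2 * (abs(th) < 0.5) -
    0.15 * (abs(th - 3 * pi / 4) < 0.2)
  foci <- contraction_foci(cv)
  expect_identical(nrow(foci), 2L)
  expect_identical(sum(foci$ectopic), 1L)
  ect <- foci[foci$ectopic, ]
  expect_lt(abs(ect$theta_mid - 135), 15)
  # homogeneous state: no foci
  cv$strain_rate <- rep(0, n)
  expect_identical(nrow(contraction_foci(cv)), 0L)
})

test_that("halving mesh size and time step barely moves the contracting fraction", {
  sc <- scenario_spec("intact", t_end = 3)
  coarse <- simulate_scenario(sc, params_2d(), record_every = 1,
                              tracer_spacing = NA, flow_snapshots = 1L)
  fine <- simulate_scenario(sc, params_2d(h = 0.05, dt = 0.01,
                                          n_margin = 256L),
                            record_every = 1, tracer_spacing = NA,
                            flow_snapshots = 1L)
  f1 <- coarse$summary$domain_fraction_velocity[3]
  f2 <- fine$summary$domain_fraction_velocity[3]
  expect_lt(abs(f1 - f2) / f1, 0.02)
})

test_that("margin history table round-trips with the documented schema", {
  p <- params_2d(n_margin = 32L, h = 0.125, w_margin = 0.25)
  traj <- simulate_scenario(scenario_spec("intact", t_end = 0.2), p,
                            record_every = 0.1, tracer_spacing = NA,
                            flow_snapshots = 1L)
  f <- tempfile(fileext = ".tsv")
  write_margin_history_2d(traj, f)
  tab <- utils::read.delim(f)
  expect_identical(names(tab), c("time", "s", "x", "y", "c", "T",
                                 "strain_rate"))
  expect_equal(nrow(tab), 2L * 32L)
  unlink(f)
})
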