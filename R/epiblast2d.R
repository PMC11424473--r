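# 2D fluid-mechanical model of the epiblast driven by a self-organizing
# viscoelastic margin.
#
# The embryonic disk is a viscous fluid with substrate friction and a
# prescribed divergence gamma (extraembryonic expansion, streak ingression).
# The margin is a Lagrangian polyline carrying contractility c, elastic
# tension T and rest length l0; its line forces are spread onto the flow mesh
# with a Gaussian of half-width w_margin (immersed-boundary style), and the
# nodes ride the resulting flow. Contraction of cables follows a saturating
# "walking kernel" with a stall tension c*Ts, and contractility is up- or
# down-regulated by the local strain rate -- locally self-activating, with
# tissue tension acting as the long-range inhibitor whose range is set by the
# friction screening length sqrt(mu / friction).

#' Parameters of the 2D epiblast model
#'
#' Defaults are calibrated (see `scripts/calibrate.R`) to give a single
#' stable posterior contracting domain in the intact embryo (the model's
#' homeostatic proportion is about 0.17 of the margin), anterior inhibition
#' by stretching transmitted from the contracting domain, and marginal
#' inhibition in the one-sided obstacle configuration. Units: mm, h, and an
#' arbitrary force unit.
#'
#' @param c0 baseline contractility (dimensionless density of active
#'   machinery).
#' @param delta_c modulation amplitude of contractility (`0 <= delta_c < c0`).
#' @param alpha feedback offset; `c` relaxes to
#'   `c0 + delta_c * tanh(alpha - beta * eps / (lam * eps0))`.
#' @param beta mechanical feedback strength.
#' @param tau contractility regulation timescale (h).
#' @param D contractility diffusivity along the margin (mm^2/h).
#' @param lam walking-kernel nonlinearity (dimensionless, > 0).
#' @param eps0 strain-rate scale (1/h); the plateau contraction rate of an
#'   unloaded cable is `eps0 * (1 - exp(-lam))`.
#' @param Ts stall tension per unit contractility (force).
#' @param E margin elastic modulus (force).
#' @param mu tissue shear viscosity (force h / mm^2).
#' @param kappa bulk viscosity of the compressible formulation (penalty
#'   imposing `div u = gamma`).
#' @param friction0 baseline substrate drag (force h / mm^4); sets the
#'   tension-propagation screening length `sqrt(mu / friction0)`.
#' @param range_scale the documented tension-propagation-range knob: the
#'   effective friction is `friction0 / range_scale^2`, so `range_scale`
#'   multiplies the screening length.
#' @param w_margin Gaussian half-width of the margin force profile (mm);
#'   must be at least 2 mesh lengths.
#' @param disk_radius,margin_radius geometry (mm).
#' @param bias_amp amplitude of the initial posterior contractility bias
#'   (fraction of `delta_c`).
#' @param bias_shape `"domain"` (default): an established two-level posterior
#'   domain, `c = c0 + bias_amp * delta_c * tanh((theta_f - |theta|) / w)`
#'   with half-angle `theta_f = bias_fraction * pi` -- the configuration at
#'   the onset of tissue motion, when the contractile domain already exists;
#'   or `"cosine"`: the weak pre-patterning bias
#'   `c = c0 + bias_amp * delta_c * cos(theta)`.
#' @param bias_fraction initial contracting fraction of the margin for the
#'   `"domain"` shape; default 0.18, the model's homeostatic proportion, so
#'   intact runs hold stable proportions from the start.
#' @param bias_gradient weight of the graded (cosine) component blended into
#'   the `"domain"` initial profile: the pre-existing posterior-to-anterior
#'   polarity that seeds ectopic focus nucleation at the posterior-most
#'   accessible margin position after perturbations.
#' @param T_init_ratio initial tension inside the established domain as a
#'   fraction of the stall tension `c * Ts` (below 1: cables actively
#'   contracting at t = 0).
#' @param T_init_ratio_out initial tension outside the domain as a fraction
#'   of stall (slightly above 1: the stretched, yielding state of the
#'   developed margin at the staging time when scenarios start).
#' @param epiboly_accommodation_cut accommodation fraction used for bisected
#'   halves and sectors with ongoing epiboly: the halved extraembryonic
#'   supply accommodates less of the edge flux, so the remaining epiblast is
#'   stretched more strongly.
#' @param v_epiboly outward edge-migration speed when epiboly is on (mm/h).
#' @param epiboly_accommodation fraction of the edge-migration areal flux
#'   supplied by extraembryonic expansion (the annulus gamma bump); the
#'   remainder is drawn from the tissue and generates the epiboly-induced
#'   stretching that opposes contraction.
#' @param gamma_ingression peak (negative) divergence of the Gaussian sink at
#'   the streak (cell ingression) (1/h).
#' @param h mesh cell size (mm); `dt` time step (h); `n_margin` margin nodes.
#' @param seed integer seed.
#' @return object of class `params_2d`.
#' @export
params_2d <- function(c0 = 1, delta_c = 0.5, alpha = -0.5, beta = 4.5,
                      tau = 0.5, D = 0.02, lam = 0.5, eps0 = 0.5, Ts = 3,
                      E = 10, mu = 0.3, kappa = 50, friction0 = 0.0166,
                      range_scale = 1, w_margin = 0.2,
                      disk_radius = 2, margin_radius = 1.3, bias_amp = 1,
                      bias_shape = c("domain", "cosine"),
                      bias_fraction = 0.18, bias_gradient = 0.3,
                      T_init_ratio = 0.7, T_init_ratio_out = 1.1,
                      epiboly_accommodation_cut = 0,
                      v_epiboly = 0.1, epiboly_accommodation = 0.9,
                      gamma_ingression = -0.3,
                      h = 0.1, dt = 0.02, n_margin = 128L, seed = 1L) {
  stopifnot(tau > 0, D >= 0, lam > 0, eps0 > 0, Ts > 0, E > 0, mu > 0,
            kappa > 0, friction0 >= 0, range_scale > 0,
            delta_c >= 0, delta_c < c0, margin_radius < disk_radius,
            w_margin >= 2 * h, dt > 0, dt <= tau, n_margin >= 16L)
  p <- as.list(environment())
  p$bias_shape <- match.arg(bias_shape)
  p$n_margin <- as.integer(n_margin)
  p$seed <- as.integer(seed)
  class(p) <- "params_2d"
  p
}

#' Saturating walking kernel
#'
#' Relation between normalized load `x = T / (c * Ts)` and cable kinetics:
#' `W(x; lam) = (exp(lam * (x - 1)) - 1) / lam`. Properties: `W(1) = 0`
#' (stall); monotone increasing; `lam * eps0 * W -> -eps0 (1 - exp(-lam))`
#' as `x -> 0` (contraction-rate plateau, so unloaded margins do not contract
#' faster); `W > 0` for `x > 1` (yielding); `W -> x - 1` as `lam -> 0`
#' (linear viscoelastic limit). The argument is capped at `x = 6` as a
#' numerical guard against transient overload.
#'
#' @param x normalized tension (vector ok).
#' @param lam nonlinearity parameter (> 0).
#' @return dimensionless rate factor.
#' @export
walking_kernel <- function(x, lam) {
  if (lam <= 0) stop("lam must be > 0")
  x <- pmin(x, 6)
  (exp(lam * (x - 1)) - 1) / lam
}

#' Margin curve constructor
#'
#' @param nodes n x 2 matrix of positions (mm), ordered along the margin;
#'   posterior (or the posterior-most end) first.
#' @param c contractility per node.
#' @param T_elastic elastic tension per node (force).
#' @param free_ends logical; open margin with traction-released cut ends
#'   (tension clamped to 0 there).
#' @param closed logical.
#' @return object of class `margin_curve` with derived arclength `s`,
#'   per-segment rest lengths `l0` (initialized to current lengths) and a
#'   zero strain-rate field.
#' @export
margin_curve <- function(nodes, c, T_elastic, free_ends = FALSE,
                         closed = TRUE) {
  n <- nrow(nodes)
  stopifnot(length(c) == n, length(T_elastic) == n)
  cl <- curve_lengths(nodes, closed)
  if (free_ends) T_elastic[c(1L, n)] <- 0
  cv <- list(nodes = nodes, c = c, T = T_elastic, l0 = cl$seg,
             s = cl$s, strain_rate = numeric(n),
             free_ends = isTRUE(free_ends), closed = isTRUE(closed))
  class(cv) <- "margin_curve"
  cv
}

curve_lengths <- function(nodes, closed) {
  n <- nrow(nodes)
  j <- if (closed) c(2:n, 1L) else 2:n
  i <- if (closed) 1:n else 1:(n - 1L)
  seg <- sqrt((nodes[j, 1] - nodes[i, 1])^2 + (nodes[j, 2] - nodes[i, 2])^2)
  list(seg = seg, s = c(0, cumsum(seg))[seq_len(n)], total = sum(seg))
}

# unit tangents per segment
segment_tangents <- function(nodes, closed) {
  n <- nrow(nodes)
  j <- if (closed) c(2:n, 1L) else 2:n
  i <- if (closed) 1:n else 1:(n - 1L)
  dx <- nodes[j, 1] - nodes[i, 1]
  dy <- nodes[j, 2] - nodes[i, 2]
  l <- sqrt(dx^2 + dy^2)
  if (any(l <= 0)) stop("degenerate (zero-length) margin segment")
  cbind(dx / l, dy / l)
}

#' Margin line forces spread onto the flow mesh
#'
#' The force per unit margin length is `d(T t)/ds` (tangential tension
#' gradient plus `T * curvature` pointing centripetally). Discretely each
#' node receives `T_seg(i) t_i - T_seg(i-1) t_(i-1)` (telescoping, so the
#' total force on a closed curve is exactly zero), and each nodal force is
#' spread onto mesh nodes with a discretely normalized Gaussian of half-width
#' `w_margin`.
#'
#' @param curve a [margin_curve()].
#' @param mesh a [make_mesh()] mesh.
#' @param w_margin Gaussian half-width (mm).
#' @return list with `loads` (mesh-node point loads, N x 2) and `node_force`
#'   (force per margin node, n x 2).
#' @export
margin_force_density <- function(curve, mesh, w_margin) {
  nodes <- curve$nodes
  n <- nrow(nodes)
  tg <- segment_tangents(nodes, curve$closed)
  nseg <- nrow(tg)
  iseg_next <- if (curve$closed) seq_len(n) else c(seq_len(n - 1L), NA)
  iseg_prev <- if (curve$closed) c(n, seq_len(n - 1L)) else c(NA, seq_len(n - 1L))
  Tn <- curve$T
  Tseg <- if (curve$closed) (Tn + Tn[c(2:n, 1L)]) / 2
          else (Tn[-n] + Tn[-1L]) / 2
  Fx <- Fy <- numeric(n)
  ok_n <- !is.na(iseg_next)
  Fx[ok_n] <- Tseg[iseg_next[ok_n]] * tg[iseg_next[ok_n], 1]
  Fy[ok_n] <- Tseg[iseg_next[ok_n]] * tg[iseg_next[ok_n], 2]
  ok_p <- !is.na(iseg_prev)
  Fx[ok_p] <- Fx[ok_p] - Tseg[iseg_prev[ok_p]] * tg[iseg_prev[ok_p], 1]
  Fy[ok_p] <- Fy[ok_p] - Tseg[iseg_prev[ok_p]] * tg[iseg_prev[ok_p], 2]
  loads <- spread_gaussian(mesh, nodes, cbind(Fx, Fy), w_margin)
  list(loads = loads, node_force = cbind(Fx, Fy))
}

# spread point forces at `points` onto mesh nodes with normalized Gaussians
spread_gaussian <- function(mesh, points, forces, w) {
  N <- nrow(mesh$nodes)
  loads <- matrix(0, N, 2)
  h <- mesh$h
  reach <- ceiling(3 * w / h)
  for (p in seq_len(nrow(points))) {
    ix <- floor((points[p, 1] - mesh$bbox[1]) / h) + 1L
    iy <- floor((points[p, 2] - mesh$bbox[3]) / h) + 1L
    rx <- max(1L, ix - reach):min(mesh$nx + 1L, ix + reach + 1L)
    ry <- max(1L, iy - reach):min(mesh$ny + 1L, iy + reach + 1L)
    ids <- mesh$node_id[rx, ry]
    sel <- ids > 0L
    if (!any(sel)) next
    ids <- ids[sel]
    dx <- mesh$nodes[ids, 1] - points[p, 1]
    dy <- mesh$nodes[ids, 2] - points[p, 2]
    g <- exp(-(dx^2 + dy^2) / (2 * w^2))
    g <- g / sum(g)
    loads[ids, 1] <- loads[ids, 1] + forces[p, 1] * g
    loads[ids, 2] <- loads[ids, 2] + forces[p, 2] * g
  }
  loads
}

#' Prescribed divergence field
#'
#' Areal growth imposed on the flow: a smooth positive bump in the
#' extraembryonic annulus (epiboly expansion) plus, when enabled, a negative
#' Gaussian sink at the posterior streak position (cell ingression). Both
#' contributions are analytic; the ingression sink ramps up over the first
#' hour.
#'
#' @param gamma_spec list with `epiboly = list(on, amp, r0, width)` and
#'   `ingression = list(on, amp, x0, width, ramp)`; see
#'   [default_gamma_spec()].
#' @param x m x 2 matrix of evaluation points.
#' @param t time (h).
#' @return numeric vector gamma(x, t) (1/h).
#' @export
prescribed_divergence <- function(gamma_spec, x, t = 0) {
  if (!is.list(gamma_spec) || is.null(gamma_spec$epiboly) ||
      is.null(gamma_spec$ingression))
    stop("malformed gamma_spec: need epiboly and ingression blocks")
  g <- numeric(nrow(x))
  ep <- gamma_spec$epiboly
  if (isTRUE(ep$on)) {
    r <- sqrt(x[, 1]^2 + x[, 2]^2)
    g <- g + ep$amp * exp(-(r - ep$r0)^2 / (2 * ep$width^2))
  }
  ing <- gamma_spec$ingression
  if (isTRUE(ing$on)) {
    ramp <- min(1, t / max(ing$ramp, 1e-9))
    # sink distributed along the posterior margin arc (the streak region):
    # Gaussian in angle around the posterior and in radius about the margin
    th <- atan2(x[, 2], x[, 1])
    r <- sqrt(x[, 1]^2 + x[, 2]^2)
    g <- g + ing$amp * ramp *
      exp(-th^2 / (2 * ing$sigma_theta^2)) *
      exp(-(r - ing$r0)^2 / (2 * ing$width^2))
  }
  g
}

#' Default prescribed-divergence specification
#'
#' @param params a [params_2d()].
#' @param epiboly,ingression logical toggles.
#' @return gamma_spec list for [prescribed_divergence()].
#' @export
default_gamma_spec <- function(params, epiboly = TRUE, ingression = TRUE) {
  # annulus bump kept clear of the margin (tail < 3 sigma at margin_radius)
  r_ann <- params$margin_radius + 0.6 * (params$disk_radius -
                                           params$margin_radius)
  width <- (params$disk_radius - params$margin_radius) / 6
  # annulus amplitude chosen so the annular integral of gamma supplies a
  # fraction `epiboly_accommodation` of the edge-migration areal flux
  # 2 pi Rd v_epi; the annular integral is amp * 2 pi r0 * sqrt(2 pi) * width
  amp <- params$epiboly_accommodation * params$disk_radius *
    params$v_epiboly / (r_ann * sqrt(2 * pi) * width)
  list(epiboly = list(on = epiboly, amp = amp, r0 = r_ann, width = width),
       ingression = list(on = ingression, amp = params$gamma_ingression,
                         r0 = params$margin_radius,
                         sigma_theta = 0.9, width = 0.2, ramp = 1))
}

#' Advance the margin curve through one time step
#'
#' (i) advects nodes with the interpolated flow velocity; (ii) computes the
#' margin strain rate from the tangential velocity gradient; (iii) updates
#' the segment rest lengths by `dlog(l0)/dt = lam*eps0*W(T/(c Ts)) + gamma/2`
#' (ingression shrinks cables); (iv) updates the elastic tension by
#' `dT/dt = E * (eps - gamma/2 - lam*eps0*W(T/(c Ts)))` in the node-following
#' frame; free cut ends keep `T = 0`.
#'
#' @param curve a [margin_curve()].
#' @param flow a [solve_flow()] result.
#' @param params a [params_2d()].
#' @param dt time step (h).
#' @param gamma_nodes prescribed divergence evaluated at the margin nodes.
#' @return advanced `margin_curve` (with `strain_rate` filled in).
#' @export
advance_margin <- function(curve, flow, params, dt,
                           gamma_nodes = numeric(nrow(curve$nodes))) {
  n <- nrow(curve$nodes)
  vel <- interp_nodal(flow$mesh, flow$velocity, curve$nodes)
  tg <- segment_tangents(curve$nodes, curve$closed)
  cl <- curve_lengths(curve$nodes, curve$closed)
  j <- if (curve$closed) c(2:n, 1L) else 2:n
  i <- if (curve$closed) 1:n else 1:(n - 1L)
  eps_seg <- ((vel[j, 1] - vel[i, 1]) * tg[, 1] +
              (vel[j, 2] - vel[i, 2]) * tg[, 2]) / cl$seg
  eps_node <- if (curve$closed) (eps_seg + eps_seg[c(n, 1:(n - 1L))]) / 2
              else c(eps_seg[1L], (eps_seg[-1L] + eps_seg[-(n - 1L)]) / 2,
                     eps_seg[n - 1L])
  # implicit Euler for the cable term (stiff when c*Ts is small):
  # solve Tn = T + dt*E*(eps - gamma/2 - lam*eps0*W(Tn/(c*Ts))) by Newton
  cTs <- curve$c * params$Ts
  rhs0 <- curve$T + dt * params$E * (eps_node - gamma_nodes / 2)
  Tn <- curve$T
  for (it in 1:6) {
    x <- Tn / cTs
    W <- walking_kernel(x, params$lam)
    Wp <- ifelse(x < 6, exp(params$lam * (pmin(x, 6) - 1)), 0)
    f <- Tn - rhs0 + dt * params$E * params$lam * params$eps0 * W
    fp <- 1 + dt * params$E * params$lam * params$eps0 * Wp / cTs
    Tn <- Tn - f / fp
  }
  if (curve$free_ends) Tn[c(1L, n)] <- 0
  if (!all(is.finite(Tn)))
    stop("non-finite margin tension (reduce dt or check parameters)")
  # rest lengths (bookkeeping for cable kinetics diagnostics)
  c_seg <- if (curve$closed) (curve$c + curve$c[c(2:n, 1L)]) / 2
           else (curve$c[-n] + curve$c[-1L]) / 2
  T_seg <- if (curve$closed) (curve$T + curve$T[c(2:n, 1L)]) / 2
           else (curve$T[-n] + curve$T[-1L]) / 2
  g_seg <- if (curve$closed) (gamma_nodes + gamma_nodes[c(2:n, 1L)]) / 2
           else (gamma_nodes[-n] + gamma_nodes[-1L]) / 2
  Ws <- walking_kernel(T_seg / (c_seg * params$Ts), params$lam)
  l0 <- curve$l0 * exp(dt * (params$lam * params$eps0 * Ws + g_seg / 2))
  nodes <- curve$nodes + dt * vel
  cl2 <- curve_lengths(nodes, curve$closed)
  if (any(cl2$seg < 1e-6))
    stop("margin node collision (segment collapsed)")
  # node tangential velocity (for velocity profiles along the margin)
  tg_node <- rbind(tg[1L, ], (tg[-1L, , drop = FALSE] +
                              tg[-nrow(tg), , drop = FALSE]) / 2)
  if (curve$closed) tg_node[1L, ] <- (tg[1L, ] + tg[nrow(tg), ]) / 2
  else tg_node <- rbind(tg_node, tg[nrow(tg), ])
  tg_node <- tg_node / sqrt(rowSums(tg_node^2))
  out <- curve
  out$nodes <- nodes
  out$T <- Tn
  out$l0 <- l0
  out$s <- cl2$s
  out$strain_rate <- eps_node
  out$u_t <- rowSums(vel * tg_node)
  out
}

#' Advance margin contractility through one time step
#'
#' Reaction towards `c0 + delta_c * tanh(alpha - beta * eps / (lam * eps0))`
#' with timescale `tau` (a convex-combination update, so `c` stays within
#' `[c0 - delta_c, c0 + delta_c]`), plus explicit diffusion along arclength.
#' Advection along the margin is handled implicitly by the Lagrangian node
#' frame.
#'
#' @param curve a [margin_curve()] (with current `strain_rate`).
#' @param params a [params_2d()].
#' @param dt time step (h).
#' @return curve with updated contractility.
#' @export
update_contractility <- function(curve, params, dt) {
  n <- nrow(curve$nodes)
  target <- params$c0 + params$delta_c *
    tanh(params$alpha - params$beta * curve$strain_rate /
           (params$lam * params$eps0))
  cn <- curve$c + dt / params$tau * (target - curve$c)
  if (params$D > 0) {
    cl <- curve_lengths(curve$nodes, curve$closed)
    ds <- mean(cl$seg)
    # explicit diffusion, substepped to respect the stability bound as the
    # Lagrangian spacing shrinks
    m_sub <- max(1L, ceiling(dt * params$D / (0.4 * ds^2)))
    dts <- dt / m_sub
    for (ss in seq_len(m_sub)) {
      if (curve$closed) {
        lap <- (cn[c(2:n, 1L)] - 2 * cn + cn[c(n, 1:(n - 1L))]) / ds^2
      } else {
        lap <- c(0, (cn[3:n] - 2 * cn[2:(n - 1L)] + cn[1:(n - 2L)]) / ds^2, 0)
      }
      cn <- cn + dts * params$D * lap
    }
  }
  out <- curve
  out$c <- cn
  out
}

#' Scenario specification
#'
#' @param kind `"intact"`, `"bisect"` (kept as an alias of the half
#'   scenarios), `"posterior_half"`, `"anterior_half"`, `"sector"` or
#'   `"obstacle"`.
#' @param cut_angle orientation of the bisection line relative to the
#'   anteroposterior axis (degrees; 90 = perpendicular bisection into
#'   anterior and posterior halves).
#' @param which_half `"anterior"` or `"posterior"` (for `kind = "bisect"`).
#' @param boundary cut-edge condition: `"attached"` (zero velocity) or
#'   `"free"` (zero traction; margin cut ends release tension).
#' @param epiboly logical: outward edge migration plus extraembryonic-annulus
#'   divergence.
#' @param sector_angle posterior sector opening (degrees), for
#'   `kind = "sector"`.
#' @param obstacle `"none"`, `"full"` or `"half"`: a band of strongly
#'   increased substrate friction crossing the whole disk or only the
#'   `y > 0` side, anterior of centre.
#' @param obstacle_x band centre position along the AP axis (mm; negative =
#'   anterior of centre).
#' @param obstacle_width band width (mm; ~100-um hair).
#' @param obstacle_mult friction multiplier inside the band.
#' @param drug `"none"`, `"h1152"` (contractility x 0.3), `"calyculin"`
#'   (x 1.6) or `"ski1"` (mechanics unchanged; expression readout disabled).
#' @param t_end simulated time (h).
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("intact", "bisect", "posterior_half",
                                   "anterior_half", "sector", "obstacle"),
                          cut_angle = 90, which_half = c("anterior",
                                                         "posterior"),
                          boundary = c("free", "attached"),
                          epiboly = NULL, sector_angle = 120,
                          obstacle = c("none", "full", "half"),
                          obstacle_x = -0.5, obstacle_width = 0.1,
                          obstacle_mult = 1e4,
                          drug = c("none", "h1152", "calyculin", "ski1"),
                          t_end = 8) {
  kind <- match.arg(kind)
  which_half <- match.arg(which_half)
  boundary <- match.arg(boundary)
  obstacle <- match.arg(obstacle)
  drug <- match.arg(drug)
  if (kind == "anterior_half") { kind <- "bisect"; which_half <- "anterior" }
  if (kind == "posterior_half") { kind <- "bisect"; which_half <- "posterior" }
  if (kind == "obstacle" && obstacle == "none") obstacle <- "full"
  if (kind != "obstacle" && obstacle != "none")
    stop("obstacle settings require kind = 'obstacle'")
  if (is.null(epiboly)) epiboly <- kind %in% c("intact", "obstacle")
  if (kind %in% c("intact", "obstacle") && !epiboly && kind == "obstacle")
    stop("obstacle scenarios assume an intact, epiboly-on epiblast")
  sp <- list(kind = kind, cut_angle = cut_angle, which_half = which_half,
             boundary = boundary, epiboly = isTRUE(epiboly),
             sector_angle = sector_angle, obstacle = obstacle,
             obstacle_x = obstacle_x, obstacle_width = obstacle_width,
             obstacle_mult = obstacle_mult, drug = drug, t_end = t_end)
  class(sp) <- "scenario_spec"
  sp
}

#' Realize the geometry, margin and boundary conditions of a scenario
#'
#' Builds the (half-)disk or sector mesh, the open or closed margin polyline
#' with its posterior contractility bias, the Dirichlet set (attached edges;
#' outward epiboly motion on the outer rim), the per-element friction field
#' (obstacle band) and the prescribed-divergence specification. Drug presets
#' rescale `(c0, delta_c)`; Ski-1 leaves mechanics unchanged and flags the
#' expression readout as disabled.
#'
#' @param spec a [scenario_spec()].
#' @param params a [params_2d()].
#' @return list: `mesh`, `curve`, `dirichlet` (node ids + values), `friction`
#'   (per element), `gamma_spec`, adjusted `params`,
#'   `expression_disabled` flag.
#' @export
apply_scenario_geometry <- function(spec, params) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(params, "params_2d"))
  p <- params
  if (spec$drug == "h1152") { p$c0 <- p$c0 * 0.3; p$delta_c <- p$delta_c * 0.3 }
  if (spec$drug == "calyculin") {
    # raised baseline myosin activity: contraction becomes more even
    # (relative modulation delta_c / c0 drops), net flow decreases
    p$c0 <- p$c0 * 1.6
  }
  Rd <- p$disk_radius; Rm <- p$margin_radius
  pad <- 2 * p$h
  # half-plane indicator for cuts: keep side `sgn` of the line through the
  # origin with direction angle `cut_angle` from the AP (x) axis
  # cut line through the origin with direction angle `phi` from the AP (x)
  # axis; its normal is (-sin phi, cos phi). For the default phi = 90 the
  # anterior half is x < 0 (sgn = +1 keeps it).
  phi <- spec$cut_angle * pi / 180
  keep_half <- function(x, y, sgn) sgn * (-x * sin(phi) + y * cos(phi)) >= 0
  half_sgn <- if (spec$which_half == "anterior") 1 else -1
  if (spec$kind %in% c("intact", "obstacle")) {
    inside <- function(x, y) x^2 + y^2 <= Rd^2
    th <- 2 * pi * (seq_len(p$n_margin) - 1L) / p$n_margin  # posterior first
    closed <- TRUE; free_ends <- FALSE
  } else if (spec$kind == "bisect") {
    inside <- function(x, y) (x^2 + y^2 <= Rd^2) & keep_half(x, y, half_sgn)
    # margin arc inside the kept half; posterior-most node first
    th_all <- seq(-pi, pi, length.out = 4 * p$n_margin)
    ok <- keep_half(Rm * cos(th_all), Rm * sin(th_all), half_sgn) &
      abs(Rm * (cos(th_all) * cos(phi) + sin(th_all) * sin(phi))) > 0.5 * p$h
    if (spec$which_half == "anterior") {
      th0 <- sort(th_all[ok & th_all >= 0])  # 90..180
      th1 <- sort(th_all[ok & th_all < 0])   # -180..-90
      th_arc <- c(th0, th1 + 2 * pi)         # continuous 90..270 deg
    } else {
      th_arc <- sort(th_all[ok])             # -90..90 deg through posterior
    }
    th <- seq(th_arc[1], th_arc[length(th_arc)], length.out = p$n_margin)
    closed <- FALSE
    # ongoing epiboly keeps the half adherent: the cut edge behaves as
    # attached and margin tension re-anchors at the cut; abrogating epiboly
    # (ring cut) releases everything
    free_ends <- spec$boundary == "free" && !spec$epiboly
  } else if (spec$kind == "sector") {
    half_open <- spec$sector_angle * pi / 360
    inside <- function(x, y) (x^2 + y^2 <= Rd^2) &
      (abs(atan2(y, x)) <= half_open)
    th <- seq(-half_open + 2 * p$h / Rm, half_open - 2 * p$h / Rm,
              length.out = p$n_margin)
    closed <- FALSE
    free_ends <- spec$boundary == "free"
  }
  mesh <- make_mesh(inside, c(-Rd - pad, Rd + pad, -Rd - pad, Rd + pad), p$h)
  nodes <- cbind(Rm * cos(th), Rm * sin(th))
  th_wrap <- abs(((th + pi) %% (2 * pi)) - pi)  # angular distance to posterior
  dom <- 0.5 * (1 + tanh((p$bias_fraction * pi - th_wrap) / 0.25))
  cini <- if (p$bias_shape == "cosine") {
    p$c0 + p$bias_amp * p$delta_c * cos(th)
  } else {
    # established two-level domain blended with a graded posterior-to-
    # anterior tail (the pre-existing polarity): the gradient seeds focus
    # nucleation at the posterior-most accessible position when tension
    # transmission is interrupted
    p$c0 + p$bias_amp * p$delta_c *
      ((1 - p$bias_gradient) * (2 * dom - 1) + p$bias_gradient * cos(th))
  }
  # cables inside the established contracting domain start below stall
  # (actively contracting); outside slightly above stall (the stretched,
  # yielding state of the developed margin at staging)
  T_ini <- cini * p$Ts * (p$T_init_ratio_out +
                            (p$T_init_ratio - p$T_init_ratio_out) * dom)
  curve <- margin_curve(nodes, c = cini, T_elastic = T_ini,
                        free_ends = free_ends, closed = closed)
  # boundary conditions: outer rim attached; cut edge per spec
  bn <- mesh$boundary_nodes
  bx <- mesh$nodes[bn, 1]; by <- mesh$nodes[bn, 2]
  r_b <- sqrt(bx^2 + by^2)
  on_rim <- r_b > Rd - 2.5 * p$h
  if (spec$kind %in% c("intact", "obstacle")) {
    att <- bn[on_rim]
  } else if (spec$boundary == "attached" || spec$epiboly) {
    att <- bn  # cut/sector edges attached (reattachment or adherent epiboly)
  } else if (spec$kind == "bisect" && spec$which_half == "anterior") {
    att <- integer(0)  # ring cut: the whole anterior half floats free
  } else {
    att <- bn[on_rim]
  }
  vals <- matrix(0, length(att), 2)
  if (spec$epiboly) {
    ax <- mesh$nodes[att, 1]; ay <- mesh$nodes[att, 2]
    ar <- sqrt(ax^2 + ay^2)
    rim <- ar > Rd - 2.5 * p$h
    vals[rim, 1] <- p$v_epiboly * ax[rim] / ar[rim]
    vals[rim, 2] <- p$v_epiboly * ay[rim] / ar[rim]
  }
  # friction field with obstacle band
  fr0 <- p$friction0 / p$range_scale^2
  fr <- rep(fr0, nrow(mesh$centres))
  if (spec$kind == "obstacle") {
    inband <- abs(mesh$centres[, 1] - spec$obstacle_x) <
      spec$obstacle_width / 2
    if (spec$obstacle == "half") inband <- inband & mesh$centres[, 2] > 0
    fr[inband] <- fr0 * spec$obstacle_mult
  }
  ingress_on <- spec$kind == "intact" ||
    (spec$kind == "obstacle" && spec$obstacle == "half")
  # a bisected half bears the epiboly load of its rim with a halved
  # extraembryonic supply: a larger fraction of the edge flux is drawn from
  # the epiblast, stretching it
  if (spec$kind %in% c("bisect", "sector") && spec$epiboly)
    p$epiboly_accommodation <- p$epiboly_accommodation_cut
  gamma_spec <- default_gamma_spec(p, epiboly = spec$epiboly,
                                   ingression = ingress_on)
  list(mesh = mesh, curve = curve, dirichlet_nodes = att,
       dirichlet_values = vals, friction = fr, gamma_spec = gamma_spec,
       params = p, expression_disabled = spec$drug == "ski1")
}

#' Simulate a 2D scenario
#'
#' Driver alternating flow solve, margin advection/tension update and
#' contractility regulation. Records margin states and tracked tracer-grid
#' positions at the imaging cadence (default 6 simulated minutes).
#'
#' @param spec a [scenario_spec()].
#' @param params a [params_2d()].
#' @param record_every recording interval (h).
#' @param tracer_spacing tracer-grid spacing (mm); `NA` disables tracers.
#' @param flow_snapshots number of evenly spaced stored flow fields.
#' @return object of class `scenario_trajectory`: `times`, `margin` (list of
#'   margin-curve states), `tracks` (long node-track table: time, node, x,
#'   y), `summary` (per-frame margin length, contracting fraction, mean
#'   speed), `tracer` (list with `ref` and `adv` grids), `flows`, plus the
#'   realized `scenario` and `params`.
#' @export
simulate_scenario <- function(spec, params = params_2d(),
                              record_every = 0.1, tracer_spacing = 0.25,
                              flow_snapshots = 3L, remesh_every = 0.5) {
  geo <- apply_scenario_geometry(spec, params)
  p <- geo$params
  op <- assemble_flow_operator(geo$mesh, p$mu, p$kappa + p$mu / 3,
                               geo$friction)
  solver <- flow_solver(op, geo$dirichlet_nodes, geo$dirichlet_values)
  curve <- geo$curve
  n_steps <- ceiling(spec$t_end / p$dt)
  rec_steps <- max(1L, round(record_every / p$dt))
  snap_at <- unique(pmax(1L, round(seq(1L, n_steps,
                                       length.out = flow_snapshots))))
  # tracer grid over the embryonic territory
  tracer <- NULL
  if (!is.na(tracer_spacing)) {
    g <- seq(-p$margin_radius, p$margin_radius, by = tracer_spacing)
    tr <- expand.grid(x = g, y = g)
    nrow_g <- length(g)
    tracer <- list(ref = list(x = matrix(tr$x, nrow_g), y = matrix(tr$y, nrow_g)),
                   pts = as.matrix(tr))
  }
  times <- numeric(0)
  margin_states <- list()
  flows <- list()
  summ <- NULL
  t <- 0
  markers <- curve$nodes  # passive material points for track output
  marker_hist <- list()
  remesh_steps <- max(1L, round(remesh_every / p$dt))
  for (k in seq_len(n_steps)) {
    mf <- margin_force_density(curve, geo$mesh, p$w_margin)
    gamma_elem <- prescribed_divergence(geo$gamma_spec, geo$mesh$centres, t)
    flow <- solve_flow(solver, mf$loads, gamma_elem)
    gamma_nodes <- prescribed_divergence(geo$gamma_spec, curve$nodes, t)
    curve <- advance_margin(curve, flow, p, p$dt, gamma_nodes)
    curve <- update_contractility(curve, p, p$dt)
    markers <- markers + p$dt * interp_nodal(geo$mesh, flow$velocity, markers)
    if (k %% remesh_steps == 0L) curve <- remesh_curve(curve)
    if (!is.null(tracer)) {
      vel_tr <- interp_nodal(geo$mesh, flow$velocity, tracer$pts)
      tracer$pts <- tracer$pts + p$dt * vel_tr
    }
    t <- t + p$dt
    if (k %% rec_steps == 0L || k == n_steps) {
      times <- c(times, t)
      margin_states[[length(margin_states) + 1L]] <- curve
      marker_hist[[length(marker_hist) + 1L]] <- markers
      cl <- curve_lengths(curve$nodes, curve$closed)
      dfv <- tryCatch(
        contracting_domain_size(margin_velocity_profile(curve, t))$fraction,
        error = function(e) NA_real_)
      summ <- rbind(summ, data.frame(
        time = t, margin_length = cl$total,
        contracting_fraction = contracting_fraction_2d(curve),
        domain_fraction_velocity = dfv,
        mean_speed = mean(sqrt(rowSums(flow$velocity^2)))))
    }
    if (k %in% snap_at) flows[[length(flows) + 1L]] <- flow
  }
  nfr <- length(times)
  nn <- nrow(markers)
  tracks <- data.frame(
    time = rep(times, each = nn),
    node = rep(seq_len(nn), times = nfr),
    x = unlist(lapply(marker_hist, function(m) m[, 1])),
    y = unlist(lapply(marker_hist, function(m) m[, 2])))
  out <- list(times = times, margin = margin_states, tracks = tracks,
              summary = summ,
              tracer = if (!is.null(tracer))
                list(ref = tracer$ref,
                     adv = list(x = matrix(tracer$pts[, 1], nrow(tracer$ref$x)),
                                y = matrix(tracer$pts[, 2], nrow(tracer$ref$x)))),
              flows = flows, scenario = spec, params = p, geometry = geo)
  class(out) <- "scenario_trajectory"
  out
}

#' Arclength fraction of the margin that is contracting
#'
#' Arclength-weighted (segments, not nodes: Lagrangian nodes crowd into
#' contracting regions, so a node count would be biased).
#'
#' @param curve a `margin_curve` with a current strain-rate field.
#' @param threshold strain-rate threshold (1/h); margin with
#'   `strain_rate < -threshold` counts as contracting.
#' @return fraction in `[0, 1]`.
#' @export
contracting_fraction_2d <- function(curve, threshold = 0.02) {
  n <- nrow(curve$nodes)
  cl <- curve_lengths(curve$nodes, curve$closed)
  eps_seg <- if (curve$closed)
    (curve$strain_rate + curve$strain_rate[c(2:n, 1L)]) / 2
  else (curve$strain_rate[-n] + curve$strain_rate[-1L]) / 2
  sum(cl$seg[eps_seg < -threshold]) / sum(cl$seg)
}

#' Resample a margin curve to uniform arclength
#'
#' Redistributes the computational nodes uniformly along the current
#' polyline, interpolating contractility, tension and the rest-length ratio
#' by arclength. Used periodically during simulations because the Lagrangian
#' nodes crowd into contracting regions; material motion is tracked by
#' separate passive markers.
#'
#' @param curve a [margin_curve()].
#' @param n number of nodes after resampling (default: unchanged).
#' @return resampled `margin_curve`.
#' @export
remesh_curve <- function(curve, n = nrow(curve$nodes)) {
  n_old <- nrow(curve$nodes)
  cl <- curve_lengths(curve$nodes, curve$closed)
  if (curve$closed) {
    s_node <- c(cl$s, cl$total)
    wrap <- function(v) c(v, v[1L])
    s_new <- (seq_len(n) - 1L) / n * cl$total
  } else {
    s_node <- cl$s
    wrap <- identity
    s_new <- seq(0, cl$total, length.out = n)
  }
  itp <- function(v) stats::approx(s_node, wrap(v), xout = s_new, rule = 2)$y
  nodes <- cbind(itp(curve$nodes[, 1]), itp(curve$nodes[, 2]))
  # keep exact endpoints for open curves
  if (!curve$closed) {
    nodes[1L, ] <- curve$nodes[1L, ]
    nodes[n, ] <- curve$nodes[n_old, ]
  }
  out <- margin_curve(nodes, c = itp(curve$c), T_elastic = itp(curve$T),
                      free_ends = curve$free_ends, closed = curve$closed)
  # carry the rest-length state over as the local ratio l0 / l
  ratio <- curve$l0 / cl$seg
  seg_mid <- function(cl) {
    ends <- if (curve$closed) c(cl$s[-1L], cl$total) else cl$s[-1L]
    (cl$s[seq_along(cl$seg)] + ends) / 2
  }
  s_seg_old <- seg_mid(cl)
  cl2 <- curve_lengths(nodes, curve$closed)
  s_seg_new <- seg_mid(cl2)
  r_new <- stats::approx(s_seg_old, ratio, xout = s_seg_new, rule = 2)$y
  out$l0 <- r_new * cl2$seg
  out$strain_rate <- itp(curve$strain_rate)
  if (!is.null(curve$u_t)) out$u_t <- itp(curve$u_t)
  out
}

#' Margin velocity profile of a 2D margin state
#'
#' @param curve a `margin_curve` carrying the tangential velocity `u_t`
#'   (present after the first simulation step).
#' @param t time stamp.
#' @return a [velocity_profile()].
#' @export
margin_velocity_profile <- function(curve, t = NA_real_) {
  if (is.null(curve$u_t)) stop("curve carries no tangential velocity yet")
  cl <- curve_lengths(curve$nodes, curve$closed)
  velocity_profile(curve$s, curve$u_t, t = t, L = cl$total,
                   closed = curve$closed)
}

#' Detect contraction foci along the margin
#'
#' Maximal contiguous arcs where the (lightly smoothed) strain rate is below
#' `-threshold`. Each focus is reported with its angular position (degrees,
#' posterior = 0) and arc extent; foci whose arc does not contain the
#' posterior are flagged ectopic.
#'
#' @param curve a `margin_curve` with strain-rate field.
#' @param threshold strain-rate magnitude defining active contraction (1/h).
#' @param min_arc minimum arc length (mm) for a focus.
#' @return data frame with one row per focus: `theta_mid` (deg), `arc_mm`,
#'   `peak_rate`, `ectopic`.
#' @export
contraction_foci <- function(curve, threshold = 0.05, min_arc = 0.2) {
  n <- nrow(curve$nodes)
  eps <- smooth_ma(curve$strain_rate, 3L, periodic = curve$closed)
  neg <- eps < -threshold
  cl <- curve_lengths(curve$nodes, curve$closed)
  th <- atan2(curve$nodes[, 2], curve$nodes[, 1]) * 180 / pi
  runs <- rle(neg)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  foci <- NULL
  for (r in seq_along(runs$values)) {
    if (!runs$values[r]) next
    ids <- idx_start[r]:idx_end[r]
    arc <- sum(cl$seg[pmin(ids, length(cl$seg))])
    if (arc < min_arc) next
    pk <- min(eps[ids])
    tmid <- th[ids[which.min(eps[ids])]]
    contains_post <- any(abs(th[ids]) < 15)
    foci <- rbind(foci, data.frame(theta_mid = tmid, arc_mm = arc,
                                   peak_rate = pk,
                                   ectopic = !contains_post))
  }
  # merge wrap-around runs on a closed margin
  if (curve$closed && !is.null(foci) && nrow(foci) >= 2L && neg[1L] && neg[n]) {
    foci <- foci[-nrow(foci), , drop = FALSE]
  }
  if (is.null(foci))
    data.frame(theta_mid = numeric(0), arc_mm = numeric(0),
               peak_rate = numeric(0), ectopic = logical(0))
  else foci
}

#' Write a 2D margin history table
#'
#' Long-format tab-separated table: `time`, `s`, `x`, `y`, `c`, `T`,
#' `strain_rate`.
#'
#' @param traj a [simulate_scenario()] trajectory.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_margin_history_2d <- function(traj, file) {
  rows <- lapply(seq_along(traj$times), function(k) {
    m <- traj$margin[[k]]
    data.frame(time = traj$times[k], s = m$s, x = m$nodes[, 1],
               y = m$nodes[, 2], c = m$c, T = m$T,
               strain_rate = m$strain_rate)
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
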