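# 2D tissue-flow solver: Q1 finite elements on a masked regular grid.
#
# The tissue is a compressible Stokes fluid with substrate friction:
#   mu * Lap(u) + lam_b * grad(div u - gamma) - friction * u + f = 0
# with lam_b = kappa + mu/3 a large bulk viscosity imposing div u ~ gamma
# (penalty formulation). Weak form, per element:
#   mu grad(u):grad(v) + lam_b (div u)(div v) + friction u.v
#     = f.v + lam_b gamma (div v)
# The grad-grad term uses full 2x2 Gauss quadrature; the div-div penalty is
# integrated at the element centre (selective reduced integration, the
# standard cure for locking). Friction uses a lumped mass matrix and may vary
# per element (obstacles). Attached boundaries are Dirichlet; free boundaries
# are natural (zero traction of the penalized stress).

#' Build a masked regular-grid mesh
#'
#' Q1 quadrilateral mesh of cell size `h` covering the region where
#' `inside(x, y)` is `TRUE` (evaluated at cell centres).
#'
#' @param inside vectorized indicator function of the domain.
#' @param bbox numeric `c(xmin, xmax, ymin, ymax)`.
#' @param h cell size (mm).
#' @return object of class `mesh2d`: node coordinates, cell connectivity,
#'   cell centres, boundary-node ids, and grid bookkeeping for point location.
#' @export
make_mesh <- function(inside, bbox, h) {
  nx <- ceiling((bbox[2] - bbox[1]) / h)
  ny <- ceiling((bbox[4] - bbox[3]) / h)
  cx <- bbox[1] + (seq_len(nx) - 0.5) * h
  cy <- bbox[3] + (seq_len(ny) - 0.5) * h
  cc <- expand.grid(x = cx, y = cy)
  act <- matrix(inside(cc$x, cc$y), nx, ny)
  if (!any(act)) stop("empty mesh: no cell centre lies inside the domain")
  # nodes on the (nx+1) x (ny+1) corner grid that touch an active cell
  used <- matrix(FALSE, nx + 1L, ny + 1L)
  ij <- which(act, arr.ind = TRUE)
  for (d in list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
    used[ij + rep(d, each = nrow(ij))] <- TRUE
  node_id <- matrix(0L, nx + 1L, ny + 1L)
  node_id[used] <- seq_len(sum(used))
  nid <- which(used, arr.ind = TRUE)
  nodes <- cbind(x = bbox[1] + (nid[, 1] - 1L) * h,
                 y = bbox[3] + (nid[, 2] - 1L) * h)
  # cells: counterclockwise corner nodes
  cells <- cbind(node_id[ij],
                 node_id[ij + rep(c(1L, 0L), each = nrow(ij))],
                 node_id[ij + rep(c(1L, 1L), each = nrow(ij))],
                 node_id[ij + rep(c(0L, 1L), each = nrow(ij))])
  centres <- cbind(x = cx[ij[, 1]], y = cy[ij[, 2]])
  # boundary nodes: corner not surrounded by 4 active cells
  actp <- matrix(FALSE, nx + 2L, ny + 2L)
  actp[2:(nx + 1L), 2:(ny + 1L)] <- act
  n_adj <- actp[cbind(nid[, 1], nid[, 2])] + actp[cbind(nid[, 1] + 1L, nid[, 2])] +
    actp[cbind(nid[, 1], nid[, 2] + 1L)] + actp[cbind(nid[, 1] + 1L, nid[, 2] + 1L)]
  m <- list(nodes = nodes, cells = cells, centres = centres, h = h,
            bbox = bbox, nx = nx, ny = ny, active = act, node_id = node_id,
            boundary_nodes = which(n_adj < 4L), n_adjacent = n_adj)
  class(m) <- "mesh2d"
  m
}

# Q1 element matrices (reference square scaled by h; h-independent in 2D)
q1_stiffness <- function() {
  matrix(c(4, -1, -2, -1,
           -1, 4, -1, -2,
           -2, -1, 4, -1,
           -1, -2, -1, 4), 4, 4) / 6
}

# centre-point div vector for the 8 element dofs [x-dofs, y-dofs];
# h^2 * outer(g, g) with g = grad at centre gives outer(v, v), v below
q1_div_vector <- function() c(-0.5, 0.5, 0.5, -0.5, -0.5, -0.5, 0.5, 0.5)

#' Assemble the tissue-flow operator
#'
#' Sparse symmetric positive-definite operator for the penalized compressible
#' Stokes problem. Degrees of freedom are stacked: `u_x` at dofs `1..N`,
#' `u_y` at `N + 1 .. 2N`.
#'
#' @param mesh a [make_mesh()] mesh.
#' @param mu shear viscosity.
#' @param lam_b bulk (penalty) viscosity `kappa + mu/3`.
#' @param friction per-element substrate friction coefficient (recycled).
#' @return list with the assembled `A` (dgCMatrix) and the pieces needed for
#'   right-hand sides (`lam_b`, lumped node areas).
#' @export
assemble_flow_operator <- function(mesh, mu, lam_b, friction) {
  ncell <- nrow(mesh$cells)
  N <- nrow(mesh$nodes)
  friction <- rep_len(friction, ncell)
  h <- mesh$h
  K <- q1_stiffness()
  v8 <- q1_div_vector()
  E_visc <- mu * rbind(cbind(K, matrix(0, 4, 4)), cbind(matrix(0, 4, 4), K)) +
    lam_b * outer(v8, v8)
  idx8 <- cbind(mesh$cells, mesh$cells + N)  # ncell x 8 global dofs
  # constant 8x8 block: triplets by outer product of index columns
  rows <- idx8[, rep(seq_len(8), times = 8)]
  cols <- idx8[, rep(seq_len(8), each = 8)]
  vals <- matrix(rep(as.vector(E_visc), each = ncell), ncell, 64)
  # lumped friction mass: h^2/4 per corner, per component
  fr_rows <- as.vector(idx8)
  fr_vals <- rep(friction * h^2 / 4, 8)
  A <- Matrix::sparseMatrix(i = c(as.vector(rows), fr_rows),
                            j = c(as.vector(cols), fr_rows),
                            x = c(as.vector(vals), fr_vals),
                            dims = c(2 * N, 2 * N), symmetric = FALSE)
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  lumped <- tabulate(as.vector(mesh$cells), N) * h^2 / 4
  list(A = A, lam_b = lam_b, lumped_area = lumped, mesh = mesh)
}

#' Prepare a flow solver with boundary conditions
#'
#' Applies Dirichlet conditions (attached boundary: prescribed velocity,
#' usually zero) by row/column elimination and caches the Cholesky
#' factorization, so that repeated solves with new forces are cheap.
#'
#' @param op result of [assemble_flow_operator()].
#' @param dirichlet_nodes node ids with prescribed velocity.
#' @param dirichlet_values matrix (length(dirichlet_nodes) x 2) of velocities,
#'   or NULL for zero.
#' @return solver closure environment (class `flow_solver`).
#' @export
flow_solver <- function(op, dirichlet_nodes, dirichlet_values = NULL) {
  N <- nrow(op$mesh$nodes)
  dir_dofs <- c(dirichlet_nodes, dirichlet_nodes + N)
  dir_vals <- if (is.null(dirichlet_values)) numeric(length(dir_dofs))
              else c(dirichlet_values[, 1], dirichlet_values[, 2])
  A <- op$A
  if (length(dir_dofs)) {
    # keep the lifting column action for inhomogeneous conditions
    Adir <- A[, dir_dofs, drop = FALSE]
    A[dir_dofs, ] <- 0
    A[, dir_dofs] <- 0
    A[cbind(dir_dofs, dir_dofs)] <- 1
  } else {
    Adir <- NULL
    # no Dirichlet dof: solvability requires friction > 0 somewhere
    fr_diag <- Matrix::diag(op$A)
    if (min(fr_diag) <= 0)
      stop("singular system: all-free boundary with zero friction")
  }
  A <- methods::as(A, "symmetricMatrix")
  ch <- tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = TRUE),
                 error = function(e)
                   stop("singular flow operator (all-free boundary with zero friction?): ",
                        conditionMessage(e)))
  sol <- list(chol = ch, A = A, Adir = Adir, dir_dofs = dir_dofs,
              dir_vals = dir_vals, op = op)
  class(sol) <- "flow_solver"
  sol
}

#' Solve for the tissue flow
#'
#' @param solver a [flow_solver()].
#' @param loads N x 2 matrix of nodal point loads (force), e.g. from
#'   [margin_force_density()]; may be NULL.
#' @param gamma_elem prescribed divergence per element (1/h); may be NULL.
#' @return object of class `flow_field`: `velocity` (N x 2), `divergence`
#'   per element, the `mesh`, and the boundary-condition residual.
#' @export
solve_flow <- function(solver, loads = NULL, gamma_elem = NULL) {
  op <- solver$op
  mesh <- op$mesh
  N <- nrow(mesh$nodes)
  b <- numeric(2 * N)
  if (!is.null(loads)) b <- b + c(loads[, 1], loads[, 2])
  if (!is.null(gamma_elem)) {
    v8 <- q1_div_vector() * mesh$h * op$lam_b
    idx8 <- cbind(mesh$cells, mesh$cells + N)
    contrib <- outer(gamma_elem, v8)
    b <- b + as.numeric(Matrix::sparseMatrix(
      i = as.vector(idx8), j = rep(1L, length(idx8)),
      x = as.vector(contrib), dims = c(2 * N, 1)))
  }
  if (length(solver$dir_dofs)) {
    b <- b - as.numeric(solver$Adir %*% solver$dir_vals)
    b[solver$dir_dofs] <- solver$dir_vals
  }
  u <- as.numeric(Matrix::solve(solver$chol, b, system = "A"))
  vel <- cbind(u[seq_len(N)], u[N + seq_len(N)])
  div <- flow_divergence(mesh, vel)
  ff <- list(velocity = vel, divergence = div, mesh = mesh,
             bc_residual = if (length(solver$dir_dofs))
               max(abs(u[solver$dir_dofs] - solver$dir_vals)) else 0)
  class(ff) <- "flow_field"
  ff
}

#' Discrete divergence of a nodal velocity field at element centres
#'
#' @param mesh a [make_mesh()] mesh.
#' @param vel N x 2 nodal velocity.
#' @return numeric vector, one value per element (1/h).
#' @export
flow_divergence <- function(mesh, vel) {
  v8 <- q1_div_vector() / mesh$h
  ux <- matrix(vel[mesh$cells, 1], ncol = 4)
  uy <- matrix(vel[mesh$cells, 2], ncol = 4)
  as.numeric(cbind(ux, uy) %*% v8)
}

#' Vorticity (curl) of a nodal velocity field at element centres
#'
#' @param mesh a [make_mesh()] mesh.
#' @param vel N x 2 nodal velocity.
#' @return numeric vector per element (1/h).
#' @export
flow_vorticity <- function(mesh, vel) {
  gx <- c(-0.5, 0.5, 0.5, -0.5) / mesh$h
  gy <- c(-0.5, -0.5, 0.5, 0.5) / mesh$h
  ux <- matrix(vel[mesh$cells, 1], ncol = 4)
  uy <- matrix(vel[mesh$cells, 2], ncol = 4)
  as.numeric(uy %*% gx - ux %*% gy)
}

#' Interpolate a nodal field at arbitrary points
#'
#' Bilinear interpolation on the structured grid; points falling in an
#' inactive cell are snapped to the nearest active cell (staircase
#' boundaries).
#'
#' @param mesh a [make_mesh()] mesh.
#' @param values N x k matrix of nodal values.
#' @param points m x 2 matrix of coordinates.
#' @return m x k matrix of interpolated values.
#' @export
interp_nodal <- function(mesh, values, points) {
  values <- as.matrix(values)
  h <- mesh$h
  ix <- pmin(pmax(floor((points[, 1] - mesh$bbox[1]) / h) + 1L, 1L), mesh$nx)
  iy <- pmin(pmax(floor((points[, 2] - mesh$bbox[3]) / h) + 1L, 1L), mesh$ny)
  out <- matrix(0, nrow(points), ncol(values))
  for (p in seq_len(nrow(points))) {
    cx <- ix[p]; cy <- iy[p]
    if (!mesh$active[cx, cy]) {
      # search outward for the nearest active cell (small staircase offsets)
      found <- FALSE
      for (r in 1:3) {
        cand <- expand.grid(dx = -r:r, dy = -r:r)
        cand <- cand[order(cand$dx^2 + cand$dy^2), ]
        for (q in seq_len(nrow(cand))) {
          tx <- cx + cand$dx[q]; ty <- cy + cand$dy[q]
          if (tx >= 1L && tx <= mesh$nx && ty >= 1L && ty <= mesh$ny &&
              mesh$active[tx, ty]) {
            cx <- tx; cy <- ty; found <- TRUE; break
          }
        }
        if (found) break
      }
      if (!found) next  # leave zero: far outside the tissue
    }
    n00 <- mesh$node_id[cx, cy];     n10 <- mesh$node_id[cx + 1L, cy]
    n11 <- mesh$node_id[cx + 1L, cy + 1L]; n01 <- mesh$node_id[cx, cy + 1L]
    x0 <- mesh$bbox[1] + (cx - 1L) * h
    y0 <- mesh$bbox[3] + (cy - 1L) * h
    fx <- min(max((points[p, 1] - x0) / h, 0), 1)
    fy <- min(max((points[p, 2] - y0) / h, 0), 1)
    g <- function(id) if (id > 0L) values[id, ] else numeric(ncol(values))
    out[p, ] <- (1 - fx) * (1 - fy) * g(n00) + fx * (1 - fy) * g(n10) +
      fx * fy * g(n11) + (1 - fx) * fy * g(n01)
  }
  out
}

#' Test for a dominant counter-rotating vortex pair
#'
#' The intact-embryo ("polonaise") flow consists of two counter-rotating
#' vortices mirrored about the anteroposterior (x) axis. This holds when the
#' strong-vorticity cells (|curl| above `rel_threshold` of the maximum) are
#' predominantly of one sign in the upper half-plane and of the opposite sign
#' in the lower half-plane.
#'
#' @param flow a [solve_flow()] result.
#' @param rel_threshold relative vorticity threshold.
#' @param purity minimum fraction of strong cells per half-plane sharing the
#'   half-plane's dominant sign.
#' @return logical.
#' @export
dominant_vortex_pair <- function(flow, rel_threshold = 0.5, purity = 0.8) {
  vort <- flow_vorticity(flow$mesh, flow$velocity)
  strong <- abs(vort) > rel_threshold * max(abs(vort))
  up <- flow$mesh$centres[, 2] > 0
  if (!any(strong & up) || !any(strong & !up)) return(FALSE)
  s_up <- sign(sum(sign(vort[strong & up])))
  s_dn <- sign(sum(sign(vort[strong & !up])))
  if (s_up == 0 || s_up == s_dn) return(FALSE)
  p_up <- mean(sign(vort[strong & up]) == s_up)
  p_dn <- mean(sign(vort[strong & !up]) == s_dn)
  p_up >= purity && p_dn >= purity
}

#' Count coherent vortices in a flow field
#'
#' Clusters elements whose vorticity magnitude exceeds `rel_threshold` times
#' the maximum into 4-connected components and counts components larger than
#' `min_cells`.
#'
#' @param flow a [solve_flow()] result.
#' @param rel_threshold relative vorticity threshold.
#' @param min_cells minimum component size.
#' @return number of vortices.
#' @export
count_vortices <- function(flow, rel_threshold = 0.5, min_cells = 5L) {
  mesh <- flow$mesh
  vort <- flow_vorticity(mesh, flow$velocity)
  thr <- rel_threshold * max(abs(vort))
  # map elements back onto the cell grid for connectivity
  lab <- matrix(0L, mesh$nx, mesh$ny)
  ij <- which(mesh$active, arr.ind = TRUE)
  strong <- abs(vort) > thr
  sgn <- sign(vort)
  grid_s <- matrix(0, mesh$nx, mesh$ny)
  grid_s[ij[strong, , drop = FALSE]] <- sgn[strong]
  comp <- 0L
  sizes <- integer(0)
  for (k in which(grid_s != 0)) {
    if (lab[k] != 0L) next
    comp <- comp + 1L
    queue <- k
    lab[k] <- comp
    sz <- 0L
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]; sz <- sz + 1L
      ci <- (cur - 1L) %% mesh$nx + 1L
      cj <- (cur - 1L) %/% mesh$nx + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ni <- ci + d[1L]; nj <- cj + d[2L]
        if (ni < 1L || ni > mesh$nx || nj < 1L || nj > mesh$ny) next
        lin <- ni + (nj - 1L) * mesh$nx
        if (lab[lin] == 0L && grid_s[lin] == grid_s[cur]) {
          lab[lin] <- comp
          queue <- c(queue, lin)
        }
      }
    }
    sizes <- c(sizes, sz)
  }
  sum(sizes >= min_cells)
}
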