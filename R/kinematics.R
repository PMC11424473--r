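#' Strain-rate kymograph container
#'
#' Space-time map of the strain rate along the margin. The margin coordinate
#' convention follows the imaging convention: 0 mm (0 degrees) is posterior,
#' +/- half-length (+/-180 degrees) is anterior.
#'
#' @param times numeric vector of frame times (h).
#' @param positions margin coordinate of each column (mm, posterior = 0).
#' @param strain_rate matrix, `length(times)` x `length(positions)` (1/h).
#' @param margin_length total margin length (mm) used for the degree scale.
#' @param material_tracks optional matrix of node margin-coordinates over time
#'   (grey track overlay), same number of rows as `times`.
#' @return object of class `kymograph` with an additional `positions_deg`
#'   field (degrees, posterior = 0).
#' @export
kymograph <- function(times, positions, strain_rate, margin_length,
                      material_tracks = NULL) {
  strain_rate <- as.matrix(strain_rate)
  stopifnot(length(times) == nrow(strain_rate),
            length(positions) == ncol(strain_rate),
            all(is.finite(strain_rate)), margin_length > 0)
  if (!is.null(material_tracks))
    stopifnot(nrow(material_tracks) == length(times))
  # wrap to the posterior-centred convention: coordinates in (-L/2, L/2]
  pos_c <- ((positions + margin_length / 2) %% margin_length) - margin_length / 2
  ky <- list(times = times, positions = positions,
             positions_centred = pos_c,
             positions_deg = pos_c / margin_length * 360,
             strain_rate = strain_rate, margin_length = margin_length,
             material_tracks = material_tracks)
  class(ky) <- "kymograph"
  ky
}

# 1D moving-average smoothing with edge truncation (or periodic wrap)
smooth_ma <- function(x, width = 3L, periodic = FALSE) {
  if (width <= 1L) return(x)
  n <- length(x)
  half <- (width - 1L) %/% 2L
  if (periodic) {
    xp <- c(x[(n - half + 1L):n], x, x[1:half])
    out <- stats::filter(xp, rep(1 / width, width), sides = 2)
    as.numeric(out[(half + 1L):(half + n)])
  } else {
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1L, i - half):min(n, i + half)
      out[i] <- mean(x[j])
    }
    out
  }
}

pivot_tracks <- function(tracks) {
  stopifnot(all(c("time", "node", "x", "y") %in% names(tracks)))
  times <- sort(unique(tracks$time))
  nodes <- sort(unique(tracks$node))
  it <- match(tracks$time, times)
  ino <- match(tracks$node, nodes)
  X <- matrix(NA_real_, length(times), length(nodes))
  Y <- X
  X[cbind(it, ino)] <- tracks$x
  Y[cbind(it, ino)] <- tracks$y
  if (anyNA(X) || anyNA(Y)) stop("track table has missing (time, node) pairs")
  list(times = times, X = X, Y = Y)
}

# segment lengths per frame; wraps for a closed margin
segment_lengths <- function(X, Y, closed) {
  n <- ncol(X)
  j <- if (closed) c(2:n, 1L) else 2:n
  i <- if (closed) 1:n else 1:(n - 1L)
  sqrt((X[, j, drop = FALSE] - X[, i, drop = FALSE])^2 +
       (Y[, j, drop = FALSE] - Y[, i, drop = FALSE])^2)
}

#' Strain-rate kymograph from tracked margin nodes
#'
#' Computes the Lagrangian strain rate per margin segment as the finite
#' difference of log segment length over the track cadence, and resamples it
#' onto a fixed grid of relative margin coordinate (posterior node = node 1 =
#' coordinate 0). Smoothing is a fixed-width moving average over 3 frames and
#' 3 bins (configurable).
#'
#' @param tracks data frame with columns `time` (h), `node` (id, ordered along
#'   the margin starting at the posterior), `x`, `y` (mm).
#' @param closed logical; `TRUE` for an intact (closed) margin.
#' @param n_bins number of margin-coordinate bins (default 128).
#' @param smooth_frames,smooth_bins moving-average widths (set to 1 to
#'   disable).
#' @return a [kymograph()]; the `material_tracks` field holds each node's
#'   relative margin coordinate over time, and attribute `lengths` the total
#'   margin length per frame.
#' @export
strain_rate_along_margin <- function(tracks, closed = TRUE, n_bins = 128L,
                                     smooth_frames = 3L, smooth_bins = 3L) {
  pv <- pivot_tracks(tracks)
  if (length(pv$times) < 2L) stop("need at least 2 time points")
  dtv <- diff(pv$times)
  segl <- segment_lengths(pv$X, pv$Y, closed)
  if (any(segl <= 0)) stop("degenerate (zero-length) margin segment")
  nt <- length(pv$times)
  # per-interval strain rate per segment, assigned to interval midpoints
  eps_seg <- (log(segl[-1L, , drop = FALSE]) -
              log(segl[-nt, , drop = FALSE])) / dtv
  tmid <- (pv$times[-1L] + pv$times[-nt]) / 2
  tot_len <- rowSums(segl)
  # relative coordinate of segment midpoints per frame (posterior node at 0)
  bin_edges <- seq(0, 1, length.out = n_bins + 1L)
  bin_mid <- (bin_edges[-1L] + bin_edges[-(n_bins + 1L)]) / 2
  K <- matrix(NA_real_, nt - 1L, n_bins)
  for (k in seq_len(nt - 1L)) {
    l0 <- segl[k, ]
    cum <- cumsum(l0)
    mids <- (cum - l0 / 2) / tot_len[k]
    idx <- findInterval(mids, bin_edges, rightmost.closed = TRUE)
    row <- tapply(eps_seg[k, ], factor(idx, levels = seq_len(n_bins)), mean)
    row <- as.numeric(row)
    # fill empty bins by nearest non-empty neighbour (coarse tracks)
    if (anyNA(row)) {
      ok <- which(!is.na(row))
      row <- row[ok[pmax(1L, sapply(seq_len(n_bins), function(i)
        which.min(abs(bin_mid[ok] - bin_mid[i]))))]]
    }
    K[k, ] <- row
  }
  if (smooth_bins > 1L)
    K <- t(apply(K, 1L, smooth_ma, width = smooth_bins, periodic = closed))
  if (smooth_frames > 1L && nrow(K) > 1L)
    K <- apply(K, 2L, smooth_ma, width = smooth_frames, periodic = FALSE)
  K <- matrix(K, nt - 1L, n_bins)
  L0 <- tot_len[1L]
  # node relative coordinates for the material-track overlay
  cum_nodes <- cbind(0, t(apply(segl, 1L, cumsum)))[, seq_len(ncol(pv$X)),
                                                    drop = FALSE]
  mt <- (cum_nodes / tot_len)[-nt, , drop = FALSE]
  ky <- kymograph(times = tmid, positions = bin_mid * L0, strain_rate = K,
                  margin_length = L0, material_tracks = mt)
  attr(ky, "lengths") <- tot_len
  ky
}

#' Tangential velocity profile along the margin
#'
#' @param s margin coordinate per node (mm, posterior = 0, increasing).
#' @param u tangential velocity per node (mm/h).
#' @param t time stamp (h).
#' @param L total margin length (mm); needed to wrap closed margins.
#' @param closed logical.
#' @return object of class `velocity_profile`.
#' @export
velocity_profile <- function(s, u, t = NA_real_, L = max(s), closed = TRUE) {
  stopifnot(length(s) == length(u), all(is.finite(u)), !is.unsorted(s))
  vp <- list(s = s, u = u, t = t, L = L, closed = closed)
  class(vp) <- "velocity_profile"
  vp
}

#' Tangential velocity profile from tracked nodes at a given frame
#'
#' Projects each node's frame-to-frame displacement onto the local margin
#' tangent. The velocity is averaged over `average_frames` consecutive frame
#' pairs starting at `t_index` (tracking noise on a single 6-min displacement
#' is substantial; profiles from embryos are likewise time-window averages).
#'
#' @param tracks node-track table as in [strain_rate_along_margin()].
#' @param t_index first frame index of the averaging window.
#' @param average_frames number of consecutive frame pairs averaged
#'   (truncated to the available frames).
#' @param closed logical.
#' @return a [velocity_profile()] (geometry taken from frame `t_index`).
#' @export
velocity_profile_from_tracks <- function(tracks, t_index = 1L,
                                         average_frames = 3L,
                                         closed = TRUE) {
  pv <- pivot_tracks(tracks)
  nt <- length(pv$times)
  stopifnot(t_index >= 1L, t_index < nt)
  k_last <- min(nt - 1L, t_index + average_frames - 1L)
  dt <- pv$times[k_last + 1L] - pv$times[t_index]
  x <- pv$X[t_index, ]; y <- pv$Y[t_index, ]
  vx <- (pv$X[k_last + 1L, ] - x) / dt
  vy <- (pv$Y[k_last + 1L, ] - y) / dt
  n <- length(x)
  ip <- if (closed) c(2:n, 1L) else c(2:n, n)
  im <- if (closed) c(n, 1:(n - 1L)) else c(1L, 1:(n - 1L))
  tx <- x[ip] - x[im]; ty <- y[ip] - y[im]
  tl <- sqrt(tx^2 + ty^2)
  u <- (vx * tx + vy * ty) / tl
  segl <- segment_lengths(matrix(x, 1), matrix(y, 1), closed)[1L, ]
  s <- c(0, cumsum(segl))[seq_len(n)]
  velocity_profile(s, u, pv$times[t_index], L = sum(segl), closed = closed)
}

#' Size of the contracting domain from a velocity profile
#'
#' The instantaneous contracting-domain size is the arclength interval between
#' the extrema of the tangential velocity that contains the contracting region
#' (negative slope, i.e. running from the velocity maximum to the minimum in
#' the direction of increasing margin coordinate). Ties between equal extrema
#' are broken towards the shortest contracting interval. The profile is
#' smoothed with the same 3-bin moving average as the kymographs.
#'
#' @param profile a [velocity_profile()].
#' @param smooth_bins moving-average width (1 disables smoothing).
#' @return list with `size` (mm), `fraction` of total margin length, and the
#'   coordinates `s_max`, `s_min` of the bounding extrema.
#' @export
contracting_domain_size <- function(profile, smooth_bins = 3L) {
  stopifnot(inherits(profile, "velocity_profile"))
  u <- smooth_ma(profile$u, smooth_bins, periodic = profile$closed)
  if (diff(range(u)) < 1e-12 * max(abs(u), 1e-300))
    stop("degenerate (flat) velocity profile: no extrema")
  tol <- 1e-9 * diff(range(u))
  imax <- which(u >= max(u) - tol)
  imin <- which(u <= min(u) + tol)
  L <- profile$L
  arc <- function(a, b) {  # arclength from s[a] to s[b] in +s direction
    d <- profile$s[b] - profile$s[a]
    if (profile$closed) d %% L else d
  }
  best <- NULL
  for (a in imax) for (b in imin) {
    d <- arc(a, b)
    if (!profile$closed && d < 0) next
    if (is.null(best) || d < best$size)
      best <- list(size = d, s_max = profile$s[a], s_min = profile$s[b])
  }
  if (is.null(best)) {  # open profile with min before max: mirror interval
    best <- list(size = abs(profile$s[imin[1L]] - profile$s[imax[1L]]),
                 s_max = profile$s[imax[1L]], s_min = profile$s[imin[1L]])
  }
  best$fraction <- best$size / L
  best
}

#' Normalized integrated contraction of a margin portion
#'
#' Logarithm of the fold change in length of a margin portion over the course
#' of an experiment, normalized to the logarithm of the target contraction for
#' that experiment, with the sign convention that a portion contracting by
#' exactly the target yields -1 (posterior convention). Targets: 0.5 (50%
#' reduction) for epiblast halves, 0.6 for intact epiblasts.
#'
#' @param lengths numeric vector of the portion's length over time (mm); only
#'   the first and last values enter.
#' @param target target contraction as a fraction in (0, 1) (e.g. 0.5 = 50%
#'   reduction in length).
#' @return normalized integrated contraction (dimensionless); ~-1 for a
#'   portion that contracted by the target, +1 for the mirror-image
#'   stretching.
#' @export
integrated_contraction <- function(lengths, target = 0.5) {
  stopifnot(length(lengths) >= 2L, all(lengths > 0),
            target > 0, target < 1)
  log(lengths[length(lengths)] / lengths[1L]) / abs(log(1 - target))
}

#' Deformation map from a tracer-grid trajectory
#'
#' Log ratio of final to initial area of each grid cell of an advected,
#' initially regular tracer grid. Red encodes contraction (negative values),
#' blue expansion, matching the kymograph colour convention.
#'
#' @param ref list with matrices `x`, `y`: reference grid-node positions.
#' @param adv list with matrices `x`, `y`: advected positions (same shape).
#' @return object of class `deformation_map` with the per-cell
#'   `log_area_ratio` matrix, per-cell initial/final areas, and an
#'   `inverted` logical matrix flagging cells whose final area is
#'   non-positive.
#' @export
deformation_map <- function(ref, adv) {
  stopifnot(identical(dim(ref$x), dim(adv$x)),
            identical(dim(ref$y), dim(adv$y)))
  quad_area <- function(x, y) {
    n1 <- nrow(x) - 1L; n2 <- ncol(x) - 1L
    a <- matrix(0, n1, n2)
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      xs <- c(x[i, j], x[i + 1L, j], x[i + 1L, j + 1L], x[i, j + 1L])
      ys <- c(y[i, j], y[i + 1L, j], y[i + 1L, j + 1L], y[i, j + 1L])
      a[i, j] <- 0.5 * sum(xs * c(ys[-1L], ys[1L]) - c(xs[-1L], xs[1L]) * ys)
    }
    a
  }
  a0 <- quad_area(ref$x, ref$y)
  a1 <- quad_area(adv$x, adv$y)
  if (any(a0 <= 0)) stop("degenerate reference grid cells")
  inverted <- a1 <= 0
  lar <- matrix(NA_real_, nrow(a0), ncol(a0))
  lar[!inverted] <- log(a1[!inverted] / a0[!inverted])
  dm <- list(ref = ref, adv = adv, area_initial = a0, area_final = a1,
             log_area_ratio = lar, inverted = inverted,
             colour = c(contraction = "red", expansion = "blue"))
  class(dm) <- "deformation_map"
  dm
}

#' Staging time by integrated contraction of a posterior segment
#'
#' First time at which a tracked margin segment has shrunk by
#' `target_fraction` of its initial length (linear interpolation between
#' frames). Used to align conditions: 20% contraction triggers the cut,
#' 50% is the endpoint for epiblast halves, 60% for intact epiblasts.
#'
#' @param times frame times (h).
#' @param lengths segment length per frame (mm).
#' @param target_fraction fractional reduction in (0, 1).
#' @return crossing time (h), or `NA_real_` (the explicit not-reached signal)
#'   if the target is never reached within the track.
#' @export
stage_by_contraction <- function(times, lengths, target_fraction) {
  stopifnot(length(times) == length(lengths), all(lengths > 0),
            target_fraction > 0, target_fraction < 1)
  thr <- lengths[1L] * (1 - target_fraction)
  below <- which(lengths <= thr)
  if (!length(below)) return(NA_real_)
  k <- below[1L]
  if (k == 1L) return(times[1L])
  # linear interpolation in length between frames k-1 and k
  f <- (lengths[k - 1L] - thr) / (lengths[k - 1L] - lengths[k])
  times[k - 1L] + f * (times[k] - times[k - 1L])
}

#' Contracting fraction measured from a kymograph row
#'
#' Fraction of margin-coordinate bins with strain rate below `-tol` at the
#' frame nearest `t` (or averaged over the last `average_frames` frames).
#'
#' @param ky a [kymograph()].
#' @param t time (h); default: last frame.
#' @param tol strain-rate threshold magnitude (1/h).
#' @param average_frames average the fraction over this many trailing frames.
#' @return fraction in `[0, 1]`.
#' @export
kymograph_contracting_fraction <- function(ky, t = NULL, tol = 1e-6,
                                           average_frames = 1L) {
  stopifnot(inherits(ky, "kymograph"))
  k <- if (is.null(t)) nrow(ky$strain_rate)
       else which.min(abs(ky$times - t))
  rows <- max(1L, k - average_frames + 1L):k
  mean(ky$strain_rate[rows, , drop = FALSE] < -tol)
}
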