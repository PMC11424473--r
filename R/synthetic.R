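#' Ground-truth specification for synthetic margin-tracking data
#'
#' Describes a stated world for the quantification pipeline: a margin of
#' given length with a posterior contracting arc (a known fraction of the
#' margin contracting at a known rate, the complement stretching so as to
#' conserve total length), imaged at a fixed cadence with additive tracking
#' noise. Defaults mirror the imaging conditions: 6-min frame interval, 8-h
#' window, ~6-mm margin, contracting fraction 0.37 (control embryos).
#'
#' @param margin_length total margin length (mm).
#' @param fraction contracting fraction of the margin, in (0, 1).
#' @param rate contraction rate of the contracting arc (1/h, positive number;
#'   the arc's strain rate is `-rate`).
#' @param noise_sigma positional tracking noise, as a fraction of the typical
#'   inter-frame node displacement (PIV-like).
#' @param frame_interval frame interval (min).
#' @param duration imaging duration (h).
#' @param n_nodes number of tracked margin nodes.
#' @param closed `FALSE` for a cut-open margin (cut at the anterior; the two
#'   cut ends are simply not connected).
#' @param expression_midpoint,expression_slope parameters of the
#'   contraction-to-expression map used by [gen_expression_image()].
#' @param seed integer seed; generator output depends only on fields + seed.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(margin_length = 6, fraction = 0.37, rate = 0.2,
                            noise_sigma = 0.1, frame_interval = 6,
                            duration = 8, n_nodes = 128L, closed = TRUE,
                            expression_midpoint = -0.25,
                            expression_slope = 1, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1, margin_length > 0, rate > 0,
            noise_sigma >= 0, frame_interval > 0, duration > 0, n_nodes >= 8L)
  tr <- list(margin_length = margin_length, fraction = fraction, rate = rate,
             noise_sigma = noise_sigma, frame_interval = frame_interval,
             duration = duration, n_nodes = as.integer(n_nodes),
             closed = isTRUE(closed),
             expression_midpoint = expression_midpoint,
             expression_slope = expression_slope, seed = as.integer(seed))
  class(tr) <- "synthetic_truth"
  tr
}

#' Generate synthetic margin node tracks
#'
#' Nodes on a (closed or cut-open) margin move under a prescribed piecewise
#' material strain-rate field: segments within the posterior contracting arc
#' (|s| < fraction * L / 2, posterior at s = 0) contract at `-rate`; the
#' complementary arc stretches at `rate * fraction / (1 - fraction)` so total
#' length is conserved to leading order. Nodes are laid out on a circle whose
#' radius tracks the current total length; seeded Gaussian positional noise is
#' added with standard deviation `noise_sigma` times the mean noiseless
#' inter-frame displacement.
#'
#' @param truth a [synthetic_truth()].
#' @return list with `tracks` (data frame: `time` (h), `node`, `x`, `y` (mm),
#'   the same schema the 2D simulator emits) and `truth` (the input record,
#'   augmented with the realized noise standard deviation in mm and the
#'   contracting-arc node indicator).
#' @export
gen_margin_tracks <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  L <- truth$margin_length
  n <- truth$n_nodes
  nt <- round(truth$duration * 60 / truth$frame_interval)  # e.g. 80 frames
  times <- (seq_len(nt) - 1L) * truth$frame_interval / 60
  # node 1 at the posterior (s = 0), centre of the contracting arc
  s0 <- (seq_len(n) - 1L) / n * L
  nseg <- if (truth$closed) n else n - 1L
  mid <- (s0[seq_len(nseg)] + L / n / 2)          # segment midpoints
  sc <- pmin(mid, L - mid)                         # distance from posterior
  contracting <- sc < truth$fraction * L / 2
  r_stretch <- truth$rate * truth$fraction / (1 - truth$fraction)
  seg_rate <- ifelse(contracting, -truth$rate, r_stretch)
  ds0 <- L / n
  X <- matrix(0, nt, n); Y <- matrix(0, nt, n)
  for (k in seq_len(nt)) {
    segl <- ds0 * exp(seg_rate * times[k])
    tot <- sum(segl)
    cum <- c(0, cumsum(segl))[seq_len(n)]
    # centre the posterior node's arc position so the pattern stays put
    theta <- 2 * pi * (cum - cum[1L]) / tot
    R <- tot / (2 * pi)
    X[k, ] <- R * cos(theta)
    Y[k, ] <- R * sin(theta)
  }
  disp <- sqrt(diff(X)^2 + diff(Y)^2)
  sigma_mm <- truth$noise_sigma * mean(disp)
  if (sigma_mm > 0) {
    set.seed(truth$seed)
    X <- X + matrix(stats::rnorm(nt * n, sd = sigma_mm), nt, n)
    Y <- Y + matrix(stats::rnorm(nt * n, sd = sigma_mm), nt, n)
  }
  tracks <- data.frame(time = rep(times, n),
                       node = rep(seq_len(n), each = nt),
                       x = as.vector(X), y = as.vector(Y))
  truth$sigma_mm <- sigma_mm
  truth$segment_contracting <- contracting
  list(tracks = tracks, truth = truth)
}

# separable Gaussian blur of a matrix (truncated kernel, renormalized edges)
blur_matrix <- function(z, sigma_px) {
  if (sigma_px <= 0) return(z)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1L], half), v, rep(v[n], half))
    as.numeric(stats::filter(vp, k, sides = 2))[(half + 1L):(half + n)]
  }
  z <- apply(z, 2L, conv1)
  t(apply(z, 1L, conv1))
}

#' Generate a synthetic margin-centred expression image
#'
#' Paints an expression level along a band centred on the margin curve
#' (band kept within the 400-um quantification strip), applies a Gaussian
#' blur, and adds a background offset and seeded shot-like noise
#' (sd proportional to sqrt(intensity)).
#'
#' @param curve matrix of margin-node positions (columns x, y, mm), ordered,
#'   posterior first.
#' @param chi normalized integrated contraction per node; the painted level is
#'   `gdf1_readout(chi, slope)`.
#' @param slope slope passed to [gdf1_readout()].
#' @param band_halfwidth half-width of the painted band (mm); default 0.12 so
#'   band + blur stay within the 0.2-mm strip half-width.
#' @param pixel_size image pixel size (mm).
#' @param blur_sigma Gaussian blur sigma (mm).
#' @param background additive background level.
#' @param noise_amp shot-noise amplitude (sd = `noise_amp * sqrt(intensity)`).
#' @param closed logical.
#' @param seed integer seed.
#' @return list with `field` (list `x`, `y`, `z` as consumed by
#'   [quantify_profile()]) and `truth` (painted level per node and the
#'   relative size of the above-1/2 domain).
#' @export
gen_expression_image <- function(curve, chi, slope = 1, band_halfwidth = 0.12,
                                 pixel_size = 0.02, blur_sigma = 0.02,
                                 background = 0.05, noise_amp = 0.02,
                                 closed = TRUE, seed = 1L) {
  stopifnot(is.matrix(curve), nrow(curve) == length(chi))
  level <- gdf1_readout(chi, slope = slope)
  pad <- band_halfwidth + 4 * blur_sigma + 0.1
  xr <- range(curve[, 1L]) + c(-pad, pad)
  yr <- range(curve[, 2L]) + c(-pad, pad)
  gx <- seq(xr[1L], xr[2L], by = pixel_size)
  gy <- seq(yr[1L], yr[2L], by = pixel_size)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  # nearest margin node and its painted level, per pixel
  best_d2 <- rep(Inf, length(px))
  best_lv <- numeric(length(px))
  for (i in seq_len(nrow(curve))) {
    d2 <- (px - curve[i, 1L])^2 + (py - curve[i, 2L])^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_lv[upd] <- level[i]
  }
  z <- matrix(ifelse(best_d2 <= band_halfwidth^2, best_lv, 0),
              length(gx), length(gy))
  z <- blur_matrix(z, blur_sigma / pixel_size)
  set.seed(as.integer(seed))
  z <- z + background +
    matrix(stats::rnorm(length(z), sd = noise_amp * sqrt(pmax(z, 0))),
           length(gx), length(gy))
  list(field = list(x = gx, y = gy, z = z),
       truth = list(level = level,
                    domain_rel_size = mean(level > 0.5)))
}

#' Closed-form flow fixtures for deformation-map and solver tests
#'
#' Tracer-grid trajectories under a named analytic flow with known area
#' change: `rigid_rotation` (zero deformation), `uniform_dilation` (log area
#' ratio `log(factor^2)` everywhere), `ring_contraction` (inward displacement
#' localized near a ring, mimicking margin-driven flow).
#'
#' @param kind one of `"rigid_rotation"`, `"uniform_dilation"`,
#'   `"ring_contraction"`.
#' @param n grid nodes per side.
#' @param extent half-width of the tracer grid (mm).
#' @param angle rotation angle (radians) for `rigid_rotation`.
#' @param factor dilation factor for `uniform_dilation`.
#' @param ring_radius,ring_width,amplitude ring-contraction parameters (mm,
#'   mm, mm of inward displacement at the ring).
#' @return list with `ref`, `adv` (each a list of `x`, `y` matrices), `kind`,
#'   and `log_area_truth` (matrix or NA where no closed form is asserted).
#' @export
gen_flow_fixture <- function(kind = c("rigid_rotation", "uniform_dilation",
                                      "ring_contraction"),
                             n = 21L, extent = 2, angle = pi / 5, factor = 1.3,
                             ring_radius = 1.3, ring_width = 0.3,
                             amplitude = 0.2) {
  kind <- match.arg(kind)
  g <- seq(-extent, extent, length.out = n)
  x0 <- matrix(rep(g, times = n), n, n)
  y0 <- matrix(rep(g, each = n), n, n)
  if (kind == "rigid_rotation") {
    x1 <- cos(angle) * x0 - sin(angle) * y0
    y1 <- sin(angle) * x0 + cos(angle) * y0
    truth <- matrix(0, n - 1L, n - 1L)
  } else if (kind == "uniform_dilation") {
    x1 <- factor * x0; y1 <- factor * y0
    truth <- matrix(log(factor^2), n - 1L, n - 1L)
  } else {
    r <- sqrt(x0^2 + y0^2)
    dr <- -amplitude * exp(-(r - ring_radius)^2 / (2 * ring_width^2))
    scl <- ifelse(r > 0, (r + dr) / r, 1)
    x1 <- x0 * scl; y1 <- y0 * scl
    truth <- matrix(NA_real_, n - 1L, n - 1L)
  }
  list(ref = list(x = x0, y = y0), adv = list(x = x1, y = y1),
       kind = kind, log_area_truth = truth)
}
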