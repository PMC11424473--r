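#' Strip-integrated expression profile along the margin
#'
#' Quantifies an expression signal (e.g. a maximum-z-projected in situ or
#' RNAscope image) along the margin by integrating intensity across a
#' transverse strip centred on the margin (default width 400 um = 0.4 mm),
#' then normalizing so that background maps to ~0 and the expression plateau
#' to ~1 (5th/95th percentile anchors).
#'
#' @param field list describing the intensity image: `x`, `y` (coordinate
#'   vectors, mm) and `z` (intensity matrix, `length(x)` x `length(y)`).
#' @param curve matrix of margin-node positions (columns x, y, mm), ordered
#'   along the margin with the posterior first; closed unless `closed=FALSE`.
#' @param strip_width full transverse width of the integration strip (mm).
#' @param n_bins number of margin-coordinate bins.
#' @param n_transverse transverse samples across the strip.
#' @param normalize logical; apply the two-level percentile normalization.
#' @param closed logical.
#' @param gene gene label carried in the result (GDF1/BRA/SOX3 proxy).
#' @return object of class `expression_profile`: `s_rel` (relative margin
#'   coordinate in `[0,1)`), `s_mm`, `intensity` (normalized), `gene`.
#' @export
quantify_profile <- function(field, curve, strip_width = 0.4, n_bins = 128L,
                             n_transverse = 21L, normalize = TRUE,
                             closed = TRUE, gene = "GDF1") {
  stopifnot(is.matrix(curve), ncol(curve) == 2L,
            length(field$x) == nrow(field$z),
            length(field$y) == ncol(field$z))
  n <- nrow(curve)
  nxt <- if (closed) c(2:n, 1L) else c(2:n, n)
  prv <- if (closed) c(n, 1:(n - 1L)) else c(1L, 1:(n - 1L))
  tx <- curve[nxt, 1L] - curve[prv, 1L]
  ty <- curve[nxt, 2L] - curve[prv, 2L]
  tl <- sqrt(tx^2 + ty^2)
  nx <- -ty / tl; ny <- tx / tl  # unit normal
  segl <- sqrt(diff(c(curve[, 1L], if (closed) curve[1L, 1L]))^2 +
               diff(c(curve[, 2L], if (closed) curve[1L, 2L]))^2)
  L <- sum(segl[seq_len(if (closed) n else n - 1L)])
  s_node <- c(0, cumsum(segl))[seq_len(n)]
  # resample curve to bin centres by arclength
  s_bin <- (seq_len(n_bins) - 0.5) / n_bins * L
  interp_wrap <- function(v) stats::approx(c(s_node, L), c(v, v[1L]),
                                           xout = s_bin, rule = 2)$y
  interp_open <- function(v) stats::approx(s_node, v, xout = s_bin, rule = 2)$y
  itp <- if (closed) interp_wrap else interp_open
  cx <- itp(curve[, 1L]); cy <- itp(curve[, 2L])
  bnx <- itp(nx); bny <- itp(ny)
  nl <- sqrt(bnx^2 + bny^2); bnx <- bnx / nl; bny <- bny / nl
  offs <- seq(-strip_width / 2, strip_width / 2, length.out = n_transverse)
  bil <- function(px, py) {
    # bilinear sample of field$z at (px, py); 0 outside the field
    ix <- findInterval(px, field$x)
    iy <- findInterval(py, field$y)
    ok <- ix >= 1L & ix < length(field$x) & iy >= 1L & iy < length(field$y)
    out <- numeric(length(px))
    if (!any(ok)) return(out)
    ix <- ix[ok]; iy <- iy[ok]
    fx <- (px[ok] - field$x[ix]) / (field$x[ix + 1L] - field$x[ix])
    fy <- (py[ok] - field$y[iy]) / (field$y[iy + 1L] - field$y[iy])
    z <- field$z
    out[ok] <- (1 - fx) * (1 - fy) * z[cbind(ix, iy)] +
      fx * (1 - fy) * z[cbind(ix + 1L, iy)] +
      (1 - fx) * fy * z[cbind(ix, iy + 1L)] +
      fx * fy * z[cbind(ix + 1L, iy + 1L)]
    out
  }
  prof <- numeric(n_bins)
  for (k in seq_along(offs)) {
    prof <- prof + bil(cx + offs[k] * bnx, cy + offs[k] * bny)
  }
  prof <- prof / length(offs)
  if (normalize) prof <- normalize_profile(prof)
  out <- list(s_rel = s_bin / L, s_mm = s_bin, intensity = prof,
              gene = gene, margin_length = L)
  class(out) <- "expression_profile"
  out
}

#' Two-level percentile normalization of an intensity profile
#'
#' Affine map sending the 5th percentile of the profile to 0 (background) and
#' the 95th percentile to 1 (expression plateau). This operationalizes the
#' "normalized to ~0 outside and ~1 inside the expression domain" convention;
#' being an affine-equivariant quantile map, it is exactly idempotent.
#'
#' @param values numeric profile.
#' @param anchors length-2 probability vector of the low/high anchors.
#' @return normalized profile.
#' @export
normalize_profile <- function(values, anchors = c(0.05, 0.95)) {
  lo <- stats::quantile(values, anchors[1L], names = FALSE)
  hi <- stats::quantile(values, anchors[2L], names = FALSE)
  if (hi - lo < .Machine$double.eps * max(abs(hi), 1))
    stop("flat intensity profile: normalization anchors coincide")
  (values - lo) / (hi - lo)
}

#' Phenomenological contraction-to-GDF1 readout
#'
#' Maps normalized integrated contraction `chi` (-1 in steadily contracted
#' posterior tissue, positive in stretched tissue) to a normalized expression
#' level in `[0, 1]`. The map is piecewise linear: it passes through the
#' stated midpoint pairing (chi = -1/4, level = 1/2), has configurable slope
#' (default 1 on the normalized-contraction axis, so the linear band spans
#' chi in [-3/4, 1/4]), saturates at 1 for strong steady contraction and at 0
#' for strong stretching. With the Ski-1 preset the mechanosensitive relay is
#' blocked and the readout is disabled (returns `NA`).
#'
#' @param chi normalized integrated contraction (vector ok).
#' @param slope magnitude of d(level)/d(chi) in the linear band.
#' @param ski1 logical; Ski-1 treatment disables the readout.
#' @return expression level(s) in `[0, 1]`, or `NA` under Ski-1.
#' @export
gdf1_readout <- function(chi, slope = 1, ski1 = FALSE) {
  stopifnot(all(is.finite(chi)), slope > 0)
  if (isTRUE(ski1)) return(rep(NA_real_, length(chi)))
  pmin(1, pmax(0, 0.5 - slope * (chi + 0.25)))
}

#' Relative domain size by thresholding a profile
#'
#' Fraction of the margin where a normalized profile exceeds a threshold
#' (expression convention, `direction = "above"`, default threshold 1/2) or
#' falls below it (contraction convention, `direction = "below"`, default
#' threshold -1/4).
#'
#' @param values profile values on an (implicitly uniform) normalized margin
#'   coordinate, or an `expression_profile`.
#' @param threshold threshold; default 1/2 for `"above"`, -1/4 for `"below"`.
#' @param direction `"above"` (expression) or `"below"` (contraction).
#' @return relative size in `[0, 1]`.
#' @export
domain_size_by_threshold <- function(values, threshold = NULL,
                                     direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (inherits(values, "expression_profile")) values <- values$intensity
  if (!length(values)) stop("empty profile")
  if (is.null(threshold))
    threshold <- if (direction == "above") 0.5 else -0.25
  if (direction == "above") mean(values > threshold)
  else mean(values < threshold)
}

#' One-sided permutation test of a positive Pearson correlation
#'
#' Tests whether paired domain sizes are positively associated: the observed
#' Pearson R is compared with R under random permutations of `y`, and the
#' one-sided p-value uses the add-one estimator
#' `p = (1 + #permutations with R_perm >= R_obs) / (n_perm + 1)`.
#'
#' @param x,y equal-length numeric vectors, `n >= 3`, non-constant.
#' @param n_perm number of random permutations (the reference analysis uses
#'   1e6; tests use fewer).
#' @param seed integer seed (reproducibility contract).
#' @return list with `R` (observed Pearson correlation), `p` (one-sided
#'   p-value), `n_perm`.
#' @export
permutation_test_correlation <- function(x, y, n_perm = 1e4L, seed = 1L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined")
  r_obs <- stats::cor(x, y)
  set.seed(as.integer(seed))
  # centred/scaled once; R_perm is a dot product per permutation
  xs <- (x - mean(x)) / stats::sd(x)
  ys <- (y - mean(y)) / stats::sd(y)
  nm1 <- length(x) - 1
  count <- 0L
  for (b in seq_len(n_perm)) {
    rp <- sum(xs * ys[sample.int(length(y))]) / nm1
    if (rp >= r_obs - 1e-12) count <- count + 1L
  }
  list(R = r_obs, p = (1 + count) / (n_perm + 1), n_perm = n_perm)
}
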