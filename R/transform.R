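#' @include utils.R volume.R
NULL

#' Invert an affine transform
#'
#' @param a an [AffineTransform-class].
#' @return The inverse [AffineTransform-class] with the direction tag
#'   flipped; composing the two is the identity to numerical precision.
#' @export
invertAffine <- function(a) {
  if (abs(det(a@linear)) < 1e-12) stop("affine is singular")
  Minv <- solve(a@linear)
  AffineTransform(Minv, -as.vector(Minv %*% a@translation),
                  direction = if (a@direction == "atlas->sample")
                    "sample->atlas" else "atlas->sample")
}

# y = M x + t applied to an n x 3 matrix of points.
.apply_affine <- function(points, a) {
  sweep(points %*% t(a@linear), 2L, a@translation, "+")
}

# Trilinear sample of a deformation field at n x 3 physical points (um).
# Points outside the field support are clamped to the edge displacement and
# flagged.
.sample_field <- function(points, field) {
  dm <- dim(field@displacements)[1:3]
  vc <- .to_voxel_coord(points, field@spacing, field@origin)
  outside <- apply(vc < 0 | sweep(vc, 2L, dm - 1, ">"), 1L, any)
  disp <- vapply(1:3, function(k) {
    cpp_trilinear(as.numeric(field@displacements[, , , k]), as.integer(dm), vc)
  }, numeric(nrow(points)))
  list(disp = matrix(disp, ncol = 3L), outside = outside)
}

#' Normalize sample-space points into atlas space
#'
#' Applies the registration chain the way nuclear coordinates are
#' normalized: the stored forward (atlas to sample) affine is used
#' *inversely* to pre-align the points, then the inverse deformation field
#' is applied *directly* (its displacement, interpolated trilinearly at the
#' pre-aligned location, is added). Points that land outside the atlas grid
#' are clamped to it and flagged, never dropped: the output always has as
#' many points as the input.
#'
#' @param points a [NucleusSet-class] tagged "sample".
#' @param chain a [TransformChain-class].
#' @param atlas optional [LabelAtlas-class] (or [ImageVolume-class]) whose
#'   grid bounds define the outside-atlas clamp; when NULL only the field
#'   support (if any) is used for flagging.
#' @return A [NucleusSet-class] tagged "atlas", same length, with the
#'   `outside` flag set where clamping occurred.
#' @export
applyChainToPoints <- function(points, chain, atlas = NULL) {
  if (pointSpace(points) != "sample")
    stop("points must be tagged \"sample\"; got \"", pointSpace(points), "\"")
  if (chain@affine@direction != "atlas->sample")
    stop("chain affine direction contradicts the inverse-use convention")
  p <- coords(points)
  q <- .apply_affine(p, invertAffine(chain@affine))
  outside <- rep(FALSE, nrow(q))
  if (!is.null(chain@field)) {
    sf <- .sample_field(q, chain@field)
    q <- q + sf$disp
    outside <- outside | sf$outside
  }
  if (!is.null(atlas)) {
    lo <- origin(atlas)
    hi <- origin(atlas) + dim(atlas) * spacing(atlas)
    for (k in 1:3) {
      bad <- q[, k] < lo[k] | q[, k] >= hi[k]
      outside <- outside | bad
      q[, k] <- pmin(pmax(q[, k], lo[k]), hi[k] - 1e-9 * spacing(atlas)[k])
    }
  }
  initialize(points, coords = q, space = "atlas", outside = outside)
}

#' Map atlas-space points forward into sample space
#'
#' The exact inverse of [applyChainToPoints()]: given the chain's inverse
#' deformation field v (atlas grid), the pre-image q of an atlas point p
#' solves q + v(q) = p and is found by fixed-point iteration; the forward
#' affine then carries q into sample space. Used to place simulated
#' ground-truth nuclei into the "as imaged" frame.
#'
#' @param points_atlas n x 3 matrix of atlas-space coordinates (um).
#' @param chain a [TransformChain-class].
#' @param iterations fixed-point iterations (default 20).
#' @return n x 3 matrix of sample-space coordinates (um).
#' @export
forwardTransformPoints <- function(points_atlas, chain, iterations = 20L) {
  q <- matrix(as.numeric(points_atlas), ncol = 3L)
  if (!is.null(chain@field)) {
    p <- q
    for (i in seq_len(iterations))
      q <- p - .sample_field(q, chain@field)$disp
  }
  .apply_affine(q, chain@affine)
}

# Build a 3x3 linear part from rotation (deg), log-free scale and shear.
.compose_linear <- function(rot_deg, scale, shear) {
  r <- rot_deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  U <- diag(scale)
  U[1, 2] <- shear[1]; U[1, 3] <- shear[2]; U[2, 3] <- shear[3]
  Rz %*% Ry %*% Rx %*% U
}

#' Estimate the affine aligning a moving volume to a fixed volume
#'
#' Intensity-based affine registration: centre-of-mass plus principal-axes
#' initialization ("moments") followed by derivative-free (Nelder-Mead)
#' refinement of the mean-squared intensity difference. The estimated map
#' sends fixed-space (atlas) coordinates to moving-space (sample)
#' coordinates, i.e. it is returned in the "atlas->sample" direction that
#' [applyChainToPoints()] consumes inversely. Deformable registration is
#' deliberately not estimated here; nonlinear fields are supplied.
#'
#' @param moving,fixed [ImageVolume-class] objects in the same physical units.
#' @param init "moments" or "identity".
#' @param seed integer; the optimization itself is deterministic, the seed
#'   is accepted for interface uniformity and recorded.
#' @param max_eval Nelder-Mead function-evaluation budget per level.
#' @param coarse_factor integer block-mean factor for the first (coarse)
#'   level; 1 disables the coarse level.
#' @return An [AffineTransform-class] ("atlas->sample") with attributes
#'   `final_cost`, `init_cost` and `improved` (FALSE means the refinement
#'   failed to beat the initialization and the init was returned).
#' @export
estimateAffine <- function(moving, fixed, init = c("moments", "identity"),
                           seed = 1L, max_eval = 1200L, coarse_factor = 2L) {
  init <- match.arg(init)
  moments <- function(v) {
    w <- pmax(as.numeric(v@data), 0)
    tw <- sum(w)
    if (tw <= 0) stop("volume has no positive intensity mass")
    g <- as.matrix(expand.grid(seq_len(dim(v@data)[1]), seq_len(dim(v@data)[2]),
                               seq_len(dim(v@data)[3])))
    x <- .voxel_centers(g, spacing(v), origin(v))
    mu <- colSums(x * w) / tw
    xc <- sweep(x, 2L, mu, "-")
    S <- crossprod(xc * sqrt(w / tw))
    list(mu = mu, S = S)
  }
  par0 <- rep(0, 12)
  par0[4:6] <- 1
  t0 <- c(0, 0, 0)
  if (init == "moments") {
    mf <- moments(fixed); mm <- moments(moving)
    s <- sqrt(diag(mm$S) / pmax(diag(mf$S), 1e-12))
    par0[4:6] <- s
    t0 <- mm$mu - s * mf$mu
  }
  par0[10:12] <- t0
  cost_on <- function(fx, mv) {
    d <- dim(fx@data)
    stride <- ifelse(d > 48, 2L, 1L)
    g <- as.matrix(expand.grid(seq(1L, d[1], by = stride[1]),
                               seq(1L, d[2], by = stride[2]),
                               seq(1L, d[3], by = stride[3])))
    x <- .voxel_centers(g, spacing(fx), origin(fx))
    fvals <- fx@data[cbind(g[, 1], g[, 2], g[, 3])]
    mdata <- as.numeric(mv@data)
    mdim <- .as_dim(mv@data)
    function(par) {
      A <- .compose_linear(par[1:3], par[4:6], par[7:9])
      y <- sweep(x %*% t(A), 2L, par[10:12], "+")
      mvals <- cpp_trilinear(mdata, mdim, .to_voxel_coord(y, spacing(mv), origin(mv)))
      mean((mvals - fvals)^2)
    }
  }
  par <- par0
  levels <- if (coarse_factor > 1L) c(coarse_factor, 1L) else 1L
  for (f in levels) {
    fx <- if (f > 1L) downsampleVolume(fixed, spacing(fixed) * f) else fixed
    mv <- if (f > 1L) downsampleVolume(moving, spacing(moving) * f) else moving
    fn <- cost_on(fx, mv)
    opt <- stats::optim(par, fn, method = "Nelder-Mead",
                        control = list(maxit = max_eval, reltol = 1e-10))
    par <- opt$par
  }
  fn_full <- cost_on(fixed, moving)
  init_cost <- fn_full(par0)
  final_cost <- fn_full(par)
  improved <- final_cost <= init_cost + 1e-12
  if (!improved) {
    warning("refinement failed to improve over the initialization; returning init")
    par <- par0
    final_cost <- init_cost
  }
  a <- AffineTransform(.compose_linear(par[1:3], par[4:6], par[7:9]),
                       par[10:12], direction = "atlas->sample")
  attr(a, "final_cost") <- final_cost
  attr(a, "init_cost") <- init_cost
  attr(a, "improved") <- improved
  attr(a, "seed") <- as.integer(seed)
  a
}
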