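#' @include synthgen.R
NULL

# sample->atlas mapping of a raw coordinate matrix (the normalization math
# without NucleusSet bookkeeping).
.chain_sample_to_atlas <- function(points, chain) {
  q <- .apply_affine(points, invertAffine(chain@affine))
  if (!is.null(chain@field)) q <- q + .sample_field(q, chain@field)$disp
  q
}

# Accumulate antialiased spheres into a zero array. Values reach 1 inside a
# nucleus and fall to 0 over about one voxel at the surface.
.render_spheres <- function(dm, sp, or, centers, radius) {
  arr <- array(0, dm)
  if (!nrow(centers)) return(arr)
  for (i in seq_len(nrow(centers))) {
    c_um <- centers[i, ]
    r <- radius[i]
    lo <- pmax(floor((c_um - r - sp) / sp - or / sp) + 1, 1)
    hi <- pmin(ceiling((c_um + r + sp) / sp - or / sp) + 1, dm)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    cx <- or[1] + (ii - 0.5) * sp[1]
    cy <- or[2] + (jj - 0.5) * sp[2]
    cz <- or[3] + (kk - 0.5) * sp[3]
    d <- sqrt(outer(outer((cx - c_um[1])^2, (cy - c_um[2])^2, "+"),
                    (cz - c_um[3])^2, "+"))
    v <- pmin(pmax((r - d) / mean(sp) + 0.5, 0), 1)
    arr[ii, jj, kk] <- arr[ii, jj, kk] + v
  }
  arr
}

#' Binary mask of voxels covered by the scene's nuclei
#'
#' @param scene a [SyntheticScene-class].
#' @param geometry an [ImageVolume-class] (or anything with spacing, origin,
#'   dim) defining the target grid.
#' @param dilate_um extra margin added to each nuclear radius.
#' @return 3D 0/1 integer array on the target grid.
#' @export
nucleusMask <- function(scene, geometry, dilate_um = 0) {
  dm <- dim(geometry)
  sp <- spacing(geometry)
  or <- origin(geometry)
  arr <- array(0L, dm)
  nuc <- scene@nuclei
  for (i in seq_len(nrow(nuc))) {
    c_um <- as.numeric(nuc[i, c("x_um", "y_um", "z_um")])
    r <- nuc$radius_um[i] + dilate_um
    lo <- pmax(floor((c_um - r - or) / sp) + 1, 1)
    hi <- pmin(ceiling((c_um + r - or) / sp), dm)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    d <- sqrt(outer(outer((or[1] + (ii - 0.5) * sp[1] - c_um[1])^2,
                          (or[2] + (jj - 0.5) * sp[2] - c_um[2])^2, "+"),
                    (or[3] + (kk - 0.5) * sp[3] - c_um[3])^2, "+"))
    blk <- arr[ii, jj, kk]
    blk[d <= r] <- 1L
    arr[ii, jj, kk] <- blk
  }
  arr
}

#' Render image channels from a simulated scene
#'
#' Produces LSFM-like intensity volumes on an isotropic grid covering the
#' scene's atlas. Nuclei render as PSF-blurred antialiased spheres; the
#' "marker" channel images the same nuclei with an independent noise draw
#' (every S-phase nucleus is marker-positive); the autofluorescence channel
#' is a smooth anatomy-correlated field plus a bright one-voxel surface rim
#' artifact. Photon (Poisson) noise at `photon_scale`, Gaussian read noise,
#' and optional exponential depth attenuation complete the camera model.
#' With `space = "sample"` and a scene transform present, nuclei are moved
#' through the forward (atlas to sample) transform and the anatomy is pulled
#' back through the inverse, emulating the deformed as-imaged brain.
#'
#' @param scene a [SyntheticScene-class].
#' @param params a [RenderParams-class].
#' @param channels subset of c("edu", "marker", "autofluorescence").
#' @param seed integer seed for the noise draws.
#' @param space "atlas" (default) or "sample".
#' @return Named list of [ImageVolume-class] objects.
#' @export
renderChannels <- function(scene, params = RenderParams(),
                           channels = c("edu", "autofluorescence"),
                           seed = 1L, space = c("atlas", "sample")) {
  space <- match.arg(space)
  channels <- match.arg(channels, c("edu", "marker", "autofluorescence"),
                        several.ok = TRUE)
  atlas <- scene@atlas
  s <- rep_len(params@spacing_um, 3L)
  extent <- dim(atlas) * spacing(atlas)
  dm <- pmax(as.integer(floor(extent / s)), 1L)
  or <- origin(atlas)
  nuc <- scene@nuclei
  centers <- as.matrix(nuc[, c("x_um", "y_um", "z_um"), drop = FALSE])
  if (nrow(nuc) && any(2 * nuc$radius_um < min(s)))
    warning("some nuclei are smaller than one voxel at spacing ",
            min(s), " um; rendered anyway")
  chain <- scene@trueTransform
  if (space == "sample") {
    if (is.null(chain)) stop("scene has no transform; cannot render sample space")
    if (nrow(centers)) centers <- forwardTransformPoints(centers, chain)
  }
  # anatomy intensity: per-label pseudo-random base level, heavily smoothed
  anatomy_for <- function() {
    g <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])))
    x <- .voxel_centers(g, s, or)
    if (space == "sample" && !is.null(chain)) x <- .chain_sample_to_atlas(x, chain)
    iv <- pointToVoxel(x, atlas)
    lab <- rep(0L, nrow(g))
    ok <- !is.na(iv[, 1])
    lab[ok] <- atlas@labels[iv[ok, , drop = FALSE]]
    base <- ifelse(lab == 0, 0, 0.35 + 0.6 * ((lab * 2654435761) %% 97) / 96)
    arr <- array(base, dm)
    sm <- cpp_gaussian_blur(as.numeric(arr), dm, rep(2, 3))
    list(anatomy = array(sm, dm), brain = array(lab != 0L, dm))
  }
  psf_vox <- params@psf_sigma_um / s
  depth_mm <- array(rep((seq_len(dm[3]) - 0.5) * s[3] / 1000, each = dm[1] * dm[2]), dm)
  atten <- if (params@attenuation_per_mm > 0)
    exp(-params@attenuation_per_mm * depth_mm) else 1
  noise <- function(expected) {
    lam <- pmax(expected, 0)
    n <- length(lam)
    counts <- stats::rpois(n, lam) + stats::rnorm(n, 0, params@read_noise_sd)
    array(pmax(counts, 0), dm)
  }
  withSeed(seed, {
    out <- list()
    for (ch in channels) {
      if (ch %in% c("edu", "marker")) {
        sig <- .render_spheres(dm, s, or, centers, rep_len(nuc$radius_um, nrow(centers)))
        if (any(psf_vox > 0)) sig <- array(cpp_gaussian_blur(as.numeric(sig), dm, psf_vox), dm)
        expected <- params@photon_scale * sig * atten
      } else {
        an <- anatomy_for()
        rim <- an$brain & array(cpp_edt(as.integer(an$brain), dm, s) <= 1.5 * min(s), dm)
        expected <- (0.5 * params@photon_scale * an$anatomy +
                     params@surface_rim_amplitude * rim) * atten
      }
      vol <- if (params@photon_scale == 0 && params@read_noise_sd == 0 &&
                 (ch != "autofluorescence" || params@surface_rim_amplitude == 0))
        array(0, dm) else noise(expected)
      if (params@read_noise_sd == 0 && params@photon_scale == 0)
        vol <- array(pmax(expected, 0), dm)
      out[[ch]] <- ImageVolume(vol, spacing = s, origin = or)
    }
    out
  })
}

#' Render a noise-free channel (no camera model)
#'
#' Deterministic expected-signal rendering of the scene's nuclei (unit peak
#' intensity, optional PSF blur), for fixtures and oracle checks.
#'
#' @inheritParams renderChannels
#' @return An [ImageVolume-class].
#' @export
renderCleanEdu <- function(scene, params = RenderParams(), space = c("atlas", "sample")) {
  space <- match.arg(space)
  atlas <- scene@atlas
  s <- rep_len(params@spacing_um, 3L)
  dm <- pmax(as.integer(floor(dim(atlas) * spacing(atlas) / s)), 1L)
  or <- origin(atlas)
  centers <- as.matrix(scene@nuclei[, c("x_um", "y_um", "z_um"), drop = FALSE])
  if (space == "sample") {
    if (is.null(scene@trueTransform)) stop("scene has no transform")
    if (nrow(centers)) centers <- forwardTransformPoints(centers, scene@trueTransform)
  }
  sig <- .render_spheres(dm, s, or, centers,
                         rep_len(scene@nuclei$radius_um, nrow(centers)))
  if (params@psf_sigma_um > 0)
    sig <- array(cpp_gaussian_blur(as.numeric(sig), dm, params@psf_sigma_um / s), dm)
  ImageVolume(sig, spacing = s, origin = or)
}

#' Inject single-voxel speckle noise
#'
#' Adds `n_speckles` bright single-voxel impulses at positions drawn
#' uniformly from voxels that are free of true nuclei (and, optionally,
#' inside a support mask), returning the positions as ground truth.
#'
#' @param volume an [ImageVolume-class].
#' @param n_speckles number of speckles (>= 0).
#' @param amplitude intensity added at each speckle voxel.
#' @param seed integer seed.
#' @param exclude_mask optional 0/1 array marking voxels that must stay
#'   speckle-free (e.g. [nucleusMask()] of the true scene).
#' @param within_mask optional 0/1 array restricting candidate voxels.
#' @return list(volume = speckled [ImageVolume-class], indices = n x 3
#'   integer matrix of 1-based voxel indices).
#' @export
injectSpeckle <- function(volume, n_speckles, amplitude, seed = 1L,
                          exclude_mask = NULL, within_mask = NULL) {
  if (n_speckles < 0) stop("'n_speckles' must be >= 0")
  dm <- dim(volume@data)
  free <- rep(TRUE, prod(dm))
  if (!is.null(exclude_mask)) free <- free & (as.integer(exclude_mask) == 0L)
  if (!is.null(within_mask)) free <- free & (as.integer(within_mask) != 0L)
  cand <- which(free)
  if (n_speckles == 0L)
    return(list(volume = volume,
                indices = matrix(integer(0), 0, 3,
                                 dimnames = list(NULL, c("i", "j", "k")))))
  if (length(cand) < n_speckles)
    stop("not enough free voxels for ", n_speckles, " speckles")
  pick <- withSeed(seed, sample(cand, n_speckles))
  dat <- volume@data
  dat[pick] <- dat[pick] + amplitude
  idx <- arrayInd(pick, dm)
  colnames(idx) <- c("i", "j", "k")
  list(volume = initialize(volume, data = dat), indices = idx)
}

#' Synthesize a known atlas-to-sample transform chain
#'
#' Builds a ground-truth [TransformChain-class]: an affine (rotation, scale,
#' translation about the atlas centre) plus a smooth nonlinear field made of
#' Gaussian-filtered noise with a prescribed maximum displacement. The
#' stored field is the *inverse* warp on the atlas grid that the
#' normalization stage applies directly; the forward (atlas to sample) map
#' is recovered by fixed-point iteration in [forwardTransformPoints()], so
#' forward-then-normalize round-trips by construction. Parameters outside
#' the practical invertibility envelope (|rotation| <= 20 deg, scale in
#' [0.8, 1.25], warp <= 5 voxels) are refused.
#'
#' @param atlas a [LabelAtlas-class] supplying the field grid.
#' @param rotation_deg numeric(3) Euler angles (deg).
#' @param scale numeric(3) per-axis scale factors.
#' @param translation_um numeric(3), um.
#' @param warp_amplitude_um maximum displacement magnitude of the field (um).
#' @param warp_smoothness_um Gaussian smoothing scale of the field (um).
#' @param seed integer seed for the field noise.
#' @return A [TransformChain-class] (affine "atlas->sample" + inverse field).
#' @export
makeGroundTruthTransform <- function(atlas, rotation_deg = c(0, 0, 0),
                                     scale = c(1, 1, 1),
                                     translation_um = c(0, 0, 0),
                                     warp_amplitude_um = 0,
                                     warp_smoothness_um = 100,
                                     seed = 1L) {
  rotation_deg <- rep_len(rotation_deg, 3L)
  scale <- rep_len(scale, 3L)
  translation_um <- rep_len(translation_um, 3L)
  if (any(abs(rotation_deg) > 20)) stop("|rotation| must be <= 20 deg")
  if (any(scale < 0.8 | scale > 1.25)) stop("scale must lie in [0.8, 1.25]")
  if (warp_amplitude_um > 5 * min(spacing(atlas)))
    stop("warp amplitude above 5 voxels breaks practical invertibility")
  ctr <- origin(atlas) + dim(atlas) * spacing(atlas) / 2
  M <- .compose_linear(rotation_deg, scale, c(0, 0, 0))
  affine <- AffineTransform(M, ctr - as.vector(M %*% ctr) + translation_um,
                            direction = "atlas->sample")
  field <- NULL
  if (warp_amplitude_um > 0) {
    dm <- dim(atlas)
    sig <- warp_smoothness_um / spacing(atlas)
    disp <- withSeed(seed, {
      d <- array(0, c(dm, 3L))
      for (k in 1:3) {
        w <- array(stats::rnorm(prod(dm)), dm)
        d[, , , k] <- array(cpp_gaussian_blur(as.numeric(w), as.integer(dm), sig), dm)
      }
      d
    })
    mx <- max(sqrt(disp[, , , 1]^2 + disp[, , , 2]^2 + disp[, , , 3]^2))
    disp <- disp * (warp_amplitude_um / mx)
    field <- DeformationField(disp, spacing = spacing(atlas), origin = origin(atlas))
  }
  TransformChain(affine, field)
}
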