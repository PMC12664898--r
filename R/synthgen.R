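#' @include transform.R
NULL

#' Simulated ground-truth scene
#'
#' A fully known scene in atlas space: nuclear centres with cluster
#' membership, injected single-voxel speckle positions, the per-region
#' density targets, the seed that fixes everything, and (optionally) the
#' known transform between atlas and sample space.
#'
#' @slot nuclei data.frame: `x_um`, `y_um`, `z_um`, `cluster_id`,
#'   `region_id`, `radius_um`.
#' @slot speckles data.frame of 1-based voxel indices (`i`, `j`, `k`) on the
#'   rendered grid, empty until speckles are injected.
#' @slot regionDensities named numeric, nuclei per mm^3 by region ID.
#' @slot atlas the [LabelAtlas-class] the scene lives in.
#' @slot trueTransform a [TransformChain-class] or NULL.
#' @slot seed integer seed that reproduces the scene.
#' @export
setClass("SyntheticScene",
  representation(nuclei = "data.frame", speckles = "data.frame",
                 regionDensities = "numeric", atlas = "LabelAtlas",
                 trueTransform = "ANY", seed = "integer"),
  validity = function(object) {
    msg <- character()
    nuc <- object@nuclei
    need <- c("x_um", "y_um", "z_um", "cluster_id", "region_id", "radius_um")
    if (!all(need %in% names(nuc))) return("missing nuclei columns")
    if (nrow(nuc)) {
      if (any(nuc$radius_um <= 0)) msg <- c(msg, "radii must be > 0")
      idx <- pointToVoxel(as.matrix(nuc[, c("x_um", "y_um", "z_um")]), object@atlas)
      if (anyNA(idx)) msg <- c(msg, "nucleus centres must lie inside the atlas grid")
      else if (any(object@atlas@labels[idx] == 0))
        msg <- c(msg, "nucleus centres must lie inside nonzero-label voxels")
      for (cl in unique(nuc$cluster_id)) {
        m <- nuc[nuc$cluster_id == cl, c("x_um", "y_um", "z_um")]
        if (nrow(m) > 1 && max(stats::dist(m)) > 3 * max(nuc$radius_um) + 1e-6) {
          msg <- c(msg, "cluster members must be within 3 radii of each other")
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Rendering parameters for simulated channels
#'
#' @slot spacing_um voxel spacing of the rendered grid (isotropic, um).
#' @slot psf_sigma_um isotropic Gaussian PSF standard deviation (um).
#' @slot photon_scale expected photon count at unit normalized intensity;
#'   the Poisson component of the camera model.
#' @slot read_noise_sd Gaussian read-noise standard deviation (photons).
#' @slot surface_rim_amplitude brightness of the surface-rim artifact added
#'   to the autofluorescence channel (photons).
#' @slot attenuation_per_mm exponential signal attenuation with depth.
#' @export
setClass("RenderParams",
  representation(spacing_um = "numeric", psf_sigma_um = "numeric",
                 photon_scale = "numeric", read_noise_sd = "numeric",
                 surface_rim_amplitude = "numeric", attenuation_per_mm = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@spacing_um <= 0) msg <- c(msg, "spacing must be > 0")
    if (object@psf_sigma_um < 0) msg <- c(msg, "psf_sigma must be >= 0")
    if (object@photon_scale < 0 || object@read_noise_sd < 0 ||
        object@surface_rim_amplitude < 0 || object@attenuation_per_mm < 0)
      msg <- c(msg, "amplitudes must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Construct RenderParams
#'
#' Defaults reflect the working acquisition setting: 3.65-um isotropic
#' voxels, a 1.5-um PSF, and modest Poisson-Gaussian camera noise.
#'
#' @param spacing_um,psf_sigma_um,photon_scale,read_noise_sd,surface_rim_amplitude,attenuation_per_mm
#'   see [RenderParams-class].
#' @return A [RenderParams-class] object.
#' @export
RenderParams <- function(spacing_um = 3.65, psf_sigma_um = 1.5,
                         photon_scale = 80, read_noise_sd = 2,
                         surface_rim_amplitude = 20, attenuation_per_mm = 0) {
  new("RenderParams", spacing_um = spacing_um, psf_sigma_um = psf_sigma_um,
      photon_scale = photon_scale, read_noise_sd = read_noise_sd,
      surface_rim_amplitude = surface_rim_amplitude,
      attenuation_per_mm = attenuation_per_mm)
}

#' Build a toy bilaterally symmetric label atlas
#'
#' Generates a small stand-in for a reference brain atlas: an ellipsoidal
#' "brain" partitioned into top-level regions each split into two leaf
#' regions, with a central "ventricle" region and an adjacent
#' "caudoputamen-like" shell so that ventricular-zone annotation is
#' exercisable. The grid is mirror-symmetric about the midline of the
#' designated axis, and the ontology is an Allen-style tree (root, top
#' level, leaves) whose IDs avoid the reserved custom-annotation ID.
#'
#' @param spacing_um isotropic voxel spacing (10, 25 or 50 recommended).
#' @param shape integer triple of grid dimensions, each >= 20.
#' @param n_regions number of top-level regions (>= 3; the first two are the
#'   ventricle and the caudoputamen-like region).
#' @param seed integer seed fixing the random region partition.
#' @param midline_axis axis (1:3) carrying the left/right symmetry.
#' @param custom_id reserved ID that must not collide with generated IDs.
#' @return A [LabelAtlas-class].
#' @export
buildToyAtlas <- function(spacing_um, shape, n_regions = 6L, seed = 1L,
                          midline_axis = 3L, custom_id = 5L) {
  shape <- rep_len(as.integer(shape), 3L)
  if (any(shape < 20L)) stop("shape must be at least 20 voxels per axis")
  if (n_regions < 3L) stop("need at least 3 top-level regions")
  top_ids <- 100L * seq_len(n_regions)
  leaf_ids <- c(rbind(top_ids + 1L, top_ids + 2L))
  root_id <- 997L
  all_ids <- c(root_id, top_ids, leaf_ids)
  if (custom_id %in% all_ids)
    stop("reserved custom ID ", custom_id, " collides with a generated ID")

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  ax <- midline_axis
  ctr <- (shape + 1) / 2
  g <- as.matrix(expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz)))
  # normalized coordinates in [-1, 1]
  u <- sweep(sweep(g, 2L, ctr, "-"), 2L, (shape - 1) / 2, "/")
  brain <- rowSums(u^2 / c(0.9, 0.8, 0.85)^2) <= 1
  # fold the midline axis so construction is symmetric by design
  uf <- u
  uf[, ax] <- abs(u[, ax])
  # ventricle: small ellipsoid within each hemisphere
  vent_ctr <- c(0, 0, 0); vent_ctr[ax] <- 0.35
  dv <- sweep(uf, 2L, vent_ctr, "-")
  vent <- brain & rowSums(dv^2 / c(0.18, 0.30, 0.12)^2) <= 1
  # caudoputamen-like shell around the ventricle
  cp <- brain & !vent & rowSums(dv^2 / (c(0.18, 0.30, 0.12) * 2.2)^2) <= 1

  labels <- integer(nrow(g))
  labels[vent] <- 101L
  labels[cp] <- 201L
  rest <- which(brain & labels == 0L)
  n_other <- n_regions - 2L
  seeds <- withSeed(seed, {
    s <- matrix(stats::runif(3 * n_other), ncol = 3L) * 2 - 1
    s[, ax] <- abs(s[, ax])
    s
  })
  if (length(rest)) {
    d2 <- vapply(seq_len(n_other), function(r)
      rowSums(sweep(uf[rest, , drop = FALSE], 2L, seeds[r, ], "-")^2),
      numeric(length(rest)))
    labels[rest] <- top_ids[2L + max.col(-d2)] + 1L
  }
  # split each top region into its two leaves by the first non-midline axis
  split_ax <- setdiff(1:3, ax)[1]
  for (tid in top_ids) {
    inr <- which(labels == tid + 1L)
    if (!length(inr)) next
    cut <- stats::median(u[inr, split_ax])
    labels[inr[u[inr, split_ax] > cut]] <- tid + 2L
  }
  arr <- array(labels, shape)
  # mirror one half onto the other for exact symmetry
  half <- seq_len(floor(shape[ax] / 2))
  mirr <- shape[ax] + 1L - half
  idx_src <- idx_dst <- list(seq_len(nx), seq_len(ny), seq_len(nz))
  idx_src[[ax]] <- mirr; idx_dst[[ax]] <- half
  arr <- do.call("[<-", c(list(arr), idx_dst,
                          list(do.call("[", c(list(arr), idx_src)))))
  onto <- data.frame(
    id = all_ids,
    acronym = c("root", paste0("R", seq_len(n_regions)),
                paste0("R", rep(seq_len(n_regions), each = 2), letters[1:2])),
    name = c("root", "ventricles", "caudoputamen-like",
             paste("region", seq_len(n_regions)[-(1:2)]),
             paste("leaf", leaf_ids)),
    parent_structure_id = c(NA_integer_, rep(root_id, n_regions),
                            rep(top_ids, each = 2)),
    stringsAsFactors = FALSE)
  LabelAtlas(arr, spacing = spacing_um, ontology = onto,
             customID = custom_id, midlineAxis = as.integer(ax))
}

# Regular simplex vertex coordinates (unit edge) for cluster geometry.
.simplex_vertices <- function(m) {
  v <- switch(m,
    matrix(0, 1, 3),
    rbind(c(-0.5, 0, 0), c(0.5, 0, 0)),
    rbind(c(0, sqrt(3) / 3, 0), c(-0.5, -sqrt(3) / 6, 0), c(0.5, -sqrt(3) / 6, 0)),
    rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(8))
  sweep(v, 2L, colMeans(v), "-")
}

.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3)
}

#' Sample clustered nuclei into an atlas
#'
#' Draws ground-truth nuclear centres region by region. The nucleus count
#' per region is Poisson with mean density x region volume; nuclei are
#' organized into clusters of 1-4 whose sizes follow `cluster_mix`. A
#' cluster is laid out as a randomly rotated regular simplex with edge
#' length 1.0-1.5 nuclear diameters, so every pair of members is that far
#' apart (touching to nearly touching). All centres land in nonzero-label
#' voxels; regions too crowded for rejection sampling raise an error naming
#' the region.
#'
#' @param atlas a [LabelAtlas-class].
#' @param region_densities named numeric, nuclei per mm^3 keyed by leaf
#'   region ID.
#' @param cluster_mix probabilities of cluster sizes 1-4 (normalized
#'   internally).
#' @param seed integer seed.
#' @param radius_um nuclear radius (default 5, a 10-um nucleus).
#' @return A [SyntheticScene-class] (speckles empty, transform NULL).
#' @export
sampleNuclei <- function(atlas, region_densities,
                         cluster_mix = c(0.25, 0.25, 0.25, 0.25),
                         seed = 1L, radius_um = 5) {
  if (any(region_densities < 0)) stop("densities must be >= 0")
  cluster_mix <- rep_len(cluster_mix, 4L)
  cluster_mix <- cluster_mix / sum(cluster_mix)
  sp <- spacing(atlas)
  vox_mm3 <- prod(sp) * 1e-9
  lab <- atlas@labels
  nuc <- withSeed(seed, {
    rows <- list()
    cl_id <- 0L
    for (rid in names(region_densities)) {
      dens <- region_densities[[rid]]
      if (dens <= 0) next
      vox <- which(lab == as.integer(rid))
      if (!length(vox))
        stop("region ", rid, " has no voxels in the atlas")
      lambda <- dens * length(vox) * vox_mm3
      n_target <- stats::rpois(1L, lambda)
      if (n_target == 0L) next
      sizes <- integer(0)
      while (sum(sizes) < n_target)
        sizes <- c(sizes, sample.int(4L, 1L, prob = cluster_mix))
      sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n_target)
      sizes <- sizes[sizes > 0L]
      vidx <- arrayInd(vox, dim(lab))
      for (m in sizes) {
        placed <- NULL
        for (try in seq_len(500L)) {
          a <- sample.int(nrow(vidx), 1L)
          anchor <- origin(atlas) + (vidx[a, ] - 1 + stats::runif(3)) * sp
          edge <- stats::runif(1, 1.0, 1.5) * 2 * radius_um
          pts <- sweep(.simplex_vertices(m) %*% t(.random_rotation()) * edge,
                       2L, anchor, "+")
          iv <- pointToVoxel(pts, atlas)
          if (anyNA(iv) || any(lab[iv] == 0)) next
          # hard-core constraint: nuclei are solid, so members of different
          # clusters must not interpenetrate
          if (length(rows)) {
            prev <- do.call(rbind, lapply(rows, function(r)
              cbind(r$x_um, r$y_um, r$z_um)))
            d2 <- outer(rowSums(pts^2), rowSums(prev^2), "+") -
              2 * pts %*% t(prev)
            if (min(d2) < (2 * radius_um)^2) next
          }
          placed <- pts
          break
        }
        if (is.null(placed))
          stop("rejection sampling failed in region ", rid,
               ": density too high or region too thin")
        cl_id <- cl_id + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          x_um = placed[, 1], y_um = placed[, 2], z_um = placed[, 3],
          cluster_id = cl_id, region_id = as.integer(rid),
          radius_um = radius_um)
      }
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                    cluster_id = integer(0), region_id = integer(0),
                    radius_um = numeric(0))
  })
  new("SyntheticScene", nuclei = nuc,
      speckles = data.frame(i = integer(0), j = integer(0), k = integer(0)),
      regionDensities = unlist(region_densities), atlas = atlas,
      trueTransform = NULL, seed = as.integer(seed))
}
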