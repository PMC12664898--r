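#' @include volume.R
NULL

# Greedy one-to-one matching on ascending distance with strict threshold.
# Ties broken by (indexA, indexB). Returns data.frame(indexA, indexB,
# distance_um).
.greedy_match <- function(A, B, threshold, strict = TRUE) {
  empty <- data.frame(indexA = integer(0), indexB = integer(0),
                      distance_um = numeric(0))
  if (!nrow(A) || !nrow(B)) return(empty)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  keep <- if (strict) which(d < threshold) else which(d <= threshold)
  if (!length(keep)) return(empty)
  ia <- ((keep - 1) %% nrow(A)) + 1
  ib <- ((keep - 1) %/% nrow(A)) + 1
  ord <- order(d[keep], ia, ib)
  usedA <- logical(nrow(A)); usedB <- logical(nrow(B))
  out <- vector("list", length(ord))
  n <- 0L
  for (t in ord) {
    a <- ia[t]; b <- ib[t]
    if (usedA[a] || usedB[b]) next
    usedA[a] <- TRUE; usedB[b] <- TRUE
    n <- n + 1L
    out[[n]] <- c(a, b, d[keep[t]])
  }
  if (!n) return(empty)
  m <- do.call(rbind, out[seq_len(n)])
  data.frame(indexA = as.integer(m[, 1]), indexB = as.integer(m[, 2]),
             distance_um = m[, 3])
}

#' Label 3D connected components
#'
#' @param mask an [ImageVolume-class] with 0/1 data, or a 3D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return 3D integer array of component labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  arr <- if (is(mask, "ImageVolume")) mask@data else mask
  if (!connectivity %in% c(6L, 18L, 26L)) stop("connectivity must be 6, 18 or 26")
  lab <- cpp_label3d(as.integer(arr != 0), .as_dim(arr), as.integer(connectivity))
  array(lab, dim(arr))
}

# Multi-scale voxel features: raw intensity plus Gaussian, gradient
# magnitude and Laplacian at each scale. Returns a matrix n_vox x n_feat.
.voxel_features <- function(volume, feature_spec) {
  dat <- volume@data
  dm <- .as_dim(dat)
  sp <- spacing(volume)
  feats <- list(raw = as.numeric(dat))
  grad_lap <- function(g) {
    gx <- (g[c(2:dm[1], dm[1]), , , drop = FALSE] -
           g[c(1, 1:(dm[1] - 1)), , , drop = FALSE]) / (2 * sp[1])
    gy <- (g[, c(2:dm[2], dm[2]), , drop = FALSE] -
           g[, c(1, 1:(dm[2] - 1)), , drop = FALSE]) / (2 * sp[2])
    gz <- (g[, , c(2:dm[3], dm[3]), drop = FALSE] -
           g[, , c(1, 1:(dm[3] - 1)), drop = FALSE]) / (2 * sp[3])
    lap <- (g[c(2:dm[1], dm[1]), , , drop = FALSE] +
            g[c(1, 1:(dm[1] - 1)), , , drop = FALSE] - 2 * g) / sp[1]^2 +
           (g[, c(2:dm[2], dm[2]), , drop = FALSE] +
            g[, c(1, 1:(dm[2] - 1)), , drop = FALSE] - 2 * g) / sp[2]^2 +
           (g[, , c(2:dm[3], dm[3]), drop = FALSE] +
            g[, , c(1, 1:(dm[3] - 1)), drop = FALSE] - 2 * g) / sp[3]^2
    list(grad = sqrt(gx^2 + gy^2 + gz^2), lap = lap)
  }
  for (r in seq_len(nrow(feature_spec))) {
    sg <- feature_spec$sigma_um[r]
    g <- array(cpp_gaussian_blur(as.numeric(dat), dm, sg / sp), dm)
    gl <- grad_lap(g)
    feats[[paste0("gauss_", r)]] <- as.numeric(g)
    feats[[paste0("grad_", r)]] <- as.numeric(gl$grad)
    feats[[paste0("lap_", r)]] <- as.numeric(gl$lap)
  }
  do.call(cbind, feats)
}

# Default Labkit-like feature scales relative to voxel spacing.
.default_feature_spec <- function(spacing_um) {
  data.frame(feature = "multiscale",
             sigma_um = c(0.7, 1.6, 3.5) * mean(spacing_um))
}

#' Train a random-forest pixel classifier
#'
#' Learns to separate nucleus ("foreground") voxels from noise
#' ("background") voxels from sparse manual annotations, using multi-scale
#' features (raw intensity plus Gaussian smoothing, gradient magnitude and
#' Laplacian at three scales tied to the voxel spacing).
#'
#' @param volumes an [ImageVolume-class] or list of them.
#' @param labels for each volume, a data.frame with columns `i`, `j`, `k`
#'   (1-based voxel indices) and `class` ("foreground"/"background"); a
#'   single data.frame if `volumes` is a single volume.
#' @param feature_spec data.frame(feature, sigma_um); default three scales
#'   at 0.7, 1.6 and 3.5 x the voxel spacing.
#' @param seed integer seed; training is deterministic given it.
#' @param num_trees,max_depth forest size (defaults 100 trees, unlimited
#'   depth).
#' @return A [PixelClassifierModel-class].
#' @export
trainPixelClassifier <- function(volumes, labels, feature_spec = NULL,
                                 seed = 1L, num_trees = 100L, max_depth = 0L) {
  if (is(volumes, "ImageVolume")) {
    volumes <- list(volumes)
    labels <- list(labels)
  }
  if (is.null(feature_spec))
    feature_spec <- .default_feature_spec(spacing(volumes[[1]]))
  X <- NULL; y <- character(0)
  for (v in seq_along(volumes)) {
    lb <- labels[[v]]
    f <- .voxel_features(volumes[[v]], feature_spec)
    lin <- .linear_index(as.matrix(lb[, c("i", "j", "k")]), dim(volumes[[v]]@data))
    X <- rbind(X, f[lin, , drop = FALSE])
    y <- c(y, as.character(lb$class))
  }
  if (length(unique(y)) < 2L)
    stop("training labels must contain both foreground and background")
  df <- data.frame(X)
  df$.class <- factor(y, levels = c("background", "foreground"))
  forest <- withSeed(seed,
    ranger::ranger(dependent.variable.name = ".class", data = df,
                   num.trees = num_trees, max.depth = max_depth,
                   num.threads = 1L, seed = as.integer(seed)))
  new("PixelClassifierModel", forest = forest, featureSpec = feature_spec,
      threshold = NA_real_, trainSeed = as.integer(seed),
      provenance = list(mode = "random_forest",
                        n_foreground = sum(y == "foreground"),
                        n_background = sum(y == "background"),
                        num_trees = num_trees, max_depth = max_depth))
}

#' Threshold "classifier" fallback
#'
#' A pure intensity threshold packaged as a classifier model and flagged as
#' such in provenance; `threshold = "otsu"` picks the threshold by Otsu's
#' method on the volume histogram at classification time.
#'
#' @param threshold numeric cut (voxels with intensity >= threshold are
#'   foreground), or "otsu".
#' @return A [PixelClassifierModel-class] in threshold mode.
#' @export
thresholdClassifier <- function(threshold = "otsu") {
  new("PixelClassifierModel", forest = NULL,
      featureSpec = data.frame(feature = "raw", sigma_um = 0),
      threshold = if (identical(threshold, "otsu")) NA_real_
                  else as.numeric(threshold),
      trainSeed = NA_integer_,
      provenance = list(mode = "threshold",
                        otsu = identical(threshold, "otsu")))
}

.otsu <- function(x, nbins = 256L) {
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1] + 1e-9)
  h <- tabulate(pmin(as.integer((x - rng[1]) / diff(rng) * nbins) + 1L, nbins),
                nbins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nbins))
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  k <- which.max(sb)
  rng[1] + k / nbins * diff(rng)
}

#' Classify voxels into signal and background
#'
#' Applies a trained [PixelClassifierModel-class] (or its threshold
#' fallback) to a volume, producing a binary mask on the same grid.
#'
#' @param model a [PixelClassifierModel-class].
#' @param volume an [ImageVolume-class].
#' @return An [ImageVolume-class] whose data is 0/1.
#' @export
classifyVoxels <- function(model, volume) {
  if (model@provenance$mode == "threshold") {
    thr <- if (is.na(model@threshold)) .otsu(as.numeric(volume@data))
           else model@threshold
    mask <- volume@data >= thr
  } else {
    f <- .voxel_features(volume, model@featureSpec)
    if (ncol(f) != model@forest$num.independent.variables)
      stop("feature spec does not match the trained model")
    pred <- stats::predict(model@forest, data = data.frame(f),
                           num.threads = 1L)$predictions
    mask <- array(pred == "foreground", dim(volume@data))
  }
  initialize(volume, data = array(as.numeric(mask), dim(volume@data)))
}

#' Detect nuclei from a binary mask
#'
#' Connected components of the signal mask are filtered by the three-voxel
#' noise rule (components smaller than `min_voxels` are discarded; at the
#' working resolution a real nucleus always spans three or more adjacent
#' voxels while single-voxel speckle does not). Components consistent with
#' more than one nucleus are then split by marker-controlled watershed on
#' the Euclidean distance transform. Because the working resolution leaves
#' a touching pair only ~3 voxels apart, the default splitter refines to
#' sub-voxel precision: the denoised intensity is trilinearly upsampled
#' (`upsample` x), each component is re-thresholded at half its peak
#' intensity (the full-width-half-maximum surface of a blurred sphere),
#' and the cores `EDT >= seed_frac x per-component EDT max` become the
#' watershed markers. `method = "hmaxima"` instead seeds with classical
#' h-maxima of the native-resolution EDT (h = `h_frac` x expected radius),
#' which is adequate when nuclei span many voxels. Each instance
#' contributes one intensity-weighted centroid in physical um.
#'
#' @param mask binary [ImageVolume-class] (from [classifyVoxels()]).
#' @param intensity matching [ImageVolume-class]; required for the
#'   sub-voxel splitter and used for centroid weights. NULL falls back to
#'   unweighted centroids and h-maxima splitting.
#' @param min_voxels minimum component size in voxels (default 3).
#' @param connectivity 6, 18 or 26 (default 26).
#' @param split split multi-nucleus components (default TRUE).
#' @param method "subvoxel" (default) or "hmaxima".
#' @param expected_radius_um expected nuclear radius (default 5 um).
#' @param upsample integer sub-voxel refinement factor (default 3).
#' @param interior_frac per-component re-threshold as a fraction of the
#'   component's peak intensity (default 0.5, the FWHM surface).
#' @param seed_frac EDT core level as a fraction of the per-component EDT
#'   maximum (default 0.8).
#' @param denoise_sigma_um Gaussian denoising before upsampling (default 1).
#' @param h_frac h-maxima depth for `method = "hmaxima"` (default 0.3).
#' @param weighted intensity-weighted centroids (default TRUE).
#' @param space space tag for the resulting points (default "sample").
#' @param channel channel tag.
#' @return A [NucleusSet-class]; `componentSizes()` records the size of the
#'   parent connected component each centre came from.
#' @export
detectNuclei <- function(mask, intensity = NULL, min_voxels = 3L,
                         connectivity = 26L, split = TRUE,
                         method = c("subvoxel", "hmaxima"),
                         expected_radius_um = 5, upsample = 3L,
                         interior_frac = 0.5, seed_frac = 0.8,
                         denoise_sigma_um = 1, h_frac = 0.3,
                         weighted = TRUE, space = "sample", channel = "edu") {
  method <- match.arg(method)
  if (is.null(intensity)) method <- "hmaxima"
  dm <- .as_dim(mask@data)
  sp <- spacing(mask)
  conn <- as.integer(connectivity)
  m <- as.integer(mask@data != 0)
  comp <- cpp_label3d(m, dm, conn)
  n_comp <- max(comp)
  empty <- NucleusSet(matrix(numeric(0), 0, 3), space = space, channel = channel)
  if (n_comp == 0L) return(empty)
  sizes <- tabulate(comp, n_comp)
  keep <- sizes >= min_voxels
  if (!any(keep)) return(empty)
  comp[!keep[pmax(comp, 1L)]] <- 0L
  m_ret <- as.integer(comp > 0L)

  finish <- function(centers, parents) {
    NucleusSet(centers, space = space, channel = channel,
               componentSize = as.integer(sizes[parents]))
  }
  centroids_of <- function(inst, vox_idx, w, centers_um) {
    grp <- factor(inst)
    wsum <- tapply(w, grp, sum)
    cbind(tapply(w * centers_um[, 1], grp, sum) / wsum,
          tapply(w * centers_um[, 2], grp, sum) / wsum,
          tapply(w * centers_um[, 3], grp, sum) / wsum)
  }

  if (split && method == "subvoxel") {
    f <- as.integer(upsample)
    dmf <- dm * f
    spf <- sp / f
    S <- if (denoise_sigma_um > 0)
      cpp_gaussian_blur(as.numeric(intensity@data), dm, denoise_sigma_um / sp)
    else as.numeric(intensity@data)
    Sf <- cpp_upsample(S, dm, f)
    compf <- cpp_upsample_int(comp, dm, f)
    # single-nucleus brightness calibrated on the smaller half of the
    # components (overlapping PSFs raise peaks inside fused blobs, so the
    # component's own maximum is not a safe reference there)
    peak <- cpp_group_max(Sf, compf, n_comp)
    kept_sizes <- sizes[keep]
    small <- which(keep & sizes <= stats::quantile(kept_sizes, 0.5))
    peak1 <- stats::median(peak[small])
    ithr <- pmin(interior_frac * peak1, 0.8 * peak)
    interior <- as.integer(compf > 0L & Sf >= ithr[pmax(compf, 1L)])
    edtf <- cpp_edt(interior, dmf, spf)
    core_lvl <- cpp_group_max(edtf * (interior == 1L), compf, n_comp)
    r1 <- stats::median(core_lvl[small])
    lvl <- seed_frac * pmin(core_lvl, r1)
    cores <- as.integer(interior == 1L & edtf >= lvl[pmax(compf, 1L)])
    mlE <- cpp_label3d(cores, dmf, conn)
    selE <- which(mlE > 0L)
    cntE <- rep(0L, n_comp)
    tabE <- tapply(mlE[selE], compf[selE], function(x) length(unique(x)))
    cntE[as.integer(names(tabE))] <- as.integer(tabE)
    # intensity h-maxima islands resolve tight simplex clusters whose
    # interior erodes to a single central core
    h <- 0.12 * peak1
    Sm <- ifelse(interior == 1L, Sf, 0)
    recon <- cpp_reconstruct(pmax(Sm - h, 0), Sm, dmf, conn)
    mlI <- cpp_label3d(cpp_regional_maxima(recon, interior, dmf, conn), dmf, conn)
    selI <- which(mlI > 0L)
    cntI <- rep(0L, n_comp)
    tabI <- tapply(mlI[selI], compf[selI], function(x) length(unique(x)))
    cntI[as.integer(names(tabI))] <- as.integer(tabI)
    # interior-volume bound: how many single-nucleus interiors fit
    iv_tab <- tapply(rep(prod(spf), sum(interior == 1L)),
                     compf[interior == 1L], sum)
    intvol <- rep(0, n_comp)
    intvol[as.integer(names(iv_tab))] <- as.numeric(iv_tab)
    v1_pool <- intvol[cntE == 1L & intvol > 0]
    V1 <- if (length(v1_pool)) stats::median(v1_pool) else 4 / 3 * pi * expected_radius_um^3
    volcap <- pmax(floor(intvol / V1 + 0.2), 1L)
    target <- pmax(cntE, pmin(cntI, volcap))
    # markers: EDT cores where they meet the target, otherwise the
    # brightest `target` intensity islands of the component
    use_int <- which(keep & target > cntE & cntI > 0L)
    marker <- integer(length(mlE))
    marker[selE] <- ifelse(compf[selE] %in% use_int, 0L, mlE[selE])
    if (length(use_int)) {
      isl_comp <- tapply(compf[selI], mlI[selI], function(v) v[1])
      isl_peak <- tapply(Sm[selI], mlI[selI], max)
      chosen <- unlist(lapply(use_int, function(cmp) {
        isl <- as.integer(names(isl_comp))[isl_comp == cmp]
        isl[order(isl_peak[as.character(isl)], decreasing = TRUE)][seq_len(min(target[cmp], length(isl)))]
      }))
      off <- max(mlE)
      keep_isl <- mlI[selI] %in% chosen
      marker[selI[keep_isl]] <- mlI[selI[keep_isl]] + off
    }
    inst <- cpp_watershed(edtf, marker, interior, dmf, conn)
    vox <- which(inst > 0L)
    covered <- unique(compf[vox])
    orphans <- setdiff(which(keep), covered)
    w <- pmax(Sf[vox], 1e-12)
    centers_um <- .voxel_centers(arrayInd(vox, dmf), spf, origin(mask))
    inst_id <- inst[vox]
    cen <- centroids_of(inst_id, vox, w, centers_um)
    parents <- tapply(compf[vox], factor(inst_id), function(v) v[1])
    if (length(orphans)) {
      # components whose interior vanished entirely keep one instance each
      ovox <- which(comp %in% orphans)
      ow <- pmax(intensity@data[ovox], 1e-12)
      ocen <- centroids_of(comp[ovox], ovox, ow,
                           .voxel_centers(arrayInd(ovox, dm), sp, origin(mask)))
      cen <- rbind(cen, ocen)
      parents <- c(parents, sort(orphans))
    }
    return(finish(cen, parents))
  }

  if (split) {
    edt <- cpp_edt(m_ret, dm, sp)
    h <- h_frac * expected_radius_um
    recon <- cpp_reconstruct(pmax(edt - h, 0), edt, dm, conn)
    seeds <- cpp_regional_maxima(recon, m_ret, dm, conn)
    marker <- cpp_label3d(seeds, dm, conn)
    inst <- cpp_watershed(edt, marker, m_ret, dm, conn)
    orphan <- m_ret == 1L & inst == 0L
    if (any(orphan)) inst[orphan] <- max(inst) + comp[orphan]
  } else {
    inst <- comp
  }
  vox <- which(inst > 0L)
  inst_id <- inst[vox]
  w <- if (weighted && !is.null(intensity)) pmax(intensity@data[vox], 1e-12)
       else rep(1, length(vox))
  centers_um <- .voxel_centers(arrayInd(vox, dm), sp, origin(mask))
  cen <- centroids_of(inst_id, vox, w, centers_um)
  parents <- tapply(comp[vox], factor(inst_id), function(v) v[1])
  finish(cen, parents)
}

#' Validate detection against a simulated ground truth
#'
#' Two accuracies mirroring the two separate validations of the workflow.
#' Signal/noise accuracy asks whether each ground-truth object was given
#' the right class by classification plus component filtering: a nucleus is
#' correctly "signal" when any predicted centre lies within one nuclear
#' diameter of it (members of an under-split cluster still count — they
#' were classified signal, merely not counted apart), and a speckle is
#' correctly "noise" when no predicted centre lies within half a diameter
#' of it. Count accuracy asks whether nuclei were counted apart correctly:
#' predicted centres are matched one-to-one to true centres by ascending
#' distance within one diameter, and a cluster is correct when its
#' matched-prediction count equals its true member count.
#'
#' @param predicted a [NucleusSet-class].
#' @param truth a [SyntheticScene-class] in the same coordinate space.
#' @param geometry the rendered [ImageVolume-class] (needed to place
#'   speckle voxel indices in um); NULL skips speckles.
#' @return A [ValidationReport-class].
#' @export
validateDetection <- function(predicted, truth, geometry = NULL) {
  nuc <- truth@nuclei
  if (!nrow(nuc)) stop("ground-truth scene has no nuclei")
  diam <- 2 * max(nuc$radius_um)
  P <- coords(predicted)
  Tn <- as.matrix(nuc[, c("x_um", "y_um", "z_um")])
  matches <- .greedy_match(P, Tn, diam, strict = FALSE)
  matched_t <- logical(nrow(Tn)); matched_t[matches$indexB] <- TRUE
  # class assignment is non-exclusive: any prediction nearby means the
  # object survived classification as signal
  near_t <- if (nrow(P)) {
    d2 <- outer(rowSums(Tn^2), rowSums(P^2), "+") - 2 * Tn %*% t(P)
    sqrt(pmax(apply(d2, 1, min), 0)) <= diam
  } else rep(FALSE, nrow(Tn))

  # per-cluster predicted counts
  clusters <- split(seq_len(nrow(Tn)), nuc$cluster_id)
  pred_count <- vapply(clusters, function(members)
    sum(matches$indexB %in% members), integer(1))
  true_count <- lengths(clusters)
  count_ok <- pred_count == true_count

  # a prediction sitting on a speckle means it was wrongly kept as signal
  n_speck <- nrow(truth@speckles)
  speck_ok <- logical(0)
  if (n_speck > 0L) {
    if (is.null(geometry))
      stop("geometry is required to evaluate speckle positions")
    Sc <- .voxel_centers(as.matrix(truth@speckles), spacing(geometry),
                         origin(geometry))
    if (nrow(P)) {
      d2 <- outer(rowSums(Sc^2), rowSums(P^2), "+") - 2 * Sc %*% t(P)
      speck_ok <- sqrt(pmax(apply(d2, 1, min), 0)) > diam / 2
    } else speck_ok <- rep(TRUE, n_speck)
  }
  objs_ok <- c(near_t, speck_ok)
  strata <- rbind(
    data.frame(stratum = "nucleus", n = nrow(Tn), correct = sum(near_t)),
    if (n_speck) data.frame(stratum = "speckle", n = n_speck,
                            correct = sum(speck_ok)),
    data.frame(stratum = paste0("cluster_size_", sort(unique(true_count))),
               n = as.vector(table(true_count)),
               correct = as.vector(tapply(count_ok, true_count, sum))))
  new("ValidationReport",
      signalNoiseAccuracy = mean(objs_ok),
      countAccuracy = mean(count_ok),
      strata = strata)
}
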