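#' @include pipeline.R render.R
NULL

#' Default conditions of the synthetic validation benchmark
#'
#' One place defining the fixed benchmark the validation suite and the
#' acceptance checks run: a 300-um toy atlas at 10-um spacing, nuclei of
#' 5-um radius enriched in the caudoputamen-like region (about 2.2x the
#' background density), clusters of 1-4 touching nuclei in equal
#' proportions, rendering at 3.65-um working resolution with the default
#' Poisson-Gaussian camera model, and 150 injected single-voxel speckles
#' per volume at nucleus-level brightness.
#'
#' @return Named list of benchmark parameters.
#' @export
benchmarkConfig <- function() {
  list(atlas_spacing_um = 10,
       atlas_shape = c(30L, 30L, 30L),
       atlas_regions = 6L,
       atlas_seed = 101L,
       densities = c("201" = 40000, "202" = 40000,
                     "301" = 18000, "302" = 18000,
                     "401" = 18000, "402" = 18000,
                     "501" = 18000, "502" = 18000,
                     "601" = 18000, "602" = 18000),
       cluster_mix = c(0.25, 0.25, 0.25, 0.25),
       radius_um = 5,
       n_volumes = 5L,
       n_train = 2L,
       speckles_per_volume = 150L,
       speckle_amplitude = 60,
       n_foreground_labels = 2500L,
       n_background_labels = 4000L,
       render = RenderParams())
}

# Brain mask of the atlas resampled onto a rendered grid (nearest label).
.brain_mask_on_grid <- function(atlas, geometry) {
  dm <- dim(geometry)
  g <- as.matrix(expand.grid(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])))
  x <- .voxel_centers(g, spacing(geometry), origin(geometry))
  iv <- pointToVoxel(x, atlas)
  m <- rep(0L, nrow(g))
  ok <- !is.na(iv[, 1])
  m[ok] <- as.integer(atlas@labels[iv[ok, , drop = FALSE]] != 0L)
  array(m, dm)
}

# One benchmark volume: scene, rendered edu channel with speckles, masks.
.benchmark_volume <- function(atlas, cfg, scene_seed, render_seed, speckle_seed) {
  scene <- sampleNuclei(atlas, cfg$densities, cfg$cluster_mix,
                        seed = scene_seed, radius_um = cfg$radius_um)
  vol <- renderChannels(scene, cfg$render, channels = "edu",
                        seed = render_seed)$edu
  nmask <- nucleusMask(scene, vol, dilate_um = 4)
  brain <- .brain_mask_on_grid(atlas, vol)
  sp <- injectSpeckle(vol, cfg$speckles_per_volume, cfg$speckle_amplitude,
                      seed = speckle_seed, exclude_mask = nmask,
                      within_mask = brain)
  scene@speckles <- as.data.frame(sp$indices)
  list(scene = scene, volume = sp$volume, nucleus_mask = nmask, brain = brain)
}

# Sparse ground-truth-derived training labels for one volume.
.benchmark_labels <- function(bv, cfg, seed) {
  clean <- renderCleanEdu(bv$scene, cfg$render)
  fg_pool <- which(clean@data > 0.5)
  sp_lin <- .linear_index(as.matrix(bv$scene@speckles), dim(bv$volume@data))
  bg_pool <- setdiff(which(bv$nucleus_mask == 0L), sp_lin)
  withSeed(seed, {
    fg <- sample(fg_pool, min(cfg$n_foreground_labels, length(fg_pool)))
    bg <- sample(bg_pool, min(cfg$n_background_labels, length(bg_pool)))
    bg <- c(bg, sp_lin)  # every injected speckle is annotated as noise
    idx <- arrayInd(c(fg, bg), dim(bv$volume@data))
    data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3],
               class = rep(c("foreground", "background"),
                           c(length(fg), length(bg))))
  })
}

#' Run the self-validating synthetic benchmark
#'
#' Builds the fixed benchmark of [benchmarkConfig()]: five simulated
#' volumes of clustered nuclei with injected speckle noise, a pixel
#' classifier trained on sparse ground-truth labels from the first two
#' volumes, and detection (classification, three-voxel filter, watershed
#' splitting) on the three held-out volumes. Reports the component-level
#' signal/noise accuracy and the cluster-level count accuracy pooled over
#' the held-out volumes, with per-volume detail.
#'
#' @param seed integer master seed; per-volume and per-stage seeds are
#'   derived from it by fixed offsets so stages can be rerun in isolation.
#' @param config benchmark conditions, see [benchmarkConfig()].
#' @param progress print per-volume progress messages.
#' @return list: `report` (a pooled [ValidationReport-class]),
#'   `count_accuracy`, `signal_noise_accuracy`, `n_clusters`, `n_objects`,
#'   `per_volume` (data.frame), `model`.
#' @export
runBenchmark <- function(seed = 1L, config = benchmarkConfig(),
                         progress = FALSE) {
  cfg <- config
  atlas <- buildToyAtlas(cfg$atlas_spacing_um, cfg$atlas_shape,
                         cfg$atlas_regions, seed = cfg$atlas_seed)
  base <- as.integer(seed) * 100L
  vols <- lapply(seq_len(cfg$n_volumes), function(v) {
    if (progress) message("benchmark volume ", v)
    .benchmark_volume(atlas, cfg, scene_seed = base + v,
                      render_seed = base + 10L + v,
                      speckle_seed = base + 20L + v)
  })
  train_ix <- seq_len(cfg$n_train)
  labels <- lapply(vols[train_ix], .benchmark_labels, cfg = cfg,
                   seed = base + 30L)
  model <- trainPixelClassifier(lapply(vols[train_ix], `[[`, "volume"),
                                labels, seed = base + 40L)
  held <- setdiff(seq_len(cfg$n_volumes), train_ix)
  per <- list()
  tot_obj <- tot_obj_ok <- tot_cl <- tot_cl_ok <- 0
  for (v in held) {
    if (progress) message("evaluating held-out volume ", v)
    bv <- vols[[v]]
    mask <- classifyVoxels(model, bv$volume)
    det <- detectNuclei(mask, bv$volume, min_voxels = 3L, connectivity = 26L,
                        split = TRUE, expected_radius_um = cfg$radius_um)
    rep_v <- validateDetection(det, bv$scene, geometry = bv$volume)
    n_cl <- length(unique(bv$scene@nuclei$cluster_id))
    n_obj <- nrow(bv$scene@nuclei) + nrow(bv$scene@speckles)
    tot_cl <- tot_cl + n_cl
    tot_cl_ok <- tot_cl_ok + rep_v@countAccuracy * n_cl
    tot_obj <- tot_obj + n_obj
    tot_obj_ok <- tot_obj_ok + rep_v@signalNoiseAccuracy * n_obj
    per[[length(per) + 1L]] <- data.frame(
      volume = v, n_nuclei = nrow(bv$scene@nuclei), n_clusters = n_cl,
      n_speckles = nrow(bv$scene@speckles), n_detected = length(det),
      signal_noise_accuracy = rep_v@signalNoiseAccuracy,
      count_accuracy = rep_v@countAccuracy)
  }
  per <- do.call(rbind, per)
  report <- new("ValidationReport",
                signalNoiseAccuracy = tot_obj_ok / tot_obj,
                countAccuracy = tot_cl_ok / tot_cl,
                strata = per)
  list(report = report,
       count_accuracy = report@countAccuracy,
       signal_noise_accuracy = report@signalNoiseAccuracy,
       n_clusters = tot_cl, n_objects = tot_obj,
       per_volume = per, model = model)
}
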