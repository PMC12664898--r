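make_mask_volume <- function(arr, spacing = 3.65) {
  ImageVolume(array(as.numeric(arr), dim(arr)), spacing = spacing)
}

test_that("background subtraction flattens constants and keeps blobs", {
  const <- ImageVolume(array(100, c(16, 16, 16)), spacing = 2)
  out <- subtractBackground(const, 20)
  expect_true(all(volumeData(out) == 0))
  expect_error(subtractBackground(const, -1), "positive")
  expect_warning(subtractBackground(const, 3), "attenuated")
  # bright blob on a flat offset: peak preserved within 5%, far field ~ 0
  arr <- array(100, c(32, 32, 32))
  blob <- renderCleanEdu(new("SyntheticScene",
    nuclei = data.frame(x_um = 32, y_um = 32, z_um = 32, cluster_id = 1L,
                        region_id = 10L, radius_um = 5),
    speckles = data.frame(i = integer(0), j = integer(0), k = integer(0)),
    regionDensities = c("10" = 1), atlas = make_slab_atlas(32, 2),
    trueTransform = NULL, seed = 1L), RenderParams(spacing_um = 2, psf_sigma_um = 1))
  v <- ImageVolume(arr + 400 * volumeData(blob), spacing = 2)
  bs <- subtractBackground(v, 25)
  expect_gt(max(volumeData(bs)), 0.95 * 400 * max(volumeData(blob)))
  expect_lt(mean(volumeData(bs)[1:4, , ]), 2)
})

test_that("downsampling is identity at the same spacing and block-exact otherwise", {
  v <- ImageVolume(array(1, c(8, 8, 8)), spacing = 1)
  expect_identical(downsampleVolume(v, 1), v)
  d <- downsampleVolume(v, 4)
  expect_identical(dim(d), c(2L, 2L, 2L))
  expect_true(all(volumeData(d) == 1))
  expect_equal(spacing(d), c(4, 4, 4))
  expect_error(downsampleVolume(d, 1), "target spacing")
  # mean intensity (hence integrated mass) conserved for block means
  set.seed(1)
  r <- ImageVolume(array(runif(24^3), c(24, 24, 24)), spacing = 1)
  r3 <- downsampleVolume(r, 3)
  expect_lt(abs(mean(volumeData(r3)) - mean(volumeData(r))) / mean(volumeData(r)),
            0.01)
})

test_that("two adjacent nuclei stay separable through the resolution reduction", {
  # two 10-um nuclei 12 um apart, captured near the native resolution and
  # reduced to the 3.65-um working resolution
  atlas <- make_slab_atlas(6, spacing = 10)   # 60-um box
  nuc <- data.frame(x_um = c(24, 36), y_um = 30, z_um = 30,
                    cluster_id = 1L, region_id = c(10L, 20L), radius_um = 5)
  sc <- new("SyntheticScene", nuclei = nuc,
            speckles = data.frame(i = integer(0), j = integer(0), k = integer(0)),
            regionDensities = c("10" = 1), atlas = atlas,
            trueTransform = NULL, seed = 1L)
  hi <- renderCleanEdu(sc, RenderParams(spacing_um = 0.334, psf_sigma_um = 0.5))
  lo <- suppressMessages(downsampleVolume(hi, 3.65))
  expect_equal(spacing(lo), rep(3.65, 3))
  mask <- classifyVoxels(thresholdClassifier(0.2 * max(volumeData(lo))), lo)
  det <- detectNuclei(mask, lo, expected_radius_um = 5)
  expect_identical(length(det), 2L)
  d <- abs(coords(det)[, 1] - sort(nuc$x_um))
  expect_lt(max(d), 3.65)
})

test_that("pixel classifier training demands two classes and is reproducible", {
  set.seed(5)
  arr <- array(rnorm(20^3, 10, 1), c(20, 20, 20))
  arr[5:8, 5:8, 5:8] <- arr[5:8, 5:8, 5:8] + 100
  v <- ImageVolume(pmax(arr, 0), spacing = 3.65)
  fg <- as.data.frame(as.matrix(expand.grid(i = 5:8, j = 5:8, k = 5:8)))
  fg$class <- "foreground"
  bg <- data.frame(i = 12:17, j = 12:17, k = 12:17, class = "background")
  labs <- rbind(fg, bg)
  expect_error(trainPixelClassifier(v, fg), "both foreground and background")
  m1 <- trainPixelClassifier(v, labs, seed = 11)
  m2 <- trainPixelClassifier(v, labs, seed = 11)
  expect_identical(m1@forest$prediction.error, m2@forest$prediction.error)
  expect_identical(volumeData(classifyVoxels(m1, v)),
                   volumeData(classifyVoxels(m2, v)))
  # linearly separable labels classify their own training voxels perfectly
  mask <- classifyVoxels(m1, v)
  expect_true(all(volumeData(mask)[as.matrix(fg[, 1:3])] == 1))
  expect_true(all(volumeData(mask)[as.matrix(bg[, 1:3])] == 0))
  expect_identical(m1@provenance$mode, "random_forest")
})

test_that("threshold fallback classifies plainly and idempotently", {
  v <- ImageVolume(array(c(0, 10, 60, 100), c(4, 2, 2)), spacing = 1)
  model <- thresholdClassifier(50)
  mask <- classifyVoxels(model, v)
  expect_true(all(volumeData(mask) %in% c(0, 1)))
  expect_identical(sum(volumeData(mask)), 8)
  # re-applying a sub-unit threshold to its own binary mask changes nothing
  model01 <- thresholdClassifier(0.5)
  expect_identical(volumeData(classifyVoxels(model01, mask)),
                   volumeData(mask))
  # all-zero volume is all background under otsu fallback too
  z <- ImageVolume(array(0, c(5, 5, 5)), spacing = 1)
  expect_true(all(volumeData(classifyVoxels(thresholdClassifier(), z)) %in% c(0, 1)))
  expect_identical(thresholdClassifier()@provenance$mode, "threshold")
})

test_that("the three-voxel rule discards small components", {
  arr <- array(0, c(24, 24, 8))
  arr[2, 2, 2] <- 1                  # size 1
  arr[8:9, 2, 2] <- 1                # size 2
  arr[14:16, 2, 2] <- 1              # size 3
  arr[2:6, 10, 2] <- 1               # size 5
  v <- make_mask_volume(arr)
  det <- detectNuclei(v, v)
  expect_identical(length(det), 2L)
  expect_true(all(componentSizes(det) %in% c(3L, 5L)))
  # raising min_voxels never increases the count
  counts <- vapply(1:6, function(mv) length(detectNuclei(v, v, min_voxels = mv)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  # empty mask is an empty set, not an error
  e <- detectNuclei(make_mask_volume(array(0, c(8, 8, 8))), NULL)
  expect_identical(length(e), 0L)
})

test_that("an isolated sphere yields one centroid within half a voxel", {
  atlas <- make_slab_atlas(10)
  nuc <- data.frame(x_um = 48.2, y_um = 52.9, z_um = 50.4, cluster_id = 1L,
                    region_id = 10L, radius_um = 5)
  sc <- new("SyntheticScene", nuclei = nuc,
            speckles = data.frame(i = integer(0), j = integer(0), k = integer(0)),
            regionDensities = c("10" = 1), atlas = atlas,
            trueTransform = NULL, seed = 1L)
  v <- renderCleanEdu(sc, RenderParams(spacing_um = 3.65, psf_sigma_um = 1.5))
  mask <- classifyVoxels(thresholdClassifier(0.3 * max(volumeData(v))), v)
  det <- detectNuclei(mask, v)
  expect_identical(length(det), 1L)
  expect_lt(sqrt(sum((coords(det) - unlist(nuc[1, 1:3]))^2)), 3.65 / 2)
})

test_that("watershed splitting separates a dumbbell that plain labelling cannot", {
  atlas <- make_slab_atlas(8, spacing = 10)
  nuc <- data.frame(x_um = c(33, 46), y_um = 40, z_um = 40,  # 1.3 diameters
                    cluster_id = 1L, region_id = 10L, radius_um = 5)
  sc <- new("SyntheticScene", nuclei = nuc,
            speckles = data.frame(i = integer(0), j = integer(0), k = integer(0)),
            regionDensities = c("10" = 1), atlas = atlas,
            trueTransform = NULL, seed = 1L)
  v <- renderCleanEdu(sc, RenderParams(spacing_um = 3.65, psf_sigma_um = 2))
  mask <- classifyVoxels(thresholdClassifier(0.2 * max(volumeData(v))), v)
  # the mask fuses the pair into one component
  expect_identical(max(labelComponents(mask)), 1L)
  expect_identical(length(detectNuclei(mask, v, split = FALSE)), 1L)
  det <- detectNuclei(mask, v, split = TRUE)
  expect_identical(length(det), 2L)
  expect_lt(max(abs(sort(coords(det)[, 1]) - nuc$x_um)), 3.65)
})

test_that("component labelling agrees with a brute-force flood fill", {
  set.seed(42)
  for (conn in c(6L, 26L)) {
    mask <- array(as.integer(runif(14^3) < 0.18), c(14, 14, 14))
    ours <- labelComponents(mask, conn)
    oracle <- brute_flood_fill(mask, conn)
    expect_identical(max(ours), max(oracle))
    # same partition: label pairs must be in bijection
    key <- paste(ours[mask == 1], oracle[mask == 1])
    expect_identical(length(unique(key)), max(ours))
  }
})

test_that("no nucleus is ever reported at a single-voxel speckle", {
  atlas <- toy_atlas()
  sc <- sampleNuclei(atlas, c("201" = 15000, "301" = 8000), seed = 6)
  vol <- renderChannels(sc, RenderParams(), channels = "edu", seed = 16)$edu
  nm <- nucleusMask(sc, vol, dilate_um = 4)
  sp <- injectSpeckle(vol, 120, 60, seed = 26, exclude_mask = nm)
  mask <- classifyVoxels(thresholdClassifier(25), sp$volume)
  det <- detectNuclei(mask, sp$volume)
  sc_centres <- clickmap3d:::.voxel_centers(sp$indices, spacing(vol), origin(vol))
  if (length(det)) {
    d2 <- outer(rowSums(sc_centres^2), rowSums(coords(det)^2), "+") -
      2 * sc_centres %*% t(coords(det))
    expect_gt(min(sqrt(pmax(d2, 0))), 3.65)
  }
})

test_that("SNR is the ratio of ROI means", {
  v <- ImageVolume(array(7, c(6, 6, 6)), spacing = 1)
  expect_equal(computeSnr(v, 1:10, 100:140), 1)
  arr <- array(10, c(6, 6, 6)); arr[1:10] <- 40
  v2 <- ImageVolume(arr, spacing = 1)
  expect_equal(computeSnr(v2, 1:10, 50:100), 4)
  set.seed(2)
  v3 <- ImageVolume(array(runif(6^3, 1, 2), c(6, 6, 6)), spacing = 1)
  s <- sample(216, 30); b <- sample(216, 40)
  expect_equal(computeSnr(v3, s, b),
               mean(volumeData(v3)[s]) / mean(volumeData(v3)[b]),
               tolerance = 1e-12)
  expect_error(computeSnr(v3, integer(0), b), "empty")
  z <- ImageVolume(array(0, c(4, 4, 4)), spacing = 1)
  expect_error(computeSnr(z, 1:2, 3:4), "background mean")
})

test_that("validation accuracies behave on constructed truths", {
  atlas <- make_slab_atlas(12)
  nuc <- data.frame(
    x_um = c(20, 32, 60, 72, 95, 107, 101),
    y_um = c(20, 20, 50, 50, 80, 80, 90),
    z_um = 60,
    cluster_id = c(1L, 1L, 2L, 2L, 3L, 3L, 3L),
    region_id = 10L, radius_um = 5)
  sc <- new("SyntheticScene", nuclei = nuc,
            speckles = data.frame(i = integer(0), j = integer(0), k = integer(0)),
            regionDensities = c("10" = 1), atlas = atlas,
            trueTransform = NULL, seed = 1L)
  perfect <- NucleusSet(as.matrix(nuc[, 1:3]), space = "atlas")
  rep1 <- validateDetection(perfect, sc)
  expect_equal(rep1@signalNoiseAccuracy, 1)
  expect_equal(rep1@countAccuracy, 1)
  # predicted counts (2, 1, 3) against true (2, 2, 3): 2 of 3 clusters exact
  partial <- perfect[-3]
  rep2 <- validateDetection(partial, sc)
  expect_equal(rep2@countAccuracy, 2 / 3)
  expect_error(validateDetection(perfect, new("SyntheticScene",
    nuclei = nuc[0, ], speckles = sc@speckles, regionDensities = c("10" = 1),
    atlas = atlas, trueTransform = NULL, seed = 1L)), "no nuclei")
})
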