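test_that("toy atlas is bilaterally symmetric, deterministic, and well-formed", {
  a1 <- buildToyAtlas(10, c(40, 40, 40), 6, seed = 1)
  a2 <- buildToyAtlas(10, c(40, 40, 40), 6, seed = 1)
  expect_identical(atlasLabels(a1), atlasLabels(a2))
  lab <- atlasLabels(a1)
  expect_identical(lab[, , 1:20], lab[, , 40:21])
  expect_true(all(c(101L, 201L) %in% as.vector(lab)))
  # ventricle and caudoputamen-like regions must share an interface
  expect_gt(sum(atlasLabels(annotateSvz(a1, 201, 101)) == 5), 0)
})

test_that("toy atlas ontology has the configured top-level count (tree-walk oracle)", {
  for (nreg in c(3L, 6L)) {
    a <- buildToyAtlas(10, c(30, 30, 30), nreg, seed = 2)
    onto <- ontology(a)
    root <- onto$id[is.na(onto$parent_structure_id)]
    expect_length(root, 1)
    # brute-force walk: depth-1 ancestors of every leaf in use
    parent <- setNames(onto$parent_structure_id, onto$id)
    top_of <- function(id) {
      while (!is.na(parent[[as.character(id)]]) &&
             parent[[as.character(id)]] != root) id <- parent[[as.character(id)]]
      id
    }
    tops <- unique(vapply(setdiff(unique(as.vector(atlasLabels(a))), 0),
                          top_of, numeric(1)))
    expect_length(tops, nreg)
    expect_gte(length(unique(onto$id)), nreg * 3 + 1)  # root + tops + leaves
  }
})

test_that("reserved-ID collision is a hard error", {
  expect_error(buildToyAtlas(10, c(30, 30, 30), 6, seed = 1, custom_id = 201L),
               "collides")
  expect_error(buildToyAtlas(10, c(10, 30, 30), 6, seed = 1), "at least 20")
})

test_that("sampleNuclei honours densities, cluster mix and placement invariants", {
  atlas <- toy_atlas()
  # all-zero densities give an empty scene
  sc0 <- sampleNuclei(atlas, c("201" = 0, "301" = 0), seed = 1)
  expect_identical(nrow(sc0@nuclei), 0L)
  # degenerate mix at size 2: every cluster has exactly two members
  sc2 <- sampleNuclei(atlas, c("201" = 20000), cluster_mix = c(0, 1, 0, 0),
                      seed = 3)
  sizes <- table(sc2@nuclei$cluster_id)
  expect_true(all(sizes[-length(sizes)] == 2))  # last cluster may be trimmed
  # placement invariants: inside nonzero voxels, pairwise within 3 radii
  sc <- sampleNuclei(atlas, benchmarkConfig()$densities, seed = 4)
  idx <- pointToVoxel(as.matrix(sc@nuclei[, 1:3]), atlas)
  expect_false(anyNA(idx))
  expect_true(all(atlasLabels(atlas)[idx] != 0))
  r <- max(sc@nuclei$radius_um)
  for (cl in unique(sc@nuclei$cluster_id)) {
    m <- sc@nuclei[sc@nuclei$cluster_id == cl, 1:3]
    if (nrow(m) > 1) {
      d <- as.matrix(dist(m))
      diag(d) <- NA
      expect_true(all(d[!is.na(d)] >= 2 * r - 1e-9 & d[!is.na(d)] <= 3 * r + 1e-9))
    }
  }
  # determinism
  sc_b <- sampleNuclei(atlas, benchmarkConfig()$densities, seed = 4)
  expect_identical(sc@nuclei, sc_b@nuclei)
})

test_that("expected nucleus counts follow density x volume (Monte-Carlo)", {
  atlas <- make_slab_atlas(10, spacing = 10)   # region 10: 500 voxels = 5e-4 mm3
  dens <- 100 / (500 * 1e-6)                   # lambda = 100 nuclei
  counts <- vapply(1:200, function(s)
    nrow(sampleNuclei(atlas, setNames(dens, "10"),
                      cluster_mix = c(1, 0, 0, 0), seed = s)@nuclei),
    numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 100), 3 * se + 1e-9)
})

test_that("overfull regions fail rejection sampling with a named error", {
  atlas <- make_slab_atlas(10)
  expect_error(sampleNuclei(atlas, c("10" = 5e7), seed = 1), "region 10")
})

test_that("noise-free rendering is analytically predictable", {
  atlas <- make_slab_atlas(10)
  nuc <- data.frame(x_um = 52, y_um = 47, z_um = 55, cluster_id = 1L,
                    region_id = 10L, radius_um = 5)
  sc <- new("SyntheticScene", nuclei = nuc,
            speckles = data.frame(i = integer(0), j = integer(0), k = integer(0)),
            regionDensities = c("10" = 1), atlas = atlas,
            trueTransform = NULL, seed = 1L)
  # psf 0, no noise: intensity-weighted centroid within half a voxel
  vol <- renderCleanEdu(sc, RenderParams(spacing_um = 2, psf_sigma_um = 0))
  w <- volumeData(vol)
  g <- which(w > 0)
  idx <- arrayInd(g, dim(w))
  cen <- colSums((idx - 0.5) * 2 * w[g]) / sum(w[g])
  expect_lt(max(abs(cen - c(52, 47, 55))), 1)
  # zeroed camera model gives an all-zero edu channel
  z <- renderChannels(sc, RenderParams(spacing_um = 2, photon_scale = 0,
                                       read_noise_sd = 0,
                                       surface_rim_amplitude = 0),
                      channels = "edu", seed = 1)$edu
  expect_true(all(volumeData(z) == 0))
  # identical seed, identical volume
  p <- RenderParams(spacing_um = 5)
  v1 <- renderChannels(sc, p, channels = "edu", seed = 9)$edu
  v2 <- renderChannels(sc, p, channels = "edu", seed = 9)$edu
  expect_identical(volumeData(v1), volumeData(v2))
})

test_that("surface rim brightens the outer shell of the autofluorescence channel", {
  atlas <- toy_atlas()
  sc <- sampleNuclei(atlas, c("201" = 1000), seed = 1)
  p <- RenderParams(spacing_um = 10, surface_rim_amplitude = 50,
                    read_noise_sd = 0, photon_scale = 0)
  af <- renderChannels(sc, p, channels = "autofluorescence", seed = 1)$autofluorescence
  lab <- atlasLabels(atlas)
  brain <- lab != 0
  edt <- array(clickmap3d:::cpp_edt(as.integer(brain), dim(lab), spacing(atlas)),
               dim(lab))
  shell <- brain & edt <= 15
  core <- brain & edt > 30
  expect_gt(mean(volumeData(af)[shell]), mean(volumeData(af)[core]))
})

test_that("speckle injection returns disjoint ground-truth positions", {
  vol <- ImageVolume(array(0, c(20, 20, 20)), spacing = 3.65)
  nm <- array(0L, c(20, 20, 20)); nm[8:12, 8:12, 8:12] <- 1L
  # n = 0 leaves the volume untouched
  r0 <- injectSpeckle(vol, 0, 50, seed = 1)
  expect_identical(volumeData(r0$volume), volumeData(vol))
  r <- injectSpeckle(vol, 50, 50, seed = 7, exclude_mask = nm)
  expect_identical(nrow(r$indices), 50L)
  expect_false(any(duplicated(r$indices)))
  expect_true(all(nm[r$indices] == 0L))
  expect_equal(sum(volumeData(r$volume)) , 50 * 50)
  # no free voxels -> error
  full <- array(1L, c(20, 20, 20))
  expect_error(injectSpeckle(vol, 5, 50, seed = 1, exclude_mask = full),
               "not enough free voxels")
})

test_that("ground-truth transforms are identity at zero and invert numerically", {
  atlas <- toy_atlas()
  id <- makeGroundTruthTransform(atlas)
  pts <- matrix(runif(30, 40, 260), ncol = 3)
  expect_equal(forwardTransformPoints(pts, id), pts)
  tr <- makeGroundTruthTransform(atlas, translation_um = c(10, 0, 0))
  expect_equal(forwardTransformPoints(pts, tr), sweep(pts, 2, c(10, 0, 0), "+"))
  # random chain round trip within 0.25 voxel RMS
  ch <- makeGroundTruthTransform(atlas, rotation_deg = c(4, -6, 10),
                                 scale = c(1.1, 0.9, 1.05),
                                 translation_um = c(20, -5, 12),
                                 warp_amplitude_um = 15,
                                 warp_smoothness_um = 60, seed = 3)
  set.seed(33)
  p <- matrix(runif(300, 50, 250), ncol = 3)
  s <- forwardTransformPoints(p, ch)
  back <- coords(applyChainToPoints(NucleusSet(s, space = "sample"), ch))
  rms <- sqrt(mean(rowSums((back - p)^2)))
  expect_lt(rms, 0.25 * 10)
  # invertibility envelope is enforced
  expect_error(makeGroundTruthTransform(atlas, rotation_deg = c(30, 0, 0)), "rotation")
  expect_error(makeGroundTruthTransform(atlas, scale = c(0.5, 1, 1)), "scale")
  expect_error(makeGroundTruthTransform(atlas, warp_amplitude_um = 100), "amplitude")
})
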