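test_that("per-region counting matches a brute-force loop and conserves totals", {
  atlas <- make_slab_atlas(10)
  pts <- rbind(c(20, 20, 20), c(22, 50, 30), c(40, 40, 40), c(80, 20, 20))
  ns <- NucleusSet(pts, space = "atlas")
  st <- countPerRegion(ns, atlas, "top")
  tab <- regionTable(st)
  expect_identical(tab$count[tab$id == 10], 3L)
  expect_identical(tab$count[tab$id == 20], 1L)
  expect_equal(tab$fraction[tab$id == 10], 0.75)
  expect_equal(tab$fraction[tab$id == 20], 0.25)
  # empty set: zero counts everywhere, no division errors
  st0 <- countPerRegion(NucleusSet(matrix(numeric(0), 0, 3), space = "atlas"),
                        atlas)
  expect_true(all(regionTable(st0)$count == 0))
  expect_true(all(is.finite(regionTable(st0)$density_per_mm3)))
  # oracle on a large random set, plus count conservation
  atlas2 <- toy_atlas()
  set.seed(7)
  rp <- matrix(runif(30000, -20, 320), ncol = 3)
  ns2 <- NucleusSet(rp, space = "atlas")
  st2 <- countPerRegion(ns2, atlas2, "leaf")
  lab <- atlasLabels(atlas2)
  oracle <- integer(0)
  for (i in seq_len(nrow(rp))) {
    v <- floor(rp[i, ] / 10) + 1
    oracle[i] <- if (any(v < 1) || any(v > 30)) 0L else lab[v[1], v[2], v[3]]
  }
  tab2 <- regionTable(st2)
  for (id in tab2$id)
    expect_identical(tab2$count[tab2$id == id], sum(oracle == id))
  expect_identical(st2@unassigned, sum(oracle == 0L))
  expect_identical(sum(tab2$count) + st2@unassigned, nrow(rp))
  expect_equal(sum(tab2$fraction), 1)
  # density really is count / volume
  expect_equal(tab2$density_per_mm3, tab2$count / tab2$volume_mm3)
})

test_that("voxel collisions follow absolute half-open binning", {
  atlas <- make_slab_atlas(10)
  # 5 um apart inside one 10-um voxel
  same <- NucleusSet(rbind(c(12, 5, 5), c(17, 5, 5)), space = "atlas")
  r_same <- voxelCollisionRatio(same, atlas, 10)
  expect_equal(r_same$ratio[is.na(r_same$region_id)], 1)
  # 5 um apart straddling an absolute grid boundary: no collision
  straddle <- NucleusSet(rbind(c(8, 5, 5), c(13, 5, 5)), space = "atlas")
  r_str <- voxelCollisionRatio(straddle, atlas, 10)
  expect_equal(r_str$ratio[is.na(r_str$region_id)], 0)
  # single point collides nowhere
  single <- NucleusSet(matrix(c(33, 33, 33), 1), space = "atlas")
  expect_true(all(voxelCollisionRatio(single, atlas)$ratio == 0))
  expect_error(voxelCollisionRatio(single, atlas, c(10, -5)), "positive")
})

test_that("overall collision ratio grows with voxel size (100 random point sets)", {
  atlas <- toy_atlas()
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(50:250, 1)
    pts <- matrix(runif(3 * n, 0, 300), ncol = 3)
    cr <- voxelCollisionRatio(NucleusSet(pts, space = "atlas"), atlas)
    overall <- cr$ratio[is.na(cr$region_id)]
    expect_true(all(diff(overall) >= 0))
    expect_true(all(overall >= 0 & overall <= 1))
  }
})

test_that("colocalization matches strictly below the threshold", {
  A <- NucleusSet(rbind(c(0, 0, 0), c(100, 0, 0)), space = "atlas")
  B <- NucleusSet(rbind(c(4.9, 0, 0), c(105.0, 0, 0)), space = "atlas")
  res <- colocalize(A, B, threshold_um = 5)
  expect_identical(nrow(res@pairs), 1L)   # 4.9 matched, 5.0 not
  expect_identical(res@pairs$indexA, 1L)
  expect_equal(res@pairs$distance_um, 4.9)
  tallies <- regionTable(res)
  expect_identical(tallies$n_AposBpos[1], 1L)
  expect_identical(tallies$n_AnegBpos[1], 1L)
  # empty A: every B is single-positive
  empty <- NucleusSet(matrix(numeric(0), 0, 3), space = "atlas")
  res0 <- colocalize(empty, B)
  expect_identical(nrow(res0@pairs), 0L)
  expect_identical(regionTable(res0)$n_AnegBpos[1], 2L)
  # mixed spaces refuse
  expect_error(colocalize(NucleusSet(coords(A), space = "sample"), B),
               "different spaces")
})

test_that("greedy matching attains brute-force maximum cardinality (<= 12 points)", {
  set.seed(9)
  for (rep in 1:25) {
    # the colocalization regime: B points are jittered copies of a subset of
    # A, with the match radius well below the inter-point spacing
    nA <- sample(4:12, 1); nB <- sample(2:nA, 1)
    A <- matrix(runif(3 * nA, 0, 80), ncol = 3)
    B <- A[sample(nA, nB), , drop = FALSE] +
      matrix(runif(3 * nB, -6, 6), ncol = 3)
    g <- clickmap3d:::.greedy_match(A, B, 10, strict = TRUE)
    expect_identical(nrow(g), brute_max_matching(A, B, 10))
    # one-to-one
    expect_false(any(duplicated(g$indexA)))
    expect_false(any(duplicated(g$indexB)))
    expect_true(all(g$distance_um < 10))
    # cardinality symmetry
    g2 <- clickmap3d:::.greedy_match(B, A, 10, strict = TRUE)
    expect_identical(nrow(g2), nrow(g))
  }
})

test_that("hemisphere comparison pairs base regions correctly", {
  atlas <- annotateHemispheres(toy_atlas())
  # symmetric points: mirror every point through the midline
  set.seed(15)
  right <- matrix(runif(600, 0, 300), ncol = 3)
  right[, 3] <- runif(200, 155, 295)
  left <- right
  left[, 3] <- 300 - right[, 3]
  ns <- NucleusSet(rbind(right, left), space = "atlas")
  st <- countPerRegion(ns, atlas, "top")
  hc <- hemisphereCompare(st)
  paired <- hc[!hc$one_sided & hc$right_count + hc$left_count > 0, ]
  expect_true(nrow(paired) > 0)
  expect_equal(paired$left_count, paired$right_count)
  expect_equal(paired$ratio_left_over_right, rep(1, nrow(paired)))
  # manual base-ID arithmetic oracle
  tab <- regionTable(st)
  for (r in seq_len(nrow(paired))) {
    expect_equal(paired$left_count[r],
                 tab$count[tab$id == paired$base_id[r] + 1e9])
    expect_equal(paired$right_count[r],
                 tab$count[tab$id == paired$base_id[r]])
  }
  # all points on the left: right densities zero, infinite ratios flagged
  only_left <- NucleusSet(left, space = "atlas")
  hc2 <- hemisphereCompare(countPerRegion(only_left, atlas, "top"))
  got <- hc2[hc2$left_count > 0, ]
  expect_true(all(got$right_density == 0))
  expect_true(all(is.infinite(got$ratio_left_over_right)))
  # refuses plain atlases
  expect_error(hemisphereCompare(countPerRegion(ns, toy_atlas(), "top")),
               "hemisphere")
})

test_that("heatmap volumes paint region densities voxel by voxel", {
  atlas <- make_slab_atlas(10)
  pts <- NucleusSet(rbind(c(20, 20, 20), c(25, 25, 25), c(80, 40, 40)),
                    space = "atlas")
  st <- countPerRegion(pts, atlas, "top")
  hm <- heatmapVolume(st, atlas)
  tab <- regionTable(st)
  lab <- atlasLabels(atlas)
  # brute-force label -> density substitution
  oracle <- array(0, dim(lab))
  for (id in tab$id)
    oracle[lab == id] <- tab$density_per_mm3[tab$id == id]
  expect_equal(volumeData(hm), oracle)
  # empty stats give an all-zero volume
  st0 <- countPerRegion(NucleusSet(matrix(numeric(0), 0, 3), space = "atlas"),
                        atlas)
  expect_true(all(volumeData(heatmapVolume(st0, atlas)) == 0))
})

test_that("migration distance is speed times chase time", {
  expect_identical(expectedMigrationDistance(17.98, 24), 431.52)
  expect_identical(expectedMigrationDistance(5, 0), 0)
  expect_identical(expectedMigrationDistance(1, 1), 1)
  expect_error(expectedMigrationDistance(-1, 5), ">= 0")
})
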