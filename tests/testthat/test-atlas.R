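test_that("region lookup matches brute-force grid indexing", {
  atlas <- toy_atlas()
  set.seed(12)
  pts <- matrix(runif(3000, -10, 310), ncol = 3)
  ns <- NucleusSet(pts, space = "atlas")
  ids <- lookupRegions(ns, atlas, "leaf")
  lab <- atlasLabels(atlas)
  oracle <- apply(pts, 1, function(p) {
    i <- floor(p / 10) + 1
    if (any(i < 1) || any(i > 30)) 0 else lab[i[1], i[2], i[3]]
  })
  expect_equal(ids, as.numeric(oracle))
  # leaf -> top ancestry
  tops <- lookupRegions(ns, atlas, "top")
  expect_true(all(tops[ids == 101] == 100))
  expect_true(all(tops[ids == 202] == 200))
  expect_true(all(tops[ids == 0] == 0))
  expect_error(lookupRegions(NucleusSet(pts, space = "sample"), atlas), "atlas")
})

test_that("region volumes are voxel counts times voxel volume and aggregate up", {
  atlas <- make_slab_atlas(10, spacing = 10)
  vols <- regionVolumes(atlas, "leaf")
  expect_equal(unname(vols[["10"]]), 500 * 1e-6)  # 500 voxels at 1000 um3
  lab <- atlasLabels(toy_atlas())
  v_leaf <- regionVolumes(toy_atlas(), "leaf")
  v_top <- regionVolumes(toy_atlas(), "top")
  expect_equal(sum(v_leaf), sum(lab != 0) * 1e-6)
  expect_equal(sum(v_top), sum(v_leaf))
  # tree-sum oracle: each top volume equals the sum of its leaves
  expect_equal(unname(v_top[["200"]]),
               unname(v_leaf[["201"]] + v_leaf[["202"]]))
})

test_that("ventricular-wall annotation relabels exactly the interface layer", {
  atlas <- make_slab_atlas(10)
  ann <- annotateSvz(atlas, parent_id = 10, adjacent_id = 20)
  lab <- atlasLabels(ann)
  # two abutting slabs: the interface plane of A, one voxel thick
  expect_true(all(lab[5, , ] == 5))
  expect_true(all(lab[1:4, , ] == 10))
  expect_true(all(lab[6:10, , ] == 20))
  expect_identical(length(lab), length(atlasLabels(atlas)))
  expect_true(5 %in% ontology(ann)$id)
  # oracle: A-voxels with at least one face-adjacent B neighbour
  labo <- atlasLabels(atlas)
  oracle <- array(FALSE, dim(labo))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    if (labo[i, j, k] != 10) next
    nb <- rbind(c(i + 1, j, k), c(i - 1, j, k), c(i, j + 1, k),
                c(i, j - 1, k), c(i, j, k + 1), c(i, j, k - 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= 10 & nb[, 2] >= 1 & nb[, 2] <= 10 &
             nb[, 3] >= 1 & nb[, 3] <= 10, , drop = FALSE]
    if (any(labo[nb] == 20)) oracle[i, j, k] <- TRUE
  }
  expect_identical(lab == 5, oracle)
  # both reporting semantics exist: separate top region vs child of parent
  sep <- ontology(annotateSvz(atlas, 10, 20, exclude_from_parent = TRUE))
  kept <- ontology(annotateSvz(atlas, 10, 20, exclude_from_parent = FALSE))
  expect_identical(sep$parent_structure_id[sep$id == 5], 997)
  expect_identical(kept$parent_structure_id[kept$id == 5], 10)
  expect_error(annotateSvz(atlas, 10, 999), "not in ontology")
  # no interface: two regions that never touch
  lab2 <- array(0L, c(10, 10, 10)); lab2[1, 1, 1] <- 10L; lab2[10, 10, 10] <- 20L
  a2 <- LabelAtlas(lab2, 10, ontology(atlas))
  expect_error(annotateSvz(a2, 10, 20), "no interface")
})

test_that("consensus annotation applies the vote rule exactly", {
  atlas <- make_slab_atlas(10)
  base <- array(0L, c(10, 10, 10))
  m4 <- base; m4[2, 2, 2] <- 1L   # voxel positive in 4 masks
  m3 <- base; m3[4, 4, 4] <- 1L   # voxel positive in only 3 masks
  masks <- c(rep(list(m4), 4), rep(list(m3), 3))
  ann <- annotateConsensus(atlas, masks, min_votes = 4)
  expect_identical(atlasLabels(ann)[2, 2, 2], 5L)
  expect_identical(atlasLabels(ann)[4, 4, 4], atlasLabels(atlas)[4, 4, 4])
  # min_votes = 1 is the union, min_votes = N the intersection
  set.seed(4)
  rmasks <- lapply(1:5, function(i) array(as.integer(runif(1000) < 0.3), c(10, 10, 10)))
  u <- annotateConsensus(atlas, rmasks, min_votes = 1)
  expect_identical(atlasLabels(u) == 5, Reduce("|", lapply(rmasks, function(m) m == 1)))
  it <- annotateConsensus(atlas, rmasks, min_votes = 5)
  expect_identical(atlasLabels(it) == 5, Reduce("&", lapply(rmasks, function(m) m == 1)))
  expect_error(annotateConsensus(atlas, rmasks, min_votes = 9), "1..5")
  expect_error(annotateConsensus(atlas, list(array(0L, c(5, 5, 5))), 1),
               "geometry")
  # non-excluding variant keeps labels and attaches the mask
  ne <- annotateConsensus(atlas, masks, min_votes = 4, exclude_from_regions = FALSE)
  expect_identical(atlasLabels(ne), atlasLabels(atlas))
  expect_identical(attr(ne, "consensus_mask")[2, 2, 2], 1L)
})

test_that("hemisphere annotation offsets the left side by exactly 1e9", {
  atlas <- toy_atlas()
  ann <- annotateHemispheres(atlas)
  lab0 <- atlasLabels(atlas)
  lab1 <- atlasLabels(ann)
  left <- 1:15; right <- 16:30
  nzl <- lab0[, , left] != 0
  expect_true(all(lab1[, , left][nzl] == lab0[, , left][nzl] + 1e9))
  expect_identical(lab1[, , right], lab0[, , right] + 0)
  # histogram oracle: per (base ID, side) voxel counts preserved
  expect_equal(table(lab0[, , left][nzl]),
               table(lab1[, , left][nzl] - 1e9), ignore_attr = TRUE)
  # names get side prefixes
  onto <- ontology(ann)
  expect_true(any(grepl("^left ", onto$name)))
  expect_true(any(grepl("^right ", onto$name)))
  expect_error(annotateHemispheres(ann), "already")
  # odd-length midline axis: midplane column goes to the right, with a message
  odd <- buildToyAtlas(10, c(30, 30, 31), 6, seed = 2)
  expect_message(ho <- annotateHemispheres(odd), "midplane")
  mid <- atlasLabels(ho)[, , 16]
  expect_true(all(mid[mid != 0] < 1e9))
})

test_that("ventricular and hemisphere annotations commute up to the offset", {
  atlas <- toy_atlas()
  a1 <- annotateHemispheres(annotateSvz(atlas, 201, 101))
  lab1 <- atlasLabels(a1)
  a2pre <- annotateHemispheres(atlas)
  # annotate the wall on each side of the hemisphere-split atlas
  lab2 <- atlasLabels(a2pre)
  wallR <- clickmap3d:::.interface_voxels(lab2, 201, 101, 6L)
  wallL <- clickmap3d:::.interface_voxels(lab2, 201 + 1e9, 101 + 1e9, 6L)
  lab2[wallR] <- 5
  lab2[wallL] <- 5 + 1e9
  expect_identical(lab1 %% 1e9 == 5, lab2 %% 1e9 == 5)
  # top-level aggregation is idempotent
  onto <- ontology(a2pre)
  ids <- setdiff(unique(as.vector(atlasLabels(a2pre))), 0)
  top1 <- clickmap3d:::.top_ancestor(ids, onto)
  expect_identical(clickmap3d:::.top_ancestor(top1, onto), top1)
})

test_that("ontology JSON round-trips and rejects malformed trees", {
  onto <- ontology(toy_atlas())
  path <- withr::local_tempfile(fileext = ".json")
  writeOntology(onto, path)
  back <- readOntology(path)
  back <- back[order(back$id), ]
  ref <- onto[order(onto$id), ]
  expect_equal(back$id, as.numeric(ref$id))
  expect_equal(back$name, ref$name)
  expect_equal(ifelse(is.na(back$parent_structure_id), -1, back$parent_structure_id),
               ifelse(is.na(ref$parent_structure_id), -1,
                      as.numeric(ref$parent_structure_id)))
  # inserting the custom record under a parent preserves ancestry
  with5 <- rbind(onto, data.frame(id = 5, acronym = "SVZ",
                                  name = "subventricular zone",
                                  parent_structure_id = 200))
  writeOntology(with5, path)
  back5 <- readOntology(path)
  expect_true(5 %in% back5$id)
  expect_identical(clickmap3d:::.top_ancestor(5, back5), 200)
  # orphan parent and duplicate IDs are named errors
  bad <- onto
  bad$parent_structure_id[bad$id == 201] <- 31415
  expect_error(writeOntology(bad, path), "orphan parent")
  writeLines('[{"id":1,"acronym":"r","name":"root","parent_structure_id":null,
    "children":[{"id":2,"acronym":"a","name":"a","parent_structure_id":1,"children":[]},
                {"id":2,"acronym":"b","name":"b","parent_structure_id":1,"children":[]}]}]',
    path)
  expect_error(readOntology(path), "duplicate")
})
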