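#' @include atlas.R detect.R
NULL

#' Per-region counts, densities and fractions
#'
#' Counts nuclei per atlas region, divides by the region volume to get the
#' density (nuclei per mm^3 — the "ratio" of positive nuclei), and reports
#' the fraction of assigned nuclei per region. Points mapped to ID 0
#' (outside the brain after normalization) go into a dedicated unassigned
#' count, never silently dropped, and are excluded from fractions.
#'
#' @param points a [NucleusSet-class] tagged "atlas".
#' @param atlas a [LabelAtlas-class].
#' @param level "leaf" or "top".
#' @return A [RegionStats-class].
#' @export
countPerRegion <- function(points, atlas, level = c("leaf", "top")) {
  level <- match.arg(level)
  ids <- lookupRegions(points, atlas, level)
  vols <- regionVolumes(atlas, level)
  all_ids <- as.numeric(names(vols))
  counts <- stats::setNames(rep(0L, length(all_ids)), names(vols))
  tt <- table(ids[ids != 0])
  counts[names(tt)] <- as.integer(tt)
  if (any(counts > 0 & vols <= 0))
    stop("region with nonzero count has zero volume: geometry bug")
  assigned <- sum(counts)
  onto <- atlas@ontology
  meta <- onto[match(all_ids, onto$id), c("acronym", "name")]
  tab <- data.frame(id = all_ids,
                    acronym = meta$acronym, name = meta$name,
                    count = as.integer(counts),
                    volume_mm3 = as.numeric(vols),
                    density_per_mm3 = as.numeric(counts) / as.numeric(vols),
                    fraction = if (assigned > 0) as.numeric(counts) / assigned
                               else rep(0, length(all_ids)),
                    row.names = NULL, stringsAsFactors = FALSE)
  new("RegionStats", table = tab, unassigned = sum(ids == 0),
      level = level,
      hemisphereAnnotated = any(onto$id >= atlas@hemisphereOffset))
}

#' Ratio of nuclei sharing an atlas voxel, per voxel size
#'
#' Bins the normalized points into absolute half-open grids of the given
#' voxel sizes (anchored at the atlas origin, no shift). A point "collides"
#' when its voxel holds two or more points; the report gives, per voxel
#' size and per top-level region (plus an "all" row), the fraction of
#' points that collide. Coarser voxels merge more neighbours, which is why
#' the finest (10 um) size is needed to keep adjacent nuclei distinct.
#'
#' @param points a [NucleusSet-class] tagged "atlas".
#' @param atlas a [LabelAtlas-class].
#' @param voxel_sizes_um grid sizes to evaluate (default c(10, 25, 50)).
#' @return data.frame: `voxel_size_um`, `region_id`, `n_total`,
#'   `n_colliding`, `ratio`; `region_id` NA marks the all-points row.
#' @export
voxelCollisionRatio <- function(points, atlas, voxel_sizes_um = c(10, 25, 50)) {
  if (any(voxel_sizes_um <= 0)) stop("voxel sizes must be positive")
  p <- coords(points)
  region <- if (length(points)) lookupRegions(points, atlas, "top") else numeric(0)
  out <- list()
  for (s in voxel_sizes_um) {
    key <- apply(floor(sweep(sweep(p, 2L, origin(atlas), "-"), 2L, rep(s, 3), "/")),
                 1L, paste, collapse = ",")
    n_in_vox <- table(key)
    collide <- as.vector(n_in_vox[key]) >= 2
    rows <- data.frame(voxel_size_um = s, region_id = NA_real_,
                       n_total = length(collide),
                       n_colliding = sum(collide),
                       ratio = if (length(collide)) mean(collide) else 0)
    for (r in sort(unique(region))) {
      inr <- region == r
      rows <- rbind(rows, data.frame(voxel_size_um = s, region_id = r,
                                     n_total = sum(inr),
                                     n_colliding = sum(collide[inr]),
                                     ratio = mean(collide[inr])))
    }
    out[[length(out) + 1L]] <- rows
  }
  do.call(rbind, out)
}

#' Colocalize two channels by strict distance matching
#'
#' One-to-one greedy matching of channel-A points (e.g. EdU) to channel-B
#' points (e.g. Ki-67) on ascending distance; only pairs strictly closer
#' than the threshold (default 5 um) count as colocalized. Unmatched B
#' points are A-/B+. With an atlas, per-region tallies and the
#' A+-within-B+ ratio are reported, alongside an "all" row, since the
#' denominator may be read as all B+ nuclei or per-region B+ nuclei.
#'
#' @param setA,setB [NucleusSet-class] objects in the same space.
#' @param threshold_um strict matching threshold (default 5).
#' @param atlas optional [LabelAtlas-class] for per-region tallies.
#' @param level aggregation level for the tallies (default "top").
#' @return A [ColocalizationResult-class].
#' @export
colocalize <- function(setA, setB, threshold_um = 5, atlas = NULL,
                       level = "top") {
  if (pointSpace(setA) != pointSpace(setB))
    stop("point sets live in different spaces (",
         pointSpace(setA), " vs ", pointSpace(setB), ")")
  pairs <- .greedy_match(coords(setA), coords(setB), threshold_um, strict = TRUE)
  nB <- length(setB)
  bpos <- logical(nB)
  bpos[pairs$indexB] <- TRUE
  per <- data.frame(region_id = NA_real_,
                    n_Bpos = nB,
                    n_AposBpos = sum(bpos),
                    n_AnegBpos = sum(!bpos),
                    ratio_Apos_in_Bpos = if (nB) mean(bpos) else NA_real_)
  if (!is.null(atlas) && nB) {
    region <- lookupRegions(setB, atlas, level)
    for (r in sort(unique(region))) {
      inr <- region == r
      per <- rbind(per, data.frame(region_id = r, n_Bpos = sum(inr),
                                   n_AposBpos = sum(bpos[inr]),
                                   n_AnegBpos = sum(!bpos[inr]),
                                   ratio_Apos_in_Bpos = mean(bpos[inr])))
    }
  }
  new("ColocalizationResult", pairs = pairs, thresholdUm = threshold_um,
      perRegion = per)
}

#' Pair left/right hemisphere densities
#'
#' For region stats computed on a hemisphere-annotated atlas, pairs each
#' base region's left (base ID + offset) and right (base ID) rows and
#' reports the density ratio; regions present on only one side are
#' flagged (`one_sided`), with an infinite ratio where the right side is
#' empty.
#'
#' @param stats a [RegionStats-class] from a hemisphere-annotated atlas.
#' @param offset the hemisphere ID offset (default 1e9).
#' @return data.frame: `base_id`, `name`, left/right counts and densities,
#'   `ratio_left_over_right`, `one_sided`.
#' @export
hemisphereCompare <- function(stats, offset = 1e9) {
  if (!stats@hemisphereAnnotated)
    stop("stats were not computed on a hemisphere-annotated atlas")
  tab <- stats@table
  left <- tab[tab$id >= offset, ]
  right <- tab[tab$id < offset, ]
  base <- sort(union(right$id, left$id - offset))
  li <- match(base + offset, left$id)
  ri <- match(base, right$id)
  name <- ifelse(!is.na(ri), sub("^right ", "", right$name[ri]),
                 sub("^left ", "", left$name[li]))
  lc <- ifelse(is.na(li), NA_integer_, left$count[li])
  rc <- ifelse(is.na(ri), NA_integer_, right$count[ri])
  ld <- ifelse(is.na(li), NA_real_, left$density_per_mm3[li])
  rd <- ifelse(is.na(ri), NA_real_, right$density_per_mm3[ri])
  data.frame(base_id = base, name = name,
             left_count = lc, right_count = rc,
             left_density = ld, right_density = rd,
             ratio_left_over_right = ld / rd,
             one_sided = is.na(li) | is.na(ri),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paint per-region densities into a volume
#'
#' Every voxel takes the density of its region (0 for background or regions
#' missing from the stats), producing the 3D heatmap volume any external
#' viewer can render.
#'
#' @param stats a [RegionStats-class].
#' @param atlas the [LabelAtlas-class] the stats refer to.
#' @return An [ImageVolume-class] of densities (nuclei per mm^3).
#' @export
heatmapVolume <- function(stats, atlas) {
  lab <- atlas@labels
  u <- setdiff(unique(as.vector(lab)), 0)
  key <- u
  if (stats@level == "top")
    key <- .top_ancestor(u, atlas@ontology, atlas@hemisphereOffset)
  dens <- stats@table$density_per_mm3[match(key, stats@table$id)]
  dens[is.na(dens)] <- 0
  lut <- stats::setNames(dens, u)
  out <- array(0, dim(lab))
  nz <- lab != 0
  out[nz] <- lut[as.character(lab[nz])]
  ImageVolume(out, spacing = spacing(atlas), origin = origin(atlas))
}

#' Expected pulse-chase migration distance
#'
#' Displacement expected for cells migrating at a constant speed over the
#' chase interval between label injection and sacrifice (speed x time); at
#' the reported SVZ migration speed of 17.98 um/h a 24-h chase gives
#' 431.52 um.
#'
#' @param speed_um_per_h migration speed (um/h), >= 0.
#' @param chase_h chase duration (h), >= 0.
#' @return distance in um.
#' @export
expectedMigrationDistance <- function(speed_um_per_h, chase_h) {
  if (speed_um_per_h < 0 || chase_h < 0)
    stop("speed and chase duration must be >= 0")
  speed_um_per_h * chase_h
}
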