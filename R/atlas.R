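#' @include utils.R
NULL

.onto_root <- function(onto) onto$id[is.na(onto$parent_structure_id)][1]

# Map region IDs to their top-level ancestor (the child of the root on each
# ID's path). Hemisphere-offset IDs keep their offset. ID 0 stays 0.
.top_ancestor <- function(ids, onto, offset = 1e9) {
  root <- .onto_root(onto)
  parent <- stats::setNames(onto$parent_structure_id, onto$id)
  cache <- new.env()
  top_of <- function(id) {
    key <- as.character(id)
    if (!is.null(cache[[key]])) return(cache[[key]])
    chain <- id
    cur <- id
    repeat {
      p <- parent[[as.character(cur)]]
      if (is.na(p) || p == root) break
      cur <- p
      chain <- c(chain, cur)
      if (length(chain) > nrow(onto)) stop("ontology parent cycle at ID ", id)
    }
    cache[[key]] <- cur
    cur
  }
  vapply(ids, function(id) {
    if (id == 0) return(0)
    side <- 0
    base <- id
    if (id >= offset) { side <- offset; base <- id - offset }
    if (!base %in% onto$id) {
      if (!id %in% onto$id) stop("label ", id, " absent from ontology")
      base <- id; side <- 0
    }
    top_of(base) + side
  }, numeric(1))
}

#' Annotate points with atlas region IDs
#'
#' Looks up the region ID under each normalized point via the half-open
#' voxel convention; `level = "top"` replaces each leaf ID by its top-level
#' ancestor (child of the ontology root). Points outside the brain (or
#' outside the grid) get ID 0.
#'
#' @param points a [NucleusSet-class] tagged "atlas".
#' @param atlas a [LabelAtlas-class].
#' @param level "leaf" or "top".
#' @return Numeric vector of region IDs, one per point.
#' @export
lookupRegions <- function(points, atlas, level = c("leaf", "top")) {
  level <- match.arg(level)
  if (pointSpace(points) != "atlas")
    stop("points must be tagged \"atlas\"; normalize them first")
  idx <- pointToVoxel(coords(points), atlas)
  ids <- rep(0, nrow(idx))
  ok <- !is.na(idx[, 1])
  ids[ok] <- as.numeric(atlas@labels[idx[ok, , drop = FALSE]])
  onto <- .expanded_ontology(atlas)
  in_onto <- ids == 0 |
    ids %in% onto$id |
    (ids >= atlas@hemisphereOffset & (ids - atlas@hemisphereOffset) %in% onto$id)
  if (!all(in_onto))
    stop("label absent from ontology: ", ids[!in_onto][1])
  if (level == "top") ids <- .top_ancestor(ids, onto, atlas@hemisphereOffset)
  ids
}

# Ontology including left-hemisphere mirror records when present.
.expanded_ontology <- function(atlas) atlas@ontology

#' Region volumes in mm^3
#'
#' Voxel counts per region ID times the voxel volume. Volumes over nonzero
#' IDs sum to the brain-mask volume; at `level = "top"` leaf volumes are
#' aggregated up the ontology.
#'
#' @param atlas a [LabelAtlas-class].
#' @param level "leaf" or "top".
#' @return Named numeric vector, mm^3 by region ID.
#' @export
regionVolumes <- function(atlas, level = c("leaf", "top")) {
  level <- match.arg(level)
  vox_mm3 <- prod(spacing(atlas)) * 1e-9
  tab <- table(atlas@labels[atlas@labels != 0])
  ids <- as.numeric(names(tab))
  vols <- as.numeric(tab) * vox_mm3
  if (level == "top") {
    top <- .top_ancestor(ids, atlas@ontology, atlas@hemisphereOffset)
    vols <- tapply(vols, top, sum)
    ids <- as.numeric(names(vols))
    vols <- as.numeric(vols)
  }
  stats::setNames(vols, ids)
}

.shift_neighbours <- function(connectivity) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(off))
  off[s > 0 & (connectivity == 26 | (connectivity == 18 & s <= 2) |
               (connectivity == 6 & s <= 1)), , drop = FALSE]
}

# Logical array: voxels of `arr` equal to `value` having a neighbour equal
# to `adj` under the given connectivity.
.interface_voxels <- function(arr, value, adj, connectivity) {
  dm <- dim(arr)
  res <- array(FALSE, dm)
  is_val <- arr == value
  for (r in seq_len(nrow(.shift_neighbours(connectivity)))) {
    o <- .shift_neighbours(connectivity)[r, ]
    src <- dst <- list()
    for (a in 1:3) {
      if (o[a] >= 0) {
        dst[[a]] <- seq_len(dm[a] - o[a])
        src[[a]] <- seq_len(dm[a] - o[a]) + o[a]
      } else {
        dst[[a]] <- seq_len(dm[a] + o[a]) - o[a]
        src[[a]] <- seq_len(dm[a] + o[a])
      }
    }
    nb <- array(FALSE, dm)
    nb[dst[[1]], dst[[2]], dst[[3]]] <-
      arr[src[[1]], src[[2]], src[[3]]] == adj
    res <- res | (is_val & nb)
  }
  res
}

.add_onto_record <- function(onto, id, acronym, name, parent_id) {
  if (id %in% onto$id)
    stop("custom ID ", id, " already exists in the ontology; refusing to reuse it")
  rbind(onto, data.frame(id = id, acronym = acronym, name = name,
                         parent_structure_id = parent_id,
                         stringsAsFactors = FALSE))
}

#' Annotate the ventricular-zone interface layer
#'
#' Relabels exactly those parent-region voxels that touch the adjacent
#' region (face adjacency by default, so the new region is a genuine
#' one-voxel layer, e.g. the SVZ on the lateral wall of the
#' caudoputamen-like region next to the ventricle) with the reserved custom
#' ID. The grid is only relabeled, never resized. When
#' `exclude_from_parent` is TRUE the new region becomes its own top-level
#' region; when FALSE it is recorded as a child of the parent region, so
#' top-level counts still include it in the parent.
#'
#' @param atlas a [LabelAtlas-class].
#' @param parent_id region whose wall voxels are relabeled.
#' @param adjacent_id region the wall must touch.
#' @param new_id the custom ID (default the atlas's reserved ID, 5).
#' @param exclude_from_parent report the layer separately from the parent
#'   (TRUE) or inside it (FALSE).
#' @param connectivity interface adjacency: 6 (default, single-voxel layer),
#'   18 or 26.
#' @return The annotated [LabelAtlas-class].
#' @export
annotateSvz <- function(atlas, parent_id, adjacent_id,
                        new_id = atlas@customID, exclude_from_parent = TRUE,
                        connectivity = 6L) {
  onto <- atlas@ontology
  if (!parent_id %in% onto$id) stop("parent ID ", parent_id, " not in ontology")
  if (!adjacent_id %in% onto$id) stop("adjacent ID ", adjacent_id, " not in ontology")
  sel <- .interface_voxels(atlas@labels, parent_id, adjacent_id, connectivity)
  if (!any(sel)) stop("no interface voxels between region ", parent_id,
                      " and region ", adjacent_id)
  lab <- atlas@labels
  lab[sel] <- as.integer(new_id)
  parent <- if (exclude_from_parent) .onto_root(onto) else parent_id
  onto <- .add_onto_record(onto, new_id, "SVZ", "subventricular zone", parent)
  initialize(atlas, labels = lab, ontology = onto)
}

#' Annotate a consensus region from replicate masks
#'
#' Voxels positive in at least `min_votes` of the supplied binary masks
#' (e.g. nestin-positive voxels in four or more of seven brains) are
#' relabeled with the custom ID. Only in-brain voxels (nonzero label) are
#' eligible. When `exclude_from_regions` is TRUE the consensus voxels are
#' removed from their original regions (the new ID is its own top-level
#' region); when FALSE the labels are left untouched and the consensus mask
#' is attached as attribute `"consensus_mask"` so counts can be reported
#' both ways.
#'
#' @param atlas a [LabelAtlas-class].
#' @param sample_masks list of 0/1 arrays or [ImageVolume-class]s on the
#'   atlas grid.
#' @param min_votes minimum positive count (default 4).
#' @param new_id custom ID (default the atlas's reserved ID).
#' @param exclude_from_regions see above (default TRUE).
#' @return The annotated [LabelAtlas-class].
#' @export
annotateConsensus <- function(atlas, sample_masks, min_votes = 4L,
                              new_id = atlas@customID,
                              exclude_from_regions = TRUE) {
  n <- length(sample_masks)
  if (min_votes < 1L || min_votes > n)
    stop("min_votes must lie in 1..", n)
  arrs <- lapply(sample_masks, function(m)
    if (is(m, "ImageVolume")) m@data else m)
  for (a in arrs)
    if (!all(dim(a) == dim(atlas@labels)))
      stop("mask geometry does not match the atlas grid")
  votes <- Reduce("+", lapply(arrs, function(a) array(as.integer(a != 0), dim(a))))
  sel <- votes >= min_votes & atlas@labels != 0L
  onto <- .add_onto_record(atlas@ontology, new_id, "CONS", "consensus region",
                           .onto_root(atlas@ontology))
  if (exclude_from_regions) {
    lab <- atlas@labels
    lab[sel] <- as.integer(new_id)
    out <- initialize(atlas, labels = lab, ontology = onto)
  } else {
    out <- initialize(atlas, ontology = onto)
    attr(out, "consensus_mask") <- array(as.integer(sel), dim(sel))
  }
  out
}

#' Split region IDs by hemisphere
#'
#' Adds the hemisphere offset (default 1,000,000,000) to every nonzero
#' label on the "left" half of the midline axis (lower voxel indices); the
#' right hemisphere keeps its original IDs. On an odd-length axis the exact
#' midplane column is assigned to the right side (and a message says so).
#' The ontology is duplicated with "left "/"right " name prefixes.
#'
#' @param atlas a [LabelAtlas-class].
#' @param midline_axis axis in 1:3 (default the atlas's configured one).
#' @param offset ID offset; must exceed every existing ID.
#' @return The hemisphere-annotated [LabelAtlas-class].
#' @export
annotateHemispheres <- function(atlas, midline_axis = atlas@midlineAxis,
                                offset = atlas@hemisphereOffset) {
  onto <- atlas@ontology
  if (any(onto$id >= atlas@hemisphereOffset))
    stop("atlas appears to be hemisphere-annotated already")
  if (offset <= max(onto$id))
    stop("offset must exceed the largest existing ID")
  dm <- dim(atlas@labels)
  n <- dm[midline_axis]
  if (n %% 2L == 1L)
    message("odd midline axis length ", n,
            ": the midplane voxel column is assigned to the right side")
  left <- seq_len(floor(n / 2))
  lab <- atlas@labels
  idx <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
  idx[[midline_axis]] <- left
  blk <- do.call("[", c(list(lab), idx, list(drop = FALSE)))
  blk[blk != 0L] <- blk[blk != 0L] + offset
  lab <- do.call("[<-", c(list(lab), idx, list(blk)))
  right <- onto
  right$name <- paste("right", right$name)
  leftdf <- onto
  leftdf$id <- leftdf$id + offset
  leftdf$parent_structure_id <- leftdf$parent_structure_id + offset
  leftdf$name <- paste("left", onto$name)
  storage.mode(lab) <- "numeric"   # left IDs exceed .Machine$integer.max
  initialize(atlas, labels = lab, ontology = rbind(right, leftdf))
}

# ---- ontology JSON I/O (Allen-style structure graph) ----

.flatten_onto <- function(node, parent = NA) {
  rec <- data.frame(id = node$id,
                    acronym = node$acronym,
                    name = node$name,
                    parent_structure_id =
                      if (is.null(node$parent_structure_id) ||
                          is.na(node$parent_structure_id)) parent
                      else node$parent_structure_id,
                    stringsAsFactors = FALSE)
  kids <- node$children
  if (length(kids))
    rec <- rbind(rec, do.call(rbind, lapply(kids, .flatten_onto, parent = node$id)))
  rec
}

#' Read an Allen-style structure-graph JSON ontology
#'
#' @param path JSON file with nested records (fields id, acronym, name,
#'   parent_structure_id, children).
#' @return Flat data.frame ontology; duplicate IDs or orphan parent links
#'   raise a named error.
#' @export
readOntology <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  roots <- if (!is.null(x$id)) list(x) else x
  onto <- do.call(rbind, lapply(roots, .flatten_onto))
  onto$id <- as.numeric(onto$id)
  onto$parent_structure_id <- as.numeric(onto$parent_structure_id)
  if (anyDuplicated(onto$id))
    stop("duplicate ontology ID: ", onto$id[duplicated(onto$id)][1])
  bad <- !is.na(onto$parent_structure_id) &
    !(onto$parent_structure_id %in% onto$id)
  if (any(bad))
    stop("orphan parent link: record ", onto$id[bad][1],
         " references missing parent ", onto$parent_structure_id[bad][1])
  onto
}

.nest_onto <- function(onto, id) {
  row <- onto[onto$id == id, ]
  kids <- onto$id[!is.na(onto$parent_structure_id) &
                  onto$parent_structure_id == id]
  node <- list(id = row$id, acronym = row$acronym, name = row$name,
               parent_structure_id =
                 if (is.na(row$parent_structure_id)) NA else row$parent_structure_id,
               children = lapply(kids, function(k) .nest_onto(onto, k)))
  node
}

#' Write an ontology as nested structure-graph JSON
#'
#' @param onto flat ontology data.frame.
#' @param path output JSON path.
#' @return `path`, invisibly. Reading the file back yields a structurally
#'   identical tree.
#' @export
writeOntology <- function(onto, path) {
  if (anyDuplicated(onto$id))
    stop("duplicate ontology ID: ", onto$id[duplicated(onto$id)][1])
  orphan <- !is.na(onto$parent_structure_id) &
    !(onto$parent_structure_id %in% onto$id)
  if (any(orphan))
    stop("orphan parent link: record ", onto$id[orphan][1],
         " references missing parent ", onto$parent_structure_id[orphan][1])
  roots <- onto$id[is.na(onto$parent_structure_id)]
  tree <- lapply(roots, function(r) .nest_onto(onto, r))
  if (length(tree) == 1L) tree <- tree[[1]]
  jsonlite::write_json(tree, path, auto_unbox = TRUE, na = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}
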