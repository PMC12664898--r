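#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib clickmap3d, .registration = TRUE
NULL

.valid_spacing <- function(spacing) {
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    return("'spacing' must be 3 finite positive values (um)")
  NULL
}

#' 3D intensity volume with physical geometry
#'
#' A scalar 3D grid with per-axis voxel spacing (um) and a physical origin.
#' The voxel at index (1,1,1) covers the half-open physical box
#' `[origin, origin + spacing)`; its centre sits at `origin + spacing/2`.
#'
#' @slot data 3D numeric array of intensities (arbitrary units).
#' @slot spacing numeric(3), voxel edge length per axis in um.
#' @slot origin numeric(3), physical coordinate (um) of the corner of voxel
#'   (1,1,1) (the most left-anterior-superior voxel maps to physical 0).
#' @export
setClass("ImageVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "'data' must be a 3D array")
    msg <- c(msg, .valid_spacing(object@spacing))
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "'origin' must be 3 finite values (um)")
    if (anyNA(object@data) || any(!is.finite(object@data)))
      msg <- c(msg, "'data' must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct an ImageVolume
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in um, recycled to length 3.
#' @param origin physical origin in um, recycled to length 3.
#' @return An [ImageVolume-class] object.
#' @export
ImageVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("ImageVolume", data = data, spacing = rep_len(as.numeric(spacing), 3L),
      origin = rep_len(as.numeric(origin), 3L))
}

#' Integer label atlas with region ontology
#'
#' A voxel grid of integer region IDs (0 = outside the brain) together with
#' an Allen-style hierarchical ontology (structure graph) stored as a flat
#' table. Custom annotations reserve one ID (default 5) and hemisphere
#' annotation adds a fixed offset (default 1e9) to left-side IDs.
#'
#' @slot labels 3D integer array of region IDs; 0 = outside brain.
#' @slot spacing numeric(3), um per voxel.
#' @slot origin numeric(3), um.
#' @slot ontology data.frame with columns `id`, `acronym`, `name`,
#'   `parent_structure_id` (NA for the root).
#' @slot customID reserved integer ID for custom annotations.
#' @slot hemisphereOffset numeric, the left-hemisphere ID offset.
#' @slot midlineAxis integer in 1:3, the axis split by hemisphere annotation.
#' @export
setClass("LabelAtlas",
  representation(labels = "array", spacing = "numeric", origin = "numeric",
                 ontology = "data.frame", customID = "integer",
                 hemisphereOffset = "numeric", midlineAxis = "integer"),
  prototype(customID = 5L, hemisphereOffset = 1e9, midlineAxis = 3L,
            spacing = c(10, 10, 10), origin = c(0, 0, 0)),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@labels)) != 3L)
      msg <- c(msg, "'labels' must be a 3D array")
    msg <- c(msg, .valid_spacing(object@spacing))
    need <- c("id", "acronym", "name", "parent_structure_id")
    if (!all(need %in% names(object@ontology)))
      msg <- c(msg, sprintf("ontology must have columns %s",
                            paste(need, collapse = ", ")))
    else {
      if (anyDuplicated(object@ontology$id))
        msg <- c(msg, "ontology IDs must be unique")
      ids <- object@ontology$id
      used <- setdiff(unique(as.vector(object@labels)), 0)
      base_used <- ifelse(used >= object@hemisphereOffset,
                          used - object@hemisphereOffset, used)
      if (!all(base_used %in% ids))
        msg <- c(msg, sprintf("labels absent from ontology: %s",
                              paste(head(setdiff(base_used, ids), 5), collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a LabelAtlas
#'
#' @param labels 3D integer array (0 = outside brain).
#' @param spacing um per voxel (recycled to 3).
#' @param ontology flat structure-graph data.frame (see [LabelAtlas-class]).
#' @param origin physical origin, um.
#' @param customID reserved ID for custom annotations (default 5).
#' @param hemisphereOffset left-hemisphere ID offset (default 1,000,000,000).
#' @param midlineAxis axis (1:3) split by hemisphere annotation.
#' @return A [LabelAtlas-class] object.
#' @export
LabelAtlas <- function(labels, spacing, ontology, origin = c(0, 0, 0),
                       customID = 5L, hemisphereOffset = 1e9, midlineAxis = 3L) {
  storage.mode(labels) <- "integer"
  new("LabelAtlas", labels = labels,
      spacing = rep_len(as.numeric(spacing), 3L),
      origin = rep_len(as.numeric(origin), 3L),
      ontology = ontology, customID = as.integer(customID),
      hemisphereOffset = as.numeric(hemisphereOffset),
      midlineAxis = as.integer(midlineAxis))
}

#' Set of nuclear centre coordinates
#'
#' Physical point coordinates (um) of detected or simulated nuclear centres,
#' tagged with the space they live in ("sample" = as imaged, "atlas" =
#' normalized to the reference atlas), the image channel, the size in voxels
#' of the connected component each centre came from, and a flag for points
#' that landed outside the atlas grid during normalization.
#'
#' @slot coords n x 3 numeric matrix (um), columns x/y/z.
#' @slot space "sample" or "atlas".
#' @slot channel channel tag, e.g. "edu", "marker".
#' @slot componentSize integer(n), voxels in the source component (NA if
#'   unknown, e.g. simulated truth).
#' @slot outside logical(n), TRUE if the point fell outside the atlas grid
#'   and was clamped during transformation.
#' @export
setClass("NucleusSet",
  representation(coords = "matrix", space = "character", channel = "character",
                 componentSize = "integer", outside = "logical"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@coords) != 3L) msg <- c(msg, "'coords' must have 3 columns")
    if (nrow(object@coords) && any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (!object@space %in% c("sample", "atlas"))
      msg <- c(msg, "'space' must be \"sample\" or \"atlas\"")
    n <- nrow(object@coords)
    if (length(object@componentSize) != n || length(object@outside) != n)
      msg <- c(msg, "per-point slots must match nrow(coords)")
    if (length(msg)) msg else TRUE
  })

#' Construct a NucleusSet
#'
#' @param coords n x 3 matrix of physical coordinates in um.
#' @param space "sample" or "atlas".
#' @param channel channel tag.
#' @param componentSize per-point component size in voxels (NA if unknown).
#' @param outside per-point outside-atlas flag.
#' @return A [NucleusSet-class] object.
#' @export
NucleusSet <- function(coords, space = "sample", channel = "edu",
                       componentSize = rep(NA_integer_, nrow(coords)),
                       outside = rep(FALSE, nrow(coords))) {
  coords <- matrix(as.numeric(coords), ncol = 3L,
                   dimnames = list(NULL, c("x_um", "y_um", "z_um")))
  new("NucleusSet", coords = coords, space = space, channel = channel,
      componentSize = as.integer(componentSize), outside = outside)
}

#' Affine transform with explicit direction
#'
#' `y = linear %*% x + translation`, with a mandatory direction tag saying
#' which way the map runs. The atlas-normalization convention is to store
#' the registration's forward (atlas to sample) affine and apply it
#' inversely to sample-space points.
#'
#' @slot linear 3 x 3 invertible matrix.
#' @slot translation numeric(3), um.
#' @slot direction "atlas->sample" or "sample->atlas".
#' @export
setClass("AffineTransform",
  representation(linear = "matrix", translation = "numeric",
                 direction = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@linear) == c(3, 3))) msg <- c(msg, "'linear' must be 3x3")
    else if (abs(det(object@linear)) < 1e-12 || !all(is.finite(object@linear)))
      msg <- c(msg, "'linear' must be finite and invertible")
    if (length(object@translation) != 3L) msg <- c(msg, "'translation' must be length 3")
    if (!object@direction %in% c("atlas->sample", "sample->atlas"))
      msg <- c(msg, "'direction' must be \"atlas->sample\" or \"sample->atlas\"")
    if (length(msg)) msg else TRUE
  })

#' Construct an AffineTransform
#' @param linear 3x3 matrix.
#' @param translation numeric(3) um.
#' @param direction "atlas->sample" or "sample->atlas".
#' @return An [AffineTransform-class] object.
#' @export
AffineTransform <- function(linear = diag(3), translation = c(0, 0, 0),
                            direction = "atlas->sample") {
  new("AffineTransform", linear = linear,
      translation = as.numeric(translation), direction = direction)
}

#' Dense displacement field on the atlas grid
#'
#' Voxel grid of 3-component displacement vectors in um, sharing the
#' reference atlas geometry. The field stored here is the *inverse* warp:
#' it is applied directly (added) to affinely pre-aligned points to finish
#' the sample-to-atlas mapping.
#'
#' @slot displacements 4D array `[nx, ny, nz, 3]`, um.
#' @slot spacing numeric(3), um.
#' @slot origin numeric(3), um.
#' @export
setClass("DeformationField",
  representation(displacements = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@displacements)
    if (length(d) != 4L || d[4] != 3L)
      msg <- c(msg, "'displacements' must be [nx, ny, nz, 3]")
    if (any(!is.finite(object@displacements)))
      msg <- c(msg, "displacements must be finite")
    msg <- c(msg, .valid_spacing(object@spacing))
    if (length(msg)) msg else TRUE
  })

#' Construct a DeformationField
#' @param displacements 4D array `[nx, ny, nz, 3]` of um displacements.
#' @param spacing um per voxel (recycled to 3).
#' @param origin physical origin, um.
#' @return A [DeformationField-class] object.
#' @export
DeformationField <- function(displacements, spacing, origin = c(0, 0, 0)) {
  new("DeformationField", displacements = displacements,
      spacing = rep_len(as.numeric(spacing), 3L),
      origin = rep_len(as.numeric(origin), 3L))
}

setClassUnion("DeformationFieldOrNULL", c("DeformationField", "NULL"))

#' Affine + deformation transform chain
#'
#' The mapping the normalization stage consumes: an affine stored in its
#' registration-forward (atlas to sample) direction and used inversely,
#' followed by an inverse deformation field applied directly in atlas
#' space. `field` may be NULL for an affine-only chain.
#'
#' @slot affine an [AffineTransform-class] (direction "atlas->sample").
#' @slot field a [DeformationField-class] or NULL.
#' @export
setClass("TransformChain",
  representation(affine = "AffineTransform", field = "DeformationFieldOrNULL"),
  validity = function(object) {
    if (object@affine@direction != "atlas->sample")
      "chain affine must be stored in the \"atlas->sample\" direction (it is used inversely)"
    else TRUE
  })

#' Construct a TransformChain
#' @param affine an [AffineTransform-class] with direction "atlas->sample".
#' @param field optional [DeformationField-class] (inverse warp, atlas grid).
#' @return A [TransformChain-class] object.
#' @export
TransformChain <- function(affine = AffineTransform(), field = NULL) {
  new("TransformChain", affine = affine, field = field)
}

#' Random-forest pixel classifier for signal/noise separation
#'
#' Wraps a trained random forest over multi-scale voxel features (Gaussian
#' smoothing, gradient magnitude, Laplacian), or a plain intensity threshold
#' when `mode = "threshold"` (flagged in provenance).
#'
#' @slot forest the fitted ranger forest (or NULL in threshold mode).
#' @slot featureSpec data.frame with columns `feature`, `sigma_um`.
#' @slot threshold numeric threshold for the fallback mode.
#' @slot trainSeed integer seed used for training.
#' @slot provenance list: mode, per-class training voxel counts, forest
#'   parameters.
#' @export
setClass("PixelClassifierModel",
  representation(forest = "ANY", featureSpec = "data.frame",
                 threshold = "numeric", trainSeed = "integer",
                 provenance = "list"),
  validity = function(object) {
    if (nrow(object@featureSpec) < 1L) "at least one feature is required" else TRUE
  })

#' Per-region quantification table
#'
#' Counts, volumes, densities and fractions per atlas region, with points
#' mapped outside the brain (ID 0) reported in a dedicated unassigned count
#' and excluded from fractions.
#'
#' @slot table data.frame: `id`, `acronym`, `name`, `count`, `volume_mm3`,
#'   `density_per_mm3`, `fraction`.
#' @slot unassigned integer, points with region ID 0.
#' @slot level "leaf" or "top".
#' @slot hemisphereAnnotated logical.
#' @export
setClass("RegionStats",
  representation(table = "data.frame", unassigned = "integer",
                 level = "character", hemisphereAnnotated = "logical"),
  validity = function(object) {
    tab <- object@table
    need <- c("id", "count", "volume_mm3", "density_per_mm3", "fraction")
    if (!all(need %in% names(tab))) return("missing RegionStats columns")
    if (nrow(tab) && any(tab$density_per_mm3 < 0)) return("densities must be >= 0")
    TRUE
  })

#' Detection validation report
#'
#' Object-level accuracy of signal/noise discrimination and cluster-level
#' accuracy of nucleus counting against a simulated ground-truth scene.
#'
#' @slot signalNoiseAccuracy fraction of ground-truth objects (nuclei and
#'   speckles) assigned the correct class.
#' @slot countAccuracy fraction of ground-truth clusters whose predicted
#'   nucleus count equals the true count.
#' @slot strata data.frame breakdown (per object kind / cluster size).
#' @export
setClass("ValidationReport",
  representation(signalNoiseAccuracy = "numeric", countAccuracy = "numeric",
                 strata = "data.frame"),
  validity = function(object) {
    ok <- function(x) length(x) == 1L && (is.na(x) || (x >= 0 && x <= 1))
    if (!ok(object@signalNoiseAccuracy) || !ok(object@countAccuracy))
      "accuracies must lie in [0, 1]" else TRUE
  })

#' Colocalization matching result
#'
#' One-to-one matches between two point sets under a strict distance
#' threshold, plus per-region tallies of double- and single-positive nuclei.
#'
#' @slot pairs data.frame: `indexA`, `indexB`, `distance_um`.
#' @slot thresholdUm the strict matching threshold (um).
#' @slot perRegion data.frame of per-region A+/B+ and A-/B+ counts and the
#'   A+-within-B+ ratio (NA where no B+ nuclei fall in a region).
#' @export
setClass("ColocalizationResult",
  representation(pairs = "data.frame", thresholdUm = "numeric",
                 perRegion = "data.frame"),
  validity = function(object) {
    if (nrow(object@pairs) &&
        any(object@pairs$distance_um >= object@thresholdUm))
      "all matched distances must be strictly below the threshold" else TRUE
  })
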