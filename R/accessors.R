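#' @include AllGenerics.R
NULL

#' @describeIn ImageVolume voxel spacing in um.
#' @param x,object an ImageVolume.
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)

#' @describeIn ImageVolume physical origin in um.
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)

#' @describeIn ImageVolume the 3D intensity array.
#' @export
setMethod("volumeData", "ImageVolume", function(x) x@data)

#' @describeIn ImageVolume grid dimensions.
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@data))

#' @describeIn LabelAtlas voxel spacing in um.
#' @param x,object a LabelAtlas.
#' @export
setMethod("spacing", "LabelAtlas", function(x) x@spacing)

#' @describeIn LabelAtlas physical origin in um.
#' @export
setMethod("origin", "LabelAtlas", function(x) x@origin)

#' @describeIn LabelAtlas the 3D integer region-ID array.
#' @export
setMethod("atlasLabels", "LabelAtlas", function(x) x@labels)

#' @describeIn LabelAtlas the flat ontology table.
#' @export
setMethod("ontology", "LabelAtlas", function(x) x@ontology)

#' @describeIn LabelAtlas grid dimensions.
#' @export
setMethod("dim", "LabelAtlas", function(x) dim(x@labels))

#' @describeIn NucleusSet the n x 3 coordinate matrix (um).
#' @param x,object a NucleusSet.
#' @export
setMethod("coords", "NucleusSet", function(x) x@coords)

#' @describeIn NucleusSet the space tag.
#' @export
setMethod("pointSpace", "NucleusSet", function(x) x@space)

#' @describeIn NucleusSet per-point component sizes.
#' @export
setMethod("componentSizes", "NucleusSet", function(x) x@componentSize)

#' @describeIn NucleusSet number of points.
#' @export
setMethod("length", "NucleusSet", function(x) nrow(x@coords))

#' @describeIn NucleusSet subset points.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "NucleusSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x, coords = x@coords[i, , drop = FALSE],
             componentSize = x@componentSize[i], outside = x@outside[i])
})

#' @describeIn RegionStats the per-region table.
#' @param x,object a RegionStats.
#' @export
setMethod("regionTable", "RegionStats", function(x) x@table)

#' @describeIn ColocalizationResult the per-region tally table.
#' @param x,object a ColocalizationResult.
#' @export
setMethod("regionTable", "ColocalizationResult", function(x) x@perRegion)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume: %d x %d x %d voxels, spacing (%s) um\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "LabelAtlas", function(object) {
  d <- dim(object@labels)
  nreg <- length(setdiff(unique(as.vector(object@labels)), 0))
  cat(sprintf("LabelAtlas: %d x %d x %d voxels, spacing (%s) um\n",
              d[1], d[2], d[3], paste(signif(object@spacing, 4), collapse = ", ")))
  cat(sprintf("  %d region IDs in use, ontology of %d structures\n",
              nreg, nrow(object@ontology)))
})

setMethod("show", "NucleusSet", function(object) {
  cat(sprintf("NucleusSet: %d points in %s space (channel \"%s\")\n",
              nrow(object@coords), object@space, object@channel))
  if (any(object@outside))
    cat(sprintf("  %d points flagged outside the atlas grid\n",
                sum(object@outside)))
})

setMethod("show", "AffineTransform", function(object) {
  cat(sprintf("AffineTransform (%s)\n", object@direction))
  print(signif(cbind(object@linear, t = object@translation), 5))
})

setMethod("show", "TransformChain", function(object) {
  cat("TransformChain: affine (atlas->sample, used inversely)",
      if (is.null(object@field)) "with no deformation field\n"
      else "+ inverse deformation field applied directly\n")
})

setMethod("show", "RegionStats", function(object) {
  cat(sprintf("RegionStats (%s level): %d regions, %d nuclei assigned, %d unassigned\n",
              object@level, nrow(object@table), sum(object@table$count),
              object@unassigned))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: signal/noise accuracy %.3f, count accuracy %.3f\n",
              object@signalNoiseAccuracy, object@countAccuracy))
})

setMethod("show", "ColocalizationResult", function(object) {
  cat(sprintf("ColocalizationResult: %d matched pairs (distance < %g um)\n",
              nrow(object@pairs), object@thresholdUm))
})

#' @describeIn DeformationField voxel spacing in um.
#' @param x,object a DeformationField.
#' @export
setMethod("spacing", "DeformationField", function(x) x@spacing)

#' @describeIn DeformationField physical origin in um.
#' @export
setMethod("origin", "DeformationField", function(x) x@origin)

#' @describeIn DeformationField grid dimensions (without the component axis).
#' @export
setMethod("dim", "DeformationField", function(x) dim(x@displacements)[1:3])

setMethod("show", "DeformationField", function(object) {
  d <- dim(object@displacements)
  mx <- sqrt(max(rowSums(matrix(object@displacements, ncol = 3)^2)))
  cat(sprintf("DeformationField: %d x %d x %d grid, max |displacement| %.3g um\n",
              d[1], d[2], d[3], mx))
})
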