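#' @include AllClasses.R
NULL

#' Voxel spacing in um
#' @param x an object with grid geometry.
#' @return numeric(3) spacing in um.
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' Physical origin in um
#' @param x an object with grid geometry.
#' @return numeric(3) origin in um.
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' Raw voxel data
#' @param x an [ImageVolume-class].
#' @return the 3D array of intensities.
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))

#' Region-ID grid of a label atlas
#' @param x a [LabelAtlas-class].
#' @return the 3D integer array of region IDs.
#' @export
setGeneric("atlasLabels", function(x) standardGeneric("atlasLabels"))

#' Flat ontology table of a label atlas
#' @param x a [LabelAtlas-class].
#' @return data.frame with id, acronym, name, parent_structure_id.
#' @export
setGeneric("ontology", function(x) standardGeneric("ontology"))

#' Point coordinates in um
#' @param x a [NucleusSet-class].
#' @return n x 3 numeric matrix.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Coordinate space tag ("sample" or "atlas")
#' @param x a [NucleusSet-class].
#' @return character scalar.
#' @export
setGeneric("pointSpace", function(x) standardGeneric("pointSpace"))

#' Per-point connected-component sizes (voxels)
#' @param x a [NucleusSet-class].
#' @return integer vector.
#' @export
setGeneric("componentSizes", function(x) standardGeneric("componentSizes"))

#' Per-region statistics table
#' @param x a [RegionStats-class] or [ColocalizationResult-class].
#' @return data.frame.
#' @export
setGeneric("regionTable", function(x) standardGeneric("regionTable"))
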