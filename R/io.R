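#' @include AllClasses.R
NULL

# ---- NRRD ----------------------------------------------------------------
# Minimal NRRD0004 reader/writer (raw or gzip encoding, little endian),
# enough for label atlases and scalar volumes.

.nrrd_types <- c(uchar = "integer", "unsigned char" = "integer",
                 short = "integer", "signed short" = "integer",
                 int = "integer", "signed int" = "integer",
                 float = "double", double = "double")
.nrrd_sizes <- c(uchar = 1L, "unsigned char" = 1L, short = 2L,
                 "signed short" = 2L, int = 4L, "signed int" = 4L,
                 float = 4L, double = 8L)

#' Write a volume or label atlas as NRRD
#'
#' @param x an [ImageVolume-class], [LabelAtlas-class] or 3D array.
#' @param path output file.
#' @param encoding "gzip" (default) or "raw".
#' @param type NRRD sample type; default "float" for intensity data and
#'   "int" for label data.
#' @return `path`, invisibly.
#' @export
writeNrrd <- function(x, path, encoding = c("gzip", "raw"), type = NULL) {
  encoding <- match.arg(encoding)
  if (is(x, "LabelAtlas")) {
    arr <- x@labels; sp <- spacing(x); or <- origin(x)
    if (is.null(type)) type <- "int"
  } else if (is(x, "ImageVolume")) {
    arr <- x@data; sp <- spacing(x); or <- origin(x)
    if (is.null(type)) type <- "float"
  } else {
    arr <- x; sp <- c(1, 1, 1); or <- c(0, 0, 0)
    if (is.null(type)) type <- if (is.integer(arr)) "int" else "float"
  }
  dm <- dim(arr)
  hdr <- c("NRRD0004",
           sprintf("type: %s", type),
           "dimension: 3",
           sprintf("sizes: %d %d %d", dm[1], dm[2], dm[3]),
           sprintf("spacings: %.10g %.10g %.10g", sp[1], sp[2], sp[3]),
           sprintf("axis mins: %.10g %.10g %.10g", or[1], or[2], or[3]),
           "endian: little",
           sprintf("encoding: %s", encoding),
           "")
  vals <- as.vector(arr)
  size <- .nrrd_sizes[[type]]
  raw_payload <- if (.nrrd_types[[type]] == "integer")
    writeBin(as.integer(vals), raw(), size = size, endian = "little")
  else writeBin(as.numeric(vals), raw(), size = size, endian = "little")
  if (encoding == "gzip") raw_payload <- memCompress(raw_payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(raw_payload, con)
  invisible(path)
}

#' Read an NRRD volume
#'
#' @param path NRRD file (raw or gzip encoding).
#' @return An [ImageVolume-class] (integer content preserved in `data`).
#' @export
readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L || ln == "") break
    if (startsWith(ln, "#")) next
    kv <- strsplit(ln, ": ", fixed = TRUE)[[1]]
    fields[[kv[1]]] <- kv[2]
  }
  type <- fields$type
  if (is.null(.nrrd_types[[type]])) stop("unsupported NRRD type: ", type)
  dm <- as.integer(strsplit(fields$sizes, " ")[[1]])
  sp <- if (!is.null(fields$spacings))
    as.numeric(strsplit(fields$spacings, " ")[[1]]) else rep(1, length(dm))
  or <- if (!is.null(fields$`axis mins`))
    as.numeric(strsplit(fields$`axis mins`, " ")[[1]]) else rep(0, length(dm))
  payload <- readBin(con, raw(), n = file.info(path)$size)
  if (identical(fields$encoding, "gzip"))
    payload <- memDecompress(payload, type = "gzip")
  else if (!identical(fields$encoding, "raw"))
    stop("unsupported NRRD encoding: ", fields$encoding)
  n <- prod(dm)
  size <- .nrrd_sizes[[type]]
  vals <- if (.nrrd_types[[type]] == "integer")
    readBin(payload, "integer", n = n, size = size, endian = "little",
            signed = size > 1L)
  else readBin(payload, "double", n = n, size = size, endian = "little")
  arr <- array(vals, dm)
  ImageVolume(arr, spacing = sp, origin = or)
}

#' Read an NRRD label volume plus ontology into a LabelAtlas
#'
#' @param nrrd_path integer NRRD label volume.
#' @param ontology_path structure-graph JSON (see [readOntology()]).
#' @param ... passed to [LabelAtlas()].
#' @return A [LabelAtlas-class].
#' @export
readLabelAtlas <- function(nrrd_path, ontology_path, ...) {
  v <- readNrrd(nrrd_path)
  LabelAtlas(array(as.integer(round(v@data)), dim(v@data)),
             spacing = spacing(v), ontology = readOntology(ontology_path),
             origin = origin(v), ...)
}

# ---- TIFF ----------------------------------------------------------------

#' Write a volume as a multi-page 32-bit TIFF
#'
#' Pages run along the third axis. TIFF carries no voxel spacing and the
#' float format is normalized to [0, 1], so spacing, origin and the
#' intensity scale go into a JSON sidecar (`<path>.meta.json`) that
#' [readVolumeTiff()] consumes.
#'
#' @param volume an [ImageVolume-class].
#' @param path output .tif path.
#' @return `path`, invisibly.
#' @export
writeVolumeTiff <- function(volume, path) {
  arr <- volume@data
  mx <- max(arr, 1e-12)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(spacing_um = spacing(volume),
                            origin_um = origin(volume),
                            intensity_scale = mx),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack as a volume
#'
#' @param path .tif path written by [writeVolumeTiff()] (or any stack; in
#'   that case supply `spacing_um`).
#' @param spacing_um spacing override when no sidecar exists.
#' @return An [ImageVolume-class].
#' @export
readVolumeTiff <- function(path, spacing_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  meta_path <- paste0(path, ".meta.json")
  sp <- spacing_um %||% c(1, 1, 1)
  or <- c(0, 0, 0)
  if (file.exists(meta_path)) {
    meta <- jsonlite::fromJSON(meta_path)
    arr <- arr * meta$intensity_scale
    sp <- meta$spacing_um
    or <- meta$origin_um
  }
  ImageVolume(arr, spacing = sp, origin = or)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- NIfTI deformation field --------------------------------------------

#' Write a deformation field as 4D NIfTI
#'
#' Stores the three displacement components (um) along the fourth
#' dimension.
#'
#' @param field a [DeformationField-class].
#' @param path output .nii or .nii.gz path.
#' @return `path`, invisibly.
#' @export
writeDeformationField <- function(field, path) {
  img <- RNifti::asNifti(field@displacements)
  RNifti::pixdim(img) <- c(field@spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4D NIfTI deformation field
#'
#' @param path .nii / .nii.gz with dims (nx, ny, nz, 3).
#' @param origin_um physical origin (default 0).
#' @return A [DeformationField-class].
#' @export
readDeformationField <- function(path, origin_um = c(0, 0, 0)) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 5L) arr <- arr[, , , 1, ]  # ITK-style vector images
  sp <- attr(img, "pixdim")[1:3]
  DeformationField(array(arr, c(dim(arr)[1:3], 3L)), spacing = sp,
                   origin = origin_um)
}

# ---- affine text format --------------------------------------------------

#' Write an affine transform as a 12-number text file
#'
#' Line 1 is a direction header (`# direction: atlas->sample`); the
#' remaining lines carry the 3x3 linear part row by row, then the
#' translation (um).
#'
#' @param a an [AffineTransform-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAffineText <- function(a, path) {
  lines <- c(sprintf("# direction: %s", a@direction),
             apply(a@linear, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             paste(sprintf("%.17g", a@translation), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read an affine transform text file
#'
#' @param path file written by [writeAffineText()].
#' @return An [AffineTransform-class].
#' @export
readAffineText <- function(path) {
  lines <- readLines(path)
  dir_line <- grep("^# direction:", lines, value = TRUE)
  if (!length(dir_line)) stop("affine file lacks a direction header")
  direction <- trimws(sub("^# direction:", "", dir_line[1]))
  nums <- lapply(strsplit(trimws(lines[!startsWith(lines, "#")]), "\\s+"),
                 as.numeric)
  vals <- unlist(nums)
  if (length(vals) != 12L) stop("affine file must hold 12 numbers")
  AffineTransform(matrix(vals[1:9], 3, byrow = TRUE), vals[10:12],
                  direction = direction)
}

# ---- point tables --------------------------------------------------------

#' Write a NucleusSet as CSV
#'
#' Columns: x_um, y_um, z_um, component_size, channel, space, outside.
#'
#' @param points a [NucleusSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeNucleusCsv <- function(points, path) {
  df <- data.frame(coords(points),
                   component_size = componentSizes(points),
                   channel = points@channel, space = pointSpace(points),
                   outside = points@outside)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a NucleusSet from CSV
#'
#' @param path CSV written by [writeNucleusCsv()] (or any table with
#'   x_um/y_um/z_um columns).
#' @return A [NucleusSet-class].
#' @export
readNucleusCsv <- function(path) {
  df <- utils::read.csv(path)
  NucleusSet(as.matrix(df[, c("x_um", "y_um", "z_um")]),
             space = if ("space" %in% names(df)) df$space[1] else "sample",
             channel = if ("channel" %in% names(df)) df$channel[1] else "edu",
             componentSize = if ("component_size" %in% names(df))
               df$component_size else rep(NA_integer_, nrow(df)),
             outside = if ("outside" %in% names(df)) df$outside
                       else rep(FALSE, nrow(df)))
}

#' Write scene ground truth as CSV
#'
#' Nuclei (kind "nucleus", with cluster IDs) and injected speckles (kind
#' "speckle", positioned at voxel centres of `geometry`).
#'
#' @param scene a [SyntheticScene-class].
#' @param path output CSV path.
#' @param geometry rendered [ImageVolume-class] for speckle positions
#'   (NULL drops speckles).
#' @return `path`, invisibly.
#' @export
writeGroundTruthCsv <- function(scene, path, geometry = NULL) {
  nuc <- scene@nuclei
  df <- data.frame(x_um = nuc$x_um, y_um = nuc$y_um, z_um = nuc$z_um,
                   cluster_id = nuc$cluster_id, kind = "nucleus")
  if (!is.null(geometry) && nrow(scene@speckles)) {
    sc <- .voxel_centers(as.matrix(scene@speckles), spacing(geometry),
                         origin(geometry))
    df <- rbind(df, data.frame(x_um = sc[, 1], y_um = sc[, 2], z_um = sc[, 3],
                               cluster_id = NA_integer_, kind = "speckle"))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
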