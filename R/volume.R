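#' @include utils.R
NULL

#' Gaussian smoothing of a volume
#'
#' Separable 3D Gaussian filter with reflective boundaries; sigma is given
#' in physical um and converted per axis to voxels.
#'
#' @param volume an [ImageVolume-class].
#' @param sigma_um physical standard deviation (um), scalar or length 3.
#' @return A smoothed [ImageVolume-class].
#' @export
gaussianSmooth <- function(volume, sigma_um) {
  sigma_um <- rep_len(as.numeric(sigma_um), 3L)
  if (any(sigma_um < 0)) stop("'sigma_um' must be >= 0")
  sv <- sigma_um / spacing(volume)
  out <- cpp_gaussian_blur(as.numeric(volume@data), .as_dim(volume@data), sv)
  initialize(volume, data = array(out, dim(volume@data)))
}

#' Rolling-background subtraction
#'
#' Estimates the slowly varying background as a wide Gaussian blur and
#' subtracts it, clipping at zero. The blur scale must be well above the
#' nuclear radius or nuclei themselves are flattened; a warning is issued
#' when it is not.
#'
#' @param volume an [ImageVolume-class].
#' @param sigma_um background scale in um; must exceed `nucleus_radius_um`.
#' @param nucleus_radius_um expected nuclear radius used for the contract
#'   check (default 5 um, a 10-um nucleus).
#' @return Background-subtracted [ImageVolume-class] (non-negative).
#' @export
subtractBackground <- function(volume, sigma_um, nucleus_radius_um = 5) {
  if (length(sigma_um) != 1L || !is.finite(sigma_um) || sigma_um <= 0)
    stop("'sigma_um' must be a single positive value")
  if (sigma_um <= nucleus_radius_um)
    warning("background sigma (", sigma_um,
            " um) does not exceed the nuclear radius (", nucleus_radius_um,
            " um); nuclei will be attenuated")
  bg <- gaussianSmooth(volume, sigma_um)
  initialize(volume, data = pmax(volume@data - bg@data, 0))
}

# Block-mean reduction by integer factors; trailing voxels that do not fill
# a complete block are dropped.
.block_mean <- function(arr, f) {
  d <- dim(arr)
  nd <- d %/% f
  arr <- arr[seq_len(nd[1] * f[1]), seq_len(nd[2] * f[2]), seq_len(nd[3] * f[3]),
             drop = FALSE]
  dim(arr) <- c(f[1], nd[1], f[2], nd[2], f[3], nd[3])
  out <- apply(arr, c(2, 4, 6), mean)
  array(out, nd)
}

#' Reduce the spatial resolution of a volume
#'
#' Anti-aliased resampling to a coarser voxel spacing, emulating the
#' acquisition-side reduction from the native resolution to the working
#' resolution at which nuclei remain individually recognizable. Integer
#' spacing ratios use exact block means; non-integer ratios fall back to
#' Gaussian pre-smoothing plus trilinear interpolation (and say so).
#'
#' @param volume an [ImageVolume-class].
#' @param target_spacing_um desired spacing (um), scalar or length 3; must be
#'   >= the current spacing.
#' @return The resampled [ImageVolume-class]; mean intensity (hence total
#'   integrated intensity) is conserved to within interpolation error.
#' @export
downsampleVolume <- function(volume, target_spacing_um) {
  target <- rep_len(as.numeric(target_spacing_um), 3L)
  sp <- spacing(volume)
  if (any(target < sp - 1e-9))
    stop("target spacing must be >= current spacing on every axis")
  if (all(abs(target - sp) < 1e-9)) return(volume)
  ratio <- target / sp
  if (all(abs(ratio - round(ratio)) < 1e-9)) {
    f <- as.integer(round(ratio))
    out <- .block_mean(volume@data, f)
  } else {
    message("non-integer spacing ratio (", paste(signif(ratio, 4), collapse = ", "),
            "); using Gaussian pre-smoothing + trilinear interpolation")
    sm <- gaussianSmooth(volume, 0.5 * (target - sp))
    nd <- pmax(as.integer(floor(dim(volume@data) * sp / target)), 1L)
    g <- as.matrix(expand.grid(seq_len(nd[1]), seq_len(nd[2]), seq_len(nd[3])))
    centers <- .voxel_centers(g, target, origin(volume))
    vals <- cpp_trilinear(as.numeric(sm@data), .as_dim(sm@data),
                          .to_voxel_coord(centers, sp, origin(volume)))
    out <- array(vals, nd)
  }
  ImageVolume(out, spacing = target, origin = origin(volume))
}

#' Resample a volume onto the atlas grid spacing
#'
#' Matches the voxel size of (typically autofluorescence) images to that of
#' the reference atlas before affine estimation. Coarsening uses block
#' means (mass conserving); refining uses trilinear interpolation, whose
#' output stays within the input value range.
#'
#' @param volume an [ImageVolume-class].
#' @param atlas_spacing_um the isotropic atlas spacing (um), or length 3.
#' @param mode "auto" (block means when coarsening by an integer factor,
#'   interpolation otherwise), "block", or "interp".
#' @return [ImageVolume-class] at the atlas spacing.
#' @export
resampleToAtlas <- function(volume, atlas_spacing_um, mode = c("auto", "block", "interp")) {
  mode <- match.arg(mode)
  target <- rep_len(as.numeric(atlas_spacing_um), 3L)
  sp <- spacing(volume)
  if (all(abs(target - sp) < 1e-9)) return(volume)
  ratio <- target / sp
  integerish <- all(abs(ratio - round(ratio)) < 1e-9) && all(ratio >= 1)
  if (mode == "block" && !integerish)
    stop("block-mean resampling needs an integer coarsening factor per axis")
  if ((mode == "auto" && integerish) || mode == "block")
    return(downsampleVolume(volume, target))
  nd <- pmax(as.integer(round(dim(volume@data) * sp / target)), 1L)
  g <- as.matrix(expand.grid(seq_len(nd[1]), seq_len(nd[2]), seq_len(nd[3])))
  centers <- .voxel_centers(g, target, origin(volume))
  vals <- cpp_trilinear(as.numeric(volume@data), .as_dim(volume@data),
                        .to_voxel_coord(centers, sp, origin(volume)))
  ImageVolume(array(vals, nd), spacing = target, origin = origin(volume))
}

#' Signal-to-noise ratio of two regions of interest
#'
#' SNR defined as the mean signal intensity divided by the mean background
#' intensity.
#'
#' @param volume an [ImageVolume-class].
#' @param signal_roi,background_roi voxel selections: either a vector of
#'   linear indices or an n x 3 matrix of 1-based voxel indices.
#' @return scalar SNR.
#' @export
computeSnr <- function(volume, signal_roi, background_roi) {
  pick <- function(roi) {
    if (is.matrix(roi)) roi <- .linear_index(roi, dim(volume@data))
    if (length(roi) == 0L) stop("ROI is empty")
    volume@data[roi]
  }
  s <- pick(signal_roi)
  b <- pick(background_roi)
  mb <- mean(b)
  if (mb <= 0) stop("background mean must be positive")
  mean(s) / mb
}
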