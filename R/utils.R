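#' @include AllClasses.R
NULL

# Evaluate expr under a fixed RNG seed without touching global RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.as_dim <- function(x) as.integer(dim(x))

# Physical centre (um) of 1-based voxel indices.
.voxel_centers <- function(idx, spacing, origin) {
  idx <- matrix(idx, ncol = 3L)
  sweep(sweep(idx - 0.5, 2L, spacing, "*"), 2L, origin, "+")
}

#' Map physical points to voxel indices
#'
#' Voxel i (1-based) covers the half-open interval
#' `[origin + (i-1)*spacing, origin + i*spacing)` per axis, so the physical
#' point at the grid origin falls in voxel (1,1,1). Points outside the grid
#' get NA indices (the "outside" sentinel), never an error.
#'
#' @param points n x 3 matrix or length-3 vector of physical coordinates (um).
#' @param geometry an [ImageVolume-class] or [LabelAtlas-class] supplying
#'   spacing, origin and grid extent.
#' @return n x 3 integer matrix of 1-based voxel indices; rows of NA for
#'   points outside the grid.
#' @export
pointToVoxel <- function(points, geometry) {
  points <- matrix(as.numeric(points), ncol = 3L)
  sp <- spacing(geometry)
  or <- origin(geometry)
  dm <- dim(geometry)
  idx <- floor(sweep(sweep(points, 2L, or, "-"), 2L, sp, "/")) + 1
  bad <- idx < 1 | sweep(idx, 2L, dm, ">")
  idx[rowSums(bad) > 0, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

# Linear (column-major) index from an n x 3 voxel index matrix; NA passed on.
.linear_index <- function(idx, dm) {
  idx[, 1] + as.numeric(dm[1]) * (idx[, 2] - 1) +
    as.numeric(dm[1]) * dm[2] * (idx[, 3] - 1)
}

# Continuous 0-based voxel-centre coordinates for cpp_trilinear.
.to_voxel_coord <- function(points, spacing, origin) {
  sweep(sweep(points, 2L, origin, "-"), 2L, spacing, "/") - 0.5
}
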