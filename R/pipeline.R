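#' @include io.R quantify.R transform.R
NULL

#' Read a pipeline run configuration
#'
#' A plain YAML key-value document describing one end-to-end run: input
#' volume, atlas paths, detection parameters, optional normalization files,
#' quantification options, output directory and the seed. A run is
#' reproducible from the config plus its seed alone.
#'
#' @param path YAML file.
#' @return Named list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$.config_path <- normalizePath(path)
  cfg$seed <- cfg$seed %||% 1L
  det <- cfg$detection %||% list()
  det$mode <- det$mode %||% "otsu"
  det$min_voxels <- det$min_voxels %||% 3L
  det$connectivity <- det$connectivity %||% 26L
  det$split <- det$split %||% TRUE
  det$expected_radius_um <- det$expected_radius_um %||% 5
  cfg$detection <- det
  cfg$quantification <- cfg$quantification %||% list(level = "top")
  cfg
}

.read_any_volume <- function(path) {
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) readVolumeTiff(path)
  else readNrrd(path)
}

#' Run the full pipeline from a configuration
#'
#' detect -> normalize -> region lookup -> quantify, writing the raw and
#' normalized point tables, the per-region statistics, an optional heatmap
#' volume, and a provenance JSON (package version, parameters, seed, config
#' hash, per-stage input/output counts). Any stage error aborts with the
#' stage name; outputs written before the failure are preserved.
#'
#' @param config list from [readRunConfig()], or a YAML path.
#' @return Invisibly, a list with the run's main objects (points, stats,
#'   provenance).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  for (p in c(config$volume, config$atlas$labels, config$atlas$ontology))
    if (!is.null(p) && !file.exists(p))
      stop("configuration error: missing input file ", p)
  if (is.null(config$volume) || is.null(config$atlas$labels) ||
      is.null(config$atlas$ontology))
    stop("configuration error: 'volume' and 'atlas' paths are required")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, ...) {
    msg <- sprintf(...)
    message("[", stage, "] ", msg)
    log[[length(log) + 1L]] <<- list(stage = stage, note = msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  atlas <- stage("load", readLabelAtlas(config$atlas$labels, config$atlas$ontology))
  vol <- stage("load", .read_any_volume(config$volume))
  note("load", "volume %s voxels, atlas %s voxels",
       paste(dim(vol), collapse = "x"), paste(dim(atlas), collapse = "x"))

  det <- config$detection
  raw <- stage("detect", {
    v <- vol
    if (!is.null(config$background_sigma_um))
      v <- subtractBackground(v, config$background_sigma_um)
    model <- if (det$mode == "threshold") thresholdClassifier(det$threshold)
             else thresholdClassifier("otsu")
    mask <- classifyVoxels(model, v)
    detectNuclei(mask, v, min_voxels = det$min_voxels,
                 connectivity = det$connectivity, split = det$split,
                 expected_radius_um = det$expected_radius_um)
  })
  note("detect", "%d voxels in, %d nuclei out", prod(dim(vol)), length(raw))
  writeNucleusCsv(raw, file.path(out_dir, "raw_points.csv"))

  pts <- raw
  if (!is.null(config$normalization)) {
    pts <- stage("normalize", {
      aff <- readAffineText(config$normalization$affine)
      fld <- if (!is.null(config$normalization$warp))
        readDeformationField(config$normalization$warp, origin_um = origin(atlas))
      else NULL
      applyChainToPoints(raw, TransformChain(aff, fld), atlas = atlas)
    })
    note("normalize", "%d points in, %d out (%d clamped outside)",
         length(raw), length(pts), sum(pts@outside))
  } else if (pointSpace(pts) == "sample") {
    # no transform supplied: points are taken to be atlas-aligned already
    pts <- initialize(pts, space = "atlas")
    note("normalize", "no transform supplied; points passed through")
  }
  writeNucleusCsv(pts, file.path(out_dir, "normalized_points.csv"))

  stats <- stage("quantify",
                 countPerRegion(pts, atlas,
                                level = config$quantification$level %||% "top"))
  note("quantify", "%d assigned, %d unassigned",
       sum(regionTable(stats)$count), stats@unassigned)
  utils::write.csv(regionTable(stats), file.path(out_dir, "region_stats.csv"),
                   row.names = FALSE)
  if (isTRUE(config$quantification$heatmap))
    writeNrrd(heatmapVolume(stats, atlas), file.path(out_dir, "heatmap.nrrd"))

  prov <- list(
    package = "clickmap3d",
    version = as.character(utils::packageVersion("clickmap3d")),
    seed = config$seed,
    config_md5 = if (!is.null(config$.config_path))
      unname(tools::md5sum(config$.config_path)) else NA,
    parameters = config[setdiff(names(config), ".config_path")],
    stages = log)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA, force = TRUE)
  invisible(list(raw = raw, points = pts, stats = stats, provenance = prov))
}
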