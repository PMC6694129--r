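# Configuration and the end-to-end synthetic study: phantom -> mesh ->
# marker alignment -> seeding -> tracking -> DTI measurement; projection
# -> US measurement; paired comparison over a synthetic cohort. Fully
# reproducible from (config, seed).

#' Default pipeline configuration
#'
#' Nested list of every tunable parameter of the pipeline, with the
#' defaults the package's synthetic study uses. Unknown keys are rejected
#' by [validatePipelineConfig()]. Sections:
#' \describe{
#'   \item{phantom}{slab geometry, tensor FA levels, voxel size (2.5 mm),
#'     synthetic-tract noise. The default 12 mm / 25 deg slab sits in the
#'     middle of the observed gastrocnemius range and gives a 28.4 mm
#'     fascicle, comfortably above the 20 mm tract-length filter.}
#'   \item{mesh}{surface-mesh voxel size (1 mm) and smoothing settings.}
#'   \item{tracking}{FA window, turn/length limits, step, tract count.}
#'   \item{alignment}{true US-to-MR transform (axis-angle + translation),
#'     marker noise, FOV depth, seed radius and number of seed sites.}
#'   \item{dti}{normal-averaging radius, consistency threshold, thickness
#'     stations.}
#'   \item{us}{number of digitized fascicles, thickness mode, probe yaw sd
#'     (transducer misalignment) and probe compression of the muscle.}
#'   \item{cohort}{number of synthetic subjects and the ranges their slab
#'     parameters are drawn from.}
#' }
#'
#' @return A named list of class `muscleArchConfig`.
#' @export
pipelineConfig <- function() {
  structure(list(
    version = as.character(utils::packageVersion("muscleArch")),
    phantom = list(
      thickness_mm = 12, pennation_deg = 25, muscle_length_mm = 90,
      width_mm = 40, voxel_size_mm = 2.5, fa_inside = 0.35,
      fa_outside = 0.05, endpoint_jitter_sd_mm = 1, truncation_mm = 2,
      n_tracts = 100L),
    mesh = list(
      voxel_size_mm = 1, smoothing_factor = 0.5,
      smoothing_iterations = 10L, field_sigma_vox = 1,
      decimation_fraction = 0),
    tracking = list(
      fa_min = 0.1, fa_max = 0.7, max_turn_deg = 10, min_len_mm = 20,
      max_len_mm = 200, step_mm = 1.0, n_tracts = 100L),
    alignment = list(
      rotation_axis = c(0, 0, 1), rotation_deg = 15,
      translation_mm = c(40, -25, 10), marker_noise_sd_mm = 0,
      probe_shift_mm = c(0, 0, 0), fov_depth_mm = 40,
      seed_radius_mm = 2.5, n_sites = 3L),
    dti = list(
      normal_radius_mm = 5, consistency_threshold_deg = 20,
      n_stations = 3L, station_spacing_mm = 5),
    us = list(
      n_fascicles = 3L, tm_mode = "perpendicular", yaw_sd_deg = 10,
      compression_mm = 1),
    cohort = list(
      n_subjects = 7L, thickness_range_mm = c(8, 16),
      pennation_range_deg = c(15, 35), height_range_cm = c(153, 182),
      mesh_voxel_mm = 1.5)
  ), class = "muscleArchConfig")
}

#' Validate a pipeline configuration
#'
#' Checks the nested structure against [pipelineConfig()]: unknown keys
#' (at either level) are rejected, known scalar types enforced loosely.
#'
#' @param config a configuration list.
#' @return The config, invisibly, or an error.
#' @export
validatePipelineConfig <- function(config) {
  ref <- pipelineConfig()
  extra <- setdiff(names(config), names(ref))
  if (length(extra))
    stop("unknown configuration section(s): ", paste(extra, collapse = ", "))
  for (sec in setdiff(names(ref), "version")) {
    if (is.null(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad))
      stop(sprintf("unknown key(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Values given in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return A validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  validatePipelineConfig(user)
  cfg <- pipelineConfig()
  for (sec in setdiff(names(user), "version"))
    for (k in names(user[[sec]]))
      cfg[[sec]][[k]] <- user[[sec]][[k]]
  validatePipelineConfig(cfg)
  cfg
}

.axisAngleRotation <- function(axis, angleDeg) {
  u <- .unitv(axis)
  th <- .deg2rad(angleDeg)
  K <- matrix(c(0, u[3L], -u[2L], -u[3L], 0, u[1L], u[2L], -u[1L], 0),
              3L, 3L)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

# DTI + US observation of one synthetic subject. The US arm emulates the
# two dominant sources of method disagreement: probe compression (the
# transducer thins the muscle; fascicle length is conserved, so the
# apparent pennation angle drops with asin(t'/FL)) and transducer yaw
# misalignment (which inflates the apparent angle geometrically).
.observeSubject <- function(thickness, pennation, yawDeg, config, seed) {
  cfgP <- config$phantom
  spec <- phantomSpec(thickness, pennation,
                      muscleLengthMm = cfgP$muscle_length_mm,
                      widthMm = cfgP$width_mm,
                      voxelSizeMm = cfgP$voxel_size_mm,
                      faInside = cfgP$fa_inside, faOutside = cfgP$fa_outside,
                      endpointJitterSdMm = cfgP$endpoint_jitter_sd_mm,
                      truncationMm = cfgP$truncation_mm,
                      nTracts = cfgP$n_tracts, rngSeed = seed)
  ph <- makeUnipennatePhantom(spec)
  lm <- phantomLabelMap(ph, config$cohort$mesh_voxel_mm)
  mesh <- meshFromLabelMap(lm$labels, lm$affine,
                           config$mesh$smoothing_factor,
                           config$mesh$smoothing_iterations,
                           config$mesh$field_sigma_vox)
  bundles <- lapply(1:3, function(b)
    synthesizeTracts(ph, rngSeed = seed + b))
  dti <- measureDti(bundles, mesh,
                    radiusMm = config$dti$normal_radius_mm,
                    thresholdDeg = config$dti$consistency_threshold_deg,
                    nStations = config$dti$n_stations,
                    stationSpacingMm = config$dti$station_spacing_mm)
  # compressed phantom seen by the (possibly yawed) probe
  fl <- ph@truth@flMm
  tComp <- max(thickness - config$us$compression_mm, 0.2 * thickness)
  paComp <- .rad2deg(asin(min(tComp / fl, 1)))
  specC <- phantomSpec(tComp, paComp,
                       muscleLengthMm = cfgP$muscle_length_mm,
                       widthMm = cfgP$width_mm,
                       voxelSizeMm = cfgP$voxel_size_mm, rngSeed = seed)
  phC <- makeUnipennatePhantom(specC)
  Rz <- .axisAngleRotation(c(0, 0, 1), yawDeg)
  probe <- lapply(list(c(0, 11, 30), c(0, 49, 30), c(0, 30, 45)),
                  function(p) drop(Rz %*% p))
  plane <- scanPlaneFromProbe(probe[[1L]], probe[[2L]], probe[[3L]],
                              config$alignment$fov_depth_mm)
  us <- usMeasure(projectPhantomToPlane(phC, plane,
                                        config$us$n_fascicles),
                  tmMode = config$us$tm_mode)
  list(truth = ph@truth, dti = dti$result, us = us)
}

#' Run the end-to-end synthetic study
#'
#' Executes the full pipeline on one primary subject - phantom generation,
#' fine-grid surface meshing, marker-based US/MR alignment, seeding at the
#' scan-plane/muscle intersection, streamline tracking, DTI architecture
#' measurement, phantom projection and US measurement - and then a
#' synthetic cohort whose paired US/DTI measurements are compared with
#' exact Wilcoxon signed-rank statistics (raw and height-normalized).
#' Deterministic: the same `config` and `seed` reproduce the report
#' byte-for-byte.
#'
#' @param config configuration list from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @param seed integer master seed; all stage seeds derive from it.
#' @param outDir optional directory; when given, intermediate artifacts
#'   (NIfTI volumes, PLY mesh, TCK bundles, marker CSV) and `report.json`
#'   are written there.
#' @return The report: a nested list with the subject-level results
#'   (truth, DTI, US), tracking/exclusion logs, the cohort table and the
#'   comparison table.
#' @export
runEndToEnd <- function(config = pipelineConfig(), seed = 1L,
                        outDir = NULL) {
  validatePipelineConfig(config)
  seed <- as.integer(seed)
  cfgP <- config$phantom

  ph <- .withStage("phantom", {
    spec <- phantomSpec(cfgP$thickness_mm, cfgP$pennation_deg,
                        muscleLengthMm = cfgP$muscle_length_mm,
                        widthMm = cfgP$width_mm,
                        voxelSizeMm = cfgP$voxel_size_mm,
                        faInside = cfgP$fa_inside,
                        faOutside = cfgP$fa_outside,
                        endpointJitterSdMm = cfgP$endpoint_jitter_sd_mm,
                        truncationMm = cfgP$truncation_mm,
                        nTracts = cfgP$n_tracts, rngSeed = seed)
    makeUnipennatePhantom(spec)
  })
  mesh <- .withStage("mesh_geometry", {
    lm <- phantomLabelMap(ph, config$mesh$voxel_size_mm)
    meshFromLabelMap(lm$labels, lm$affine, config$mesh$smoothing_factor,
                     config$mesh$smoothing_iterations,
                     config$mesh$field_sigma_vox,
                     config$mesh$decimation_fraction)
  })
  alignment <- .withStage("frame_alignment", {
    tr <- rigidTransform(
      .axisAngleRotation(config$alignment$rotation_axis,
                         config$alignment$rotation_deg),
      config$alignment$translation_mm)
    layout <- .defaultMarkerLayoutMr()
    layout[c("AL", "AR", "AU"), ] <- sweep(
      layout[c("AL", "AR", "AU"), ], 2L,
      config$alignment$probe_shift_mm, "+")
    scene <- makeMarkerScene(tr, config$alignment$marker_noise_sd_mm,
                             rngSeed = seed + 101L, layoutMr = layout)
    plane <- locateUsPlaneInMr(scene, config$alignment$fov_depth_mm)
    seeds <- seedFromIntersection(plane, mesh,
                                  config$alignment$seed_radius_mm,
                                  config$alignment$n_sites)
    if (is(seeds, "SeedRegion")) seeds <- list(seeds)
    list(transform = tr, scene = scene, plane = plane, seeds = seeds)
  })
  bundles <- .withStage("tracking", {
    tp <- trackingParams(config$tracking$fa_min, config$tracking$fa_max,
                         config$tracking$max_turn_deg,
                         config$tracking$min_len_mm,
                         config$tracking$max_len_mm,
                         config$tracking$step_mm,
                         config$tracking$n_tracts)
    lapply(seq_along(alignment$seeds), function(i)
      trackStreamlines(ph@tensorVolume, alignment$seeds[[i]], tp,
                       rngSeed = seed + 200L + i))
  })
  dti <- .withStage("dti_architecture",
    measureDti(bundles, mesh, radiusMm = config$dti$normal_radius_mm,
               thresholdDeg = config$dti$consistency_threshold_deg,
               nStations = config$dti$n_stations,
               stationSpacingMm = config$dti$station_spacing_mm))
  us <- .withStage("us_architecture", {
    scene2d <- projectPhantomToPlane(ph, alignment$plane,
                                     config$us$n_fascicles)
    usMeasure(scene2d, tmMode = config$us$tm_mode)
  })

  cohortTable <- NULL; comparison <- NULL
  nSub <- config$cohort$n_subjects
  if (nSub >= 2L) {
    draws <- .withSeed(seed + 500L, list(
      t = runif(nSub, config$cohort$thickness_range_mm[1L],
                config$cohort$thickness_range_mm[2L]),
      pa = runif(nSub, config$cohort$pennation_range_deg[1L],
                 config$cohort$pennation_range_deg[2L]),
      h = runif(nSub, config$cohort$height_range_cm[1L],
                config$cohort$height_range_cm[2L]),
      yaw = rnorm(nSub, 0, config$us$yaw_sd_deg)))
    rows <- list()
    for (s in seq_len(nSub)) {
      obs <- .withStage(sprintf("cohort subject %d", s),
        .observeSubject(draws$t[s], draws$pa[s], draws$yaw[s], config,
                        seed + 1000L + 17L * s))
      for (meth in c("us", "dti")) {
        r <- obs[[meth]]
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("S%d", s), muscle = "phantom",
          parameter = c("FL", "PA", "t_m"),
          method = r@method,
          value = c(r@flMm, r@paDeg, r@tmMm),
          height_cm = draws$h[s],
          true_value = c(obs$truth@flMm, obs$truth@paDeg,
                         obs$truth@tmMm),
          stringsAsFactors = FALSE)
      }
    }
    cohortTable <- do.call(rbind, rows)
    comparison <- .withStage("stats_compare", compareMethods(cohortTable))
  }

  report <- list(
    seed = seed,
    version = config$version,
    subject = list(
      truth = as.list(asArchitectureRow(ph@truth)),
      dti = as.list(asArchitectureRow(dti$result)),
      us = as.list(asArchitectureRow(us)),
      perBundle = dti$perBundle,
      exclusions = dti$exclusions,
      tracking = data.frame(
        bundle = seq_along(bundles),
        nTracts = vapply(bundles, nTracts, integer(1)),
        nDiscarded = vapply(bundles, function(b) b@nDiscarded,
                            integer(1)))),
    cohort = cohortTable,
    comparison = comparison)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeLabelNifti(ph@labels, ph@affine,
                    file.path(outDir, "phantom_labels.nii.gz"))
    writeTensorNifti(ph@tensorVolume,
                     file.path(outDir, "phantom_tensors.nii.gz"))
    writePly(mesh, file.path(outDir, "muscle_mesh.ply"))
    for (i in seq_along(bundles))
      writeTck(bundles[[i]], file.path(outDir,
                                       sprintf("bundle_%d.tck", i)))
    writeMarkersCsv(alignment$scene, file.path(outDir, "markers.csv"))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report
}
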