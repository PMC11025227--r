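# Per-case orchestration of Track A (silhouette comparison) and Track B
# (landmark + ICP registration, 3D Dice, volumes), and cohort aggregation.

#' Pipeline configuration
#'
#' Single source of every tolerance and default used by \code{\link{runCase}}
#' and \code{\link{runCohort}}; all choices taken during a run are echoed into
#' the report's \code{alignmentChoices}.
#'
#' @param seed master seed; every stochastic step (surface sampling) derives
#'   its seed from it.
#' @param camera \linkS4class{CameraSpec} for silhouette rendering.
#' @param icp An \code{\link{icpConfig}}.
#' @param photoThreshold threshold for \code{\link{binarizePhoto}} when a
#'   grayscale photo is supplied ("otsu" or numeric).
#' @return List of class "PipelineConfig".
#' @export
pipelineConfig <- function(seed = 1L, camera = cameraSpec(), icp = icpConfig(),
                           photoThreshold = "otsu") {
  structure(list(seed = as.integer(seed), camera = camera, icp = icp,
                 photoThreshold = photoThreshold),
            class = "PipelineConfig")
}

# md5 of the serialized configuration, for report provenance
.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(config, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full validation on one case
#'
#' Track A: extract the MRI-model surface, rectify its pose by PCA, render
#' its calibrated silhouette, align against (i) the specimen photograph and
#' (ii) the rendered silhouette of the CT model, and compute 2D Dice for
#' each. Track B: landmark alignment, trimmed ICP refinement, 3D Dice of the
#' registered volumes on the CT grid, and both cartilage volumes. Partial
#' inputs produce partial reports (NA fields); malformed inputs raise errors
#' labelled with the failing stage.
#'
#' @param case A \linkS4class{SyntheticCase} or a named list (a "case
#'   bundle") with \code{mriVolume} and optionally \code{photo},
#'   \code{ctVolume}, \code{landmarksMRI}, \code{landmarksCT}, \code{caseId}.
#' @param config A \code{\link{pipelineConfig}}.
#' @return A \linkS4class{CaseReport}.
#' @export
runCase <- function(case, config = pipelineConfig()) {
  if (is(case, "SyntheticCase"))
    case <- list(caseId = sprintf("phantom-seed-%d", case@params@seed),
                 mriVolume = case@mriVolume, ctVolume = case@ctVolume,
                 photo = case@photo, landmarksMRI = case@landmarksMRI,
                 landmarksCT = case@landmarksCT)
  if (is.null(case$mriVolume)) stop("[inputs] case bundle lacks mriVolume")
  caseId <- if (is.null(case$caseId)) "case" else case$caseId
  choices <- list(seed = config$seed, cameraMode = config$camera@mode,
                  mmPerPx = config$camera@mmPerPx)

  modelRender <- .stage("projection", {
    mesh <- maskToMesh(case$mriVolume)
    rect <- pcaRectify(mesh)
    renderSilhouette(rect$mesh, config$camera)
  })

  dscPhoto <- NA_real_
  if (!is.null(case$photo)) {
    al <- .stage("projection", alignSilhouettes(case$photo, modelRender))
    dscPhoto <- dsc2d(al$a, al$b)@dsc
    choices$photoAlignment <- list(rotationDeg = al$rotationDeg,
                                   candidate = al$candidate,
                                   degenerate = al$degenerate)
  }

  dscCt <- NA_real_
  volCt <- NA_real_
  if (!is.null(case$ctVolume)) {
    ctRender <- .stage("projection", {
      ctMesh <- maskToMesh(case$ctVolume)
      renderSilhouette(pcaRectify(ctMesh)$mesh, config$camera)
    })
    al <- .stage("projection", alignSilhouettes(ctRender, modelRender))
    dscCt <- dsc2d(al$a, al$b)@dsc
    choices$ctAlignment <- list(rotationDeg = al$rotationDeg,
                                candidate = al$candidate,
                                degenerate = al$degenerate)
    volCt <- cartilageVolume(case$ctVolume)
  }

  dsc3 <- NA_real_
  resid <- NA_real_
  if (!is.null(case$ctVolume) && !is.null(case$landmarksMRI) &&
      !is.null(case$landmarksCT)) {
    reg <- .stage("registration", {
      la <- landmarkAlign(case$landmarksMRI, case$landmarksCT)
      src <- surfaceCloud(case$mriVolume, config$icp$samplePoints,
                          seed = config$seed)
      dst <- surfaceCloud(case$ctVolume,
                          config$icp$samplePoints * config$icp$dstOversample,
                          seed = config$seed + 1L)
      icp <- icpRefine(src, dst, la$transform, config$icp)
      list(la = la, icp = icp)
    })
    dsc3 <- .stage("metrics",
                   dsc3d(case$mriVolume, case$ctVolume, reg$icp$transform)@dsc)
    resid <- reg$icp$diagnostics$finalMeanDistanceMm
    choices$registration <- list(
      landmarkRmsdMm = reg$la$rmsdMm,
      icpIterations = nrow(reg$icp$diagnostics$iterations),
      icpTermination = reg$icp$diagnostics$terminationReason,
      cloudSeeds = c(config$seed, config$seed + 1L))
  }

  volMri <- cartilageVolume(case$mriVolume)
  new("CaseReport", caseId = caseId, dsc2dModelVsPhoto = dscPhoto,
      dsc2dModelVsCtModel = dscCt, dsc3d = dsc3, volumeMriMm3 = volMri,
      volumeCtMm3 = volCt, registrationResidualMm = resid,
      alignmentChoices = choices)
}

#' Run the validation over a cohort and aggregate
#'
#' Per-case reports plus cohort means of each Dice field and the Pearson
#' correlation between MRI-model and CT-model cartilage volumes across cases
#' (mirroring the per-case Dice panel and the volume-agreement analysis of a
#' validation study). Fewer than 2 usable volume pairs, or constant volumes,
#' yield NA correlation with a warning rather than an error.
#'
#' @param cases list of \linkS4class{SyntheticCase}s / case bundles, or a
#'   directory containing one sub-directory per case in
#'   \code{\link{writeCase}} layout.
#' @param config A \code{\link{pipelineConfig}}.
#' @return A \linkS4class{CohortReport}.
#' @export
runCohort <- function(cases, config = pipelineConfig()) {
  if (is.character(cases)) {
    dirs <- list.dirs(cases, recursive = FALSE)
    if (!length(dirs)) stop("runCohort: no case directories found in ", cases)
    cases <- lapply(dirs, readCase)
  }
  if (length(cases) < 2) stop("runCohort: need at least 2 cases")
  reports <- lapply(seq_along(cases), function(i) {
    r <- runCase(cases[[i]], config)
    if (r@caseId == "case") r@caseId <- sprintf("case-%03d", i)
    r
  })
  g <- function(f) vapply(reports, function(r) slot(r, f), numeric(1))
  vm <- g("volumeMriMm3"); vc <- g("volumeCtMm3")
  ok <- !is.na(vm) & !is.na(vc)
  pr <- list(r = NA_real_, pValue = NA_real_)
  if (sum(ok) < 2) {
    warning("runCohort: fewer than 2 cases with both volumes; correlation omitted")
  } else {
    pr <- tryCatch(pearsonR(vm[ok], vc[ok]), error = function(e) {
      warning("runCohort: volume correlation unavailable: ", conditionMessage(e))
      list(r = NA_real_, pValue = NA_real_)
    })
  }
  new("CohortReport", perCase = reports,
      meanDsc2dPhoto = mean(g("dsc2dModelVsPhoto")),
      meanDsc2dCt = mean(g("dsc2dModelVsCtModel")),
      meanDsc3d = mean(g("dsc3d")),
      pearsonRVolumes = pr$r, pearsonP = pr$pValue,
      configHash = .configHash(config), seed = config$seed)
}

#' Per-case table of a cohort report
#' @param report A \linkS4class{CohortReport}.
#' @return data.frame with one row per case.
#' @export
cohortTable <- function(report) {
  do.call(rbind, lapply(report@perCase, function(r)
    data.frame(case_id = r@caseId,
               dsc2d_model_vs_photo = r@dsc2dModelVsPhoto,
               dsc2d_model_vs_ctmodel = r@dsc2dModelVsCtModel,
               dsc3d = r@dsc3d,
               volume_mri_mm3 = r@volumeMriMm3,
               volume_ct_mm3 = r@volumeCtMm3,
               registration_residual_mm = r@registrationResidualMm)))
}

#' Write a cohort report to CSV + JSON
#'
#' \code{cohort.csv} holds the per-case table; \code{cohort.json} holds the
#' per-case table, the aggregates, the config hash and seed, and every
#' alignment choice taken. Identical config and seeds produce bit-identical
#' files.
#'
#' @param report A \linkS4class{CohortReport}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohortReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- cohortTable(report)
  utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                   file.path(dir, "cohort.csv"), row.names = FALSE, quote = FALSE)
  obj <- list(
    per_case = lapply(report@perCase, function(r) list(
      case_id = r@caseId,
      dsc2d_model_vs_photo = r@dsc2dModelVsPhoto,
      dsc2d_model_vs_ctmodel = r@dsc2dModelVsCtModel,
      dsc3d = r@dsc3d,
      volume_mri_mm3 = r@volumeMriMm3,
      volume_ct_mm3 = r@volumeCtMm3,
      registration_residual_mm = r@registrationResidualMm,
      alignment_choices = r@alignmentChoices)),
    mean_dsc2d_photo = report@meanDsc2dPhoto,
    mean_dsc2d_ct = report@meanDsc2dCt,
    mean_dsc3d = report@meanDsc3d,
    pearson_r_volumes = report@pearsonRVolumes,
    pearson_p = report@pearsonP,
    config_hash = report@configHash,
    seed = report@seed)
  jsonlite::write_json(obj, file.path(dir, "cohort.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}

#' Plot per-case Dice values and the volume agreement scatter
#'
#' Writes a two-panel PNG: per-case bars of the three Dice statistics, and
#' MRI-model vs CT-model volume scatter with the identity line.
#'
#' @param report A \linkS4class{CohortReport}.
#' @param file output PNG path.
#' @return \code{file}, invisibly.
#' @export
plotCohort <- function(report, file) {
  tab <- cohortTable(report)
  grDevices::png(file, width = 1400, height = 600)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2), mar = c(8, 4, 3, 1))
  m <- t(as.matrix(tab[, c("dsc2d_model_vs_photo", "dsc2d_model_vs_ctmodel", "dsc3d")]))
  graphics::barplot(m, beside = TRUE, names.arg = tab$case_id, las = 2,
                    col = c("grey30", "grey55", "grey80"), ylim = c(0, 1),
                    ylab = "DSC", main = "Per-case Dice")
  graphics::legend("topright", c("2D vs photo", "2D vs CT model", "3D"),
                   fill = c("grey30", "grey55", "grey80"), bty = "n")
  lim <- range(c(tab$volume_mri_mm3, tab$volume_ct_mm3), na.rm = TRUE)
  graphics::plot(tab$volume_ct_mm3, tab$volume_mri_mm3, xlim = lim, ylim = lim,
                 xlab = "CT-model volume (mm^3)", ylab = "MRI-model volume (mm^3)",
                 main = sprintf("Volume agreement (r = %.3f)", report@pearsonRVolumes),
                 pch = 19)
  graphics::abline(0, 1, lty = 2)
  invisible(file)
}
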