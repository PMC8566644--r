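#' @include synthetic.R parametric.R extract.R modeling.R
NULL

#' Pipeline configuration
#'
#' Collects every tunable setting of the analysis with the standard protocol
#' values as defaults: summation windows 5-15 and 20-40 min, TBR threshold
#' 1.6, isotropic resampling to 2.03 mm, bin widths per image kind (the TBR
#' widths may be the string \code{"iqr4"} to derive the mean-IQR/4 width
#' from the training cohort; TTP uses 5 min), 70/30 stratified split,
#' 10-fold cross-validation, PCC threshold 0.99 and 1000 bootstrap
#' replicates. Synthetic-cohort settings mirror [cohortSpec()].
#'
#' @param path optional YAML file with overrides.
#' @param ... named overrides applied after the file.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(path = NULL, ...) {
  cfg <- list(
    outputDir = "dynfet-run",
    seed = 1L,
    cohort = list(nPatients = 40L, wildtypeFraction = 0.2,
                  gridShape = c(40L, 40L, 24L),
                  voxelSpacing = c(2.03, 2.03, 2.43),
                  effect = 1, noiseSd = 0.05),
    windows = list(TBR_5_15 = c(5, 15), TBR_20_40 = c(20, 40)),
    segmentationThreshold = 1.6,
    resampleMm = 2.03,
    binWidths = list(TBR_5_15 = "iqr4", TBR_20_40 = "iqr4", TTP = 5),
    split = list(trainFraction = 0.7),
    selection = list(folds = 10L, pccThreshold = 0.99, C = 1),
    bootstrap = list(n = 1000L)
  )
  if (!is.null(path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  overrides <- list(...)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "PipelineConfig"
  cfg
}

configHash <- function(config) {
  fnv1a32(paste(deparse(unclass(config)), collapse = ""))
}

writeManifest <- function(config, stage, dir, extra = list()) {
  man <- c(list(stage = stage, configHash = configHash(config),
                seed = config$seed,
                package = as.character(utils::packageVersion("dynFET")),
                timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(man, file.path(dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

writeVolume <- function(arr, spacing, path) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(spacing, rep(1, nd - 3L))
  RNifti::writeNifti(img, path)
}

#' Read a dynamic study from a 4D NIfTI file
#'
#' @param path 4D NIfTI file.
#' @param schedule expected [FrameSchedule-class]; the frame count must
#'   match the file's 4th dimension.
#' @return A [DynamicStudy-class].
#' @export
readStudy <- function(path, schedule = defaultFrameSchedule()) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4L)
    stop(sprintf("expected a 4D volume, got dimensions %s",
                 paste(dim(arr), collapse = " x ")))
  if (dim(arr)[4L] != nFrames(schedule))
    stop(sprintf("volume has %d frames but the schedule has %d",
                 dim(arr)[4L], nFrames(schedule)))
  dynamicStudy(arr, schedule, RNifti::pixdim(img)[1:3])
}

#' Write a parametric image as 3D NIfTI plus a JSON sidecar
#'
#' @param image a [ParametricImage-class].
#' @param path output NIfTI path; the sidecar replaces the extension with
#'   \code{.json}.
#' @param sidecar named list of provenance values (background mean,
#'   threshold, schedule hash, ...).
#' @export
writeParametric <- function(image, path, sidecar = list()) {
  arr <- imageData(image)
  arr[is.na(arr)] <- -1       # NIfTI has no NA; -1 marks outside-mask voxels
  writeVolume(arr, voxelSpacing(image), path)
  side <- c(list(kind = imageKind(image), naValue = -1), sidecar)
  jsonlite::write_json(side, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
}

#' Read a parametric image written by [writeParametric()]
#'
#' @param path NIfTI path (sidecar JSON expected alongside).
#' @return A [ParametricImage-class].
#' @export
readParametric <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path))
  arr <- array(as.numeric(img), dim(img))
  arr[arr == side$naValue] <- NA_real_
  parametricImage(arr, side$kind, RNifti::pixdim(img)[1:3])
}

readMask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim(img))
}

#' Read per-patient labels from CSV
#'
#' @param path CSV with columns \code{patient_id} and \code{label} (0 =
#'   TERTp-wildtype, 1 = TERTp-mutant).
#' @return integer label vector named by patient id.
#' @export
readLabels <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "label") %in% names(tab)))
  structure(as.integer(tab$label), names = tab$patient_id)
}

patientIds <- function(config) sprintf("P%03d", seq_len(config$cohort$nPatients))

stageDir <- function(config, stage) {
  d <- file.path(config$outputDir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

requireStage <- function(config, stage) {
  d <- file.path(config$outputDir, stage)
  if (!dir.exists(d))
    stop(sprintf("missing upstream artifact: run stage '%s' first", stage))
  d
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (write the synthetic cohort), \code{parametric}
#' (TBR/TTP maps + tumour masks), \code{extract} (107-feature tables per
#' image kind, bin widths derived on the training cohort when configured as
#' \code{"iqr4"}), \code{train} (one model per image kind) and
#' \code{evaluate} (test-cohort metrics JSON). Stages are deterministic
#' given the config and resumable; each writes a manifest with the config
#' hash and seed.
#'
#' @param config a [pipelineConfig()].
#' @param stage one of \code{"simulate"}, \code{"parametric"},
#'   \code{"extract"}, \code{"train"}, \code{"evaluate"}.
#' @return invisibly, the stage output directory.
#' @export
runStage <- function(config, stage = c("simulate", "parametric", "extract",
                                       "train", "evaluate")) {
  stage <- match.arg(stage)
  switch(stage,
         simulate = stageSimulate(config),
         parametric = stageParametric(config),
         extract = stageExtract(config),
         train = stageTrain(config),
         evaluate = stageEvaluate(config))
}

stageSimulate <- function(config) {
  d <- stageDir(config, "simulate")
  spec <- do.call(cohortSpec, c(config$cohort, list(seed = config$seed)))
  labels <- phantomLabels(spec)
  ids <- patientIds(config)
  truth <- NULL
  for (i in seq_along(ids)) {
    pat <- phantomPatient(spec, i, labels[i])
    writeVolume(studyVolume(pat$study), spec$voxelSpacing,
                file.path(d, sprintf("%s_study.nii.gz", ids[i])))
    writeVolume(array(as.numeric(pat$tumourMask), dim(pat$tumourMask)),
                spec$voxelSpacing, file.path(d, sprintf("%s_tumour.nii.gz", ids[i])))
    writeVolume(array(as.numeric(pat$backgroundMask), dim(pat$backgroundMask)),
                spec$voxelSpacing,
                file.path(d, sprintf("%s_background.nii.gz", ids[i])))
    truth <- rbind(truth, data.frame(patient_id = ids[i], label = labels[i],
                                     dominant_category = pat$truth$dominant,
                                     mixing = pat$truth$mixing))
  }
  write.csv(data.frame(patient_id = ids, label = labels),
            file.path(d, "labels.csv"), row.names = FALSE)
  write.csv(truth, file.path(d, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(config), file.path(d, "config.yaml"))
  message(sprintf("simulate: %d patients (%d wildtype / %d mutant)",
                  length(ids), sum(labels == 0L), sum(labels == 1L)))
  writeManifest(config, "simulate", d)
  invisible(d)
}

stageParametric <- function(config) {
  sim <- requireStage(config, "simulate")
  d <- stageDir(config, "parametric")
  ids <- patientIds(config)
  for (id in ids) {
    study <- readStudy(file.path(sim, sprintf("%s_study.nii.gz", id)))
    background <- readMask(file.path(sim, sprintf("%s_background.nii.gz", id)))
    par <- parametricImages(study, background,
                            threshold = config$segmentationThreshold)
    side <- list(backgroundMeans = as.list(par$backgroundMeans),
                 threshold = par$threshold,
                 scheduleHash = fnv1a32(paste(frameEnds(studySchedule(study)),
                                              collapse = ",")))
    writeParametric(par$tbr0515, file.path(d, sprintf("%s_TBR_5_15.nii.gz", id)), side)
    writeParametric(par$tbr2040, file.path(d, sprintf("%s_TBR_20_40.nii.gz", id)), side)
    writeParametric(par$ttp, file.path(d, sprintf("%s_TTP.nii.gz", id)), side)
    writeVolume(array(as.numeric(par$tumourMask), dim(par$tumourMask)),
                voxelSpacing(study), file.path(d, sprintf("%s_mask.nii.gz", id)))
  }
  writeManifest(config, "parametric", d)
  invisible(d)
}

stageExtract <- function(config) {
  par <- requireStage(config, "parametric")
  sim <- requireStage(config, "simulate")
  d <- stageDir(config, "extract")
  ids <- patientIds(config)
  labels <- readLabels(file.path(sim, "labels.csv"))
  split <- stratifiedSplit(labels, config$split$trainFraction,
                           deriveSeed(config$seed, "split"))
  kinds <- c("TBR_5_15", "TBR_20_40", "TTP")
  binWidths <- config$binWidths
  for (kind in kinds) {
    images <- lapply(ids, function(id)
      readParametric(file.path(par, sprintf("%s_%s.nii.gz", id, kind))))
    masks <- lapply(ids, function(id)
      readMask(file.path(par, sprintf("%s_mask.nii.gz", id))))
    bw <- binWidths[[kind]]
    if (identical(bw, "iqr4"))
      bw <- iqr4BinWidth(lapply(split$train, function(i)
        imageData(images[[i]])[masks[[i]]]))
    names(images) <- ids
    tab <- featureTable(images, masks, binWidth = bw,
                        targetMm = config$resampleMm)
    long <- data.frame(patient_id = rep(ids, each = ncol(tab)),
                       image_kind = kind,
                       feature_name = rep(colnames(tab), times = nrow(tab)),
                       value = as.vector(t(tab)),
                       bin_width = bw)
    write.csv(long, file.path(d, sprintf("features_%s.csv", kind)),
              row.names = FALSE)
  }
  writeManifest(config, "extract", d,
                extra = list(trainIds = ids[split$train]))
  invisible(d)
}

readFeatureTable <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(long$patient_id)
  feats <- unique(long$feature_name)
  tab <- matrix(long$value, nrow = length(ids), ncol = length(feats),
                byrow = TRUE, dimnames = list(ids, feats))
  attr(tab, "binWidth") <- long$bin_width[1L]
  tab
}

stageTrain <- function(config) {
  ext <- requireStage(config, "extract")
  sim <- requireStage(config, "simulate")
  d <- stageDir(config, "train")
  labels <- readLabels(file.path(sim, "labels.csv"))
  split <- stratifiedSplit(labels, config$split$trainFraction,
                           deriveSeed(config$seed, "split"))
  for (kind in c("TBR_5_15", "TBR_20_40", "TTP")) {
    tab <- readFeatureTable(file.path(ext, sprintf("features_%s.csv", kind)))
    fit <- trainModel(tab[split$train, , drop = FALSE], labels[split$train],
                      folds = config$selection$folds,
                      pccThreshold = config$selection$pccThreshold,
                      seed = deriveSeed(config$seed, "cv", kind),
                      C = config$selection$C)
    message(sprintf("train[%s]: %d features retained after PCC, %d selected",
                    kind, length(fit$retained), fit$nSelected))
    model <- fit$model
    jsonlite::write_json(
      list(kind = kind, features = selectedFeatures(model),
           theta = as.list(coef(model)), intercept = modelIntercept(model),
           classWeights = as.list(classWeights(model)),
           center = as.list(model@center), scale = as.list(model@scale),
           C = model@C, seed = config$seed),
      file.path(d, sprintf("model_%s.json", kind)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(data.frame(n_features = seq_along(fit$cvAuc),
                         mean_cv_auc = fit$cvAuc),
              file.path(d, sprintf("cv_curve_%s.csv", kind)), row.names = FALSE)
  }
  writeManifest(config, "train", d,
                extra = list(trainIds = names(labels)[split$train]))
  invisible(d)
}

readModelJson <- function(path) {
  m <- jsonlite::read_json(path)
  nm <- unlist(m$features)
  new(Class = "LogisticModel", features = nm,
      theta = structure(unlist(m$theta)[nm], names = nm),
      intercept = m$intercept,
      classWeights = unlist(m$classWeights),
      center = structure(unlist(m$center)[nm], names = nm),
      scale = structure(unlist(m$scale)[nm], names = nm),
      threshold = 0.5, C = m$C)
}

stageEvaluate <- function(config) {
  trn <- requireStage(config, "train")
  ext <- requireStage(config, "extract")
  sim <- requireStage(config, "simulate")
  d <- stageDir(config, "evaluate")
  labels <- readLabels(file.path(sim, "labels.csv"))
  split <- stratifiedSplit(labels, config$split$trainFraction,
                           deriveSeed(config$seed, "split"))
  out <- list()
  for (kind in c("TBR_5_15", "TBR_20_40", "TTP")) {
    model <- readModelJson(file.path(trn, sprintf("model_%s.json", kind)))
    tab <- readFeatureTable(file.path(ext, sprintf("features_%s.csv", kind)))
    res <- list()
    for (cohort in c("train", "test")) {
      idx <- split[[cohort]]
      pred <- applyModel(model, tab[idx, , drop = FALSE])
      rep_ <- evaluateModel(pred$probability, labels[idx],
                            nBootstrap = config$bootstrap$n,
                            seed = deriveSeed(config$seed, "boot", kind, cohort))
      tabm <- metricTable(rep_)
      res[[cohort]] <- stats::setNames(
        lapply(seq_len(nrow(tabm)), function(r)
          list(value = tabm$value[r],
               ci95 = c(tabm$ci_lower[r], tabm$ci_upper[r]))),
        tabm$metric)
    }
    out[[kind]] <- res
  }
  jsonlite::write_json(out, file.path(d, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeManifest(config, "evaluate", d)
  invisible(d)
}

#' Run pipeline stages in order
#'
#' @param config a [pipelineConfig()].
#' @param stages character vector of stages to run (default all five, in
#'   dependency order).
#' @return invisibly, the output directory.
#' @export
runPipeline <- function(config, stages = c("simulate", "parametric", "extract",
                                           "train", "evaluate")) {
  for (s in stages) runStage(config, s)
  invisible(config$outputDir)
}
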