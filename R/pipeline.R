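#' @include AllClasses.R accessors.R simulate.R drift.R merge.R frc.R voronoi.R cluster-analysis.R
NULL

#' Default pipeline configuration
#'
#' Returns the fully populated configuration of \code{\link{runPipeline}};
#' pass overrides as a nested list (unknown keys are rejected). Units are
#' embedded in the key names. The defaults emulate the study conditions:
#' shell-like (early G1 rosette) versus filled (late G1) clusters of outer
#' diameter 280 nm and cavity 100 nm, imaged at 10 nm localization precision
#' over 15000 frames with a slow linear stage drift.
#'
#' @param overrides nested list of values replacing defaults.
#' @param seed master seed overriding \code{config$seed}.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(overrides = list(), seed = NULL) {
    cfg <- list(
        seed = 1L,
        simulate = list(
            conditions = c("shell", "filled"),
            nCellsPerCondition = 3L,
            clustersPerCell = 6L,
            nMoleculesPerCluster = 500L,
            outerDiameterNm = 280,
            innerDiameterNm = 100,
            subclusterCount = 0L,
            fieldSizeNm = c(2400, 2400, 600),
            nFrames = 10000L,
            meanOnFrames = 3,
            locPrecisionNm = 10,
            meanPhotons = 1000,
            backgroundDensityPerUm2PerFrame = 1e-3,
            driftTotalNm = c(40, 25)),
        correct = list(
            enabled = TRUE,
            nSubsets = 10L,
            pixelSizeNm = 20,
            nIterations = 3L,
            mergeRadiusNm = 50,
            frc = FALSE,
            frcPixelSizeNm = 10),
        segment = list(
            enabled = TRUE,
            alpha = 0.05,
            nSim = 5L,
            minSize = 25L),
        profiles = list(
            enabled = TRUE,
            boxNm = 500,
            renderPixelSizeNm = 20,
            alignIterations = 3L,
            rotStepDeg = 10,
            comSearchRadiusNm = 250,
            comRmaxNm = 200,
            comBinNm = 20),
        reconstruct = list(
            enabled = FALSE,
            angularStepDeg = 2,
            gridStepDeg = 15,
            refinePasses = 1L))
    cfg <- mergeConfig(cfg, overrides)
    if (!is.null(seed)) cfg$seed <- as.integer(seed)
    cfg
}

mergeConfig <- function(base, over, path = "") {
    for (k in names(over)) {
        full <- paste0(path, k)
        if (!k %in% names(base))
            stop("unknown configuration key: ", full)
        if (is.list(base[[k]])) {
            if (!is.list(over[[k]]))
                stop("configuration key ", full, " must be a list")
            base[[k]] <- mergeConfig(base[[k]], over[[k]], paste0(full, "$"))
        } else {
            base[[k]] <- over[[k]]
        }
    }
    base
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with (a subset of) the keys of
#'   \code{\link{pipelineConfig}}.
#' @param seed optional master seed override.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path, seed = NULL) {
    pipelineConfig(yaml::read_yaml(path), seed = seed)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes simulate, corrections (drift, merging), Voronoi segmentation,
#' image- and localization-based radial profiling, and optionally the 3D
#' reconstruction, for every configured condition and cell. Every
#' intermediate table and summary is written under \code{outDir} together
#' with a JSON-lines run log carrying the parameters, seeds and a config
#' hash; reruns with an identical configuration produce bit-identical CSV
#' outputs.
#'
#' @param config configuration from \code{\link{pipelineConfig}}.
#' @param outDir artifact directory (created if needed).
#' @return invisibly, a list with per-condition profile objects and the paths
#'   of all written artifacts.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("run")) {
    config <- pipelineConfig(config)   # validates keys, fills defaults
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    cfgPath <- file.path(outDir, "config.json")
    jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA)
    cfgHash <- unname(tools::md5sum(cfgPath))
    logPath <- file.path(outDir, "run-log.jsonl")
    if (file.exists(logPath)) unlink(logPath)
    logLine <- function(...) {
        rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    configHash = cfgHash, ...)
        cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
            sep = "", file = logPath, append = TRUE)
    }
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    logLine(event = "start", config = config)
    sc <- config$simulate
    results <- list(); artifacts <- character(0)
    for (cond in sc$conditions) {
        stacks <- NULL; comPerCell <- NULL
        for (cell in seq_len(sc$nCellsPerCondition)) {
            cellSeed <- subSeed(config$seed,
                                100 * match(cond, sc$conditions) + cell)
            base <- sprintf("%s_cell%02d", cond, cell)
            sim <- stage("simulate", {
                k <- ceiling(sqrt(sc$clustersPerCell))
                pitch <- sc$fieldSizeNm[1] / (k + 1)
                idx <- seq_len(sc$clustersPerCell) - 1
                jit <- withSeed(subSeed(cellSeed, 1),
                                matrix(stats::runif(2 * sc$clustersPerCell,
                                                    -0.15, 0.15) * pitch,
                                       ncol = 2))
                centers <- cbind(pitch * (idx %% k + 1) + jit[, 1],
                                 pitch * (idx %/% k + 1) + jit[, 2],
                                 sc$fieldSizeNm[3] / 2)
                models <- lapply(seq_len(sc$clustersPerCell), function(i)
                    ClusterModel(cond, sc$outerDiameterNm, sc$innerDiameterNm,
                                 nMolecules = sc$nMoleculesPerCluster,
                                 subclusterCount = sc$subclusterCount,
                                 center = centers[i, ]))
                drift <- if (any(sc$driftTotalNm != 0))
                    linearDrift(sc$nFrames, sc$driftTotalNm) else NULL
                acq <- AcquisitionModel(nFrames = sc$nFrames,
                                        meanOnFrames = sc$meanOnFrames,
                                        locPrecision = sc$locPrecisionNm,
                                        meanPhotons = sc$meanPhotons,
                                        backgroundDensity =
                                            sc$backgroundDensityPerUm2PerFrame,
                                        fieldSize = sc$fieldSizeNm,
                                        drift = drift, seed = cellSeed)
                out <- simulateField(models, acq, dims = 2)
                out$centers <- centers
                out
            })
            tab <- sim$table
            rawPath <- file.path(outDir, paste0(base, "_raw.csv"))
            writeLocalizations(tab, rawPath)
            artifacts <- c(artifacts, rawPath)
            if (config$correct$enabled) {
                tab <- stage("correct", {
                    traj <- estimateDrift(tab,
                                          nSubsets = config$correct$nSubsets,
                                          pixelSize = config$correct$pixelSizeNm,
                                          nIterations = config$correct$nIterations)
                    writeCorrectionJSON(traj,
                        file.path(outDir, paste0(base, "_drift.json")))
                    mergeConsecutive(correctDrift(tab, traj),
                                     radius = config$correct$mergeRadiusNm)
                })
                if (config$correct$frc) {
                    res <- stage("correct", frcResolution(tab,
                        pixelSize = config$correct$frcPixelSizeNm,
                        seed = subSeed(cellSeed, 2)))
                    logLine(event = "frc", condition = cond, cell = cell,
                            resolutionNm = res$resolution)
                }
                corrPath <- file.path(outDir, paste0(base, "_corrected.csv"))
                writeLocalizations(tab, corrPath)
                artifacts <- c(artifacts, corrPath)
            }
            centers <- sim$centers[, 1:2, drop = FALSE]
            if (config$segment$enabled) {
                seg <- stage("segment", {
                    vd <- voronoiDensities(tab, dims = 2)
                    segmentClusters(vd, tab, alpha = config$segment$alpha,
                                    nSim = config$segment$nSim,
                                    minSize = config$segment$minSize,
                                    seed = subSeed(cellSeed, 3))
                })
                segPath <- file.path(outDir, paste0(base, "_segmentation.csv"))
                writeSegmentation(tab, seg, segPath)
                artifacts <- c(artifacts, segPath)
                logLine(event = "segment", condition = cond, cell = cell,
                        nClusters = nrow(clusterTable(seg)),
                        threshold = seg@threshold)
                if (nrow(clusterTable(seg)))
                    centers <- as.matrix(clusterTable(seg)[, c("cx", "cy")])
            }
            if (config$profiles$enabled) {
                st <- stage("profiles", {
                    img <- renderHistogram(tab,
                        config$profiles$renderPixelSizeNm,
                        bounds = c(0, sc$fieldSizeNm[1], 0, sc$fieldSizeNm[2]))
                    s <- pickClusters(img, centers = centers,
                                      box = config$profiles$boxNm,
                                      cell = cell)
                    alignToRotationalMean(normalizeImages(s),
                        nIterations = config$profiles$alignIterations,
                        rotStep = config$profiles$rotStepDeg)
                })
                stacks <- if (is.null(stacks)) st else
                    ClusterStack(c(stackImages(stacks), stackImages(st)),
                                 pixelSize = st@pixelSize,
                                 info = rbind(stackInfo(stacks), stackInfo(st)))
                com <- stage("profiles", comRadialProfile(tab, centers,
                    cell = rep(cell, nrow(centers)),
                    searchRadius = config$profiles$comSearchRadiusNm,
                    rmax = config$profiles$comRmaxNm,
                    binWidth = config$profiles$comBinNm))
                comPerCell <- rbind(comPerCell, profileMean(com))
            }
        }
        if (config$profiles$enabled && !is.null(stacks)) {
            prof <- perCellProfileStats(stacks)
            profPath <- file.path(outDir, paste0(cond, "_image_profile.csv"))
            writeRadialProfile(prof, profPath)
            comProf <- data.frame(bin_center_nm =
                                      (seq_len(ncol(comPerCell)) - 0.5) *
                                      config$profiles$comBinNm,
                                  mean = colMeans(comPerCell),
                                  sd = if (nrow(comPerCell) > 1)
                                      apply(comPerCell, 2, stats::sd)
                                  else rep(0, ncol(comPerCell)))
            comPath <- file.path(outDir, paste0(cond, "_com_profile.csv"))
            utils::write.csv(comProf, comPath, row.names = FALSE)
            artifacts <- c(artifacts, profPath, comPath)
            results[[cond]] <- list(imageProfile = prof, comProfile = comProf,
                                    stack = stacks)
            logLine(event = "profiles", condition = cond,
                    halfRadiusNm = halfRadius(prof))
        }
        if (config$reconstruct$enabled && !is.null(stacks)) {
            rec <- stage("reconstruct", {
                ang <- assignAngles(stacks,
                    angularStep = config$reconstruct$angularStepDeg,
                    gridStep = config$reconstruct$gridStepDeg,
                    refinePasses = config$reconstruct$refinePasses)
                vol <- backprojectVolume(stacks, ang)
                val <- reprojectAndValidate(vol, ang, stacks)
                volPath <- file.path(outDir, paste0(cond, "_reconstruction.mrc"))
                writeVolumeMRC(vol, volPath)
                angPath <- file.path(outDir, paste0(cond, "_angles.csv"))
                utils::write.csv(data.frame(image = seq_len(length(stacks)),
                                            eulerAngles(ang)),
                                 angPath, row.names = FALSE)
                logLine(event = "reconstruct", condition = cond,
                        medianReprojectionCorrelation = val$median)
                list(volume = vol, angles = ang, validation = val)
            })
            results[[cond]]$reconstruction <- rec
        }
    }
    logLine(event = "done", artifacts = length(artifacts))
    invisible(list(results = results, artifacts = artifacts, outDir = outDir,
                   configHash = cfgHash))
}

#' Write a radial profile as CSV
#'
#' @param profile a \linkS4class{RadialProfile}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeRadialProfile <- function(profile, path) {
    df <- data.frame(bin_center_nm = profileBins(profile),
                     raw = profile@raw,
                     corrected = profileDensity(profile),
                     normalized = profileNormalized(profile))
    if (length(profileMean(profile))) {
        df$mean <- profileMean(profile)
        df$sd <- profileSd(profile)
    }
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' Write / read a cluster stack as multi-page 32-bit float TIFF
#'
#' @param stack a \linkS4class{ClusterStack}.
#' @param path file path.
#' @return \code{writeClusterStack}: the path, invisibly;
#'   \code{readClusterStack}: a \linkS4class{ClusterStack} (metadata limited
#'   to what TIFF carries: pixel size and scale).
#' @export
writeClusterStack <- function(stack, path) {
    lo <- min(vapply(stackImages(stack), min, numeric(1)), 0)
    hi <- max(vapply(stackImages(stack), max, numeric(1)), lo + 1e-300)
    jsonlite::write_json(list(pixel_size_nm = stack@pixelSize,
                              offset = lo, scale = hi - lo),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    pages <- lapply(stackImages(stack), function(m) (t(m) - lo) / (hi - lo))
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                     reduce = FALSE, compression = "none"))
    invisible(path)
}

#' @rdname writeClusterStack
#' @export
readClusterStack <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    meta <- jsonlite::fromJSON(paste0(path, ".json"))
    imgs <- lapply(pages, function(pg) t(pg) * meta$scale + meta$offset)
    ClusterStack(imgs, pixelSize = meta$pixel_size_nm)
}
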