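# Experiment-level pipeline: stitch -> project -> segment -> quantify ->
# combine angles -> align time -> fit growth models, over a folder
# hierarchy experiment/<fish>/<angle>/<timepoint>/<channel>/tile_*.tif
# with one positions.csv per timepoint. Stages log their inputs and
# outputs and are skipped on re-runs when their outputs already exist.

#' Pipeline configuration
#'
#' @param experimentDir experiment folder (fish/angle/timepoint/channel
#'   hierarchy; see package vignette for the layout).
#' @param outputDir output folder.
#' @param voxelSpacing voxel spacing (z, y, x) in micrometres.
#' @param t0Hpf developmental time of the first timepoint (hours post
#'   fertilisation).
#' @param intervalMinutes time-lapse interval.
#' @param segmentation a \code{\link{segmentationConfig}}.
#' @param searchRadius,scoreFloor stitching parameters.
#' @param models growth models to fit.
#' @param timeOffsetsCsv optional CSV (fish_id, shift_hpf) of per-fish
#'   temporal alignment shifts.
#' @return classed list.
#' @export
pipelineConfig <- function(experimentDir, outputDir,
                           voxelSpacing = c(4, 1.138, 1.138),
                           t0Hpf = 17, intervalMinutes = 20,
                           segmentation = segmentationConfig(),
                           searchRadius = 20, scoreFloor = 0.3,
                           models = c("log_logistic", "log_normal"),
                           timeOffsetsCsv = NULL) {
  structure(list(experimentDir = experimentDir, outputDir = outputDir,
                 voxelSpacing = voxelSpacing, t0Hpf = t0Hpf,
                 intervalMinutes = intervalMinutes,
                 segmentation = segmentation, searchRadius = searchRadius,
                 scoreFloor = scoreFloor, models = models,
                 timeOffsetsCsv = timeOffsetsCsv),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys match the arguments of \code{\link{pipelineConfig}}; the
#' \code{segmentation} section uses \code{nSamples} for the training
#' set size (a bare \code{N} key is a YAML boolean).
#'
#' @param path .yaml/.yml or .json configuration file.
#' @return a \code{pipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  segArgs <- as.list(cfg$segmentation %||% list())
  names(segArgs)[names(segArgs) == "nSamples"] <- "N"
  seg <- do.call(segmentationConfig, segArgs)
  args <- cfg[setdiff(names(cfg), "segmentation")]
  args$segmentation <- seg
  do.call(pipelineConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(logFile, level, ...) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, paste0(...))
  message(line)
  if (!is.null(logFile)) cat(line, "\n", file = logFile, append = TRUE)
}

#' Run the full processing pipeline over an experiment folder
#'
#' Per fish/angle/timepoint: stitches the tiles of both channels (using
#' the endothelial channel's registration for both), writes the fused
#' stacks and a maximum-intensity-projection QC image, segments, and
#' measures the vascular volume. Per fish the angle series are averaged,
#' temporally aligned, and the configured growth models fitted and
#' ranked by RSS. Item failures are recorded and the pipeline continues;
#' completed stages (existing outputs) are skipped on re-runs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return run report list with \code{volumes}, \code{fits},
#'   \code{failures} and \code{log} path.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  ed <- config$experimentDir
  if (!dir.exists(ed)) stop("experiment folder does not exist: ", ed)
  fishDirs <- list.dirs(ed, recursive = FALSE)
  if (length(fishDirs) == 0) stop("experiment folder contains no fish folders")
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$outputDir, "pipeline.log")
  failures <- list()
  rows <- list()
  sp <- config$voxelSpacing

  for (fd in fishDirs) {
    fish <- basename(fd)
    for (ad in list.dirs(fd, recursive = FALSE)) {
      angle <- basename(ad)
      tps <- sort(list.dirs(ad, recursive = FALSE))
      for (ti in seq_along(tps)) {
        tp <- tps[ti]
        item <- sprintf("%s/%s/%s", fish, angle, basename(tp))
        outBase <- file.path(config$outputDir, fish, angle, basename(tp))
        dir.create(outBase, showWarnings = FALSE, recursive = TRUE)
        maskPath <- file.path(outBase, "mask.tif")
        volPath <- file.path(outBase, "volume.csv")
        res <- tryCatch({
          if (file.exists(volPath)) {
            .log(logFile, "INFO", item, ": outputs exist, skipping")
            utils::read.csv(volPath)
          } else {
            .log(logFile, "INFO", item, ": stitching")
            fused <- .stitchTimepoint(tp, sp, config)
            writeVolumeTiff(fused$endothelial,
                            file.path(outBase, "fused_endothelial.tif"))
            mip <- maxProject(intensities(fused$endothelial), 1)
            tiff::writeTIFF(mip / max(mip, 1e-12),
                            file.path(outBase, "mip_qc.tif"),
                            bits.per.sample = 32L)
            .log(logFile, "INFO", item, ": segmenting")
            seg <- segmentVolume(fused$endothelial, fused$rbc,
                                 config$segmentation)
            writeMaskTiff(seg$mask, maskPath)
            writeModelJson(seg$model, file.path(outBase, "model.json"))
            mv <- measureVolume(seg$mask)
            df <- data.frame(fish_id = fish, angle = angle,
                             timepoint = ti,
                             time_hpf = config$t0Hpf +
                               (ti - 1) * config$intervalMinutes / 60,
                             volume_um3 = mv$volumeUm3,
                             voxel_count = mv$voxelCount)
            utils::write.csv(df, volPath, row.names = FALSE)
            .log(logFile, "INFO", item, sprintf(": volume %.4g um^3",
                                                mv$volumeUm3))
            df
          }
        }, error = function(e) {
          .log(logFile, "ERROR", item, ": ", conditionMessage(e))
          failures[[item]] <<- conditionMessage(e)
          NULL
        })
        if (!is.null(res)) rows[[length(rows) + 1]] <- res
      }
    }
  }
  volumes <- if (length(rows)) do.call(rbind, rows) else NULL

  shifts <- NULL
  if (!is.null(config$timeOffsetsCsv) && file.exists(config$timeOffsetsCsv))
    shifts <- utils::read.csv(config$timeOffsetsCsv)

  fits <- list()
  seriesOut <- list()
  if (!is.null(volumes)) {
    for (fish in unique(volumes$fish_id)) {
      sub <- volumes[volumes$fish_id == fish, ]
      angles <- unique(sub$angle)
      series <- lapply(angles, function(a) {
        s <- sub[sub$angle == a, ]
        s <- s[order(s$time_hpf), ]
        VolumeSeries(s$time_hpf, s$volume_um3, fishId = fish,
                     region = "whole", angleIds = a)
      })
      comb <- Reduce(combineAngles, series)
      if (!is.null(shifts)) {
        hit <- match(fish, shifts$fish_id)
        if (!is.na(hit)) comb <- alignTime(comb, shifts$shift_hpf[hit])
      }
      seriesOut[[fish]] <- comb
      if (length(comb@times) > 6 && length(config$models) >= 2) {
        cmp <- tryCatch(compareModels(comb, config$models),
                        error = function(e) NULL)
        if (!is.null(cmp)) {
          fits[[fish]] <- cmp
          utils::write.csv(cbind(fish_id = fish, cmp$table),
                           file.path(config$outputDir,
                                     paste0("fits_", fish, ".csv")),
                           row.names = FALSE)
        }
      }
    }
    writeVolumeSeries(seriesOut,
                      file.path(config$outputDir, "volumes.csv"))
  }
  .log(logFile, "INFO", sprintf("pipeline done: %d items, %d failures",
                                length(rows), length(failures)))
  list(volumes = volumes, series = seriesOut, fits = fits,
       failures = failures, log = logFile)
}

# stitch one timepoint folder: tiles of the endothelial channel drive
# the registration; the same positions are applied to the RBC channel
.stitchTimepoint <- function(tpDir, spacing, config) {
  posCsv <- file.path(tpDir, "positions.csv")
  chDirs <- list.dirs(tpDir, recursive = FALSE)
  chNames <- basename(chDirs)
  need <- c("endothelial", "rbc")
  if (!all(need %in% chNames))
    stop("timepoint folder must contain 'endothelial' and 'rbc' channels")
  # tiles are 16-bit camera frames; restore the count scale so that
  # intensity-dependent features (raw / (1 + |grad|)) behave as they do
  # on native data
  loadTiles <- function(ch) {
    files <- sort(list.files(file.path(tpDir, ch), pattern = "^tile_.*\\.tif$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no tiles for channel ", ch)
    lapply(files, function(f)
      intensities(readVolumeTiff(f, spacing, maxValue = 65535)))
  }
  endoTiles <- loadTiles("endothelial")
  rbcTiles <- loadTiles("rbc")
  n <- length(endoTiles)
  nominal <- if (file.exists(posCsv)) readStagePositions(posCsv, spacing)
             else matrix(0L, n, 3)
  adj <- if (n > 1) cbind(seq_len(n - 1), 2:n) else matrix(integer(0), ncol = 2)
  ts <- new("TileSet", tiles = endoTiles, nominalPositions = nominal,
            refinedPositions = matrix(numeric(0), ncol = 3, nrow = 0),
            truePositions = matrix(numeric(0), ncol = 3, nrow = 0),
            adjacency = adj)
  st <- stitchDataset(ts, config$searchRadius, config$scoreFloor)
  fusedRbc <- fuseLinearBlending(rbcTiles, st$positions)
  list(endothelial = ChannelVolume(pmax(st$fused, 0), spacing, "endothelial"),
       rbc = ChannelVolume(pmax(fusedRbc, 0), spacing, "rbc"))
}
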