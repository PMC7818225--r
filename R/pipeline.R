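# End-to-end orchestration: simulate -> preprocess -> volumes -> fit ->
# group -> compare -> report, as one configured, logged, reproducible run.

.pipelineDefaults <- function() {
  list(simulation = unclass(simulationConfig()),
       preproc = unclass(preprocConfig()),
       grid = list(n = 32L, pixelSizeMm = 4.25, rimMm = 60,
                   headRadiusMm = 85),
       windowMs = c(50, 500),
       smoothing = list(fwhm = c(16, 16, 16)),
       glm = list(models = c("exponential", "linear", "chdet"), tau = 1),
       group = list(alpha = 0.05, model = "exponential"),
       comparison = list(maskMode = "all"),
       seed = 1L, runId = "run")
}

.checkKeys <- function(x, template, path = "") {
  bad <- setdiff(names(x), names(template))
  if (length(bad))
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(bad) > 1) "s" else "",
                 paste0(path, bad, collapse = ", ")))
  for (nm in names(x))
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(x[[nm]]))
      .checkKeys(x[[nm]], template[[nm]], paste0(path, nm, "$"))
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Nested configuration for every stage; defaults are the emulated study
#' conditions (17 subjects, 4 blocks, 6 presentations, 61 channels,
#' 500 Hz, [16 16 16] FWHM smoothing, alpha 0.05). \code{overrides} may
#' replace any subset of keys; unknown keys are rejected before anything
#' runs. \code{readPipelineConfig} reads the same structure from a YAML
#' file.
#'
#' @param overrides named list of overrides, nested like the defaults.
#' @param path YAML file path.
#' @return configuration list of class "PipelineConfig".
#' @export
pipelineConfig <- function(overrides = list()) {
  template <- .pipelineDefaults()
  .checkKeys(overrides, template)
  cfg <- utils::modifyList(template, overrides)
  if (!is.null(overrides$simulation$effects))
    cfg$simulation$effects <- overrides$simulation$effects
  structure(cfg, class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation$effects))
    raw$simulation$effects <- lapply(raw$simulation$effects, function(e)
      do.call(effectSpec, e))
  pipelineConfig(raw)
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

.hashFiles <- function(files) {
  h <- tools::md5sum(files)
  data.frame(file = basename(names(h)), md5 = unname(h),
             row.names = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order on synthetic data, writing per-stage
#' outputs and a run manifest (file hashes, timestamps, config echo) to
#' \code{outDir}. With \code{resume = TRUE} the expensive subject
#' simulation/preprocessing stage is skipped when its outputs from an
#' identical configuration are already present.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory.
#' @param resume reuse existing per-subject averages when valid.
#' @return the manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        resume = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgHash <- .configHash(config)
  manifest <- list(runId = config$runId, seed = config$seed,
                   outDir = outDir,
                   configHash = cfgHash, config = unclass(config),
                   version = as.character(utils::packageVersion("erpmass")),
                   stages = list())
  simcfg <- do.call(simulationConfig,
                    c(config$simulation[setdiff(names(config$simulation),
                                                "seed")],
                      list(seed = config$seed)))
  precfg <- do.call(preprocConfig, config$preproc)
  montage <- makeDefaultMontage()
  grid <- do.call(scalpGrid, c(list(montage = montage), config$grid))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      name = name, files = .hashFiles(out),
      elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"))
    .writeManifest(manifest, outDir)
    out
  }

  # simulate + preprocess (per subject, averages written to disk)
  avgPrefix <- function(s) file.path(outDir, sprintf("avg_s%03d", s))
  oldManifestPath <- file.path(outDir, "manifest.json")
  canResume <- resume && file.exists(oldManifestPath) &&
    identical(jsonlite::read_json(oldManifestPath)$configHash,
              as.character(cfgHash)) &&
    all(file.exists(paste0(vapply(seq_len(simcfg$nSubjects), avgPrefix,
                                  ""), ".f64")))
  avgFiles <- stage("preprocess", {
    fls <- character()
    for (s in seq_len(simcfg$nSubjects)) {
      if (!canResume) {
        ep <- simulateSubject(simcfg, s, montage)
        av <- preprocess(ep, precfg)
        writeAverageSet(av, avgPrefix(s))
        rm(ep)
      }
      fls <- c(fls, paste0(avgPrefix(s), c(".f64", ".json")))
    }
    fls
  })

  # volumes + first-level fits + group + comparison
  spec <- smoothingSpec(config$smoothing$fwhm)
  models <- config$glm$models
  info <- .maskInfo(grid@mask, length(seq(config$windowMs[1],
                                          config$windowMs[2],
                                          by = 1000 / simcfg$samplingRate)))
  pooled <- list(); lme <- list()
  fitFiles <- stage("fit", {
    fls <- character()
    for (m in models) pooled[[m]] <- lme[[m]] <- NULL
    for (s in seq_len(simcfg$nSubjects)) {
      av <- readAverageSet(avgPrefix(s), montage)
      Y <- subjectVoxelMatrix(av, grid, config$windowMs, spec)
      for (m in models) {
        X <- buildDesign(m, simcfg$nBlocks, simcfg$nPresentations,
                         config$glm$tau)
        fit <- fitGLM(Y, X, subject = s)
        pooled[[m] ] <- rbind(pooled[[m]], poolBlocks(fit))
        lme[[m]] <- rbind(lme[[m]], computeLME(fit))
      }
    }
    for (m in models) {
      fn <- file.path(outDir, sprintf("pooled_beta_%s.f64", m))
      con <- file(fn, "wb")
      writeBin(as.vector(pooled[[m]]), con, size = 8, endian = "little")
      close(con)
      fls <- c(fls, fn)
    }
    fls
  })

  groupRes <- list()
  groupFiles <- stage("group", {
    fls <- character()
    for (m in models) {
      spm <- oneSampleF(pooled[[m]], maskDim = info$dim,
                        maskIdx = info$idx,
                        times = seq(config$windowMs[1], config$windowMs[2],
                                    by = 1000 / simcfg$samplingRate))
      resid <- sweep(pooled[[m]], 2, colMeans(pooled[[m]]))
      fw <- estimateSmoothness(resid, info$dim, info$idx)
      thr <- fweThreshold(spm@df, fw, info$dim, info$idx,
                          config$group$alpha)
      tab <- extractClusters(spm, thr, grid, fw)
      groupRes[[m]] <- list(spm = spm, fwhm = fw, threshold = thr,
                             clusters = tab,
                             sigMask = is.finite(spm@F) & spm@F > thr)
      fn <- file.path(outDir, sprintf("clusters_%s.csv", m))
      utils::write.csv(if (is.null(tab)) data.frame() else tab, fn,
                       row.names = FALSE)
      fls <- c(fls, fn)
    }
    fls
  })

  cmpFiles <- stage("compare", {
    pairs <- list(c("exponential", "linear"), c("exponential", "chdet"),
                  c("chdet", "linear"))
    pairs <- Filter(function(p) all(p %in% models), pairs)
    maskAll <- conjunctionMask(lapply(models, function(m)
      groupRes[[m]]$sigMask), mode = config$comparison$maskMode)
    rows <- list()
    for (p in pairs) {
      d <- deltaLME(lme[[p[1]]], lme[[p[2]]], models = p)
      if (any(maskAll))
        rows[[length(rows) + 1L]] <-
          cbind(summarizeComparison(d, maskAll), voxel_set = "mask")
      rows[[length(rows) + 1L]] <-
        cbind(summarizeComparison(d), voxel_set = "all")
    }
    fn <- file.path(outDir, "model_comparison.csv")
    utils::write.csv(do.call(rbind, rows), fn, row.names = FALSE)
    fls <- fn
    for (p in pairs) {
      d <- deltaLME(lme[[p[1]]], lme[[p[2]]], models = p)
      hn <- file.path(outDir, sprintf("dlme_hist_%s_vs_%s.csv",
                                      p[1], p[2]))
      utils::write.csv(deltaLMEHistogram(d), hn, row.names = FALSE)
      fls <- c(fls, hn)
    }
    fls
  })

  manifest$results <- list(
    thresholds = lapply(groupRes, `[[`, "threshold"),
    smoothness = lapply(groupRes, `[[`, "fwhm"),
    nClusters = lapply(groupRes, function(g)
      if (is.null(g$clusters) || !nrow(g$clusters)) 0L else
        length(unique(g$clusters$activation))))
  .writeManifest(manifest, outDir)
  attr(manifest, "groupRes") <- groupRes
  attr(manifest, "lme") <- lme
  attr(manifest, "pooled") <- pooled
  attr(manifest, "grid") <- grid
  invisible(manifest)
}

.writeManifest <- function(manifest, outDir) {
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
}

#' Generate the report bundle of a pipeline run
#'
#' Emits the cluster table (activation / size / latency_ms / p_fwe / F /
#' Z), the model-comparison table, scalp-map PNGs of the group F map at
#' the peak latencies, and per-electrode amplitude-by-presentation data
#' for box plots. With no suprathreshold voxels the cluster CSV contains
#' headers only and a note is printed.
#'
#' @param manifest the value of \code{\link{runPipeline}} (with attached
#'   results).
#' @param outDir report directory.
#' @return character vector of written files, invisibly.
#' @export
reportPipeline <- function(manifest, outDir) {
  groupRes <- attr(manifest, "groupRes")
  grid <- attr(manifest, "grid")
  if (is.null(groupRes))
    stop("missing upstream outputs from stage 'group': re-run the pipeline")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  m <- manifest$config$group$model
  g <- groupRes[[m]]
  files <- character()
  tab <- g$clusters
  fn <- file.path(outDir, "cluster_table.csv")
  if (is.null(tab) || !nrow(tab)) {
    message("no suprathreshold voxels")
    tab <- data.frame(activation = integer(), size = integer(),
                      latency_ms = numeric(), p_fwe = numeric(),
                      F = numeric(), Z = numeric())
  }
  utils::write.csv(tab, fn, row.names = FALSE)
  files <- c(files, fn)
  # scalp maps of the F field at peak latencies
  if (nrow(tab)) {
    spm <- g$spm
    Fvol <- .voxelsToVolume(spm@F, list(dim = spm@maskDim,
                                        idx = spm@maskIdx))
    for (lat in unique(tab$latency_ms[!duplicated(tab$activation)])) {
      fi <- which.min(abs(spm@times - lat))
      png(fp <- file.path(outDir, sprintf("scalp_F_%dms.png",
                                          round(lat))),
          width = 480, height = 480)
      image(pixelCentres(grid), pixelCentres(grid), Fvol[, , fi],
            asp = 1, xlab = "x (mm)", ylab = "y (mm)",
            main = sprintf("group F at %g ms", spm@times[fi]),
            useRaster = TRUE)
      dev.off()
      files <- c(files, fp)
    }
  }
  fn2 <- file.path(outDir, "model_comparison.csv")
  file.copy(file.path(manifest$outDir, "model_comparison.csv"), fn2,
            overwrite = TRUE)
  # per-electrode amplitude-by-presentation data for box plots: mean
  # amplitude over each ground-truth effect window at its centre channel,
  # pooled over blocks, one row per subject and presentation
  montage <- grid@montage
  simcfg <- manifest$config$simulation
  rows <- list()
  for (s in seq_len(simcfg$nSubjects)) {
    av <- readAverageSet(file.path(manifest$outDir,
                                   sprintf("avg_s%03d", s)), montage)
    for (e in simcfg$effects) {
      ch <- which(channelLabels(montage) == e$centerChannel)
      ti <- which(av@times >= e$windowMs[1] & av@times <= e$windowMs[2])
      for (r in seq_len(dim(av@means)[2])) {
        amp <- mean(av@means[, r, ch, ti])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, electrode = e$centerChannel,
          window_start_ms = e$windowMs[1], window_end_ms = e$windowMs[2],
          presentation = r, amplitude_uv = amp)
      }
    }
  }
  fn3 <- file.path(outDir, "boxplot_data.csv")
  utils::write.csv(do.call(rbind, rows), fn3, row.names = FALSE)
  invisible(c(files, fn2, fn3))
}
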