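#' @include AllClasses.R
NULL

#' Pipeline run configuration
#'
#' @slot preset preset name.
#' @slot stages ordered stage selection.
#' @slot seed global seed; every stochastic stage derives its own seed from it.
#' @slot params nested parameter list (scene / patches / detect / measure /
#'   symmetry / gold).
#' @export
setClass("RunConfig", representation(
  preset = "character", stages = "character", seed = "integer",
  params = "list"
))

pipelineStages <- c("simulate", "detect", "measure", "symmetry", "gold", "report")

setValidity("RunConfig", function(object) {
  if (length(object@stages) == 0L)
    return("stage selection must not be empty")
  bad <- setdiff(object@stages, pipelineStages)
  if (length(bad))
    return(paste0("unknown stages: ", paste(bad, collapse = ", ")))
  TRUE
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf("RunConfig '%s': stages %s, seed %d\n", object@preset,
              paste(object@stages, collapse = " -> "), object@seed))
})

presetParams <- function(preset) {
  switch(preset,
    "large-pore" = list(
      mode = "patches",
      patches = list(class = "large", n = 50L, pixelSize = 0.69,
                     patchRadius = 26, snr = 5, background = 0.5,
                     psfSigma = 1.0),
      symmetry = list(snr = 3, nMax = 12L, mControls = 99L)
    ),
    "sheet-lysed-87" = list(
      mode = "sheet",
      scene = list(widthNm = 1500, heightNm = 1500, density = 87,
                   minSeparation = 40, noiseSigma = 0.08, psfSigma = 1.0,
                   pixelSize = 0.69),
      detect = list(radiusGrid = seq(12, 22, by = 2), scoreThreshold = 0.3,
                    minSeparation = 25, ringWidthNm = 2.2),
      measure = list(maxPores = 50L, patchRadius = 26),
      symmetry = list(nMax = 12L, mControls = 99L)
    ),
    "sheet-fraction3-200" = list(
      mode = "sheet",
      scene = list(widthNm = 1500, heightNm = 1500, density = 200,
                   minSeparation = 35, noiseSigma = 0.08, psfSigma = 1.0,
                   pixelSize = 0.69),
      detect = list(radiusGrid = seq(12, 22, by = 2), scoreThreshold = 0.3,
                    minSeparation = 25, ringWidthNm = 2.2),
      measure = list(maxPores = 50L, patchRadius = 26),
      symmetry = list(nMax = 12L, mControls = 99L)
    ),
    "immunogold" = list(
      mode = "sheet",
      scene = list(widthNm = 1500, heightNm = 1500, density = 87,
                   minSeparation = 40, noiseSigma = 0.08, psfSigma = 1.0,
                   pixelSize = 0.69),
      detect = list(radiusGrid = seq(12, 22, by = 2), scoreThreshold = 0.3,
                    minSeparation = 25, ringWidthNm = 2.2),
      measure = list(maxPores = 50L, patchRadius = 26),
      symmetry = list(nMax = 12L, mControls = 99L),
      gold = list(nParticles = 442L, fracAssociated = 0.9, thresholdNm = 20,
                  B = 999L)
    ),
    stop(sprintf("unknown preset '%s'", preset))
  )
}

mergeParams <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeParams(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Build a pipeline configuration
#'
#' Presets encode the study conditions: \code{"large-pore"} (patch-based
#' morphometry and symmetry of the 33.5 nm pore class),
#' \code{"sheet-lysed-87"} and \code{"sheet-fraction3-200"} (membrane sheets
#' at 87 and 200 pores per square micron), and \code{"immunogold"} (a sheet
#' plus gold labelling at the 20 nm association rule).
#'
#' @param preset preset name.
#' @param seed global integer seed.
#' @param stages stage subset (default: all stages meaningful for the preset).
#' @param overrides nested list merged over the preset parameters.
#' @return A \linkS4class{RunConfig}.
#' @examples
#' cfg <- runConfig("large-pore", seed = 7,
#'                  overrides = list(patches = list(n = 5L)))
#' @export
runConfig <- function(preset = c("large-pore", "sheet-lysed-87",
                                 "sheet-fraction3-200", "immunogold"),
                      seed = 1L, stages = NULL, overrides = list()) {
  preset <- match.arg(preset)
  params <- mergeParams(presetParams(preset), overrides)
  if (is.null(stages)) {
    stages <- if (params$mode == "patches")
      c("simulate", "measure", "symmetry", "report")
    else if (preset == "immunogold")
      c("simulate", "detect", "measure", "gold", "report")
    else c("simulate", "detect", "measure", "symmetry", "report")
  }
  new("RunConfig", preset = preset, stages = stages, seed = as.integer(seed),
      params = params)
}

#' Serialize / restore a configuration as YAML
#'
#' @param cfg a \linkS4class{RunConfig}.
#' @param path YAML path.
#' @return \code{writeRunConfig}: the path; \code{readRunConfig}: the
#'   \linkS4class{RunConfig}.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(list(preset = cfg@preset, stages = cfg@stages,
                        seed = cfg@seed, params = cfg@params), path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  new("RunConfig", preset = y$preset, stages = y$stages,
      seed = as.integer(y$seed), params = y$params)
}

sceneFromParams <- function(sp, seed) {
  SheetScene(widthNm = sp$widthNm, heightNm = sp$heightNm,
             density = sp$density, minSeparation = sp$minSeparation,
             noiseSigma = sp$noiseSigma, psfSigma = sp$psfSigma,
             pixelSize = sp$pixelSize, seed = seed)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order (simulate, detect, measure,
#' symmetry, gold, report), writing every stage artifact under \code{outdir}
#' and a machine-readable \code{report.json} aggregating recovered diameters
#' versus ground truth, density estimates, the symmetry scan and the gold
#' association result. The report contains no timestamps, so a rerun with an
#' identical configuration is byte-identical; timings go to \code{run.log}.
#' A stage failure aborts with the failing stage named; artifacts of earlier
#' stages are retained.
#'
#' @param cfg a \linkS4class{RunConfig}.
#' @param outdir output directory (created if needed).
#' @return The report, invisibly (a nested list mirroring report.json).
#' @export
runPipeline <- function(cfg, outdir) {
  stopifnot(is(cfg, "RunConfig"))
  validObject(cfg)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outdir, "run.log")
  logLine <- function(...) cat(sprintf("[%s] %s\n", format(Sys.time()),
                                       sprintf(...)), file = logPath,
                               append = TRUE)
  stageSeeds <- withSeed(cfg@seed, sample.int(.Machine$integer.max - 1L, 8L))
  p <- cfg@params
  state <- new.env(parent = emptyenv())
  report <- list(config = list(preset = cfg@preset, stages = cfg@stages,
                               seed = cfg@seed, params = p),
                 stage_seeds = as.list(stageSeeds))

  runStage <- function(name, fun) {
    logLine("stage %s: start", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logLine("stage %s: done in %.1f s", name, proc.time()[["elapsed"]] - t0)
    out
  }

  for (stage in cfg@stages) {
    if (stage == "simulate") {
      report$simulate <- runStage("simulate", function() {
        if (p$mode == "patches") {
          pp <- p$patches
          model <- poreModelPreset(pp$class)
          noise <- abs(model@contrastOuter) / pp$snr
          patchSeeds <- withSeed(stageSeeds[1], sample.int(1e6, pp$n))
          state$patches <- lapply(seq_len(pp$n), function(i)
            renderPorePatch(model, pixelSize = pp$pixelSize,
                            patchRadius = pp$patchRadius,
                            noiseSigma = noise, seed = patchSeeds[i],
                            background = pp$background,
                            psfSigma = pp$psfSigma))
          state$model <- model
          writeMicrograph(state$patches[[1L]],
                          file.path(outdir, "patch_001.mrc"))
          list(n_patches = pp$n, snr = pp$snr,
               truth = list(d_plug_nm = model@dPlug, d_inner_nm = model@dInner,
                            d_outer_nm = model@dOuter, n_fold = model@nFold))
        } else {
          scene <- sceneFromParams(p$scene, stageSeeds[1])
          out <- renderSheet(scene)
          state$scene <- scene
          state$micrograph <- out$micrograph
          state$truth <- out$truth
          writeMicrograph(out$micrograph, file.path(outdir, "sheet.tif"))
          writeGroundTruth(out$truth, file.path(outdir, "truth_pores.csv"))
          list(n_pores = nrow(out$truth@pores),
               density_true = p$scene$density,
               mask_area_um2 = sceneMaskArea(scene))
        }
      })
    } else if (stage == "detect") {
      report$detect <- runStage("detect", function() {
        if (is.null(state$micrograph)) stop("no simulated sheet to detect on")
        mask <- makeMembraneMask(state$micrograph)
        dt <- detectPores(state$micrograph, mask,
                          radiusGrid = p$detect$radiusGrid,
                          scoreThreshold = p$detect$scoreThreshold,
                          minSeparation = p$detect$minSeparation,
                          ringWidthNm = p$detect$ringWidthNm)
        state$detections <- dt
        writeDetections(dt, file.path(outdir, "detections.csv"))
        dens <- estimateDensity(dt)
        writeJSONFile(dens, file.path(outdir, "density.json"))
        list(n_detections = nrow(dt@detections), density = dens)
      })
    } else if (stage == "measure") {
      report$measure <- runStage("measure", function() {
        if (p$mode == "patches") {
          patches <- state$patches
        } else {
          if (is.null(state$detections)) stop("no detections to measure")
          det <- state$detections@detections
          det <- det[!det$edge_flag, , drop = FALSE]
          det <- utils::head(det, p$measure$maxPores)
          patches <- lapply(seq_len(nrow(det)), function(i)
            extractPatch(state$micrograph, c(det$x_nm[i], det$y_nm[i]),
                         p$measure$patchRadius))
        }
        rows <- lapply(seq_along(patches), function(i) {
          mm <- measurePore(patches[[i]])$measurement
          data.frame(pore_id = i, d_plug_nm = mm@dPlug, d_inner_nm = mm@dInner,
                     d_outer_nm = mm@dOuter,
                     flags = paste(mm@flags, collapse = ";"))
        })
        tab <- do.call(rbind, rows)
        utils::write.csv(tab, file.path(outdir, "ring_measurements.csv"),
                         row.names = FALSE)
        summary <- list(
          n = nrow(tab),
          d_plug_nm = list(mean = mean(tab$d_plug_nm, na.rm = TRUE),
                           sd = stats::sd(tab$d_plug_nm, na.rm = TRUE)),
          d_inner_nm = list(mean = mean(tab$d_inner_nm, na.rm = TRUE),
                            sd = stats::sd(tab$d_inner_nm, na.rm = TRUE)),
          d_outer_nm = list(mean = mean(tab$d_outer_nm, na.rm = TRUE),
                            sd = stats::sd(tab$d_outer_nm, na.rm = TRUE)))
        writeJSONFile(summary, file.path(outdir, "ring_summary.json"))
        state$measurements <- tab
        summary
      })
    } else if (stage == "symmetry") {
      report$symmetry <- runStage("symmetry", function() {
        if (p$mode == "patches") {
          pp <- p$patches
          noise <- abs(state$model@contrastOuter) / p$symmetry$snr
          patch <- renderPorePatch(state$model, pixelSize = pp$pixelSize,
                                   patchRadius = pp$patchRadius,
                                   noiseSigma = noise, seed = stageSeeds[3],
                                   background = pp$background,
                                   psfSigma = pp$psfSigma)
        } else {
          det <- state$detections@detections
          det <- det[!det$edge_flag, , drop = FALSE]
          if (!nrow(det)) stop("no interior detections for symmetry analysis")
          patch <- extractPatch(state$micrograph,
                                c(det$x_nm[1], det$y_nm[1]),
                                p$measure$patchRadius)
        }
        scan <- assessSymmetry(patch, nMax = p$symmetry$nMax,
                               mControls = p$symmetry$mControls,
                               seed = stageSeeds[4])
        writeSymmetryScan(scan, file.path(outdir, "symmetry.json"))
        list(selected_n = if (is.na(scan@selectedN)) "none" else scan@selectedN,
             spectrum_harmonic = scan@spectrumHarmonic,
             scores = stats::setNames(as.list(scan@scores),
                                      paste0("n", scan@orders)))
      })
    } else if (stage == "gold") {
      report$gold <- runStage("gold", function() {
        if (is.null(p$gold)) stop("preset has no gold-labelling parameters")
        if (is.null(state$truth)) stop("no ground truth to place gold on")
        truth <- placeGold(state$truth, state$scene,
                           fracAssociated = p$gold$fracAssociated,
                           thresholdNm = p$gold$thresholdNm,
                           nParticles = p$gold$nParticles,
                           seed = stageSeeds[5])
        writeGroundTruth(truth, file.path(outdir, "truth_pores.csv"),
                         file.path(outdir, "truth_gold.csv"))
        g <- GoldParticleSet(truth@gold,
                             pores = poreTableFromTruth(truth, state$scene),
                             thresholdNm = p$gold$thresholdNm)
        res <- classifyAssociation(g)
        perm <- permutationEnrichment(g, sceneMask(state$scene),
                                      B = p$gold$B, seed = stageSeeds[6])
        res@pValue <- perm$p.value
        writeAssociationResult(res, file.path(outdir, "gold_particles.csv"),
                               file.path(outdir, "association.json"))
        list(n_associated = res@nAssociated, n_not = res@nNot,
             fraction = res@fraction, p_value = perm$p.value,
             null_mean = perm$nullMean)
      })
    } else if (stage == "report") {
      runStage("report", function() {
        writeJSONFile(report, file.path(outdir, "report.json"))
        NULL
      })
    }
  }
  invisible(report)
}
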