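## End-to-end orchestration: configuration, the streaming
## simulate -> segment -> track -> metrics pipeline, and fixture profiles.

.SEGMENT_DEFAULTS <- list(sigma = 1, method = "otsu", threshold = NULL,
                          aMinFactor = 0.25, aMaxFactor = 2, midlines = TRUE)
.TRACK_DEFAULTS <- list(dMax = NULL, gap = 0L, minLen = 30L,
                        maxSpeed = 500, minCoverage = 0.9)
.METRICS_DEFAULTS <- list(angleThreshold = 50, smoothWindow = 5,
                          vCoil = NULL, vMove = NULL)

#' Assemble a pipeline configuration
#'
#' One nested configuration drives simulation, segmentation, tracking and
#' metrics; it serialises to a single JSON document and unknown keys are
#' rejected, so "what ran" is always recoverable from the manifest.
#'
#' @param sim a [WormSimConfig-class] (or a named list of overrides for
#'   [wormSimConfig()]).
#' @param segment,track,metrics named lists overriding the stage defaults
#'   (see Details).
#' @param seed integer master seed.
#' @return An object of class `wormPipelineConfig` (a validated nested
#'   list).
#' @details Stage defaults: segmentation `sigma = 1`, Otsu thresholding,
#'   size gate `[0.25, 2]` x expected worm area, midlines on; tracking
#'   `dMax` = 3 x expected per-frame displacement, `gap = 0`,
#'   `minLen = 30` frames, quality gates `maxSpeed = 500` um/s and
#'   `minCoverage = 0.9`; metrics: reversal angle threshold 50 degrees,
#'   smoothing window 5 frames, cohort-derived coil/moving speed cutoffs.
#' @export
pipelineConfig <- function(sim = wormSimConfig(), segment = list(),
                           track = list(), metrics = list(), seed = 1L) {
  if (is.list(sim)) sim <- do.call(wormSimConfig, sim)
  stopifnot(is(sim, "WormSimConfig"))
  cfg <- list(
    sim = sim,
    segment = .mergeOpts(.SEGMENT_DEFAULTS, segment, "segment"),
    track = .mergeOpts(.TRACK_DEFAULTS, track, "track"),
    metrics = .mergeOpts(.METRICS_DEFAULTS, metrics, "metrics"),
    seed = as.integer(seed)
  )
  class(cfg) <- "wormPipelineConfig"
  cfg
}

.mergeOpts <- function(defaults, opts, stage) {
  if (!length(opts)) return(defaults)
  bad <- setdiff(names(opts), names(defaults))
  if (length(bad))
    stop("unknown ", stage, " option(s): ", paste(bad, collapse = ", "))
  defaults[names(opts)] <- opts
  defaults
}

#' Write / read a pipeline configuration as JSON
#'
#' @param config a `wormPipelineConfig`.
#' @param path JSON file path.
#' @return `readPipelineConfig` returns the reconstructed
#'   `wormPipelineConfig`; the round trip is lossless.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "wormPipelineConfig"))
  simSlots <- methods::slotNames("WormSimConfig")
  simList <- stats::setNames(lapply(simSlots, function(s)
    methods::slot(config$sim, s)), simSlots)
  out <- list(sim = simList, segment = config$segment, track = config$track,
              metrics = config$metrics, seed = config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("sim", "segment", "track", "metrics", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  simArgs <- raw$sim
  badSim <- setdiff(names(simArgs), methods::slotNames("WormSimConfig"))
  if (length(badSim))
    stop("unknown sim key(s): ", paste(badSim, collapse = ", "))
  pipelineConfig(sim = do.call(wormSimConfig, simArgs),
                 segment = .dropNulls(raw$segment),
                 track = .dropNulls(raw$track),
                 metrics = .dropNulls(raw$metrics),
                 seed = raw$seed)
}

.dropNulls <- function(x) if (is.null(x)) list() else x[!vapply(x, is.null, logical(1))]

#' Run the full analysis pipeline
#'
#' Executes segmentation, trajectory linking, quality gating and behavioral
#' metrics, either on a supplied [PlateVideo-class] or — when `video` is
#' `NULL` — on a simulated cohort that is rendered and segmented one frame
#' at a time, so full-scale recordings (1280 x 1024 px, 1800 frames) never
#' have to be held in memory.
#'
#' @param config a `wormPipelineConfig` (or a [WormSimConfig-class], wrapped
#'   with defaults).
#' @param video optional [PlateVideo-class]; `NULL` simulates from
#'   `config$sim`.
#' @param outDir optional directory; when given, all stage tables and a
#'   manifest (config, seed, MD5 hash) are written there.
#' @return list of class `wormPipelineResult`: `objects`, `tracks`,
#'   `orphans`, `rejected`, `summaries`, `cohort`, `truth` (zero rows for
#'   real videos), `manifest`.
#' @examples
#' cfg <- pipelineConfig(sim = list(arenaSize = c(160L, 160L), nWorms = 2,
#'                                  duration = 20, seed = 5),
#'                       track = list(minLen = 10))
#' res <- runPipeline(cfg)
#' res$cohort$table
#' @export
runPipeline <- function(config, video = NULL, outDir = NULL) {
  if (is(config, "WormSimConfig")) config <- pipelineConfig(sim = config)
  stopifnot(inherits(config, "wormPipelineConfig"))
  sc <- config$sim
  seg <- config$segment
  aW <- expectedWormArea(sc)
  aMin <- seg$aMinFactor * aW; aMax <- seg$aMaxFactor * aW

  if (is.null(video)) {
    sim <- simulateWorms(sc)
    truth <- sim$truth
    nF <- length(sim$midlines)
    objects <- vector("list", nF)
    withSeed(sc@seed + 1L, {
      for (f in seq_len(nF)) {
        img <- .renderMidlines(sim$midlines[[f]], sc, noise = TRUE)
        objects[[f]] <- .segmentFrame(img, f, sc@umPerPx, seg$sigma,
                                      seg$method, seg$threshold, aMin, aMax,
                                      midlines = seg$midlines)
      }
    })
    objects <- do.call(rbind, objects)
  } else {
    truth <- groundTruth(video)
    objects <- detectObjects(video, sigma = seg$sigma, method = seg$method,
                             threshold = seg$threshold, aMin = aMin,
                             aMax = aMax, midlines = seg$midlines)
  }
  if (is.null(objects) || !nrow(objects))
    stop("segment stage produced no objects: check input frames and size gate")

  tk <- config$track
  dMax <- if (is.null(tk$dMax)) defaultDMax(sc) else tk$dMax
  linked <- linkTracks(objects, dMax = dMax, gap = tk$gap, minLen = tk$minLen)
  val <- validateTracks(linked$tracks, fps = sc@fps, maxSpeed = tk$maxSpeed,
                        minCoverage = tk$minCoverage)
  if (!nrow(val$accepted))
    stop("track stage: no track passed the quality gates")

  mt <- config$metrics
  summaries <- trackMetrics(val$accepted, fps = sc@fps, umPerPx = sc@umPerPx,
                            angleThreshold = mt$angleThreshold,
                            smoothWindow = mt$smoothWindow,
                            vCoil = mt$vCoil, vMove = mt$vMove)
  cohort <- summarizeCohort(summaries)

  manifest <- list(seed = config$seed, simSeed = sc@seed,
                   dMax = dMax, aMin = aMin, aMax = aMax,
                   nObjects = nrow(objects),
                   nTracks = length(unique(val$accepted$track_id)),
                   nOrphans = nrow(linked$orphans),
                   nRejected = length(unique(val$rejected$track_id)),
                   package = as.character(utils::packageVersion("wormtracer")))
  res <- list(objects = objects, tracks = val$accepted,
              orphans = linked$orphans, rejected = val$rejected,
              summaries = summaries, cohort = cohort, truth = truth,
              manifest = manifest, config = config)
  class(res) <- "wormPipelineResult"
  if (!is.null(outDir)) .writeResult(res, outDir)
  res
}

#' @export
print.wormPipelineResult <- function(x, ...) {
  cat("wormPipelineResult\n")
  cat(sprintf("  %d objects -> %d accepted tracks (%d orphan objects, %d rejected tracks)\n",
              x$manifest$nObjects, x$manifest$nTracks, x$manifest$nOrphans,
              x$manifest$nRejected))
  print(x$cohort$table, row.names = FALSE)
  invisible(x)
}

.writeResult <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dropList <- function(d) d[, !vapply(d, is.list, logical(1)), drop = FALSE]
  utils::write.csv(dropList(res$objects),
                   file.path(outDir, "objects.csv"), row.names = FALSE)
  utils::write.csv(dropList(res$tracks),
                   file.path(outDir, "tracks.csv"), row.names = FALSE)
  utils::write.csv(dropList(res$orphans),
                   file.path(outDir, "orphans.csv"), row.names = FALSE)
  utils::write.csv(dropList(res$rejected),
                   file.path(outDir, "rejected_tracks.csv"), row.names = FALSE)
  utils::write.csv(dropList(res$summaries),
                   file.path(outDir, "behavior_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cohort$table, file.path(outDir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(res$cohort$histogram,
                   file.path(outDir, "speed_histogram.csv"),
                   row.names = FALSE)
  if (nrow(res$truth))
    utils::write.csv(res$truth, file.path(outDir, "ground_truth.csv"),
                     row.names = FALSE)
  cfgPath <- file.path(outDir, "config.json")
  writePipelineConfig(res$config, cfgPath)
  manifest <- c(res$manifest,
                list(configMd5 = unname(tools::md5sum(cfgPath))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

## ---- fixture profiles ------------------------------------------------------

# scaled-down plate geometry shared by all fixture profiles: a 17.5 mm field
# at the native pixel size and frame rate, 90 s recordings — large and long
# enough that 20 animals yield informative per-track rates with few
# collisions, small enough to render quickly
.fixtureBase <- function(seed, nWorms = 20L, duration = 90) {
  wormSimConfig(arenaSize = c(640L, 640L), umPerPx = 27.3, fps = 3,
                duration = duration, nWorms = nWorms, seed = seed)
}

.FIXTURE_PROFILES <- c("wt_like", "mutant_like", "coiler", "rescue_panel")

#' Simulation configurations for named phenotype fixtures
#'
#' `wt_like` is a slow, rarely reversing, never-coiling control cohort;
#' `mutant_like` is a hyperactive cohort (faster, 4x the reversal rate,
#' frequent coiling); `coiler` spends most of its time coiled;
#' `rescue_panel` is a named list of three cohorts (wild type + solvent,
#' mutant + solvent, mutant + drug) in which the drug moves the mutant
#' reversal rate halfway back to wild type.
#'
#' @param profile one of `"wt_like"`, `"mutant_like"`, `"coiler"`,
#'   `"rescue_panel"`.
#' @param seed integer seed (cohorts within a panel get distinct derived
#'   seeds).
#' @param nWorms animals per cohort.
#' @param duration recording length (s).
#' @return A [WormSimConfig-class], or a named list of them for
#'   `"rescue_panel"`.
#' @export
fixtureConfig <- function(profile, seed = 1L, nWorms = 20L, duration = 90) {
  if (!profile %in% .FIXTURE_PROFILES)
    stop("unknown profile '", profile, "'; valid profiles: ",
         paste(.FIXTURE_PROFILES, collapse = ", "))
  base <- .fixtureBase(seed, nWorms, duration)
  tweak <- function(cfg, ...) {
    args <- list(...)
    for (nm in names(args)) methods::slot(cfg, nm) <- args[[nm]]
    validObject(cfg)
    cfg
  }
  switch(profile,
    wt_like = tweak(base, speedMean = 30, speedSd = 8, reversalRate = 1,
                    coilRate = 0),
    mutant_like = tweak(base, speedMean = 75, speedSd = 20, reversalRate = 4,
                        coilRate = 1.2, coilDurationMean = 12),
    coiler = tweak(base, speedMean = 40, speedSd = 10, reversalRate = 2,
                   coilRate = 3, coilDurationMean = 20),
    rescue_panel = list(
      wt_solvent = tweak(base, speedMean = 30, speedSd = 8,
                         reversalRate = 1, coilRate = 0,
                         seed = as.integer(seed)),
      mutant_solvent = tweak(base, speedMean = 75, speedSd = 20,
                             reversalRate = 4, coilRate = 1.2,
                             coilDurationMean = 12,
                             seed = as.integer(seed) + 1000L),
      mutant_drug = tweak(base, speedMean = 75, speedSd = 20,
                          reversalRate = 2.5, coilRate = 0.6,
                          coilDurationMean = 12,
                          seed = as.integer(seed) + 2000L)
    ))
}

#' Generate a named fixture bundle
#'
#' Simulates the profile's cohort(s) and returns (optionally writing to
#' `dir`) the image stacks, ground-truth tables and — for `rescue_panel` —
#' a per-animal assay CSV of ground-truth reversal rates suitable for
#' [groupCompare()] and [percentRescue()].
#'
#' @param profile fixture profile name, see [fixtureConfig()].
#' @param seed integer seed.
#' @param dir optional output directory (TIFF stacks + CSVs).
#' @param render logical; when `FALSE`, skip frame rendering and return only
#'   configurations, ground truth and assay tables (fast).
#' @param nWorms,duration cohort size and recording length passed to
#'   [fixtureConfig()].
#' @return list with `profile`, `configs` (named list), `truth` (named list
#'   of ground-truth data.frames), `videos` (named list of
#'   [PlateVideo-class], if rendered) and `assay` (data.frame of per-animal
#'   reversal rates, `rescue_panel` only).
#' @export
makeFixtures <- function(profile, seed = 1L, dir = NULL, render = TRUE,
                         nWorms = 20L, duration = 90) {
  cfgs <- fixtureConfig(profile, seed, nWorms, duration)
  if (is(cfgs, "WormSimConfig")) cfgs <- stats::setNames(list(cfgs), profile)
  truths <- list(); videos <- list()
  for (nm in names(cfgs)) {
    if (render) {
      v <- simulateCohort(cfgs[[nm]])
      videos[[nm]] <- v
      truths[[nm]] <- groundTruth(v)
    } else {
      truths[[nm]] <- simulateWorms(cfgs[[nm]])$truth
    }
  }
  assay <- NULL
  if (profile == "rescue_panel") {
    assay <- do.call(rbind, lapply(names(truths), function(nm) {
      tr <- truths[[nm]]
      final <- tr[tr$frame == max(tr$frame), ]
      data.frame(animal_id = paste0(nm, "_", final$worm_id), group = nm,
                 reversals_per_min = final$cum_reversals /
                   (max(tr$frame) / cfgs[[nm]]@fps / 60))
    }))
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(cfgs)) {
      if (render) writeVideo(videos[[nm]], file.path(dir, paste0(nm, ".tif")))
      utils::write.csv(truths[[nm]],
                       file.path(dir, paste0(nm, "_truth.csv")),
                       row.names = FALSE)
    }
    if (!is.null(assay))
      utils::write.csv(assay, file.path(dir, "rescue_assay.csv"),
                       row.names = FALSE)
  }
  list(profile = profile, configs = cfgs, truth = truths,
       videos = if (render) videos else NULL, assay = assay)
}
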