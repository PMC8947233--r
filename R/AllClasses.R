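#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib wormtracer, .registration = TRUE
NULL

#' Simulation configuration for synthetic plate videos
#'
#' An S4 container for all parameters of the synthetic crawling-worm video
#' generator. Defaults emulate the recording geometry of a typical automated
#' plate-tracking rig: a 1280 x 1024 px sensor imaging a 35 mm dish at
#' 3 frames/s for 10 min, with up to 20 adult animals (~1 mm long) crawling
#' on a light background.
#'
#' @slot arenaSize integer of length 2, frame size in pixels (rows, cols).
#' @slot umPerPx numeric, microns per pixel.
#' @slot fps numeric, frames per second.
#' @slot duration numeric, recording duration in seconds.
#' @slot nWorms integer, number of animals.
#' @slot bodyLength,bodyWidth numeric, worm dimensions in microns.
#' @slot speedMean,speedSd numeric, per-animal crawling speed distribution
#'   (um/s); each worm draws one speed at initialisation.
#' @slot undulationFreq numeric, dorsoventral undulation frequency (Hz).
#' @slot undulationAmp numeric, transverse undulation amplitude (um).
#' @slot reversalRate numeric, reversal events per minute (Poisson).
#' @slot reversalDurationMean numeric, mean reversal episode length (s).
#' @slot coilRate numeric, coiling events per minute (Poisson).
#' @slot coilDurationMean numeric, mean coil episode length (s).
#' @slot noiseSd numeric, additive Gaussian pixel noise SD on the [0,1]
#'   grayscale scale.
#' @slot seed integer, seed for the generator's random stream.
#'
#' @seealso [wormSimConfig()] for the user-facing constructor,
#'   [simulateCohort()] to generate a video.
#' @exportClass WormSimConfig
setClass("WormSimConfig",
  representation(
    arenaSize = "integer", umPerPx = "numeric", fps = "numeric",
    duration = "numeric", nWorms = "integer",
    bodyLength = "numeric", bodyWidth = "numeric",
    speedMean = "numeric", speedSd = "numeric",
    undulationFreq = "numeric", undulationAmp = "numeric",
    reversalRate = "numeric", reversalDurationMean = "numeric",
    coilRate = "numeric", coilDurationMean = "numeric",
    noiseSd = "numeric", seed = "integer"
  )
)

setValidity("WormSimConfig", function(object) {
  msg <- character()
  if (length(object@arenaSize) != 2L || any(object@arenaSize < 8L))
    msg <- c(msg, "arenaSize must be two integers >= 8 (rows, cols)")
  pos <- c(
    umPerPx = object@umPerPx, fps = object@fps, duration = object@duration,
    bodyLength = object@bodyLength, bodyWidth = object@bodyWidth,
    speedMean = object@speedMean, undulationFreq = object@undulationFreq,
    undulationAmp = object@undulationAmp,
    reversalDurationMean = object@reversalDurationMean,
    coilDurationMean = object@coilDurationMean
  )
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste0(paste(bad, collapse = ", "),
                                        " must be strictly positive"))
  nneg <- c(speedSd = object@speedSd, reversalRate = object@reversalRate,
            coilRate = object@coilRate, noiseSd = object@noiseSd)
  badn <- names(nneg)[!is.finite(nneg) | nneg < 0]
  if (length(badn)) msg <- c(msg, paste0(paste(badn, collapse = ", "),
                                         " must be non-negative"))
  if (object@nWorms < 1L) msg <- c(msg, "nWorms must be >= 1")
  if (length(msg) == 0 &&
      object@bodyLength / object@umPerPx >= min(object@arenaSize))
    msg <- c(msg, "arena too small to contain a worm (bodyLength/umPerPx must be < min arena dimension)")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param arenaSize integer(2), frame size in pixels (rows, cols).
#' @param umPerPx microns per pixel. The default maps a 35 mm dish onto the
#'   long sensor axis.
#' @param fps frames per second.
#' @param duration recording length in seconds.
#' @param nWorms number of animals on the plate.
#' @param bodyLength,bodyWidth worm dimensions (um).
#' @param speedMean,speedSd between-animal crawling speed distribution (um/s).
#' @param undulationFreq undulation frequency (Hz).
#' @param undulationAmp transverse undulation amplitude (um).
#' @param reversalRate reversal events per minute (Poisson, in absolute time).
#' @param reversalDurationMean mean reversal episode duration (s).
#' @param coilRate coil-onset events per minute.
#' @param coilDurationMean mean coil episode duration (s).
#' @param noiseSd additive Gaussian pixel-noise SD ([0,1] gray scale).
#' @param seed integer seed for the simulation random stream.
#'
#' @return A validated [WormSimConfig-class] object.
#' @examples
#' cfg <- wormSimConfig(nWorms = 3, duration = 20)
#' cfg
#' @export
wormSimConfig <- function(arenaSize = c(1024L, 1280L), umPerPx = 27.3,
                          fps = 3, duration = 600, nWorms = 20,
                          bodyLength = 1000, bodyWidth = 80,
                          speedMean = 50, speedSd = 10,
                          undulationFreq = 0.3, undulationAmp = 125,
                          reversalRate = 2, reversalDurationMean = 2,
                          coilRate = 0.3, coilDurationMean = 10,
                          noiseSd = 0.02, seed = 1L) {
  new("WormSimConfig",
      arenaSize = as.integer(arenaSize), umPerPx = umPerPx, fps = fps,
      duration = duration, nWorms = as.integer(nWorms),
      bodyLength = bodyLength, bodyWidth = bodyWidth,
      speedMean = speedMean, speedSd = speedSd,
      undulationFreq = undulationFreq, undulationAmp = undulationAmp,
      reversalRate = reversalRate,
      reversalDurationMean = reversalDurationMean,
      coilRate = coilRate, coilDurationMean = coilDurationMean,
      noiseSd = noiseSd, seed = as.integer(seed))
}

setMethod("show", "WormSimConfig", function(object) {
  cat("WormSimConfig\n")
  cat(sprintf("  arena: %d x %d px (%.1f um/px), %g fps, %g s\n",
              object@arenaSize[1], object@arenaSize[2], object@umPerPx,
              object@fps, object@duration))
  cat(sprintf("  worms: n=%d, body %g x %g um, speed %g +/- %g um/s\n",
              object@nWorms, object@bodyLength, object@bodyWidth,
              object@speedMean, object@speedSd))
  cat(sprintf("  behavior: reversals %g/min (dur %g s), coils %g/min (dur %g s)\n",
              object@reversalRate, object@reversalDurationMean,
              object@coilRate, object@coilDurationMean))
  cat(sprintf("  noise sd %g, seed %d\n", object@noiseSd, object@seed))
})

#' Plate video container
#'
#' Ordered grayscale frames with physical calibration (um/px) and frame rate,
#' optionally carrying the simulator's per-frame ground truth.
#'
#' @slot frames numeric array (rows x cols x nframes), intensities in [0,1].
#' @slot umPerPx microns per pixel.
#' @slot fps frames per second.
#' @slot groundTruth data.frame of per-(frame, worm) truth records (may have
#'   zero rows for real recordings): columns `frame`, `worm_id`, `x_um`,
#'   `y_um`, `mode`, `speed_um_s`, `cum_reversals`, `cum_bends`.
#'
#' @seealso [simulateCohort()], [detectObjects()]
#' @exportClass PlateVideo
setClass("PlateVideo",
  representation(frames = "array", umPerPx = "numeric", fps = "numeric",
                 groundTruth = "data.frame")
)

setValidity("PlateVideo", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a rows x cols x nframes array")
  if (any(!is.finite(object@frames))) return("frame intensities must be finite")
  if (object@umPerPx <= 0 || object@fps <= 0) return("umPerPx and fps must be > 0")
  TRUE
})

#' @describeIn PlateVideo-class number of frames.
#' @param x,object a `PlateVideo`.
#' @export
nFrames <- function(x) dim(x@frames)[3]

#' @describeIn PlateVideo-class frame rate (frames/s).
#' @export
frameRate <- function(x) x@fps

#' @describeIn PlateVideo-class pixel size (um/px).
#' @export
pixelSize <- function(x) x@umPerPx

#' @describeIn PlateVideo-class extract frame `i` as a matrix.
#' @param i frame index (1-based).
#' @export
getFrame <- function(x, i) x@frames[, , i]

#' @describeIn PlateVideo-class the simulator's ground-truth table (zero rows
#'   for real recordings).
#' @export
groundTruth <- function(x) x@groundTruth

setMethod("show", "PlateVideo", function(object) {
  d <- dim(object@frames)
  cat(sprintf("PlateVideo: %d frames of %d x %d px, %.1f um/px, %g fps (%.1f s)\n",
              d[3], d[1], d[2], object@umPerPx, object@fps, d[3] / object@fps))
  if (nrow(object@groundTruth))
    cat(sprintf("  ground truth: %d records, %d worms\n",
                nrow(object@groundTruth),
                length(unique(object@groundTruth$worm_id))))
})
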