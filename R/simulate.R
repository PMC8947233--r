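## Synthetic plate-video generator.
##
## Worms are agents with a centroid (um), heading, undulation phase and a
## behavioral mode (RUN / REVERSAL / COIL). The body is a discretised midline
## of 21 points built by integrating a tangent-angle profile, which keeps
## consecutive points exactly equidistant and the arc length exactly equal to
## the body length. Reversal and coil onsets are Poisson processes in absolute
## time; episode durations are exponential.

.N_MIDLINE <- 21L

#' Create the initial state of one simulated worm
#'
#' @param config a [WormSimConfig-class].
#' @param id integer worm id.
#' @return A `WormState`: a named list with fields `id`, `x`, `y` (centroid,
#'   um), `heading` (radians), `phase` (undulation phase, radians), `mode`
#'   (`"RUN"`, `"REVERSAL"` or `"COIL"`), `modeTimeLeft` (s), `nextReversal`
#'   and `nextCoil` (s until the next Poisson event), `speed` (um/s),
#'   `cumReversals` and `cumBends` (event counters).
#' @details Consumes random numbers from the current stream; wrap in a seeded
#'   context (as [simulateWorms()] does) for reproducibility.
#' @export
initWormState <- function(config, id = 1L) {
  xmax <- (config@arenaSize[2] - 1) * config@umPerPx
  ymax <- (config@arenaSize[1] - 1) * config@umPerPx
  m <- min(config@bodyLength, xmax / 2, ymax / 2)
  v <- -1
  while (v <= 0) v <- stats::rnorm(1, config@speedMean, config@speedSd)
  list(id = as.integer(id),
       x = stats::runif(1, m, xmax - m),
       y = stats::runif(1, m, ymax - m),
       heading = stats::runif(1, 0, 2 * pi),
       phase = stats::runif(1, 0, 2 * pi),
       mode = "RUN", modeTimeLeft = Inf,
       nextReversal = .expWait(config@reversalRate),
       nextCoil = .expWait(config@coilRate),
       speed = v, cumReversals = 0L, cumBends = 0L)
}

#' Advance one worm state by one time step
#'
#' Implements the behavioral state machine: reversal events occur as a
#' Poisson process at `reversalRate` (absolute time) and flip the heading by
#' an angle drawn uniformly in \[120, 180\] degrees (random side); coil onsets
#' occur at `coilRate` and freeze the animal in a closed-loop posture;
#' episode durations are exponential with the configured means. Inside a
#' one-body-length margin the worm steers gradually back towards the arena
#' interior; specular reflection at the wall is kept as a failsafe.
#'
#' @param state a `WormState` list (see [initWormState()]).
#' @param dt time step in seconds (normally `1/fps`).
#' @param config a [WormSimConfig-class].
#' @return The updated `WormState`.
#' @export
stepBehavior <- function(state, dt, config) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be a positive number of seconds")
  # episode expiry
  if (state$mode != "RUN") {
    state$modeTimeLeft <- state$modeTimeLeft - dt
    if (state$modeTimeLeft <= 0) {
      state$mode <- "RUN"
      state$modeTimeLeft <- Inf
    }
  }
  # coil onset (Poisson in absolute time; ignored while already coiled)
  state$nextCoil <- state$nextCoil - dt
  if (state$nextCoil <= 0) {
    if (state$mode != "COIL") {
      state$mode <- "COIL"
      state$modeTimeLeft <- stats::rexp(1, 1 / config@coilDurationMean)
    }
    state$nextCoil <- .expWait(config@coilRate)
  }
  # reversal event (also fires while coiled: counts and flips heading)
  state$nextReversal <- state$nextReversal - dt
  if (state$nextReversal <= 0) {
    flip <- stats::runif(1, 120, 180) * pi / 180 * sample(c(-1, 1), 1)
    state$heading <- (state$heading + flip) %% (2 * pi)
    state$cumReversals <- state$cumReversals + 1L
    if (state$mode != "COIL") {
      state$mode <- "REVERSAL"
      state$modeTimeLeft <- stats::rexp(1, 1 / config@reversalDurationMean)
    }
    state$nextReversal <- .expWait(config@reversalRate)
  }
  if (state$mode != "COIL") {
    state <- .steerFromWalls(state, dt, config)
    state$x <- state$x + state$speed * dt * cos(state$heading)
    state$y <- state$y + state$speed * dt * sin(state$heading)
    # undulation phase advances only while crawling; a mid-body bend completes
    # every half period
    oldPhase <- state$phase
    state$phase <- state$phase + 2 * pi * config@undulationFreq * dt
    state$cumBends <- state$cumBends +
      (floor(state$phase / pi) - floor(oldPhase / pi))
    state <- .reflectAtWalls(state, config)
  }
  state
}

# gradual steering towards the interior inside a one-body-length margin;
# turn rate capped low enough that the trajectory bend stays below a
# reversal detector's angle threshold
.steerFromWalls <- function(state, dt, config, turnRate = 15 * pi / 180) {
  xmax <- (config@arenaSize[2] - 1) * config@umPerPx
  ymax <- (config@arenaSize[1] - 1) * config@umPerPx
  m <- min(config@bodyLength, xmax / 3, ymax / 3)
  dx <- (state$x < m) - (state$x > xmax - m)
  dy <- (state$y < m) - (state$y > ymax - m)
  if (dx == 0 && dy == 0) return(state)
  target <- atan2(dy, dx)
  diff <- (target - state$heading + pi) %% (2 * pi) - pi
  step <- sign(diff) * min(abs(diff), turnRate * dt)
  state$heading <- (state$heading + step) %% (2 * pi)
  state
}

# failsafe specular reflection keeping the whole body inside the arena
.reflectAtWalls <- function(state, config) {
  xmax <- (config@arenaSize[2] - 1) * config@umPerPx
  ymax <- (config@arenaSize[1] - 1) * config@umPerPx
  half <- config@bodyLength / 2 + config@undulationAmp
  lox <- min(half, xmax / 2); loy <- min(half, ymax / 2)
  if (state$x < lox) {
    state$x <- 2 * lox - state$x
    state$heading <- (pi - state$heading) %% (2 * pi)
  } else if (state$x > xmax - lox) {
    state$x <- 2 * (xmax - lox) - state$x
    state$heading <- (pi - state$heading) %% (2 * pi)
  }
  if (state$y < loy) {
    state$y <- 2 * loy - state$y
    state$heading <- (-state$heading) %% (2 * pi)
  } else if (state$y > ymax - loy) {
    state$y <- 2 * (ymax - loy) - state$y
    state$heading <- (-state$heading) %% (2 * pi)
  }
  state
}

#' Discretised body midline of a worm state
#'
#' Builds the 21-point midline by integrating a tangent-angle profile:
#' a sinusoidal bend along the body for crawling modes, a full-circle sweep
#' (circumference equal to the body length) for the coiled posture. Points
#' are exactly equidistant in arc length and the polyline is translated so
#' its mean equals the worm centroid.
#'
#' @param state a `WormState`.
#' @param config a [WormSimConfig-class].
#' @return A 21 x 2 matrix of (x, y) positions in microns.
#' @export
wormMidline <- function(state, config) {
  n <- .N_MIDLINE
  L <- config@bodyLength
  ds <- L / (n - 1)
  s <- seq(-L / 2, L / 2, length.out = n)
  smid <- s[-n] + ds / 2
  if (state$mode == "COIL") {
    psi <- state$heading + 2 * pi * smid / L
  } else {
    alpha <- 2 * pi * config@undulationAmp / L
    psi <- state$heading + alpha * sin(2 * pi * smid / L + state$phase)
  }
  px <- cumsum(c(0, ds * cos(psi)))
  py <- cumsum(c(0, ds * sin(psi)))
  if (state$mode == "COIL") {
    # closed loop: first and last point coincide, so centre on the unique
    # vertices (the circle centre); the rendered annulus centroid then sits
    # exactly at the worm centroid regardless of heading
    cx <- mean(px[-n]); cy <- mean(py[-n])
  } else {
    cx <- mean(px); cy <- mean(py)
  }
  cbind(x = px - cx + state$x, y = py - cy + state$y)
}

#' Render one video frame from worm states
#'
#' Worm bodies are drawn dark on a light background by stroking each midline
#' with the body width (distance-to-polyline rasterisation); optional
#' additive Gaussian pixel noise emulates the camera. A coiled worm renders
#' as a closed loop enclosing at least one background pixel at the default
#' geometry.
#'
#' @param worms list of `WormState` objects (may be empty).
#' @param config a [WormSimConfig-class].
#' @param noise logical, add Gaussian pixel noise (consumes random numbers
#'   from the current stream).
#' @param bg,fg background and worm intensities on the [0,1] gray scale.
#' @return A `rows x cols` numeric matrix with values in [0,1]; pixel (r, c)
#'   (1-based matrix indices) is centred at ((r-1) um/px, (c-1) um/px).
#' @export
renderFrame <- function(worms, config, noise = TRUE, bg = 0.9, fg = 0.15) {
  nr <- config@arenaSize[1]; nc <- config@arenaSize[2]
  u <- config@umPerPx
  img <- matrix(bg, nr, nc)
  for (w in worms) {
    ml <- wormMidline(w, config)
    img <- .strokeMidline(img, ml, config@bodyWidth / 2, u, fg)
  }
  if (noise && config@noiseSd > 0)
    .noiseClampCpp(img, config@noiseSd)
  img
}

# stamp a midline stroke of radius rw (um) onto img: dense resampling of
# the polyline, then a per-point disk fill in compiled code. Open midlines
# (crawling worms) taper hemispherically over the final half-width at each
# end so the rendered extent equals the body length; closed loops (coiled
# worms) keep full width so the annulus stays intact. The image is modified
# in place (callers always pass a freshly allocated frame buffer) and
# returned for convenience.
.strokeMidline <- function(img, ml, rw, u, fg) {
  t0 <- seq_len(nrow(ml))
  tt <- seq(1, nrow(ml), by = 0.25)    # 4x resampling for a smooth stroke
  dx <- stats::approx(t0, ml[, 1], tt)$y
  dy <- stats::approx(t0, ml[, 2], tt)$y
  seg <- sqrt(diff(dx)^2 + diff(dy)^2)
  s <- c(0, cumsum(seg))
  closed <- sqrt(sum((ml[1, ] - ml[nrow(ml), ])^2)) < rw / 2
  if (closed) {
    rws <- rep(rw, length(dx))
  } else {
    dEnd <- pmin(s, max(s) - s)        # arc distance to the nearer end
    rws <- ifelse(dEnd >= rw, rw,
                  rw * sqrt(pmax(0, 1 - ((rw - dEnd) / rw)^2)))
  }
  .strokeCpp(img, dx, dy, rws, u, fg)
  img
}

#' Simulate worm kinematics and ground truth (no rendering)
#'
#' Runs the behavioral state machine for all animals over the full recording
#' and returns the per-frame ground-truth table plus the per-frame midlines
#' needed to render frames. This is the cheap, kinematics-only half of
#' [simulateCohort()]; [runPipeline()] uses it to stream frames through
#' segmentation without materialising the whole video.
#'
#' @param config a [WormSimConfig-class].
#' @return A list with elements
#'   \describe{
#'     \item{truth}{data.frame with one row per (frame, worm): `frame`,
#'       `worm_id`, `x_um`, `y_um`, `mode`, `speed_um_s`, `cum_reversals`,
#'       `cum_bends`.}
#'     \item{midlines}{list over frames; each element a list over worms of
#'       21 x 2 midline matrices (um).}
#'     \item{config}{the input configuration.}
#'   }
#' @examples
#' sim <- simulateWorms(wormSimConfig(nWorms = 2, duration = 10, seed = 7))
#' head(sim$truth)
#' @export
simulateWorms <- function(config) {
  stopifnot(is(config, "WormSimConfig"))
  validObject(config)
  .checkCrowding(config)
  nFrames <- round(config@fps * config@duration)
  dt <- 1 / config@fps
  withSeed(config@seed, {
    states <- lapply(seq_len(config@nWorms), function(i) initWormState(config, i))
    midlines <- vector("list", nFrames)
    rows <- vector("list", nFrames)
    for (f in seq_len(nFrames)) {
      states <- lapply(states, stepBehavior, dt = dt, config = config)
      midlines[[f]] <- lapply(states, wormMidline, config = config)
      rows[[f]] <- data.frame(
        frame = f,
        worm_id = vapply(states, `[[`, integer(1), "id"),
        x_um = vapply(states, `[[`, numeric(1), "x"),
        y_um = vapply(states, `[[`, numeric(1), "y"),
        mode = vapply(states, `[[`, character(1), "mode"),
        speed_um_s = vapply(states, function(s)
          if (s$mode == "COIL") 0 else s$speed, numeric(1)),
        cum_reversals = vapply(states, `[[`, integer(1), "cumReversals"),
        cum_bends = vapply(states, function(s) as.integer(s$cumBends),
                           integer(1))
      )
    }
    list(truth = do.call(rbind, rows), midlines = midlines, config = config)
  })
}

.checkCrowding <- function(config) {
  wormArea <- config@bodyLength * config@bodyWidth / config@umPerPx^2
  arena <- prod(config@arenaSize)
  if (config@nWorms * wormArea > 0.3 * arena)
    stop("overcrowded arena: total worm area exceeds 30% of the arena (",
         config@nWorms, " worms of ~", round(wormArea), " px2 in ",
         arena, " px2)")
  invisible(TRUE)
}

#' Simulate a full plate video with ground truth
#'
#' Renders every frame of the configured recording and returns a
#' [PlateVideo-class] carrying the ground-truth table. Memory scales as
#' `rows * cols * nframes` doubles, so full-scale recordings
#' (1280 x 1024 px, 1800 frames) should be analysed with the streaming
#' [runPipeline()] instead of being materialised here.
#'
#' @param config a [WormSimConfig-class].
#' @param noise logical, add pixel noise.
#' @return A [PlateVideo-class].
#' @examples
#' cfg <- wormSimConfig(arenaSize = c(128L, 128L), nWorms = 1, duration = 5,
#'                      seed = 3)
#' vid <- simulateCohort(cfg)
#' vid
#' @export
simulateCohort <- function(config, noise = TRUE) {
  sim <- simulateWorms(config)
  nF <- length(sim$midlines)
  frames <- array(0, dim = c(config@arenaSize[1], config@arenaSize[2], nF))
  withSeed(config@seed + 1L, {
    for (f in seq_len(nF))
      frames[, , f] <- .renderMidlines(sim$midlines[[f]], config, noise)
  })
  new("PlateVideo", frames = frames, umPerPx = config@umPerPx,
      fps = config@fps, groundTruth = sim$truth)
}

# render a frame directly from precomputed midlines
.renderMidlines <- function(mls, config, noise = TRUE, bg = 0.9, fg = 0.15) {
  nr <- config@arenaSize[1]; nc <- config@arenaSize[2]
  img <- matrix(bg, nr, nc)
  for (ml in mls)
    img <- .strokeMidline(img, ml, config@bodyWidth / 2, config@umPerPx, fg)
  if (noise && config@noiseSd > 0)
    .noiseClampCpp(img, config@noiseSd)
  img
}

#' Write a simulated video and its ground truth to disk
#'
#' Frames go to a multi-page 8-bit grayscale TIFF (or a directory of
#' zero-padded PNGs), the ground truth to CSV.
#'
#' @param video a [PlateVideo-class].
#' @param path output file (`.tif`) or directory (PNG mode).
#' @param format `"tiff"` or `"png"`.
#' @return `path`, invisibly.
#' @export
writeVideo <- function(video, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  nF <- nFrames(video)
  if (format == "tiff") {
    # EBImage expects x,y transposed relative to row,col matrices
    arr <- aperm(video@frames, c(2, 1, 3))
    img <- EBImage::Image(arr, colormode = "Grayscale")
    EBImage::writeImage(img, path, type = "tiff", bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (f in seq_len(nF)) {
      img <- EBImage::Image(t(video@frames[, , f]), colormode = "Grayscale")
      EBImage::writeImage(img, file.path(path, sprintf("frame_%05d.png", f)),
                          type = "png")
    }
  }
  invisible(path)
}

#' Read a plate video from disk
#'
#' @param path a multi-page TIFF file or a directory of PNG frames
#'   (lexicographic frame order).
#' @param umPerPx,fps physical calibration to attach.
#' @return A [PlateVideo-class] (no ground truth).
#' @export
readVideo <- function(path, umPerPx, fps) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG frames found in ", path)
    imgs <- lapply(files, function(f) EBImage::imageData(EBImage::readImage(f)))
    frames <- array(0, dim = c(dim(imgs[[1]])[2], dim(imgs[[1]])[1],
                               length(imgs)))
    for (f in seq_along(imgs)) frames[, , f] <- t(imgs[[f]])
  } else {
    img <- EBImage::readImage(path)
    d <- EBImage::imageData(img)
    if (length(dim(d)) == 2) d <- array(d, dim = c(dim(d), 1))
    frames <- aperm(d, c(2, 1, 3))
  }
  new("PlateVideo", frames = frames, umPerPx = umPerPx, fps = fps,
      groundTruth = .emptyTruth())
}

.emptyTruth <- function() {
  data.frame(frame = integer(), worm_id = integer(), x_um = numeric(),
             y_um = numeric(), mode = character(), speed_um_s = numeric(),
             cum_reversals = integer(), cum_bends = integer())
}
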