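## Per-track behavioral readouts: crawling speed, reversals per minute,
## fraction of time coiled, body bends per minute.

#' Per-step and mean crawling speed of a track
#'
#' Speed at each step is the centroid displacement between consecutive
#' linked frames times the frame rate.
#'
#' @param track data.frame with columns `frame`, `x_um`, `y_um` (one track).
#' @param fps frames per second.
#' @return list with `series` (um/s per step) and `mean` (um/s).
#' @export
computeSpeed <- function(track, fps) {
  if (nrow(track) < 2) stop("track must have at least 2 frames")
  tr <- track[order(track$frame), , drop = FALSE]
  dt <- diff(tr$frame) / fps
  dd <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
  series <- dd / dt
  list(series = series, mean = mean(series))
}

#' Detect reversals along a trajectory
#'
#' A reversal is a bend in the trajectory whose angle exceeds
#' `angleThreshold` degrees. At each interior point the pre- and post-
#' displacement vectors are taken over `smoothWindow` frames on either side
#' (suppressing sub-pixel jitter); points whose windowed displacement is
#' below `smoothWindow * minStep` are ignored. One event is scored per
#' contiguous excursion above the threshold (the frame of maximal angle),
#' so a single turn is never counted twice.
#'
#' @param track data.frame with `frame`, `x_um`, `y_um`.
#' @param fps frames per second.
#' @param angleThreshold bend angle threshold in degrees.
#' @param smoothWindow half-window in frames for the displacement vectors.
#' @param minStep minimum mean per-frame displacement (um) for the angle to
#'   be evaluated.
#' @return list with `events` (data.frame: `frame`, `index`, `turn_angle`)
#'   and `ratePerMin` (events per minute of observed track time).
#' @examples
#' # a 180-degree turn halfway
#' tr <- data.frame(frame = 1:60, x_um = c(1:30, 29:0) * 20, y_um = 0)
#' detectReversals(tr, fps = 3)$events
#' @export
detectReversals <- function(track, fps, angleThreshold = 50,
                            smoothWindow = 5, minStep = 5) {
  w <- as.integer(smoothWindow)
  n <- nrow(track)
  if (n < 2 * w + 2) stop("track too short for the smoothing window")
  tr <- track[order(track$frame), , drop = FALSE]
  x <- tr$x_um; y <- tr$y_um
  idx <- (w + 1):(n - w)
  preX <- x[idx] - x[idx - w];  preY <- y[idx] - y[idx - w]
  postX <- x[idx + w] - x[idx]; postY <- y[idx + w] - y[idx]
  lpre <- sqrt(preX^2 + preY^2); lpost <- sqrt(postX^2 + postY^2)
  ok <- lpre >= w * minStep & lpost >= w * minStep
  ang <- rep(0, length(idx))
  ang[ok] <- .vecAngle(preX[ok], preY[ok], postX[ok], postY[ok])
  supra <- ok & ang > angleThreshold
  events <- .runPeaks(supra, ang)
  obsMin <- (n - 1) / fps / 60
  ev <- data.frame(frame = tr$frame[idx[events]], index = idx[events],
                   turn_angle = ang[events])
  list(events = ev, ratePerMin = nrow(ev) / obsMin)
}

# running-mean filter on a track's centroid columns (edges use shrinking
# windows)
.smoothTrack <- function(tr, window = 3L) {
  tr <- tr[order(tr$frame), , drop = FALSE]
  n <- nrow(tr)
  if (n < window) return(tr)
  h <- (window - 1L) %/% 2L
  sm <- function(v) {
    cs <- cumsum(c(0, v))
    i0 <- pmax(seq_len(n) - h, 1L); i1 <- pmin(seq_len(n) + h, n)
    (cs[i1 + 1L] - cs[i0]) / (i1 - i0 + 1L)
  }
  tr$x_um <- sm(tr$x_um)
  tr$y_um <- sm(tr$y_um)
  tr
}

# indices of the maximal element (first on ties) of each TRUE run
.runPeaks <- function(supra, value) {
  out <- integer(0)
  i <- 1L; n <- length(supra)
  while (i <= n) {
    if (supra[i]) {
      j <- i
      while (j < n && supra[j + 1L]) j <- j + 1L
      seg <- i:j
      out <- c(out, seg[which.max(value[seg])])
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Fraction of track time spent coiled
#'
#' A frame counts as coiled when the segmented object has at least one hole
#' (closed-loop posture) and the instantaneous speed is at or below `vCoil`.
#'
#' The gate speed is the net displacement over a `lag`-frame window on each
#' side divided by the elapsed time: over ~1 s a stationary coiled animal's
#' segmentation jitter does not accumulate while genuine crawling does, so
#' this separates the two far more cleanly than frame-to-frame
#' differentiation.
#'
#' @param track data.frame with `frame`, `x_um`, `y_um`, `n_holes`.
#' @param fps frames per second.
#' @param vCoil speed cutoff (um/s), typically 10% of the cohort median
#'   speed.
#' @param lag half-window, in frames, of the gate-speed estimator.
#' @return fraction in [0,1].
#' @export
coilFraction <- function(track, fps, vCoil, lag = 2L) {
  stopifnot("n_holes" %in% names(track))
  tr <- track[order(track$frame), , drop = FALSE]
  gs <- .laggedSpeed(tr$x_um, tr$y_um, tr$frame, fps, lag)
  mean(tr$n_holes >= 1 & gs <= vCoil)
}

# net-displacement speed over [i-lag, i+lag], clamped at the track ends
.laggedSpeed <- function(x, y, frame, fps, lag) {
  n <- length(x)
  i0 <- pmax(seq_len(n) - lag, 1L)
  i1 <- pmin(seq_len(n) + lag, n)
  dd <- sqrt((x[i1] - x[i0])^2 + (y[i1] - y[i0])^2)
  dt <- (frame[i1] - frame[i0]) / fps
  dt[dt == 0] <- 1 / fps
  dd / dt
}

#' Body bends per minute from mid-body curvature
#'
#' The signed curvature at the midline mid-point is computed per frame on
#' the arc-length-resampled midline (three-point estimator with a
#' `curvOffset`-point lever arm). A bend is a local extremum of this series
#' whose sign is opposite to the previously counted bend, reaching at least
#' `ampFrac` of the series' 90th-percentile magnitude (hysteresis against
#' sub-pixel curvature noise), scored only in frames where the animal moves
#' at `vMove` or faster. The rate is normalised by moving time.
#'
#' @param track data.frame with `frame`, `x_um`, `y_um` and a `midline` list
#'   column of k x 2 micron matrices (zero rows when unavailable).
#' @param fps frames per second.
#' @param vMove speed cutoff (um/s) defining "moving", typically 20% of the
#'   cohort median speed.
#' @param curvOffset lever arm, in resampled points, of the curvature
#'   estimator.
#' @param ampFrac hysteresis fraction of the 90th-percentile |curvature|.
#' @param minMidlineFrac minimum fraction of frames with a usable midline.
#' @return list with `bendsPerMin`, `nBends`, `movingTime` (s), `kappa`
#'   (the per-frame mid-body curvature series, NA where unavailable) and
#'   `flag` (`"ok"` or `"insufficient_midlines"`).
#' @export
countBodyBends <- function(track, fps, vMove, curvOffset = 5, ampFrac = 0.3,
                           minMidlineFrac = 0.8) {
  stopifnot("midline" %in% names(track))
  tr <- track[order(track$frame), , drop = FALSE]
  n <- nrow(tr)
  mls <- .orientMidlines(tr$midline)
  have <- vapply(mls, function(m) !is.null(m) && nrow(m) >= 5, logical(1))
  spd <- computeSpeed(tr, fps)$series
  frameSpeed <- c(spd[1], spd)
  moving <- frameSpeed >= vMove
  movingTime <- sum(moving) / fps
  if (mean(have) < minMidlineFrac) {
    return(list(bendsPerMin = NA_real_, nBends = NA_integer_,
                movingTime = movingTime, kappa = rep(NA_real_, n),
                flag = "insufficient_midlines"))
  }
  kappa <- rep(NA_real_, n)
  for (f in which(have))
    kappa[f] <- .midBodyCurvature(mls[[f]], curvOffset)
  nb <- .countAlternatingBends(kappa, moving, ampFrac)
  list(bendsPerMin = if (movingTime > 0) nb / (movingTime / 60) else 0,
       nBends = nb, movingTime = movingTime, kappa = kappa, flag = "ok")
}

# orient each midline so that endpoints match the previous oriented midline
.orientMidlines <- function(midlines) {
  out <- vector("list", length(midlines))
  prev <- NULL
  for (f in seq_along(midlines)) {
    m <- midlines[[f]]
    if (is.null(m) || !nrow(m)) next
    if (!is.null(prev)) {
      d2 <- function(a, b) sum((a - b)^2)
      straight <- d2(m[1, ], prev[1, ]) + d2(m[nrow(m), ], prev[nrow(prev), ])
      flipped <- d2(m[nrow(m), ], prev[1, ]) + d2(m[1, ], prev[nrow(prev), ])
      if (flipped < straight) m <- m[nrow(m):1, , drop = FALSE]
    }
    out[[f]] <- m
    prev <- m
  }
  out
}

# signed curvature (rad/um) at the mid-point of an arc-length-resampled
# midline
.midBodyCurvature <- function(ml, curvOffset = 5, npts = 21L) {
  rs <- .resampleArc(ml, npts)
  mid <- (npts + 1L) %/% 2L
  k <- min(curvOffset, mid - 1L)
  p0 <- rs[mid - k, ]; p1 <- rs[mid, ]; p2 <- rs[mid + k, ]
  u <- p1 - p0; v <- p2 - p1
  crossz <- u[1] * v[2] - u[2] * v[1]
  dot <- sum(u * v)
  theta <- atan2(crossz, dot)
  arc <- sqrt(sum(u^2)) + sqrt(sum(v^2))
  if (arc == 0) return(0)
  theta / (arc / 2)
}

# resample a polyline to n points equally spaced in arc length
.resampleArc <- function(ml, n) {
  seg <- sqrt(rowSums(diff(ml)^2))
  s <- c(0, cumsum(seg))
  if (s[length(s)] == 0) return(ml[rep(1, n), , drop = FALSE])
  tt <- seq(0, s[length(s)], length.out = n)
  cbind(stats::approx(s, ml[, 1], tt)$y, stats::approx(s, ml[, 2], tt)$y)
}

# alternating-sign extremum counter with amplitude hysteresis
.countAlternatingBends <- function(kappa, moving, ampFrac) {
  valid <- which(!is.na(kappa))
  if (length(valid) < 3) return(0L)
  kv <- kappa[valid]
  thr <- ampFrac * stats::quantile(abs(kv), 0.9, names = FALSE)
  lastSign <- 0
  nb <- 0L
  for (j in 2:(length(valid) - 1)) {
    k <- kv[j]
    isMax <- k > kv[j - 1] && k >= kv[j + 1]
    isMin <- k < kv[j - 1] && k <= kv[j + 1]
    if (!isMax && !isMin) next
    if (abs(k) < thr) next
    if (!moving[valid[j]]) next
    s <- sign(k)
    if (s != 0 && s != lastSign) {
      nb <- nb + 1L
      lastSign <- s
    }
  }
  nb
}

#' Behavioral summary of every track in a cohort
#'
#' Computes the four readouts per accepted track. The coil and moving speed
#' cutoffs default to 10% and 20% of the cohort median mean speed.
#'
#' @param tracks data.frame from [linkTracks()] / [validateTracks()] with
#'   `track_id`, `frame`, `x_um`, `y_um`, `n_holes` and (for body bends) a
#'   `midline` list column.
#' @param fps frames per second.
#' @param umPerPx microns per pixel (sets the reversal detector's minimum
#'   step, 0.2 px-equivalent per frame).
#' @param angleThreshold reversal bend-angle threshold (degrees).
#' @param smoothWindow reversal smoothing half-window (frames).
#' @param vCoil,vMove speed cutoffs (um/s); `NULL` for cohort defaults.
#' @param smoothCentroids window (frames) of a running-mean filter applied
#'   to each track's centroids before any metric is computed; frame-to-frame
#'   differentiation amplifies segmentation jitter, and a light low-pass
#'   (default 3 frames = 1 s at 3 fps) removes it without attenuating
#'   crawling-scale motion. Set to 1 to disable.
#' @param minLen tracks shorter than this are skipped.
#' @return data.frame with one row per track: `track_id`, `mean_speed`,
#'   `reversals_per_min`, `body_bends_per_min`, `coil_fraction`,
#'   `observed_time`, `n_frames`, `bend_flag`, plus a `speed_series` list
#'   column.
#' @export
trackMetrics <- function(tracks, fps, umPerPx = 27.3, angleThreshold = 50,
                         smoothWindow = 5, vCoil = NULL, vMove = NULL,
                         smoothCentroids = 3L, minLen = NULL) {
  stopifnot(nrow(tracks) > 0)
  byTrack <- split(tracks, tracks$track_id)
  if (smoothCentroids > 1L)
    byTrack <- lapply(byTrack, .smoothTrack, window = smoothCentroids)
  if (is.null(minLen)) minLen <- 2 * smoothWindow + 2
  byTrack <- byTrack[vapply(byTrack, nrow, integer(1)) >= minLen]
  if (!length(byTrack)) stop("no track long enough to summarise")
  speeds <- lapply(byTrack, computeSpeed, fps = fps)
  med <- stats::median(vapply(speeds, `[[`, numeric(1), "mean"))
  if (is.null(vCoil)) vCoil <- 0.1 * med
  if (is.null(vMove)) vMove <- 0.2 * med
  minStep <- 0.2 * umPerPx
  haveMidlines <- "midline" %in% names(tracks)
  haveHoles <- "n_holes" %in% names(tracks)
  rows <- lapply(seq_along(byTrack), function(i) {
    tr <- byTrack[[i]]
    rev <- detectReversals(tr, fps, angleThreshold, smoothWindow, minStep)
    cf <- if (haveHoles) coilFraction(tr, fps, vCoil) else NA_real_
    if (haveMidlines) {
      bb <- countBodyBends(tr, fps, vMove)
    } else {
      bb <- list(bendsPerMin = NA_real_, flag = "no_midlines")
    }
    out <- data.frame(
      track_id = tr$track_id[1],
      mean_speed = speeds[[i]]$mean,
      reversals_per_min = rev$ratePerMin,
      body_bends_per_min = bb$bendsPerMin,
      coil_fraction = cf,
      observed_time = (nrow(tr) - 1) / fps,
      n_frames = nrow(tr),
      bend_flag = bb$flag
    )
    out$speed_series <- I(list(speeds[[i]]$series))
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "vCoil") <- vCoil
  attr(res, "vMove") <- vMove
  res
}

#' Cohort-level summary and pooled speed histogram
#'
#' Reports each readout two ways: the unweighted mean ± SEM across tracks
#' (the per-animal statistic used in group comparisons) and a pooled,
#' time-weighted estimate (per-step speeds pooled; event counts divided by
#' total observed time; coiled frames over total frames). The pooled value is
#' the one comparable to frame-weighted ground truth or to the mean of a
#' pooled speed histogram: tracks fragment where animals touch, and weighting
#' fragments equally would over-weight short, noisy fragments.
#'
#' @param summaries data.frame from [trackMetrics()].
#' @param binWidth histogram bin width in um/s.
#' @return list with
#'   \describe{
#'     \item{table}{data.frame `metric`, `mean`, `sem`, `n`, `pooled` for the
#'       four readouts (SEM is NA for n = 1).}
#'     \item{histogram}{data.frame `bin_lo`, `bin_hi`, `count` pooled over
#'       every per-step speed of every track.}
#'   }
#' @export
summarizeCohort <- function(summaries, binWidth = 5) {
  if (!nrow(summaries)) stop("no track summaries supplied")
  metrics <- c("mean_speed", "reversals_per_min", "body_bends_per_min",
               "coil_fraction")
  w <- summaries$observed_time
  pooledOf <- function(m) {
    v <- summaries[[m]]
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    switch(m,
      mean_speed = mean(unlist(summaries$speed_series)),
      coil_fraction = sum(v[ok] * summaries$n_frames[ok]) /
        sum(summaries$n_frames[ok]),
      sum(v[ok] * w[ok]) / sum(w[ok]))
  }
  tab <- do.call(rbind, lapply(metrics, function(m) {
    v <- summaries[[m]]
    data.frame(metric = m, mean = mean(v, na.rm = TRUE), sem = .sem(v),
               n = sum(!is.na(v)), pooled = pooledOf(m))
  }))
  pooled <- unlist(summaries$speed_series)
  if (length(pooled)) {
    breaks <- seq(0, max(pooled) + binWidth, by = binWidth)
    h <- hist(pooled, breaks = breaks, plot = FALSE)
    histo <- data.frame(bin_lo = head(breaks, -1), bin_hi = breaks[-1],
                        count = h$counts)
  } else {
    histo <- data.frame(bin_lo = numeric(), bin_hi = numeric(),
                        count = integer())
  }
  list(table = tab, histogram = histo)
}
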