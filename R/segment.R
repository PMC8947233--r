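## Per-frame image processing: Gaussian smoothing, thresholding, size-gated
## connected-component extraction with centroid, hole count and midline.
## Convention: 8-connected objects, 4-connected holes; (row, col) pixel
## coordinates are 0-based with pixel centres at integer positions, so
## physical position = pixel * umPerPx.

#' Gaussian smoothing of a frame
#'
#' Separable spatial Gaussian convolution (kernel radius 3 sigma, replicate
#' padding). `sigma = 0` returns the input unchanged.
#'
#' @param frame numeric matrix of grayscale intensities.
#' @param sigma smoothing SD in pixels (>= 0).
#' @return Smoothed matrix of the same size.
#' @export
preprocessFrame <- function(frame, sigma = 1) {
  if (!is.matrix(frame) || !length(frame)) stop("frame must be a non-empty matrix")
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(frame)
  .gaussBlurCpp(frame, sigma)
}

#' Otsu threshold of a grayscale frame
#'
#' Maximises between-class variance over a 256-bin histogram of intensities
#' in [0,1]; returns the threshold (upper bin edge midpoint) on the same
#' scale.
#'
#' @param frame numeric matrix with intensities in [0,1].
#' @return Scalar threshold.
#' @export
otsuThreshold <- function(frame) {
  h <- .hist256Cpp(frame)
  p <- h / sum(h)
  i <- seq_along(p) - 1
  w0 <- cumsum(p)
  mu <- cumsum(p * i)
  mt <- mu[length(mu)]
  bc <- (mt * w0 - mu)^2 / (w0 * (1 - w0))
  bc[!is.finite(bc)] <- -1
  bc <- bc[-length(bc)]                     # threshold below the top bin
  (which.max(bc) - 1 + 0.5) / 256
}

#' Binarize a frame into a worm mask
#'
#' Worms are dark objects on a light background, so the mask is
#' `intensity < threshold`.
#'
#' @param frame numeric matrix in [0,1].
#' @param method `"otsu"` (per-frame automatic threshold) or `"fixed"`.
#' @param threshold required when `method = "fixed"`.
#' @return Logical matrix; the threshold used is attached as attribute
#'   `"threshold"`.
#' @export
binarizeFrame <- function(frame, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  thr <- switch(method,
    otsu = otsuThreshold(frame),
    fixed = {
      if (is.null(threshold)) stop("method 'fixed' requires a threshold")
      threshold
    })
  mask <- frame < thr
  attr(mask, "threshold") <- thr
  mask
}

#' Count enclosed holes in a binary object mask
#'
#' A hole is a 4-connected background component fully enclosed by the object
#' (i.e. not reachable from the mask border). Coiled worms produce masks with
#' one or more holes.
#'
#' @param mask logical or 0/1 matrix.
#' @return Integer hole count.
#' @export
countHoles <- function(mask) {
  if (!length(mask)) stop("mask must be non-empty")
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  # pad so all outside background is one border-connected component
  p <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  bgl <- .label4Cpp(1L - p)                 # 4-connected background labels
  # the padded border always belongs to label 1; anything else is enclosed
  max(bgl) - 1L
}

#' Midline of a single segmented worm
#'
#' Thins the mask to a one-pixel skeleton (Zhang-Suen) and prunes it to its
#' longest path (double breadth-first search over the 8-connected skeleton
#' graph), giving an ordered head-to-tail point list; which end is "head" is
#' arbitrary but deterministic for a given mask. Objects with holes (coiled
#' postures) have no simple midline and return zero points with a reason
#' flag.
#'
#' @param mask logical or 0/1 matrix containing one 8-connected object.
#' @return A k x 2 matrix of 0-based (row, col) skeleton coordinates ordered
#'   along the body, with attribute `"reason"` equal to `"ok"` or `"coiled"`.
#'   Zero rows when no simple path exists.
#' @export
skeletonMidline <- function(mask) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  if (!any(m == 1)) stop("mask is empty")
  lab <- .label8Cpp(m)
  if (max(lab) > 1) stop("mask must contain a single connected object")
  empty <- function(reason) {
    out <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("row", "col")))
    attr(out, "reason") <- reason
    out
  }
  if (countHoles(m) > 0) return(empty("coiled"))
  # pad so thinning never touches the matrix border
  p <- matrix(0L, nrow(m) + 2, ncol(m) + 2)
  p[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  sk <- .thinCpp(p)
  pts <- which(sk == 1L, arr.ind = TRUE)
  if (nrow(pts) == 0) return(empty("degenerate"))
  path <- .longestSkeletonPath(pts, dim(sk))
  out <- cbind(row = pts[path, 1] - 2, col = pts[path, 2] - 2)  # unpad, 0-base
  out <- .extendToTips(out, m)
  attr(out, "reason") <- "ok"
  out
}

# thinning erodes the body ends by roughly half the body width; walk each
# endpoint outward along its local direction until leaving the mask so the
# midline spans nose to tail
.extendToTips <- function(path, mask) {
  if (nrow(path) < 2) return(path)
  extend <- function(pEnd, pIn) {
    d <- pEnd - pIn
    nd <- sqrt(sum(d^2))
    if (nd == 0) return(NULL)
    d <- d / nd
    added <- NULL
    last <- pEnd
    for (t in seq_len(nrow(mask) + ncol(mask))) {
      q <- round(pEnd + t * d)
      if (q[1] < 0 || q[2] < 0 || q[1] >= nrow(mask) || q[2] >= ncol(mask))
        break
      if (mask[q[1] + 1, q[2] + 1] == 0) break
      if (!is.null(added) && all(q == added[nrow(added), ])) next
      if (all(q == last)) next
      added <- rbind(added, q)
      last <- q
    }
    added
  }
  n <- nrow(path)
  k <- min(3L, n - 1L)
  head_ext <- extend(path[1, ], path[1 + k, ])
  tail_ext <- extend(path[n, ], path[n - k, ])
  out <- path
  if (!is.null(head_ext))
    out <- rbind(head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE], out)
  if (!is.null(tail_ext)) out <- rbind(out, tail_ext)
  dimnames(out) <- list(NULL, c("row", "col"))
  out
}

# longest geodesic path on a skeleton point set: BFS from an arbitrary pixel
# to the farthest pixel e1, then BFS from e1 recording parents
.longestSkeletonPath <- function(pts, dims) {
  n <- nrow(pts)
  if (n == 1) return(1L)
  lin <- (pts[, 2] - 1) * dims[1] + pts[, 1]
  idx <- integer(prod(dims))
  idx[lin] <- seq_len(n)
  nbOffsets <- c(-1, 1, -dims[1], dims[1],
                 -dims[1] - 1, -dims[1] + 1, dims[1] - 1, dims[1] + 1)
  bfs <- function(start) {
    dist <- rep.int(-1L, n); parent <- integer(n)
    dist[start] <- 0L
    queue <- integer(n); queue[1] <- start; qh <- 1L; qt <- 1L
    while (qh <= qt) {
      cur <- queue[qh]; qh <- qh + 1L
      for (o in nbOffsets) {
        nb <- idx[lin[cur] + o]
        if (nb > 0L && dist[nb] < 0L) {
          dist[nb] <- dist[cur] + 1L
          parent[nb] <- cur
          qt <- qt + 1L; queue[qt] <- nb
        }
      }
    }
    list(dist = dist, parent = parent)
  }
  e1 <- which.max(bfs(1L)$dist)
  b2 <- bfs(e1)
  e2 <- which.max(b2$dist)
  path <- integer(b2$dist[e2] + 1L)
  cur <- e2
  for (k in seq_along(path)) {
    path[length(path) - k + 1L] <- cur
    cur <- b2$parent[cur]
  }
  path
}

#' Extract size-gated objects from a binary mask
#'
#' Labels 8-connected components, discards those outside the `[aMin, aMax]`
#' area gate (too-small specks, merged multi-worm blobs), and computes per
#' object the centroid, bounding box, hole count and (optionally) the
#' skeleton midline.
#'
#' @param mask logical matrix from [binarizeFrame()].
#' @param frameIndex integer frame number stored with each object.
#' @param umPerPx microns per pixel for physical coordinates.
#' @param aMin,aMax inclusive area gate in pixels (`aMin < aMax`).
#' @param midlines logical, compute skeleton midlines for hole-free objects.
#' @param keepMasks logical, keep each object's cropped mask (list column).
#' @return A data.frame with one row per retained object: `frame`, `obj_id`,
#'   `row`, `col` (0-based pixel centroid), `x_um`, `y_um`, `area_px`,
#'   `n_holes`, plus list columns `midline` (k x 2 matrix of (x, y) microns,
#'   zero rows when unavailable) and optionally `mask`.
#' @export
extractObjects <- function(mask, frameIndex = 1L, umPerPx = 1, aMin, aMax,
                           midlines = TRUE, keepMasks = FALSE) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  lab <- .label8Cpp(m)
  .extractFromLabels(lab, frameIndex, umPerPx, aMin, aMax, midlines,
                     keepMasks)
}

# shared core: per-label stats in one compiled pass, then per-object hole
# count and midline on the cropped bounding box
.extractFromLabels <- function(lab, frameIndex, umPerPx, aMin, aMax,
                               midlines = TRUE, keepMasks = FALSE) {
  if (!(aMin < aMax)) stop("aMin must be < aMax")
  nlab <- max(lab)
  out <- .emptyObjects(keepMasks)
  if (nlab == 0) return(out)
  st <- .labelStatsCpp(lab, nlab)
  keep <- which(st$area >= aMin & st$area <= aMax)
  if (!length(keep)) return(out)
  nk <- length(keep)
  nh <- integer(nk)
  mls <- vector("list", nk)
  masks <- if (keepMasks) vector("list", nk) else NULL
  for (k in seq_len(nk)) {
    l <- keep[k]
    sub <- lab[(st$minR[l] + 1L):(st$maxR[l] + 1L),
               (st$minC[l] + 1L):(st$maxC[l] + 1L), drop = FALSE]
    sub <- matrix(as.integer(sub == l), nrow(sub), ncol(sub))
    nh[k] <- countHoles(sub)
    ml <- matrix(numeric(0), 0, 2)
    if (midlines && nh[k] == 0) {
      mlp <- skeletonMidline(sub)
      if (nrow(mlp)) {
        # to global 0-based pixel, then microns (x = col, y = row)
        ml <- cbind(x = (mlp[, "col"] + st$minC[l]) * umPerPx,
                    y = (mlp[, "row"] + st$minR[l]) * umPerPx)
      }
    }
    mls[[k]] <- ml
    if (keepMasks) masks[[k]] <- sub
  }
  rowC <- st$sumR[keep] / st$area[keep]
  colC <- st$sumC[keep] / st$area[keep]
  res <- data.frame(
    frame = as.integer(frameIndex), obj_id = seq_len(nk),
    row = rowC, col = colC,
    x_um = colC * umPerPx, y_um = rowC * umPerPx,
    area_px = st$area[keep], n_holes = nh,
    bbox_r0 = st$minR[keep], bbox_r1 = st$maxR[keep],
    bbox_c0 = st$minC[keep], bbox_c1 = st$maxC[keep]
  )
  res$midline <- I(mls)
  if (keepMasks) res$mask <- I(masks)
  res
}

.emptyObjects <- function(keepMasks = FALSE) {
  out <- data.frame(frame = integer(), obj_id = integer(), row = numeric(),
                    col = numeric(), x_um = numeric(), y_um = numeric(),
                    area_px = integer(), n_holes = integer(),
                    bbox_r0 = integer(), bbox_r1 = integer(),
                    bbox_c0 = integer(), bbox_c1 = integer())
  out$midline <- I(list())
  if (keepMasks) out$mask <- I(list())
  out
}

#' Expected worm area in pixels for a simulation geometry
#'
#' @param config a [WormSimConfig-class].
#' @return Approximate rendered area (length x width) in px^2, used to set
#'   the default size gate.
#' @export
expectedWormArea <- function(config) {
  config@bodyLength * config@bodyWidth / config@umPerPx^2
}

# segment one frame matrix; returns the object table (fused threshold +
# labeling avoids materialising the mask)
.segmentFrame <- function(img, frameIndex, umPerPx, sigma, method, threshold,
                          aMin, aMax, midlines = TRUE) {
  sm <- preprocessFrame(img, sigma)
  thr <- if (identical(method, "fixed")) {
    if (is.null(threshold)) stop("method 'fixed' requires a threshold")
    threshold
  } else otsuThreshold(sm)
  lab <- .labelDarkCpp(sm, thr)
  .extractFromLabels(lab, frameIndex, umPerPx, aMin, aMax, midlines)
}

#' Detect worm-sized objects in every frame of a video
#'
#' Runs the smoothing / thresholding / size-gated extraction stage on each
#' frame. The default area gate is `[0.25, 2]` times the expected worm area
#' (supplied directly or derived from a simulation config): the lower bound
#' drops noise specks, and the upper bound drops merged multi-worm blobs —
#' a touching pair is ~2.2x the single-worm area, while a single animal's
#' area varies by well under 2x with posture.
#'
#' @param video a [PlateVideo-class].
#' @param sigma Gaussian smoothing SD in px.
#' @param method,threshold thresholding method, see [binarizeFrame()].
#' @param expectedArea expected single-worm area in px^2 (or a
#'   [WormSimConfig-class] via `config`).
#' @param config optional [WormSimConfig-class] used for `expectedArea`.
#' @param aMin,aMax explicit area gate (overrides `expectedArea`).
#' @param midlines logical, compute skeleton midlines.
#' @return data.frame of detected objects (see [extractObjects()]).
#' @examples
#' cfg <- wormSimConfig(arenaSize = c(96L, 96L), nWorms = 1, duration = 3,
#'                      seed = 11)
#' vid <- simulateCohort(cfg)
#' obj <- detectObjects(vid, config = cfg)
#' head(obj[, c("frame", "x_um", "y_um", "area_px", "n_holes")])
#' @export
detectObjects <- function(video, sigma = 1, method = c("otsu", "fixed"),
                          threshold = NULL, expectedArea = NULL, config = NULL,
                          aMin = NULL, aMax = NULL, midlines = TRUE) {
  method <- match.arg(method)
  if (is.null(aMin) || is.null(aMax)) {
    if (is.null(expectedArea)) {
      if (is.null(config)) stop("supply aMin/aMax, expectedArea, or config")
      expectedArea <- expectedWormArea(config)
    }
    if (is.null(aMin)) aMin <- 0.25 * expectedArea
    if (is.null(aMax)) aMax <- 2 * expectedArea
  }
  res <- vector("list", nFrames(video))
  for (f in seq_len(nFrames(video)))
    res[[f]] <- .segmentFrame(getFrame(video, f), f, pixelSize(video),
                              sigma, method, threshold, aMin, aMax, midlines)
  do.call(rbind, res)
}
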