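## Centroid-proximity trajectory linking. Objects in consecutive frames are
## linked when their centroid displacement is at most dMax; per frame pair
## the assignment maximises the number of links and, among those, minimises
## the total linked displacement (exact matching by connected-component
## enumeration; ties broken towards lower object ids).

#' Link per-frame objects into worm trajectories
#'
#' @param objects data.frame of detected objects from [detectObjects()]
#'   (columns `frame`, `obj_id`, `x_um`, `y_um`, ... ).
#' @param dMax maximum centroid displacement (um) between linked objects.
#' @param gap maximum number of missing frames bridged inside a track
#'   (0 = strictly consecutive frames).
#' @param minLen minimum track length in frames; shorter tracks are moved to
#'   the orphan table with reason `"short_track"`.
#' @return A list with
#'   \describe{
#'     \item{tracks}{data.frame: the object columns plus `track_id`, sorted
#'       by track and frame.}
#'     \item{orphans}{data.frame of objects not in any accepted track, with a
#'       `reason` column.}
#'   }
#'   Every input object appears in exactly one of the two tables.
#' @examples
#' obj <- data.frame(frame = rep(1:50, each = 2), obj_id = rep(1:2, 50),
#'                   x_um = c(rbind(1:50 * 10, 1:50 * 10 + 2000)),
#'                   y_um = 0)
#' lt <- linkTracks(obj, dMax = 100, minLen = 10)
#' table(lt$tracks$track_id)
#' @export
linkTracks <- function(objects, dMax, gap = 0L, minLen = 30L) {
  stopifnot(all(c("frame", "obj_id", "x_um", "y_um") %in% names(objects)))
  if (!nrow(objects)) {
    return(list(tracks = cbind(objects, track_id = integer(0)),
                orphans = cbind(objects, reason = character(0))))
  }
  ord <- order(objects$frame, objects$obj_id)
  objects <- objects[ord, , drop = FALSE]
  frames <- sort(unique(objects$frame))
  rowsByFrame <- split(seq_len(nrow(objects)), objects$frame)

  trackOf <- integer(nrow(objects))      # assigned track id per object row
  nextId <- 0L
  # active track bookkeeping (parallel vectors)
  aId <- integer(0); aX <- numeric(0); aY <- numeric(0); aF <- integer(0)

  for (f in frames) {
    rows <- rowsByFrame[[as.character(f)]]
    live <- which(f - aF <= gap + 1L)
    m <- integer(length(rows))           # matched active-index per object
    if (length(live) && length(rows)) {
      cost <- outer(seq_along(live), seq_along(rows),
                    function(i, j) sqrt((aX[live[i]] - objects$x_um[rows[j]])^2 +
                                        (aY[live[i]] - objects$y_um[rows[j]])^2))
      asg <- .assignLinks(matrix(cost, length(live), length(rows)), dMax)
      m[asg$cols] <- live[asg$rows]
    }
    for (k in seq_along(rows)) {
      r <- rows[k]
      if (m[k] > 0L) {
        trackOf[r] <- aId[m[k]]
        aX[m[k]] <- objects$x_um[r]; aY[m[k]] <- objects$y_um[r]
        aF[m[k]] <- f
      } else {
        nextId <- nextId + 1L
        trackOf[r] <- nextId
        aId <- c(aId, nextId); aX <- c(aX, objects$x_um[r])
        aY <- c(aY, objects$y_um[r]); aF <- c(aF, f)
      }
    }
    stale <- f - aF > gap + 1L
    if (any(stale)) {
      aId <- aId[!stale]; aX <- aX[!stale]; aY <- aY[!stale]; aF <- aF[!stale]
    }
  }

  objects$track_id <- trackOf
  len <- table(trackOf)
  longIds <- as.integer(names(len)[len >= minLen])
  keep <- objects$track_id %in% longIds
  tracks <- objects[keep, , drop = FALSE]
  # renumber accepted tracks consecutively in order of first appearance
  if (nrow(tracks)) {
    first <- tapply(seq_len(nrow(tracks)), tracks$track_id, min)
    remap <- order(order(first))
    names(remap) <- names(first)
    tracks$track_id <- as.integer(remap[as.character(tracks$track_id)])
    tracks <- tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
  }
  orphans <- objects[!keep, , drop = FALSE]
  orphans$track_id <- NULL
  if (nrow(orphans)) orphans$reason <- "short_track"
  else orphans$reason <- character(0)
  rownames(tracks) <- rownames(orphans) <- NULL
  list(tracks = tracks, orphans = orphans)
}

# exact assignment between active tracks (rows) and objects (cols):
# feasible links are cost <= dMax; maximise matches, then minimise total
# cost, then prefer lexicographically lower object columns row by row.
# Connected components of the feasibility graph are solved independently;
# components with more than 8 rows fall back to greedy nearest pairs.
.assignLinks <- function(cost, dMax) {
  feas <- is.finite(cost) & cost <= dMax
  nr <- nrow(cost); nc <- ncol(cost)
  rowsOut <- integer(0); colsOut <- integer(0)
  if (!any(feas)) return(list(rows = rowsOut, cols = colsOut))
  # connected components over the bipartite feasibility graph
  compR <- integer(nr); compC <- integer(nc); nComp <- 0L
  for (i in seq_len(nr)) {
    if (compR[i] || !any(feas[i, ])) next
    nComp <- nComp + 1L
    qr <- i
    while (length(qr)) {
      compR[qr] <- nComp
      qc <- which(colSums(feas[qr, , drop = FALSE]) > 0 & compC == 0L)
      compC[qc] <- nComp
      qr <- if (length(qc))
        which(rowSums(feas[, qc, drop = FALSE]) > 0 & compR == 0L)
      else integer(0)
    }
  }
  for (cc in seq_len(nComp)) {
    R <- which(compR == cc); C <- which(compC == cc)
    if (length(R) == 1L && length(C) == 1L) {
      rowsOut <- c(rowsOut, R); colsOut <- c(colsOut, C)
    } else if (length(R) <= 8L) {
      sub <- .enumMatch(cost[R, C, drop = FALSE], feas[R, C, drop = FALSE])
      rowsOut <- c(rowsOut, R[sub$rows]); colsOut <- c(colsOut, C[sub$cols])
    } else {
      sub <- .greedyMatch(cost[R, C, drop = FALSE], feas[R, C, drop = FALSE])
      rowsOut <- c(rowsOut, R[sub$rows]); colsOut <- c(colsOut, C[sub$cols])
    }
  }
  list(rows = rowsOut, cols = colsOut)
}

# exhaustive max-cardinality / min-cost matching on a small component
.enumMatch <- function(cost, feas) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- list(n = -1L, cost = Inf, asg = integer(nr))
  asg <- integer(nr)
  used <- logical(nc)
  rec <- function(i, n, tot) {
    if (i > nr) {
      if (n > best$n || (n == best$n && tot < best$cost - 1e-12)) {
        best <<- list(n = n, cost = tot, asg = asg)
      }
      return()
    }
    # try columns in increasing index order so equal-cost solutions resolve
    # towards lower object ids; then the unmatched option
    for (j in seq_len(nc)) {
      if (feas[i, j] && !used[j]) {
        used[j] <<- TRUE; asg[i] <<- j
        rec(i + 1L, n + 1L, tot + cost[i, j])
        used[j] <<- FALSE; asg[i] <<- 0L
      }
    }
    rec(i + 1L, n, tot)
  }
  rec(1L, 0L, 0)
  rows <- which(best$asg > 0L)
  list(rows = rows, cols = best$asg[rows])
}

# greedy fallback for oversized components: repeatedly take the cheapest
# remaining feasible pair
.greedyMatch <- function(cost, feas) {
  cost[!feas] <- Inf
  rows <- integer(0); cols <- integer(0)
  while (any(is.finite(cost))) {
    k <- which.min(cost)
    i <- (k - 1L) %% nrow(cost) + 1L
    j <- (k - 1L) %/% nrow(cost) + 1L
    rows <- c(rows, i); cols <- c(cols, j)
    cost[i, ] <- Inf; cost[, j] <- Inf
  }
  list(rows = rows, cols = cols)
}

#' Automated quality gates for linked tracks
#'
#' Replaces track-by-track visual validation with explicit rules: a track is
#' rejected when any implied speed exceeds `maxSpeed` (segmentation artifact
#' "teleports") or when it covers less than `minCoverage` of the frames in
#' its time span.
#'
#' @param tracks data.frame from [linkTracks()].
#' @param fps frames per second.
#' @param maxSpeed maximum plausible speed (um/s).
#' @param minCoverage minimum fraction of frames present within the track's
#'   span.
#' @return list with `accepted` and `rejected` data.frames (the latter with a
#'   `reason` column: `"speed"` or `"coverage"`); the two partition the
#'   input.
#' @export
validateTracks <- function(tracks, fps, maxSpeed = 500, minCoverage = 0.9) {
  if (!nrow(tracks)) {
    rej <- tracks; rej$reason <- character(0)
    return(list(accepted = tracks, rejected = rej))
  }
  reasons <- vapply(split(seq_len(nrow(tracks)), tracks$track_id), function(ix) {
    tr <- tracks[ix, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (nrow(tr) >= 2) {
      dd <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
      sp <- dd * fps / diff(tr$frame)
      if (any(sp > maxSpeed)) return("speed")
    }
    span <- diff(range(tr$frame)) + 1
    if (nrow(tr) / span < minCoverage) return("coverage")
    "ok"
  }, character(1))
  badIds <- as.integer(names(reasons)[reasons != "ok"])
  rej <- tracks[tracks$track_id %in% badIds, , drop = FALSE]
  if (nrow(rej)) rej$reason <- reasons[as.character(rej$track_id)]
  else rej$reason <- character(0)
  acc <- tracks[!tracks$track_id %in% badIds, , drop = FALSE]
  rownames(acc) <- rownames(rej) <- NULL
  list(accepted = acc, rejected = rej)
}

#' Default linking distance for a simulation geometry
#'
#' Three times the expected per-frame displacement, in microns.
#'
#' @param config a [WormSimConfig-class].
#' @return distance in um.
#' @export
defaultDMax <- function(config) 3 * config@speedMean / config@fps
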