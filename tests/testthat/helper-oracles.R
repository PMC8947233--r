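# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with naive scalar code, separate from the package
# implementations they check.

# --- reversal detection: exhaustive index scan -------------------------------
# returns the indices (into the frame-ordered track) of detected events
reversalOracle <- function(track, angleThreshold = 50, smoothWindow = 5,
                           minStep = 5) {
  tr <- track[order(track$frame), , drop = FALSE]
  n <- nrow(tr)
  w <- smoothWindow
  ang <- numeric(n)
  supra <- logical(n)
  for (i in seq_len(n)) {
    if (i <= w || i > n - w) next
    pre <- c(tr$x_um[i] - tr$x_um[i - w], tr$y_um[i] - tr$y_um[i - w])
    post <- c(tr$x_um[i + w] - tr$x_um[i], tr$y_um[i + w] - tr$y_um[i])
    lp <- sqrt(sum(pre^2)); lq <- sqrt(sum(post^2))
    if (lp < w * minStep || lq < w * minStep) next
    ca <- sum(pre * post) / (lp * lq)
    a <- acos(min(1, max(-1, ca))) * 180 / pi
    ang[i] <- a
    supra[i] <- a > angleThreshold
  }
  ev <- integer(0)
  i <- 1L
  while (i <= n) {
    if (supra[i]) {
      j <- i
      while (j < n && supra[j + 1L]) j <- j + 1L
      seg <- i:j
      ev <- c(ev, seg[which.max(ang[seg])])
      i <- j + 1L
    } else i <- i + 1L
  }
  ev
}

# --- per-frame-pair assignment: exhaustive enumeration -----------------------
# maximise matches, then minimise cost; equal solutions resolve to the
# lexicographically smallest assignment (columns ascending, unmatched last)
bruteMatch <- function(cost, dMax) {
  nr <- nrow(cost); nc <- ncol(cost)
  best <- NULL
  rec <- function(i, asg) {
    if (i > nr) {
      matched <- which(asg > 0L)
      n <- length(matched)
      tc <- if (n) sum(cost[cbind(matched, asg[matched])]) else 0
      if (is.null(best) || n > best$n ||
          (n == best$n && tc < best$cost - 1e-12))
        best <<- list(n = n, cost = tc, asg = asg)
      return(invisible())
    }
    for (j in seq_len(nc))
      if (cost[i, j] <= dMax && !(j %in% asg)) rec(i + 1L, c(asg, j))
    rec(i + 1L, c(asg, 0L))
  }
  rec(1L, integer(0))
  best
}

# --- hole counting: queue-based flood fill from the border -------------------
holesOracle <- function(mask) {
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  nr <- nrow(m) + 2L; nc <- ncol(m) + 2L
  p <- matrix(FALSE, nr, nc)
  p[2:(nr - 1L), 2:(nc - 1L)] <- m
  visited <- p                              # object pixels never visited
  queue <- c(1L)                            # linear index of corner (1,1)
  visited[1, 1] <- TRUE
  while (length(queue)) {
    q <- queue[1]; queue <- queue[-1]
    qi <- (q - 1L) %% nr + 1L; qj <- (q - 1L) %/% nr + 1L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      ni <- qi + d[1]; nj <- qj + d[2]
      if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
      if (!visited[ni, nj]) {
        visited[ni, nj] <- TRUE
        queue <- c(queue, (nj - 1L) * nr + ni)
      }
    }
  }
  # remaining unvisited background pixels form the holes; count their
  # 4-connected components
  holes <- 0L
  while (any(!visited)) {
    start <- which(!visited)[1]
    holes <- holes + 1L
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      qi <- (q - 1L) %% nr + 1L; qj <- (q - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ni <- qi + d[1]; nj <- qj + d[2]
        if (ni < 1L || ni > nr || nj < 1L || nj > nc) next
        if (!visited[ni, nj]) {
          visited[ni, nj] <- TRUE
          queue <- c(queue, (nj - 1L) * nr + ni)
        }
      }
    }
  }
  holes
}

# --- direct 2-D Gaussian convolution with replicate padding ------------------
blurOracle <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  off <- -r:r
  k1 <- exp(-off^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in seq_along(off)) for (b in seq_along(off)) {
      ii <- min(max(i + off[a], 1L), nr)
      jj <- min(max(j + off[b], 1L), nc)
      acc <- acc + k2[a, b] * x[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

# --- two-group log-rank by direct O-E / V tabulation -------------------------
logrankOracle <- function(timeA, timeB) {
  times <- sort(unique(c(timeA, timeB)))
  O <- 0; E <- 0; V <- 0
  for (t in times) {
    nA <- sum(timeA >= t); nB <- sum(timeB >= t)
    dA <- sum(timeA == t); dB <- sum(timeB == t)
    n <- nA + nB; d <- dA + dB
    if (n < 2 || d == 0) next
    O <- O + dA
    E <- E + d * nA / n
    V <- V + d * (nA / n) * (nB / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# --- two-sided Fisher p by hypergeometric enumeration ------------------------
fisherOracle <- function(tb) {
  a <- tb[1, 1]
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# --- simple analytic undulating midline for bend tests -----------------------
# worm of length L translating at v um/s, bending sinusoidally at f Hz
analyticMidline <- function(t, L = 1000, f = 0.5, alpha = 0.7, v = 50,
                            npts = 21L) {
  ds <- L / (npts - 1)
  smid <- seq(-L / 2, L / 2, length.out = npts)[-npts] + ds / 2
  psi <- alpha * sin(2 * pi * smid / L + 2 * pi * f * t)
  px <- cumsum(c(0, ds * cos(psi)))
  py <- cumsum(c(0, ds * sin(psi)))
  cbind(x = px - mean(px) + v * t, y = py - mean(py))
}

# small binary shapes -----------------------------------------------------
diskMask <- function(n = 31, r = 10) {
  ctr <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

annulusMask <- function(n = 31, rOut = 12, rIn = 6) {
  ctr <- (n + 1) / 2
  d2 <- outer(1:n, 1:n, function(i, j) (i - ctr)^2 + (j - ctr)^2)
  d2 <= rOut^2 & d2 >= rIn^2
}
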