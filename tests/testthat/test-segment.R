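test_that("Gaussian preprocessing: identity, constants, and kernel oracle", {
  img <- matrix(runif(400), 20, 20)
  expect_identical(preprocessFrame(img, 0), img)
  expect_error(preprocessFrame(img, -1), "sigma")
  cst <- matrix(0.42, 15, 15)
  expect_equal(preprocessFrame(cst, 3), cst, tolerance = 1e-12)
  # impulse response equals the discretised 2-D Gaussian kernel
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- preprocessFrame(imp, 2)
  expect_equal(sm, blurOracle(imp, 2), tolerance = 1e-10)
  # and a random image matches the direct-convolution oracle
  set.seed(1)
  x <- matrix(runif(16 * 14), 16, 14)
  expect_equal(preprocessFrame(x, 1.5), blurOracle(x, 1.5), tolerance = 1e-10)
})

test_that("Otsu threshold separates a bimodal image exactly", {
  set.seed(2)
  img <- matrix(sample(c(30, 220) / 255, 400, replace = TRUE), 20, 20)
  mask <- binarizeFrame(img)
  expect_equal(as.vector(mask), as.vector(img < 0.5))
  # exhaustive between-class-variance oracle over all 256 candidate bins
  h <- tabulate(pmin(255, floor(img * 256)) + 1L, nbins = 256)
  p <- h / sum(h); i <- 0:255
  bc <- vapply(1:255, function(t) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) return(-1)
    mu0 <- sum(p[1:t] * i[1:t]) / w0
    mu1 <- sum(p[(t + 1):256] * i[(t + 1):256]) / w1
    w0 * w1 * (mu0 - mu1)^2
  }, numeric(1))
  expect_equal(otsuThreshold(img), (which.max(bc) - 1 + 0.5) / 256)
  # agreement with the independent EBImage implementation: exact thresholds
  # can differ on near-flat plateaus of the criterion, but the resulting
  # segmentations of a well-separated mixture must coincide
  mix <- matrix(pmin(1, pmax(0, c(rnorm(300, 0.25, 0.05),
                                  rnorm(300, 0.75, 0.05)))), 30, 20)
  mMine <- mix < otsuThreshold(mix)
  mEbi <- mix < EBImage::otsu(EBImage::Image(mix))
  expect_lt(mean(mMine != mEbi), 0.02)
})

test_that("binarize handles degenerate frames and fixed thresholds", {
  flat <- matrix(0.9, 10, 10)
  expect_equal(sum(binarizeFrame(flat, "fixed", 0.5)), 0L)
  chk <- matrix(rep(c(0, 1), length.out = 100), 10, 10)
  m <- binarizeFrame(chk, "fixed", 128 / 255)
  expect_equal(as.vector(m), as.vector(chk == 0))
  expect_error(binarizeFrame(chk, "fixed"), "threshold")
})

test_that("8-connected labeling matches a reference labeling on random masks", {
  # EBImage::bwlabel is 4-connected, so build the 8-connected reference by
  # bridging diagonal contacts before labeling
  set.seed(3)
  for (rep in 1:20) {
    m <- matrix(runif(20 * 20) < 0.35, 20, 20)
    lab <- wormtracer:::.label8Cpp(matrix(as.integer(m), 20))
    # reference count: flood fill via the hole oracle trick on each component
    ref <- 0L
    left <- m
    while (any(left)) {
      ref <- ref + 1L
      seed <- which(left)[1]
      comp <- matrix(FALSE, 20, 20); comp[seed] <- TRUE
      repeat {
        grown <- comp
        idx <- which(comp, arr.ind = TRUE)
        for (k in seq_len(nrow(idx))) {
          i <- idx[k, 1]; j <- idx[k, 2]
          ii <- max(1, i - 1):min(20, i + 1)
          jj <- max(1, j - 1):min(20, j + 1)
          grown[ii, jj] <- grown[ii, jj] | left[ii, jj]
        }
        if (identical(grown, comp)) break
        comp <- grown
      }
      left <- left & !comp
    }
    expect_equal(max(lab), ref)
  }
})

test_that("hole counting: disk, annulus, figure-eight, and random oracle", {
  expect_equal(countHoles(diskMask()), 0L)
  expect_equal(countHoles(annulusMask()), 1L)
  # figure-eight: two touching annuli
  e8 <- matrix(FALSE, 31, 62)
  e8[, 1:31] <- annulusMask()
  e8[, 32:62] <- annulusMask()
  e8[, 31] <- e8[, 31] | e8[, 32]           # fuse the loops
  expect_equal(countHoles(e8), 2L)
  set.seed(4)
  for (rep in 1:15) {
    m <- matrix(runif(15 * 15) < 0.55, 15, 15)
    expect_equal(countHoles(m), holesOracle(m))
  }
})

test_that("skeleton midline of a straight bar is the bar axis", {
  bar <- matrix(FALSE, 20, 110)
  bar[8:12, 6:105] <- TRUE
  ml <- skeletonMidline(bar)
  expect_equal(attr(ml, "reason"), "ok")
  # collinear along the bar axis, y constant
  expect_lt(diff(range(ml[, "row"])), 3)
  len <- sum(sqrt(rowSums(diff(ml)^2)))
  expect_lt(abs(len - 100), 5)
})

test_that("skeleton midline flags coiled blobs and rejects bad input", {
  ml <- skeletonMidline(annulusMask())
  expect_equal(nrow(ml), 0L)
  expect_equal(attr(ml, "reason"), "coiled")
  two <- matrix(FALSE, 10, 10); two[2, 2] <- TRUE; two[8, 8] <- TRUE
  expect_error(skeletonMidline(two), "single connected")
  expect_error(skeletonMidline(matrix(FALSE, 5, 5)), "empty")
})

test_that("midline arc length of a rendered worm approximates body length", {
  cfg <- wormSimConfig(arenaSize = c(128L, 128L), nWorms = 1, noiseSd = 0,
                       seed = 15)
  vid <- simulateCohort(wormSimConfig(arenaSize = c(128L, 128L), nWorms = 1,
                                      duration = 10, noiseSd = 0,
                                      coilRate = 0, seed = 15))
  obj <- detectObjects(vid, config = cfg)
  lens <- vapply(obj$midline, function(ml)
    sum(sqrt(rowSums(diff(ml)^2))), numeric(1))
  expect_true(all(abs(lens / cfg@bodyLength - 1) < 0.1))
})

test_that("size gate keeps single worms and drops specks and merged blobs", {
  # one disk of in-range area
  m <- diskMask(41, 8)
  obj <- extractObjects(m, aMin = 50, aMax = 500)
  expect_equal(nrow(obj), 1L)
  expect_lt(abs(obj$row - 20), 0.5)         # disk centre (0-based 20)
  expect_lt(abs(obj$col - 20), 0.5)
  # a 3-px speck is gated out
  sp <- matrix(FALSE, 20, 20); sp[5, 5:7] <- TRUE
  expect_equal(nrow(extractObjects(sp, aMin = 50, aMax = 500)), 0L)
  # two touching bars fused into one oversized blob: gated out
  mm <- matrix(FALSE, 30, 30)
  mm[10:12, 2:29] <- TRUE
  mm[12:14, 2:29] <- TRUE
  area <- sum(mm)
  expect_equal(nrow(extractObjects(mm, aMin = 10, aMax = area - 1)), 0L)
  expect_error(extractObjects(m, aMin = 10, aMax = 10), "aMin")
})

test_that("noise-free cohorts segment to exactly one object per worm with true hole counts", {
  cfg <- wormSimConfig(arenaSize = c(320L, 320L), nWorms = 2, duration = 30,
                       coilRate = 2, coilDurationMean = 6, noiseSd = 0,
                       seed = 31)
  vid <- simulateCohort(cfg)
  obj <- detectObjects(vid, config = cfg, midlines = FALSE)
  tru <- groundTruth(vid)
  perFrame <- table(obj$frame)
  expect_true(all(perFrame == 2))
  # hole counts match the behavioral mode worm by worm
  for (f in unique(obj$frame)) {
    o <- obj[obj$frame == f, ]
    t <- tru[tru$frame == f, ]
    for (k in seq_len(nrow(t))) {
      j <- which.min((o$x_um - t$x_um[k])^2 + (o$y_um - t$y_um[k])^2)
      if (t$mode[k] == "COIL") expect_gte(o$n_holes[j], 1L)
      else expect_equal(o$n_holes[j], 0L)
    }
  }
})

test_that("centroid recovery stays within 2 px under strong pixel noise", {
  # noise at 10% of the frame's dynamic range
  cfg <- wormSimConfig(arenaSize = c(256L, 256L), nWorms = 1, duration = 30,
                       coilRate = 0, noiseSd = 0.075, seed = 32)
  vid <- simulateCohort(cfg)
  obj <- detectObjects(vid, config = cfg, midlines = FALSE)
  tru <- groundTruth(vid)
  expect_equal(nrow(obj), nrow(tru))
  err <- sqrt((obj$x_um - tru$x_um)^2 + (obj$y_um - tru$y_um)^2) / cfg@umPerPx
  expect_lt(max(err), 2)
})
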