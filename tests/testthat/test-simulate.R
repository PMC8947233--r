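test_that("config validation rejects impossible geometries and rates", {
  expect_error(wormSimConfig(fps = 0), "positive")
  expect_error(wormSimConfig(nWorms = 0), "nWorms")
  expect_error(wormSimConfig(reversalRate = -1), "non-negative")
  expect_error(wormSimConfig(arenaSize = c(20L, 20L)), "arena too small")
  expect_s4_class(wormSimConfig(), "WormSimConfig")
})

test_that("zero event rates keep every worm in RUN for the whole recording", {
  cfg <- wormSimConfig(arenaSize = c(256L, 256L), nWorms = 3, duration = 60,
                       reversalRate = 0, coilRate = 0, seed = 5)
  sim <- simulateWorms(cfg)
  expect_true(all(sim$truth$mode == "RUN"))
  expect_true(all(sim$truth$cum_reversals == 0))
})

test_that("stepBehavior rejects non-positive time steps", {
  cfg <- wormSimConfig(nWorms = 1)
  st <- withr::with_seed(1, initWormState(cfg))
  expect_error(stepBehavior(st, 0, cfg), "dt")
  expect_error(stepBehavior(st, -1, cfg), "dt")
})

test_that("identical config and seed give bit-identical simulations", {
  cfg <- wormSimConfig(arenaSize = c(128L, 128L), nWorms = 2, duration = 10,
                       seed = 11)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(a@frames, b@frames)
  expect_identical(groundTruth(a), groundTruth(b))
})

test_that("midline points are equidistant and sum to the body length", {
  cfg <- wormSimConfig(nWorms = 1, seed = 3)
  st <- withr::with_seed(3, initWormState(cfg))
  for (mode in c("RUN", "COIL")) {
    st$mode <- mode
    ml <- wormMidline(st, cfg)
    seg <- sqrt(rowSums(diff(ml)^2))
    expect_lt(max(abs(seg / mean(seg) - 1)), 0.01)
    expect_lt(abs(sum(seg) / cfg@bodyLength - 1), 0.01)
    expect_equal(nrow(ml), 21L)
  }
})

test_that("reversal events follow a Poisson process at the configured rate", {
  # ~100 worm-hours aggregated over batches; empirical event rate must sit
  # within 3 standard errors of the configured rate
  rate <- 3
  totalEvents <- 0
  wormMinutes <- 0
  for (s in 1:6) {
    cfg <- wormSimConfig(arenaSize = c(2048L, 2048L), nWorms = 100,
                         duration = 600, reversalRate = rate, coilRate = 0,
                         seed = 100 + s)
    tru <- simulateWorms(cfg)$truth
    fin <- tru[tru$frame == max(tru$frame), ]
    totalEvents <- totalEvents + sum(fin$cum_reversals)
    wormMinutes <- wormMinutes + 100 * 10
  }
  est <- totalEvents / wormMinutes
  se <- sqrt(totalEvents) / wormMinutes
  expect_lt(abs(est - rate), 3 * se)
})

test_that("mean zero-rate simulation count matches the Poisson expectation", {
  # reversal_rate = 3/min over 10 min: mean count across seeds ~ 30
  cfg <- wormSimConfig(arenaSize = c(2048L, 2048L), nWorms = 60,
                       duration = 600, reversalRate = 3, coilRate = 0,
                       seed = 77)
  tru <- simulateWorms(cfg)$truth
  counts <- tru$cum_reversals[tru$frame == max(tru$frame)]
  expect_lt(abs(mean(counts) - 30), 3 * sqrt(30))
})

test_that("ground-truth counters are non-decreasing and complete", {
  cfg <- wormSimConfig(arenaSize = c(256L, 256L), nWorms = 4, duration = 60,
                       coilRate = 1, seed = 21)
  tru <- simulateWorms(cfg)$truth
  expect_equal(nrow(tru), 4 * 180)
  for (d in split(tru, tru$worm_id)) {
    expect_true(all(diff(d$cum_reversals) >= 0))
    expect_true(all(diff(d$cum_bends) >= 0))
  }
})

test_that("RUN-only ground-truth speed stays within 5% of the configured mean", {
  cfg <- wormSimConfig(arenaSize = c(1024L, 1280L), nWorms = 100,
                       duration = 60, reversalRate = 0, coilRate = 0,
                       seed = 8)
  tru <- simulateWorms(cfg)$truth
  # realized displacement speed, not the nominal per-worm draw
  sp <- vapply(split(tru, tru$worm_id), function(d) {
    mean(sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)) * cfg@fps
  }, numeric(1))
  expect_lt(abs(mean(sp) / cfg@speedMean - 1), 0.05)
})

test_that("empty arena renders to plain background plus noise", {
  cfg <- wormSimConfig(arenaSize = c(64L, 64L), nWorms = 1, seed = 2)
  img <- withr::with_seed(1, renderFrame(list(), cfg))
  expect_equal(dim(img), c(64L, 64L))
  expect_gt(min(img), 0.5)                  # nothing near worm intensity
  expect_lt(abs(mean(img) - 0.9), 0.01)
})

test_that("a rendered crawling worm matches a direct rasterisation oracle", {
  cfg <- wormSimConfig(arenaSize = c(128L, 128L), nWorms = 1, noiseSd = 0,
                       seed = 4)
  st <- withr::with_seed(4, initWormState(cfg))
  st$x <- 1700; st$y <- 1700
  img <- renderFrame(list(st), cfg, noise = FALSE)
  mask <- img < 0.5
  # exactly one connected dark component
  expect_equal(max(wormtracer:::.label8Cpp(matrix(as.integer(mask), 128))), 1L)
  # oracle: brute-force distance from every pixel to a densely resampled
  # midline
  ml <- wormMidline(st, cfg)
  tt <- seq(1, nrow(ml), by = 0.25)
  dx <- approx(seq_len(nrow(ml)), ml[, 1], tt)$y
  dy <- approx(seq_len(nrow(ml)), ml[, 2], tt)$y
  u <- cfg@umPerPx; rw <- cfg@bodyWidth / 2
  # per-point radius with the hemispherical end taper
  s <- c(0, cumsum(sqrt(diff(dx)^2 + diff(dy)^2)))
  dEnd <- pmin(s, max(s) - s)
  rws <- ifelse(dEnd >= rw, rw, rw * sqrt(pmax(0, 1 - ((rw - dEnd) / rw)^2)))
  oracle <- matrix(FALSE, 128, 128)
  for (i in 1:128) for (j in 1:128) {
    d2 <- (dx - (j - 1) * u)^2 + (dy - (i - 1) * u)^2
    oracle[i, j] <- any(d2 <= rws^2)
  }
  expect_identical(unname(mask), oracle)
  # pixel centroid within 1 px of the ground-truth centroid
  ix <- which(mask, arr.ind = TRUE)
  expect_lt(abs((mean(ix[, 2]) - 1) - st$x / u), 1)
  expect_lt(abs((mean(ix[, 1]) - 1) - st$y / u), 1)
})

test_that("a coiled worm renders as a blob with at least one hole", {
  cfg <- wormSimConfig(arenaSize = c(96L, 96L), nWorms = 1, noiseSd = 0,
                       seed = 4)
  st <- withr::with_seed(4, initWormState(cfg))
  st$x <- 1300; st$y <- 1300; st$mode <- "COIL"
  img <- renderFrame(list(st), cfg, noise = FALSE)
  expect_gte(countHoles(img < 0.5), 1L)
})

test_that("cohort simulation is sized fps x duration and reproducible", {
  cfg <- wormSimConfig(arenaSize = c(96L, 96L), nWorms = 1, duration = 20,
                       fps = 3, seed = 6)
  vid <- simulateCohort(cfg)
  expect_equal(nFrames(vid), 60L)
  expect_equal(frameRate(vid), 3)
  expect_equal(pixelSize(vid), 27.3)
  # full-scale kinematics: 20 worms x 1800 frames of ground truth
  big <- wormSimConfig(nWorms = 20, duration = 600, fps = 3, seed = 6)
  tru <- simulateWorms(big)$truth
  expect_equal(nrow(tru), 36000L)
})

test_that("overcrowded arenas are rejected with a clear message", {
  cfg <- wormSimConfig(arenaSize = c(48L, 48L), umPerPx = 27.3, nWorms = 20,
                       duration = 1)
  expect_error(simulateWorms(cfg), "overcrowded")
})

test_that("rendered centroids track ground truth within 2 px when noise-free", {
  cfg <- wormSimConfig(arenaSize = c(256L, 256L), nWorms = 2, duration = 20,
                       noiseSd = 0, coilRate = 0, seed = 9)
  vid <- simulateCohort(cfg)
  obj <- detectObjects(vid, config = cfg, midlines = FALSE)
  tru <- groundTruth(vid)
  m <- merge(obj, tru, by = "frame")
  # match detected to true by proximity within each frame
  errs <- vapply(seq_len(nFrames(vid)), function(f) {
    o <- obj[obj$frame == f, ]
    t <- tru[tru$frame == f, ]
    max(vapply(seq_len(nrow(t)), function(k) {
      min(sqrt((o$x_um - t$x_um[k])^2 + (o$y_um - t$y_um[k])^2))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(errs) / cfg@umPerPx, 2)
})

test_that("video round trips through TIFF and PNG on disk", {
  cfg <- wormSimConfig(arenaSize = c(64L, 64L), nWorms = 1, duration = 3,
                       seed = 12)
  vid <- simulateCohort(cfg)
  tf <- tempfile(fileext = ".tif")
  writeVideo(vid, tf)
  back <- readVideo(tf, umPerPx = 27.3, fps = 3)
  expect_equal(nFrames(back), nFrames(vid))
  expect_lt(max(abs(back@frames - vid@frames)), 1 / 255)
  pd <- tempfile()
  writeVideo(vid, pd, format = "png")
  back2 <- readVideo(pd, umPerPx = 27.3, fps = 3)
  expect_equal(nFrames(back2), nFrames(vid))
  expect_lt(max(abs(back2@frames - vid@frames)), 1 / 255)
  unlink(tf); unlink(pd, recursive = TRUE)
})
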