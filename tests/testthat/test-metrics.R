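track30 <- function(n = 61, step = 10) {
  data.frame(frame = seq_len(n), x_um = (seq_len(n) - 1) * step, y_um = 0)
}

test_that("speed is displacement times frame rate", {
  tr <- data.frame(frame = 1:3, x_um = c(0, 10, 20), y_um = 0)
  sp <- computeSpeed(tr, fps = 3)
  expect_equal(sp$series, c(30, 30))
  expect_equal(sp$mean, 30)
  still <- data.frame(frame = 1:10, x_um = 5, y_um = 5)
  expect_equal(computeSpeed(still, 3)$mean, 0)
  expect_error(computeSpeed(still[1, ], 3), "at least 2")
})

test_that("straight trajectories produce no reversal events", {
  det <- detectReversals(track30(), fps = 3)
  expect_equal(nrow(det$events), 0L)
  expect_equal(det$ratePerMin, 0)
  expect_error(detectReversals(track30(5), fps = 3), "too short")
})

test_that("a single 180-degree turn is exactly one event", {
  tr <- data.frame(frame = 1:60, x_um = c((0:29) * 10, (29:0) * 10),
                   y_um = 0)
  det <- detectReversals(tr, fps = 3)
  expect_equal(nrow(det$events), 1L)
  expect_gt(det$events$turn_angle, 170)
  expect_equal(det$ratePerMin, 1 / ((59 / 3) / 60))
})

test_that("reversal detection equals the exhaustive scan oracle", {
  set.seed(23)
  nAgree <- 0
  for (rep in 1:40) {
    # random walks with occasional sharp direction flips
    n <- sample(40:120, 1)
    heading <- cumsum(rnorm(n, 0, 0.15))
    flips <- runif(n) < 0.03
    heading <- heading + cumsum(flips * pi * runif(n, 0.8, 1))
    step <- runif(n, 0, 25)
    tr <- data.frame(frame = seq_len(n),
                     x_um = cumsum(step * cos(heading)),
                     y_um = cumsum(step * sin(heading)))
    det <- detectReversals(tr, fps = 3, minStep = 5)
    expect_identical(det$events$index, reversalOracle(tr, minStep = 5))
    nAgree <- nAgree + 1
  }
  expect_equal(nAgree, 40)
})

test_that("coil fraction counts frames with holes and low gate speed", {
  n <- 300
  # the animal crawls, halts, holds a coiled posture for 60 frames
  # (holes + sub-threshold displacement), then crawls on
  x <- numeric(n)
  x[1:98] <- (1:98) * 20
  x[99:162] <- x[98]
  x[163:300] <- x[98] + (1:138) * 20
  tr <- data.frame(frame = seq_len(n), x_um = x, y_um = 0, n_holes = 0L)
  tr$n_holes[101:160] <- 1L
  expect_equal(coilFraction(tr, fps = 3, vCoil = 5), 0.2)
  tr2 <- tr; tr2$n_holes <- 0L
  expect_equal(coilFraction(tr2, fps = 3, vCoil = 5), 0)
})

test_that("body bends: rigid bar none, sinusoid twice per cycle, stationary gated", {
  fps <- 3; f <- 0.5; n <- 90
  tt <- (seq_len(n) - 1) / fps
  mls <- lapply(tt, analyticMidline, f = f)
  tr <- data.frame(frame = seq_len(n),
                   x_um = vapply(mls, function(m) mean(m[, 1]), numeric(1)),
                   y_um = vapply(mls, function(m) mean(m[, 2]), numeric(1)))
  tr$midline <- I(mls)
  bb <- countBodyBends(tr, fps = fps, vMove = 5)
  expect_equal(bb$flag, "ok")
  expect_lt(abs(bb$bendsPerMin / (2 * f * 60) - 1), 0.1)
  # rigid bar translating: no bends
  bar <- lapply(tt, function(t) cbind(x = seq(0, 1000, 50) + 50 * t, y = 0))
  trBar <- data.frame(frame = seq_len(n), x_um = 50 * tt, y_um = 0)
  trBar$midline <- I(bar)
  expect_equal(countBodyBends(trBar, fps, vMove = 5)$nBends, 0L)
  # undulating but stationary: gated out by vMove
  mlsStill <- lapply(tt, analyticMidline, f = f, v = 0)
  trStill <- data.frame(frame = seq_len(n), x_um = 0, y_um = 0)
  trStill$midline <- I(mlsStill)
  expect_equal(countBodyBends(trStill, fps, vMove = 5)$nBends, 0L)
})

test_that("bend counting requires midlines in most frames", {
  n <- 60; fps <- 3
  tt <- (seq_len(n) - 1) / fps
  mls <- lapply(tt, analyticMidline)
  mls[1:30] <- list(matrix(numeric(0), 0, 2))  # half missing
  tr <- data.frame(frame = seq_len(n), x_um = 50 * tt, y_um = 0)
  tr$midline <- I(mls)
  bb <- countBodyBends(tr, fps, vMove = 5)
  expect_equal(bb$flag, "insufficient_midlines")
  expect_true(is.na(bb$bendsPerMin))
})

test_that("rates are invariant to rigid motions of the arena", {
  set.seed(29)
  n <- 120
  heading <- cumsum(rnorm(n, 0, 0.2)) + cumsum((runif(n) < 0.04) * pi)
  tr <- data.frame(frame = seq_len(n),
                   x_um = cumsum(15 * cos(heading)),
                   y_um = cumsum(15 * sin(heading)))
  base <- detectReversals(tr, fps = 3)$ratePerMin
  th <- 0.7
  rot <- data.frame(frame = tr$frame,
                    x_um = cos(th) * tr$x_um - sin(th) * tr$y_um + 5000,
                    y_um = sin(th) * tr$x_um + cos(th) * tr$y_um - 2000)
  expect_equal(detectReversals(rot, fps = 3)$ratePerMin, base)
  expect_equal(computeSpeed(rot, 3)$mean, computeSpeed(tr, 3)$mean,
               tolerance = 1e-10)
})

test_that("doubling fps on a resampled identical path preserves mean speed", {
  n <- 60
  x <- cumsum(runif(n, 5, 15))
  tr1 <- data.frame(frame = seq_len(n), x_um = x, y_um = 0)
  # same path sampled twice as often (linear interpolation)
  x2 <- approx(seq_len(n), x, seq(1, n, by = 0.5))$y
  tr2 <- data.frame(frame = seq_along(x2), x_um = x2, y_um = 0)
  v1 <- computeSpeed(tr1, fps = 3)$mean
  v2 <- computeSpeed(tr2, fps = 6)$mean
  expect_equal(v1, v2, tolerance = 1e-10)
})

test_that("cohort summaries aggregate track metrics with SEM", {
  s <- data.frame(track_id = 1:2, mean_speed = c(20, 40),
                  reversals_per_min = c(1, 3),
                  body_bends_per_min = c(30, 34),
                  coil_fraction = c(0, 0.2), observed_time = 60,
                  n_frames = 181, bend_flag = "ok")
  s$speed_series <- I(list(rep(20, 180), rep(40, 180)))
  cs <- summarizeCohort(s)
  expect_equal(cs$table$mean[cs$table$metric == "mean_speed"], 30)
  expect_equal(cs$table$sem[cs$table$metric == "mean_speed"], 10)
  expect_equal(cs$table$pooled[cs$table$metric == "mean_speed"], 30)
  expect_equal(cs$table$pooled[cs$table$metric == "reversals_per_min"], 2)
  expect_equal(sum(cs$histogram$count), 360)
  one <- s[1, ]
  cs1 <- summarizeCohort(one)
  expect_equal(cs1$table$mean[1], 20)
  expect_true(is.na(cs1$table$sem[1]))
  expect_error(summarizeCohort(s[0, ]), "no track")
})

test_that("trackMetrics recovers simulated per-track readouts end to end", {
  cfg <- wormSimConfig(arenaSize = c(256L, 256L), nWorms = 1, duration = 120,
                       coilRate = 1, coilDurationMean = 8, seed = 37)
  res <- runPipeline(pipelineConfig(sim = cfg, track = list(minLen = 15)))
  tru <- res$truth
  expect_true(all(res$summaries$coil_fraction >= 0 &
                  res$summaries$coil_fraction <= 1))
  expect_true(all(res$summaries$observed_time ==
                  (res$summaries$n_frames - 1) / cfg@fps))
  # cohort means near truth (loose sanity bounds; the acceptance suite
  # checks calibrated tolerances at scale)
  tab <- res$cohort$table
  expect_lt(abs(tab$pooled[tab$metric == "mean_speed"] /
                mean(tru$speed_um_s) - 1), 0.15)
  expect_lt(abs(tab$pooled[tab$metric == "coil_fraction"] -
                mean(tru$mode == "COIL")), 0.07)
})
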