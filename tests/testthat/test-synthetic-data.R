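test_that("train schedule is a Poisson process with the configured rates", {
  cfg <- fixtureConfig(seed = 101)
  sched <- makeTrainSchedule(cfg, duration = 1000)
  nA <- sum(sched$direction == "anterograde")
  nR <- sum(sched$direction == "retrograde")
  # ~1300 anterograde events, Poisson tolerance (4 sd)
  expect_lt(abs(nA - 1300), 4 * sqrt(1300))
  # retro/antero count ratio -> 1.15 within sampling error
  expect_lt(abs(nR / nA - 1.15), 4 * 1.15 * sqrt(1 / 1300 + 1 / 1495))
  # inter-arrival exponentiality (KS at alpha = 0.01, n >= 1e3)
  gaps <- diff(sched$start_time[sched$direction == "anterograde"])
  expect_gt(length(gaps), 999)
  # RNG granularity can produce a spurious exact tie; irrelevant to the test
  ks <- suppressWarnings(stats::ks.test(gaps, "pexp", rate = 1.3))
  expect_gt(ks$p.value, 0.01)
  # speeds from truncated normals are strictly positive
  expect_true(all(sched$speed > 0))
})

test_that("train schedule handles edge cases", {
  cfg <- fixtureConfig(seed = 102, anteroFrequency = 0)
  expect_identical(nrow(makeTrainSchedule(cfg, 100)), 0L)
  expect_error(makeTrainSchedule(fixtureConfig(), -5), "positive")
  # retrograde departures never precede the first tip arrival
  cfg2 <- fixtureConfig(seed = 103)
  s <- makeTrainSchedule(cfg2, 200)
  a <- s[s$direction == "anterograde", ]
  firstTip <- min(a$start_time + cfg2@flagellumLength / a$speed)
  expect_true(all(s$start_time[s$direction == "retrograde"] >= firstTip))
})

test_that("generators are bit-identical under the same seed", {
  cfg <- fixtureConfig(seed = 104)
  expect_identical(makeTrainSchedule(cfg, 50), makeTrainSchedule(cfg, 50))
  t1 <- makeKapTrajectory(cfg, tipPause = 1, D = 1.68)
  t2 <- makeKapTrajectory(cfg, tipPause = 1, D = 1.68)
  expect_identical(axialPosition(t1), axialPosition(t2))
})

test_that("KAP trajectory phases have the configured statistics", {
  cfg <- fixtureConfig(seed = 105)
  # diffusing-phase axial increments: variance 2 D dt (chi-square, alpha 0.01)
  n <- 0; incs <- numeric(0); i <- 0
  sigma <- sqrt(2 * 1.68 * 0.1)
  while (n < 1e4) {
    i <- i + 1
    tr <- makeKapTrajectory(cfg, tipPause = 0, D = 1.68, locNoise = 0,
                            diffusionDuration = 60, seed = 1000 + i)
    x <- axialPosition(subsetPhase(tr, "diffusing"))
    d <- diff(x)
    # keep increments starting > 3 sd from either boundary, where the
    # reflection has negligible effect on the step distribution
    keep <- x[-length(x)] > 3 * sigma & x[-length(x)] < 12 - 3 * sigma
    incs <- c(incs, d[keep]); n <- length(incs)
  }
  v <- var(incs); v0 <- 2 * 1.68 * 0.1
  stat <- (length(incs) - 1) * v / v0
  expect_gt(stat, qchisq(0.005, length(incs) - 1))
  expect_lt(stat, qchisq(0.995, length(incs) - 1))
})

test_that("KAP trajectory respects degenerate limits and input errors", {
  cfg <- fixtureConfig(seed = 106)
  tr <- makeKapTrajectory(cfg, tipPause = 1e6, D = 0, locNoise = 0,
                          diffusionDuration = 0, seed = 1)
  paused <- subsetPhase(tr, "tip_paused")
  expect_true(all(axialPosition(paused) == cfg@flagellumLength))
  expect_error(makeKapTrajectory(cfg, tipPause = 1, D = -1), ">= 0")
  # lateral scatter reproduces the configured observed sd
  tr2 <- makeKapTrajectory(cfg, tipPause = 0, D = 0, diffusionDuration = 0,
                           lateralSdTransport = 19, seed = 2)
  expect_lt(abs(sd(lateralPosition(subsetPhase(tr2, "anterograde"))) - 19), 6)
})

test_that("kymograph renders moving and stationary particles correctly", {
  cfg <- fixtureConfig(seed = 107)
  ev <- data.frame(direction = "anterograde", start_time = 1, speed = 2.1,
                   n_fluorophores = 6)
  k <- renderKymograph(ev, cfg, duration = 8)
  img <- k@image
  bright <- apply(img, 2, max) > cfg@background * 3
  pos <- (apply(img, 2, which.max) - 0.5) * k@positionScale / 1000
  tt <- (seq_len(ncol(img)) - 0.5) * k@timeScale
  fit <- lm(pos[bright] ~ tt[bright])
  expect_lt(abs(coef(fit)[2] - 2.1), 0.1)
  # stationary tip pool paints a horizontal line at the tip row
  pool <- trajectory(times = seq(0.05, 4.95, 0.1),
                     axial = rep(cfg@flagellumLength - 0.05, 50),
                     intensity = rep(500, 50),
                     phase = rep("tip_paused", 50))
  k2 <- renderKymograph(pool, cfg, duration = 5)
  rowPos <- (apply(k2@image, 2, which.max) - 0.5) * k2@positionScale / 1000
  expect_true(all(abs(rowPos - (cfg@flagellumLength - 0.05)) <
                    k2@positionScale / 1000))
})

test_that("kymograph shot noise is Poisson and empty/masked cases are valid", {
  cfg <- fixtureConfig(seed = 108)
  k <- renderKymograph(NULL, cfg, duration = 12, shotNoise = TRUE)
  px <- as.vector(k@image)
  expect_gt(length(px), 1e4)
  # per-pixel variance ~ per-pixel mean on constant background
  expect_lt(abs(var(px) / mean(px) - 1), 0.05)
  expect_s4_class(renderKymograph(NULL, cfg, duration = 1), "Kymograph")
  km <- renderKymograph(NULL, cfg, duration = 10, gateMask = TRUE)
  expect_true(length(km@maskedColumns) > 0)
  tcol <- (km@maskedColumns - 0.5) * km@timeScale
  expect_true(all(tcol %% 1 < 0.2))
})

test_that("spot stack conserves the photon budget in expectation", {
  set.seed(109)
  pos <- cbind(runif(300, 700, 900), runif(300, 700, 900))
  st <- makeSpotStack(pos, 400, 130, 3, seed = 110)
  tot <- apply(st$stack, 3, sum) - 3 * 15^2
  # PSF tails outside the box lose a small, bounded fraction
  captured <- mean(tot)
  expect_lt(abs(captured - 400), 3 * sd(tot) / sqrt(300) + 0.01 * 400)
  expect_error(makeSpotStack(cbind(500, 500), 100, 130, background = -1),
               ">= 0")
})

test_that("FRAP series conserves mass and obeys diffusion limits", {
  fs <- makeFrapSeries(D = 1.7, L = 12, window = c(3.5, 8.5), duration = 30)
  post <- which(fs@times >= fs@bleachTime)
  tot <- colSums(fs@profile[, post])
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)      # no-flux conservation
  # pre >= post inside window at bleach; outside unchanged
  pre <- max(which(fs@times < fs@bleachTime))
  post <- pre + 1
  inWin <- fs@positions >= 3.5 & fs@positions <= 8.5
  expect_true(all(fs@profile[inWin, post] <= fs@profile[inWin, pre]))
  expect_equal(fs@profile[!inWin, post], fs@profile[!inWin, pre],
               tolerance = 1e-6)
  # D = 0 never recovers
  fs0 <- makeFrapSeries(D = 0, duration = 30)
  rec0 <- frapWindowRecovery(fs0)
  expect_lt(max(rec0$intensity[rec0$time_s > 1]), 0.01)
  # t -> infinity: uniform at 1 - depth * w / L
  fsInf <- makeFrapSeries(D = 5, L = 12, window = c(3.5, 8.5), duration = 400)
  expect_equal(unname(fsInf@profile[, ncol(fsInf@profile)]),
               rep(1 - 5 / 12, length(fsInf@positions)), tolerance = 1e-3)
  expect_error(makeFrapSeries(D = 1, L = 12, window = c(-1, 5)), "window")
})

test_that("FRAP half-recovery time scales as w^2 / D", {
  g <- expand.grid(w = c(1, 1.5, 2), D = c(0.5, 1, 2))
  tHalf <- mapply(function(w, D) {
    tt <- seq(0.005, 60, 0.005)
    y <- frapRecoveryModel(tt, D, 24, c(12 - w / 2, 12 + w / 2))
    tt[min(which(y >= y[1] + 0.5 * (1 - y[1])))]
  }, g$w, g$D)
  slope <- unname(coef(lm(log(tHalf) ~ log(g$w^2 / g$D)))[2])
  expect_lt(abs(slope - 1), 0.1)
})
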