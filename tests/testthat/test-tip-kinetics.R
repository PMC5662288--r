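test_that("tip events are extracted by definition and bad records rejected", {
  ev <- data.frame(cell_id = 1, arrival_time_s = 10,
                   departure_time_s = c(13.1, 14.8))
  rec <- extractTipEvents(ev)
  expect_equal(rec$resting_time_s, c(3.1, 4.8))
  expect_equal(rec$k, c(1L, 2L))
  # departure before arrival rejected with a warning
  bad <- data.frame(cell_id = 1, arrival_time_s = 10,
                    departure_time_s = c(8, 12))
  expect_warning(r2 <- extractTipEvents(bad), "rejected")
  expect_identical(attr(r2, "rejected"), 1L)
  expect_equal(nrow(r2), 1L)
  # no departures -> empty list
  none <- data.frame(cell_id = integer(0), arrival_time_s = numeric(0),
                     departure_time_s = numeric(0))
  expect_identical(nrow(extractTipEvents(none)), 0L)
})

test_that("extraction round-trips the simulator's latent resting times", {
  rec <- simulateTipTurnaround(50, seed = 801)
  ev <- attr(rec, "events")
  back <- extractTipEvents(ev)
  ordRec <- rec[order(rec$cell_id, rec$k), ]
  expect_equal(back$resting_time_s, ordRec$resting_time_s, tolerance = 1e-12)
  expect_equal(sort(attr(rec, "latent")), sort(back$resting_time_s),
               tolerance = 1e-12)
})

test_that("simulator means converge to T_r + k * dt", {
  rec <- simulateTipTurnaround(1e5, seed = 802)
  m <- tapply(rec$resting_time_s, rec$k, mean)
  expected <- 1.3 + (1:4) * 1.7
  expect_true(all(abs(m - expected) / expected < 0.02))
  # gap between k = 1 and k = 2 is 1/departureRate
  gaps <- rec$resting_time_s[rec$k == 2] - rec$resting_time_s[rec$k == 1]
  expect_lt(abs(mean(gaps) - 1.7), 0.02 * 1.7)
  # limit: no remodeling -> first resting time is exponential
  rec0 <- simulateTipTurnaround(5000, nRemodelSteps = 0,
                                departureRate = 1 / 1.7, seed = 803)
  first <- rec0$resting_time_s[rec0$k == 1]
  expect_gt(stats::ks.test(first, "pexp", rate = 1 / 1.7)$p.value, 0.01)
  expect_error(simulateTipTurnaround(10, departureRate = 0), "> 0")
})

test_that("gamma MLE recovers known parameters and matches fitdistrplus", {
  set.seed(804)
  x <- rgamma(97, 3, 1)
  fit <- fitGammaMl(x, nBoot = 1000, seed = 805)
  expect_gt(fit$alpha, fit$ciAlpha[1])
  expect_lt(fit$alpha, fit$ciAlpha[2])
  expect_true(fit$ciAlpha[1] <= 3 && 3 <= fit$ciAlpha[2])
  expect_true(fit$ciLambda[1] <= 1 && 1 <= fit$ciLambda[2])
  # exponential sample: alpha CI contains 1
  e <- rexp(200, 0.8)
  fe <- fitGammaMl(e, nBoot = 500, seed = 806)
  expect_true(fe$ciAlpha[1] <= 1 && 1 <= fe$ciAlpha[2])
  # large-n consistency
  big <- rgamma(1e5, 3, 1)
  fb <- fitGammaMl(big, nBoot = 0)
  expect_lt(abs(fb$alpha - 3), 0.05)
  # independent cross-check of the point estimates
  skip_if_not_installed("fitdistrplus")
  ref <- fitdistrplus::fitdist(x, "gamma")
  expect_equal(fit$alpha, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$lambda, unname(ref$estimate["rate"]), tolerance = 1e-3)
  expect_error(fitGammaMl(c(x, -1)), "positive")
  expect_error(fitGammaMl(x[1:5]), "at least 10")
})

test_that("linear resting-vs-index fit recovers slope and intercept", {
  # exact algebra on noise-free means
  exact <- data.frame(k = rep(1:4, each = 5),
                      resting_time_s = rep(1 + 2 * (1:4), each = 5))
  fe <- fitRestingVsIndex(exact)
  expect_equal(fe$remodelingTime, 1, tolerance = 1e-10)
  expect_equal(fe$deltaT, 2, tolerance = 1e-10)
  # simulator at the fitted tip kinetics, 97 arrivals
  rec <- simulateTipTurnaround(97, seed = 807)
  f <- fitRestingVsIndex(rec)
  expect_lt(abs(f$deltaT - 1.7), 4 * f$seSlope + 0.3)
  expect_lt(abs(f$remodelingTime - 1.3), 4 * f$seIntercept + 0.5)
  # zero remodeling steps -> intercept ~ 0
  rec0 <- simulateTipTurnaround(5000, nRemodelSteps = 0, seed = 808)
  f0 <- fitRestingVsIndex(rec0)
  expect_lt(abs(f0$remodelingTime), 3 * f0$seIntercept + 0.1)
  # single index level errors
  expect_error(fitRestingVsIndex(exact[exact$k == 1, ]), "levels")
})

test_that("departure gaps are exchangeable across observed indices", {
  rec <- simulateTipTurnaround(2e4, nDeparturesPerArrival = 6, seed = 809)
  early <- fitRestingVsIndex(rec, kMax = 3)
  late <- fitRestingVsIndex(rec[rec$k >= 3, ], kMax = 6)
  expect_lt(abs(early$deltaT - late$deltaT),
            3 * sqrt(early$seSlope^2 + late$seSlope^2) + 0.05)
})

test_that("bootstrap CI for the gamma shape attains nominal coverage", {
  set.seed(810)
  hits <- replicate(500, {
    f <- fitGammaMl(rgamma(97, 3, 1), nBoot = 1000)
    f$ciAlpha[1] <= 3 && 3 <= f$ciAlpha[2]
  })
  expect_gt(mean(hits), 0.93)
  expect_lt(mean(hits), 0.97)
})
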