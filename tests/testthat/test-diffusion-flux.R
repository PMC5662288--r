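test_that("background profiles average out traces and flag interpolation", {
  cfg <- fixtureConfig()
  # uniform background, no traces -> flat profile at 1 after normalization
  k <- renderKymograph(NULL, cfg, duration = 10)
  p <- backgroundProfile(k)
  expect_true(all(abs(p$intensity - 1) < 1e-9))
  # a linear gradient toward the tip survives trace masking
  img <- matrix(rep(seq(1, 3, length.out = 60), 100), 60, 100)
  img[20:25, 40:60] <- 50                       # a bright trace
  kg <- new("Kymograph", image = img, positionScale = 200, timeScale = 0.1,
            maskedColumns = integer(0))
  mask <- matrix(FALSE, 60, 100); mask[20:25, 40:60] <- TRUE
  pg <- backgroundProfile(kg, mask)
  expect_true(all(diff(pg$intensity) > -1e-9))  # monotone toward the tip
  expect_false(any(pg$interpolated))
  # a fully masked position is interpolated and flagged
  mask2 <- mask; mask2[30, ] <- TRUE
  p2 <- backgroundProfile(kg, mask2)
  expect_true(p2$interpolated[30])
  expect_lt(abs(p2$intensity[30] - pg$intensity[30]), 0.05)
  expect_error(backgroundProfile(kg, matrix(TRUE, 60, 100)), "masked")
  expect_error(backgroundProfile(kg, matrix(FALSE, 10, 10)), "dimensions")
})

test_that("FRAP fitting recovers the generating D across a grid", {
  tGrid <- NULL
  for (D in c(0.5, 1, 2, 4)) {
    recs <- vapply(1:13, function(i) frapWindowRecovery(
      makeFrapSeries(D = D, L = 12, window = c(3.5, 8.5), duration = 20,
                     noise = "shot", photonScale = 50,
                     seed = 1000 * D + i))$intensity, numeric(211))
    fs0 <- makeFrapSeries(D = D, L = 12, window = c(3.5, 8.5), duration = 20)
    tt <- frapWindowRecovery(fs0)$time_s
    f <- fitFrap1d(tt, rowMeans(recs), L = 12, window = c(3.5, 8.5),
                   bleachTime = 1, nBoot = 0)
    expect_lt(abs(f$D - D) / D, 0.1)
  }
})

test_that("FRAP fit degenerates gracefully and halves recovery time when D doubles", {
  fs0 <- makeFrapSeries(D = 0, duration = 15)
  rec <- frapWindowRecovery(fs0)
  expect_warning(f0 <- fitFrap1d(rec$time_s, rec$intensity, L = 12,
                                 window = c(3.5, 8.5), bleachTime = 1,
                                 nBoot = 0), "pinned|recovery")
  expect_equal(f0$D, 0)
  # forward-model sweep: half-recovery time scales as 1/D
  tHalf <- vapply(c(1, 2), function(D) {
    tt <- seq(1e-4, 40, 1e-3)
    y <- frapRecoveryModel(tt, D, 12, c(3.5, 8.5))
    stats::approx(y, tt, xout = 0.5)$y      # recovery starts at 0 (depth 1)
  }, 0)
  expect_lt(abs(tHalf[1] / tHalf[2] - 2), 0.05)
})

test_that("FRAP forward model agrees with an independent lattice-walker ensemble", {
  D <- 1.7; dt <- 0.005; dx <- sqrt(2 * D * dt); L <- 12
  nSites <- round(L / dx)
  lo <- round(3.5 / dx); hi <- round(8.5 / dx)
  set.seed(1100)
  nPer <- 4000L
  h <- iftdyn:::bleach_recovery_walk(nPer, as.integer(nSites),
                                     as.integer(5 / dt), as.integer(lo),
                                     as.integer(hi))
  xc <- (seq_len(nSites) - 0.5) * dx
  ana <- frapProfileModel(xc, 5, D, L, c((lo - 1) * dx, hi * dx))
  # average site pairs to remove the parity structure of the +/-1 walk
  pair <- function(v) (v[seq(1, length(v) - 1, 2)] + v[seq(2, length(v), 2)]) / 2
  rms <- sqrt(mean((pair(h / nPer) - pair(as.vector(ana)))^2))
  expect_lt(rms, 0.02)
})

test_that("flux balance is exactly linear in D and closes on steady-state data", {
  prof <- list(position = seq(0.05, 0.95, 0.1), position_um = seq(0.6, 11.4, 1.2),
               intensity = 0.5 * seq(0.6, 11.4, 1.2), interpolated = rep(FALSE, 10),
               nCells = 1L)
  class(prof) <- "intensityProfile"
  f1 <- estimateFluxBalance(prof, D = 1.7, trainIntensity = 10,
                            trainFrequency = 1.3, L = 12)
  f2 <- estimateFluxBalance(prof, D = 3.4, trainIntensity = 10,
                            trainFrequency = 1.3, L = 12)
  expect_equal(f2$efflux, 2 * f1$efflux, tolerance = 1e-12)
  expect_equal(f1$efflux, 0.5 * 1.7, tolerance = 1e-10)
  # zero slope -> efflux ~ 0, flagged
  flat <- prof; flat$intensity <- rep(2, 10)
  expect_warning(fz <- estimateFluxBalance(flat, D = 1.7, trainIntensity = 1,
                                           trainFrequency = 1.3, L = 12),
                 "slope")
  expect_lt(fz$efflux, 1e-9)
  # influx/efflux ~ 1 on the transport model's own steady state:
  # efflux = slope(density) * D should equal the injected flux
  ss <- simulateSteadyState(transportConfig(seed = 1101))
  dxUm <- ss@gridSpacing
  dens <- occupancy(ss) / dxUm                   # molecules per um
  spro <- list(position = NULL, position_um = (seq_along(dens) - 0.5) * dxUm,
               intensity = dens, interpolated = FALSE, nCells = 1L)
  class(spro) <- "intensityProfile"
  fb <- estimateFluxBalance(spro, D = 1.7, trainIntensity = 6,
                            trainFrequency = 1.3, L = 12)
  expect_lt(abs(fb$ratio - 1), 0.1)
})
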