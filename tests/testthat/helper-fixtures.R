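# Shared fixtures, built in code at test time.

fixtureConfig <- function(seed = 1L, ...) trafficConfig(seed = seed, ...)

# A deterministic doublet frame: two equal noiseless spots separated by
# sepSd * psfSd nm along x, summed.
doubletFrame <- function(sepSd, photons = 3000, psfSd = 130, background = 2) {
  sep <- sepSd * psfSd
  a <- makeSpotStack(rbind(c(795 - sep / 2, 795)), photons, psfSd,
                     background / 2, noise = FALSE)
  b <- makeSpotStack(rbind(c(795 + sep / 2, 795)), photons, psfSd,
                     background / 2, noise = FALSE)
  a$stack[, , 1] + b$stack[, , 1]
}

# Per-trace diffusion estimates for a batch of Brownian traces.
brownianDs <- function(n, D, duration = 5, frameRate = 10, locNoise = 20,
                       seedBase = 0) {
  vapply(seq_len(n), function(i)
    msdFit(makeBrownianTrajectory(D, duration, frameRate, locNoise,
                                  seed = seedBase + i))$D, 0)
}
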