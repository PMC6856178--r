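# Shared fixtures: all generated in code at test time.

# Smoothed-noise texture: has gradients everywhere, good for flow oracles.
texturedFrame <- function(h = 64, w = 64, seed = 42, smooth = 1.5) {
  set.seed(seed)
  f <- matrix(runif(h * w, 0, 255), h, w)
  motiliflow:::correlateSep(f, motiliflow:::gaussianKernel1d(smooth))
}

# Circular shift by (dy, dx): the wrap-around translation oracle.
circShift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}

# One particle moving at constant velocity, rendered noise-free.
movingBlobVideo <- function(speed = 2, nFrames = 30, size = 64, seed = 3) {
  sp <- syntheticVideoSpec(nParticles = 1, classFractions = c(1, 0, 0),
                           frameSize = c(size, size), nFrames = nFrames,
                           noiseSigma = 0, seed = seed)
  kin <- kinematicsParams(progressiveSpeed = speed,
                          progressiveHeadingSigma = 0, nonprogJitter = 0.5)
  renderFrames(simulateTracks(sp, kin), sp)
}

# Perfectly static multi-particle scene (no tremor, no noise).
staticVideo <- function(nParticles = 6, nFrames = 30, size = 64, seed = 5) {
  sp <- syntheticVideoSpec(nParticles = nParticles,
                           classFractions = c(0, 0, 1),
                           frameSize = c(size, size), nFrames = nFrames,
                           noiseSigma = 0, seed = seed)
  renderFrames(simulateTracks(sp, kinematicsParams(immotileJitter = 0)), sp)
}

# Small cohort reused by slower tests (built once per test run).
smallCohortCache <- new.env()
smallCohort <- function(nVideos = 12, nFrames = 45, seed = 7) {
  key <- sprintf("c_%d_%d_%d", nVideos, nFrames, seed)
  if (is.null(smallCohortCache[[key]]))
    smallCohortCache[[key]] <- generateCohort(
      nVideos, syntheticVideoSpec(nFrames = nFrames, nParticles = 25),
      seed = seed)
  smallCohortCache[[key]]
}
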