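# Shared fixtures: all generated in code, sized for fast runs.

# deterministic hand-built connectome (values chosen, not sampled)
handConnectome <- function(n = 4) {
  sc <- matrix(0, n, n)
  sc[upper.tri(sc)] <- seq_len(n * (n - 1) / 2) * 10
  sc <- sc + t(sc)
  pl <- matrix(0, n, n)
  pl[upper.tri(pl)] <- 20 + seq_len(n * (n - 1) / 2) * 15
  pl <- pl + t(pl)
  new("StructuralConnectome", sc = sc, pl = pl)
}

# small random connectome via the generator
smallConnectome <- function(nRegions = 8, seed = 11) {
  cfg <- syntheticConfig(nRegions = nRegions, seed = seed)
  generateConnectome(cfg, "fix01", seed)
}

# quick forward-model settings used across simulation tests
quickSim <- list(duration = 30, transient = 5, dt = 2e-3, tr = 2.21)

# tiny cohort with fixed demography
tinyCohort <- function(nHC = 6, nPD = 6) {
  makeCohort(data.frame(
    id = sprintf("s%02d", seq_len(nHC + nPD)),
    group = rep(c("HC", "PD"), c(nHC, nPD)),
    sex = rep(c("F", "M"), length.out = nHC + nPD),
    age = 50 + seq_len(nHC + nPD)))
}

# synthetic landscape stack: list of grid-shaped matrices per subject,
# i.i.d. noise plus an optional per-group offset on a block of grid points
syntheticLandscapes <- function(labels, dims = c(16, 11), sd = 0.05,
                                block = NULL, shift = 0, seed = 1) {
  set.seed(seed)
  lapply(labels, function(g) {
    m <- matrix(rnorm(prod(dims), 0, sd), dims[1], dims[2])
    if (!is.null(block) && g == "PD")
      m[block$rows, block$cols] <- m[block$rows, block$cols] + shift
    m
  })
}
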