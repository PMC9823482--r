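## Shared fixtures, generated in code under fixed seeds.  The full study
## (1000 genes, 3 conditions with planted drifts 0/+2/+6 h) is built once
## per test run and reused by the detection, shift and acceptance tests.

.todTestCache <- new.env(parent = emptyenv())

sharedStudy <- function() {
  if (!is.null(.todTestCache$study)) return(.todTestCache$study)
  cfg <- simConfig(seed = 42L)
  sim <- simulateTimecourses(cfg)
  tcs <- lapply(sim$timecourses, quantileNormalize)
  lib <- buildModelLibrary(ztGrid(tcs[[1]]))
  css <- lapply(tcs, detectCycling, lib = lib)
  .todTestCache$study <- list(cfg = cfg, sim = sim, tcs = tcs, lib = lib,
                              css = css)
  .todTestCache$study
}

## Promoters for the shared study, plus their kmer dictionary (the
## dictionary build is the slow step, so it is cached too).
sharedPromoters <- function() {
  if (is.null(.todTestCache$prom)) {
    study <- sharedStudy()
    .todTestCache$prom <- simulatePromoters(study$sim$truth, seed = 42L)
  }
  .todTestCache$prom
}

sharedDict <- function() {
  if (is.null(.todTestCache$dict))
    .todTestCache$dict <- buildKmerDictionary(sharedPromoters())
  .todTestCache$dict
}

## Hand-built call set: phase NA means expressed-but-arrhythmic; expressed
## FALSE overrides everything.
makeCallSet <- function(condition, genes, phase = NULL, expressed = NULL,
                        rMin = 0.8) {
  n <- length(genes)
  if (is.null(phase)) phase <- rep(NA_real_, n)
  if (is.null(expressed)) expressed <- rep(TRUE, n)
  rhythmic <- expressed & !is.na(phase)
  R <- ifelse(rhythmic, 0.95, ifelse(expressed, 0.1, NA_real_))
  new("CyclingCallSet", condition = condition,
      calls = S4Vectors::DataFrame(
        gene = genes, expressed = expressed, rhythmic = rhythmic,
        shape = ifelse(rhythmic, "cosine", NA_character_),
        phase = ifelse(rhythmic, phase, NA_real_), R = R,
        amplitude = ifelse(rhythmic, 2, NA_real_)),
      rMin = rMin)
}

## A noiseless single-condition study with every gene cycling as a cosine
## at one phase: the sharpest possible round-trip fixture.
noiselessCosineConfig <- function(phase = 8, nGenes = 40, seed = 7L) {
  pd <- rep(0, 24); pd[phase + 1] <- 1
  simConfig(nGenes = nGenes, cyclingFraction = 1, notExpressedFraction = 0,
            phaseDistribution = pd, waveformMix = c(cosine = 1),
            noiseSd = 0, phaseJitterSd = 0,
            conditions = list(conditionSpec("single", phaseDrift = 0)),
            plantedKmers = list(), goTerms = list(), seed = seed)
}
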