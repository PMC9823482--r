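test_that("noiseless cosine genes peak exactly at their planted phase", {
  sim <- simulateTimecourses(noiselessCosineConfig(phase = 8))
  m <- intensities(sim$timecourses[[1]])
  zt <- ztGrid(sim$timecourses[[1]])
  peakCols <- which(zt %% 24 == 8)           # ZT8 and ZT32
  for (i in seq_len(nrow(m))) {
    mx <- max(m[i, ])
    expect_equal(unname(m[i, peakCols]), rep(mx, 2))
    expect_true(all(m[i, -peakCols] < mx))
  }
})

test_that("the generator is bitwise deterministic given seed and config", {
  cfg <- simConfig(nGenes = 60, seed = 9L)
  a <- simulateTimecourses(cfg)
  b <- simulateTimecourses(cfg)
  for (cn in names(a$timecourses))
    expect_identical(intensities(a$timecourses[[cn]]),
                     intensities(b$timecourses[[cn]]))
  expect_identical(truePhases(a$truth), truePhases(b$truth))
  expect_identical(as.character(simulatePromoters(a$truth, seed = 4L)),
                   as.character(simulatePromoters(b$truth, seed = 4L)))
  expect_identical(simulateGOMap(a$truth, seed = 4L),
                   simulateGOMap(b$truth, seed = 4L))
})

test_that("cycling and not-expressed fractions are applied by rounding", {
  sim <- simulateTimecourses(simConfig(nGenes = 1000, cyclingFraction = 0.6,
                                       notExpressedFraction = 0.2,
                                       seed = 5L))
  tt <- truthTable(sim$truth)
  expect_identical(sum(tt$cycling), 600L)
  expect_identical(sum(!tt$expressed), 200L)
  expect_true(all(tt$expressed[tt$cycling]))  # cycling implies expressed
})

test_that("true phases respect the per-condition drift mod 24", {
  cfg <- simConfig(nGenes = 300, seed = 2L)
  sim <- simulateTimecourses(cfg)
  ph <- truePhases(sim$truth)
  cyc <- truthTable(sim$truth)$cycling
  expect_true(all(ph[cyc, ] >= 0 & ph[cyc, ] < 24))
  expect_true(all(is.na(ph[!cyc, ])))
  drift2 <- (ph[cyc, 2] - ph[cyc, 1]) %% 24
  drift3 <- (ph[cyc, 3] - ph[cyc, 1]) %% 24
  expect_equal(unname(drift2), rep(2, sum(cyc)))
  expect_equal(unname(drift3), rep(6, sum(cyc)))
})

test_that("marginal phase histogram matches the mixture within sampling error", {
  cfg <- simConfig(nGenes = 4000, noiseSd = 0, seed = 31L,
                   conditions = list(conditionSpec("one")))
  sim <- simulateTimecourses(cfg)
  bp <- truthTable(sim$truth)$basePhase
  counts <- table(factor(bp[!is.na(bp)], levels = 0:23))
  p <- chisq.test(counts, p = cfg@phaseDistribution)$p.value
  expect_gt(p, 0.01)
})

test_that("invalid mixture weights are a configuration error", {
  expect_error(simConfig(waveformMix = c(cosine = 0.7, box = 0.7)),
               "probability")
  expect_error(simConfig(phaseDistribution = rep(1, 24)), "probability")
  expect_error(simConfig(plantedKmers = list(
    list(kmer = "AAXT", bin = 1, fraction = 1))), "alphabet")
  expect_error(simConfig(plantedKmers = list(
    list(kmer = "AAATATCTT", bin = 1, fraction = 1))), "3-8")
})

test_that("promoters are background-only without planted kmers", {
  sim <- simulateTimecourses(noiselessCosineConfig(nGenes = 20))
  ps <- simulatePromoters(sim$truth, length = 500, seed = 3L)
  expect_length(ps, 20L)
  expect_true(all(Biostrings::width(ps) == 500))
  expect_length(S4Vectors::metadata(ps)$carriers, 0L)
})

test_that("a kmer planted at fraction 1 occurs in every target-bin promoter", {
  cfg <- simConfig(nGenes = 400, seed = 8L,
                   plantedKmers = list(
                     list(kmer = "AAATATCT", bin = 12, fraction = 1)))
  sim <- simulateTimecourses(cfg)
  ps <- simulatePromoters(sim$truth, seed = 8L)
  tt <- truthTable(sim$truth)
  binGenes <- tt$gene[!is.na(tt$basePhase) & floor(tt$basePhase) == 12]
  expect_gt(length(binGenes), 0L)
  hits <- vapply(as.character(ps[binGenes]),
                 grepl, TRUE, pattern = "AAATATCT", fixed = TRUE)
  expect_true(all(hits))
})

test_that("planting at fraction 0.5 yields the rounded carrier count", {
  cfg <- simConfig(nGenes = 600, seed = 12L,
                   plantedKmers = list(
                     list(kmer = "GGGCCCTT", bin = 0, fraction = 0.5)))
  sim <- simulateTimecourses(cfg)
  ps <- simulatePromoters(sim$truth, seed = 12L)
  tt <- truthTable(sim$truth)
  nBin <- sum(!is.na(tt$basePhase) & floor(tt$basePhase) == 0)
  carriers <- S4Vectors::metadata(ps)$carriers[["GGGCCCTT"]]
  expect_identical(length(carriers), as.integer(round(0.5 * nBin)))
})

test_that("GO map: infinite odds makes a term exclusive to its bin", {
  cfg <- simConfig(nGenes = 500, seed = 6L,
                   goTerms = list(list(term = "GO:0000201", bin = 6,
                                       odds = Inf)))
  sim <- simulateTimecourses(cfg)
  map <- simulateGOMap(sim$truth, nTerms = 0L, seed = 6L)
  tt <- truthTable(sim$truth)
  carriers <- map$gene[map$term == "GO:0000201"]
  bins <- floor(tt$basePhase[match(carriers, tt$gene)])
  expect_true(all(bins == 6))
  binGenes <- tt$gene[!is.na(tt$basePhase) & floor(tt$basePhase) == 6]
  expect_setequal(carriers, binGenes)       # complete over the bin
})

test_that("GO map: odds 1 gives carriage independent of phase", {
  cfg <- simConfig(nGenes = 4000, seed = 13L,
                   conditions = list(conditionSpec("one")),
                   goTerms = list(list(term = "GO:0000201", bin = 6,
                                       odds = 1)))
  sim <- simulateTimecourses(cfg)
  map <- simulateGOMap(sim$truth, nTerms = 0L, seed = 13L, baseProb = 0.2)
  tt <- truthTable(sim$truth)
  cyc <- !is.na(tt$basePhase)
  carry <- tt$gene[cyc] %in% map$gene[map$term == "GO:0000201"]
  inBin <- floor(tt$basePhase[cyc]) == 6
  p <- chisq.test(table(carry, inBin))$p.value
  expect_gt(p, 0.01)
})

test_that("an empty GO map is accepted downstream", {
  cfg <- simConfig(nGenes = 30, seed = 3L, goTerms = list())
  sim <- simulateTimecourses(cfg)
  map <- simulateGOMap(sim$truth, nTerms = 0L, seed = 3L)
  expect_identical(nrow(map), 0L)
  res <- enrichGO(letters[1:3], letters[1:10], map)
  expect_identical(nrow(res), 0L)
})

test_that("off-library waveforms simulate and are still mostly detected", {
  cfg <- simConfig(nGenes = 200, seed = 17L, noiseSd = 0.3,
                   waveformMix = c(trapezoid = 1),
                   conditions = list(conditionSpec("one")))
  sim <- simulateTimecourses(cfg)
  tc <- quantileNormalize(sim$timecourses[[1]])
  ccs <- detectCycling(tc, buildModelLibrary(ztGrid(tc)))
  tt <- truthTable(sim$truth)
  detected <- calls(ccs)$rhythmic[tt$cycling]
  expect_gt(mean(detected), 0.8)
})
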