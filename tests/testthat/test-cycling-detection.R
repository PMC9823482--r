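zt25 <- seq(6, 54, by = 2)

test_that("the default library holds 6 shapes x 24 phases, standardized", {
  lib <- buildModelLibrary(zt25)
  tm <- templates(lib)
  expect_identical(nrow(tm), 144L)
  expect_true(all(abs(rowMeans(tm)) < 1e-9))
  expect_true(all(abs(apply(tm, 1, var) - 1) < 1e-9))
})

test_that("the cosine template at phase 8 peaks at ZT8 and ZT32", {
  lib <- buildModelLibrary(zt25, shapes = "cosine")
  row <- templates(lib)[lib@phase == 8, ]
  peaks <- which(row == max(row))
  expect_identical(zt25[peaks], c(8, 32))
})

test_that("insufficient grids are rejected", {
  expect_error(buildModelLibrary(seq(0, 46, by = 2)), "2 full")
  expect_error(buildModelLibrary(seq(0, 48, by = 8)), "spacing")
})

test_that("expressed gating: all-zero genes are not expressed, high genes are", {
  m <- rbind(zero = rep(0, 25), high = rep(100, 25),
             mid = runif(25, 40, 60))
  tc <- TimeCourse(m, zt = zt25, condition = "c")
  ex <- callExpressed(tc)
  expect_false(ex[["zero"]])
  expect_true(ex[["high"]])
})

test_that("expressed recall on synthetic truth exceeds 0.95 at defaults", {
  study <- sharedStudy()
  tt <- truthTable(study$sim$truth)
  ex <- callExpressed(study$tcs[[1]])
  expect_gt(mean(ex[tt$gene[tt$expressed]]), 0.95)
})

test_that("noiseless cosine genes come back rhythmic with R = 1 at phase 8", {
  sim <- simulateTimecourses(noiselessCosineConfig(phase = 8))
  tc <- sim$timecourses[[1]]
  ccs <- detectCycling(tc, buildModelLibrary(ztGrid(tc)),
                       expressed = setNames(rep(TRUE, nrow(tc)),
                                            rownames(tc)))
  cl <- calls(ccs)
  expect_true(all(cl$rhythmic))
  expect_equal(unname(cl$R), rep(1, nrow(cl)), tolerance = 1e-9)
  expect_equal(unname(cl$phase), rep(8, nrow(cl)))
  expect_true(all(cl$shape == "cosine"))
})

test_that("library argmax equals a brute-force correlation scan", {
  study <- sharedStudy()
  lib <- study$lib
  tc <- study$tcs[[1]]
  X <- log2(intensities(tc) + 1)
  cl <- calls(study$css[[1]])
  set.seed(1)
  for (i in sample(which(cl$expressed), 20L)) {
    oracle <- bruteArgmaxOracle(X[i, ], lib)
    expect_equal(cl$R[i], oracle$R, tolerance = 1e-12)
    expect_identical(cl$shape[i], lib@shape[oracle$idx])
  }
  ## phase is only reported for rhythmic genes; check the argmax there
  ## (skipping float-level ties, which the two routes may break apart)
  for (i in sample(which(cl$rhythmic), 20L)) {
    oracle <- bruteArgmaxOracle(X[i, ], lib)
    if (oracle$gap > 1e-9)
      expect_identical(cl$phase[i], lib@phase[oracle$idx])
  }
})

test_that("constant expressed profiles are called not rhythmic, with a note", {
  m <- rbind(flat = rep(50, 25), wave = 50 + 40 *
               waveformValue("cosine", zt25, 10))
  tc <- TimeCourse(m, zt = zt25, condition = "c")
  expect_message(
    ccs <- detectCycling(tc, buildModelLibrary(zt25),
                         expressed = c(flat = TRUE, wave = TRUE)),
    "constant")
  cl <- calls(ccs)
  expect_false(cl$rhythmic[cl$gene == "flat"])
  expect_true(cl$rhythmic[cl$gene == "wave"])
})

test_that("lowering the R threshold never decreases the rhythmic count", {
  study <- sharedStudy()
  tc <- study$tcs[[1]]
  n08 <- length(rhythmicGenes(detectCycling(tc, study$lib, rMin = 0.8)))
  n07 <- length(rhythmicGenes(detectCycling(tc, study$lib, rMin = 0.7)))
  n09 <- length(rhythmicGenes(detectCycling(tc, study$lib, rMin = 0.9)))
  expect_true(n09 <= n08 && n08 <= n07)
})

test_that("summary percentages follow the mixed-denominator convention", {
  s <- todSummary(27648, notExpressed = 4735, rhythmic = 15615)
  expect_identical(s$pctRhythmic, 68L)      # of expressed
  expect_identical(s$pctNotExpressed, 17L)  # of total
  expect_identical(s$pctNotRhythmic, 26L)   # of total
  allR <- todSummary(100, notExpressed = 0, rhythmic = 100)
  expect_identical(c(allR$pctRhythmic, allR$pctNotRhythmic,
                     allR$pctNotExpressed), c(100L, 0L, 0L))
  expect_error(todSummary(10, notExpressed = 2, notRhythmic = 5,
                          rhythmic = 5), "partition")
})

test_that("call-set summaries partition the gene total", {
  study <- sharedStudy()
  for (ccs in study$css) {
    s <- cyclingSummary(ccs)
    expect_identical(s$notExpressed + s$notRhythmic + s$rhythmic, s$total)
  }
})

test_that("phase lists split by hourly bin and merge to 23 on request", {
  study <- sharedStudy()
  ccs <- study$css[[1]]
  l24 <- phaseGeneLists(ccs, bins = 24)
  expect_identical(names(l24), as.character(0:23))
  expect_identical(sum(lengths(l24)), length(rhythmicGenes(ccs)))
  l23 <- phaseGeneLists(ccs, bins = 23)
  expect_length(l23, 23L)
  expect_identical(sum(lengths(l23)), length(rhythmicGenes(ccs)))
  expect_true(any(grepl("\\+", names(l23))))
  expect_error(phaseGeneLists(ccs, bins = 22), "24 or 23")
})
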