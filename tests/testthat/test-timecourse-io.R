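writeLinesTsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("a well-formed table loads with the full ZT grid", {
  zt <- seq(6, 54, by = 2)
  lines <- c(paste(c("gene", paste0("ZT", zt)), collapse = "\t"),
             vapply(1:3, function(i)
               paste(c(paste0("g", i), seq_along(zt) + i), collapse = "\t"),
               ""))
  tc <- readExpressionTable(writeLinesTsv(lines), condition = "c")
  expect_s4_class(tc, "TimeCourse")
  expect_length(ztGrid(tc), 25L)
  expect_identical(rownames(tc), paste0("g", 1:3))
})

test_that("expression tables round-trip through write and read", {
  sim <- simulateTimecourses(simConfig(nGenes = 25, seed = 19L))
  tc <- sim$timecourses[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTable(tc, f)
  back <- readExpressionTable(f, condition = conditionName(tc))
  expect_equal(intensities(back), intensities(tc), tolerance = 1e-12)
  expect_identical(ztGrid(back), ztGrid(tc))
})

test_that("duplicate gene ids are rejected by name", {
  lines <- c("gene\tZT0\tZT2\tZT4",
             "gA\t1\t2\t3", "gA\t4\t5\t6")
  expect_error(readExpressionTable(writeLinesTsv(lines), "c"), "gA")
})

test_that("ragged rows and non-numeric cells fail naming the line", {
  ragged <- c("gene\tZT0\tZT2\tZT4", "gA\t1\t2\t3", "gB\t4\t5")
  expect_error(readExpressionTable(writeLinesTsv(ragged), "c"), "ragged")
  badcell <- c("gene\tZT0\tZT2\tZT4", "gA\t1\t2\t3", "gB\t4\toops\t6")
  expect_error(readExpressionTable(writeLinesTsv(badcell), "c"), "line")
})

test_that("single missing values interpolate; two or more exclude the gene", {
  lines <- c("gene\tZT0\tZT2\tZT4\tZT6",
             "gA\t1\t\t3\t4",          # one missing -> interpolated
             "gB\t1\t\t\t4",           # two missing -> flagged
             "gC\t5\t6\t7\t8")
  expect_message(tc <- readExpressionTable(writeLinesTsv(lines), "c"),
                 "interpolated")
  expect_equal(unname(intensities(tc)["gA", 2]), 2)
  excl <- SummarizedExperiment::rowData(tc)$naExcluded
  expect_identical(unname(excl), c(FALSE, TRUE, FALSE))
  expressed <- callExpressed(tc, bgQuantile = 0.05)
  expect_false(expressed[["gB"]])
})

test_that("FASTA promoters round-trip and are validated", {
  sim <- simulateTimecourses(noiselessCosineConfig(nGenes = 4))
  ps <- simulatePromoters(sim$truth, length = 500, seed = 2L)
  f <- withr::local_tempfile(fileext = ".fasta")
  writePromoters(ps, f)
  back <- readPromoters(f, expectedLength = 500)
  expect_identical(as.character(back), as.character(ps))

  expect_error(readPromoters(f, expectedLength = 400), "length")
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGTX"), bad)
  expect_error(readPromoters(bad), "non-DNA")
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), empty)
  expect_error(readPromoters(empty), "empty")
})

test_that("lowercase FASTA is coerced to uppercase", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "acgtn"), f)
  expect_identical(as.character(readPromoters(f)), c(g1 = "ACGTN"))
})

test_that("gene-GO maps read from two-column TSV and from GAF", {
  map <- data.frame(gene = c("g1", "g1", "g2"),
                    term = c("GO:0000001", "GO:0000002", "GO:0000001"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneGO(map, f)
  expect_identical(readGeneGO(f), map)

  gafLine <- function(gene, term)
    paste(c("DB", gene, gene, "", term, "REF", "IEA", "", "P",
            rep("", 8)), collapse = "\t")
  gaf <- withr::local_tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", gafLine("g1", "GO:0000001"),
               gafLine("g2", "GO:0000002")), gaf)
  parsed <- readGeneGO(gaf)
  expect_identical(parsed$gene, c("g1", "g2"))
  expect_identical(parsed$term, c("GO:0000001", "GO:0000002"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\tGO:123", bad)
  expect_error(readGeneGO(bad), "malformed")
})

test_that("annotation genes absent from expression data are retained", {
  map <- data.frame(gene = c("g1", "ghost"), term = rep("GO:0000001", 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneGO(map, f)
  expect_true("ghost" %in% readGeneGO(f)$gene)
})

test_that("cycling call tables round-trip", {
  study <- sharedStudy()
  ccs <- study$css[[1]]
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCallsTable(ccs, f)
  back <- readCallsTable(f, condition = conditionName(ccs))
  expect_identical(rhythmicGenes(back), rhythmicGenes(ccs))
  expect_equal(phases(back), phases(ccs))
  expect_identical(cyclingSummary(back), cyclingSummary(ccs))
})

test_that("TimeCourse validity rejects malformed objects", {
  m <- matrix(1:12, nrow = 2, dimnames = list(c("a", "b"), NULL))
  expect_error(TimeCourse(m, zt = c(0, 2, 4, 4, 8, 10), condition = "c"),
               "increasing")
  expect_error(TimeCourse(-m, zt = seq(0, 10, 2), condition = "c"),
               "non-negative")
  m2 <- m; rownames(m2) <- c("a", "a")
  expect_error(TimeCourse(m2, zt = seq(0, 10, 2), condition = "c"),
               "unique")
})
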