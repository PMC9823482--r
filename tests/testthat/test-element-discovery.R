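tinyPromoters <- function() {
  Biostrings::DNAStringSet(c(
    p1 = "ACGTACGTACGTACGTACGTACGTACGTAC",
    p2 = "AAATATCTGGGCCCAAATATCTTTTTTTTT",
    p3 = "TTTTGGGGCCCCAAAATTTTGGGGCCCCAA",
    p4 = "ACACACACACACACACACACACACACACAC",
    p5 = "GATCGATCGATCGATCGATCGATCGATCGA"))
}

test_that("the dictionary covers all 87,360 kmers of length 3-8", {
  d <- buildKmerDictionary(tinyPromoters())
  expect_identical(length(d@counts), 87360L)
  expect_identical(sum(4^(3:8)), 87360)
})

test_that("presence is counted once per promoter regardless of occurrences", {
  d <- buildKmerDictionary(tinyPromoters())
  ## "ACGT" occurs 7 times in p1 and in no other promoter
  expect_identical(unname(d@counts[["ACGT"]]), 1L)
  expect_identical(unname(d@counts[["AAATATCT"]]), 1L)
})

test_that("dictionary counts match a naive substring scan", {
  proms <- tinyPromoters()
  d <- buildKmerDictionary(proms)
  seqs <- as.character(proms)
  ## all words actually present, plus some absent controls
  present <- unique(unlist(lapply(seqs, function(s)
    unlist(lapply(3:8, function(k)
      substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))))))
  for (w in present)
    expect_identical(unname(d@counts[[w]]), kmerPresenceOracle(seqs, w))
  for (w in c("GGGGGGGG", "TTTAAACC", "CGCGCGCG"))
    expect_identical(unname(d@counts[[w]]), kmerPresenceOracle(seqs, w))
  ## completeness: every observed substring is in the dictionary
  expect_true(all(present %in% names(d@counts)))
})

test_that("N-containing windows are skipped, not counted", {
  proms <- Biostrings::DNAStringSet(c(a = "AAANAAA", b = "CCCCCCC"))
  d <- buildKmerDictionary(proms)
  expect_identical(unname(d@counts[["AAA"]]), 1L)
  expect_identical(unname(d@counts[["AAAA"]]), 0L)
})

test_that("the hypergeometric tail matches the 6/252 worked example", {
  ## universe of 10, 4 carriers; list of 5 with 4 carriers
  seqs <- c(rep("AAATATCTGG", 4), rep("CCGGCCGGCC", 6))
  names(seqs) <- paste0("g", 1:10)
  proms <- Biostrings::DNAStringSet(seqs)
  d <- buildKmerDictionary(proms)
  res <- enrichKmers(d, proms, paste0("g", c(1:4, 10)))
  p <- res$p[res$kmer == "AAATATCT"]
  expect_equal(p, 6 / 252, tolerance = 1e-12)
  expect_equal(p, hyperEnumOracle(10, 4, 5, 4), tolerance = 1e-12)
  ## a kmer absent from the list: upper tail at 0 is certain
  pAbsent <- res$p[res$kmer == "CCGGCCGG"]
  expect_identical(pAbsent, 1)
})

test_that("an empty gene list yields an empty result", {
  d <- buildKmerDictionary(tinyPromoters())
  expect_identical(nrow(enrichKmers(d, tinyPromoters(), character())), 0L)
  expect_error(enrichKmers(d, tinyPromoters(), "ghost"), "universe")
})

test_that("per-list q-values reproduce the naive BH step-up oracle", {
  study <- sharedStudy()
  prom <- sharedPromoters()
  d <- sharedDict()
  gl <- phaseGeneLists(study$css[[1]])[["12"]]
  res <- enrichKmers(d, prom, gl)
  expect_true(all(res$q >= res$p))
  expect_identical(res$significant, bhRejectOracle(res$p, 0.05))
  ## q monotone in p
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-15))
})

test_that("a planted kmer is significant in its phase list", {
  study <- sharedStudy()
  prom <- sharedPromoters()
  d <- sharedDict()
  gl <- phaseGeneLists(study$css[[1]])[["12"]]
  res <- enrichKmers(d, prom, gl)
  expect_true(res$significant[res$kmer == "AAATATCT"])
})

test_that("kmers cluster by the (min-length - 1)-match linkage rule", {
  one <- clusters(clusterKmers(c("AAATATCT", "AATATCT")))
  expect_length(one, 1L)
  expect_setequal(one[[1]]$members, c("AAATATCT", "AATATCT"))

  two <- clusters(clusterKmers(c("AAACCCT", "GGATCCG")))
  expect_length(two, 2L)

  single <- clusters(clusterKmers("ACGT"))[[1]]
  expect_identical(single$consensus, "ACGT")
  expect_true(all(colSums(single$pfm) == 1L))
  expect_identical(unname(single$pfm["A", 1]), 1L)
})

test_that("cluster frequency-matrix columns sum to the member count where covered", {
  mcs <- clusterKmers(c("AAATATCT", "AATATCT", "AAATATC"))
  expect_length(clusters(mcs), 1L)
  cl <- clusters(mcs)[[1]]
  covered <- colSums(cl$pfm)
  ## positions covered by all members carry all three counts
  expect_equal(max(covered), 3)
  expect_equal(sum(cl$pfm), sum(nchar(cl$members)))
})

test_that("every significant kmer lands in exactly one cluster", {
  kmers <- c("AAATATCT", "AATATCT", "ATATCT", "GGGCCC", "GGGCCCA")
  mcs <- clusterKmers(kmers)
  got <- unlist(lapply(clusters(mcs), `[[`, "members"))
  expect_setequal(got, kmers)
  expect_identical(length(got), length(kmers))
})

test_that("TOD profiles are zero where never significant, peaked where planted", {
  study <- sharedStudy()
  prom <- sharedPromoters()
  d <- sharedDict()
  enr <- runElement(study$css[[1]], prom, dict = d)
  prof <- todProfile(enr, "AAATATCT")
  expect_identical(colnames(prof)[which.max(prof[1, ])], "12")
  dead <- todProfile(enr, "GCGCGCGC")
  expect_true(all(dead == 0))
})
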