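#' Condition specification for the synthetic generator
#'
#' One simulated developmental condition.  \code{phaseDrift} hours are added
#' (mod 24) to every cycling gene's true phase relative to the first
#' condition, emulating the seasonal drift of expression timing relative to
#' fixed clock-time sampling; \code{amplitudeScale} multiplies log2
#' amplitudes.
#'
#' @param name condition label, e.g. \code{"leaf_15d"}.
#' @param phaseDrift hours, interpreted mod 24.
#' @param amplitudeScale multiplier on log2 amplitude.
#' @param tissue tissue label.
#' @param dayOfSeason days after sowing (metadata only).
#' @return a plain list consumed by \code{\link{simConfig}}.
#' @export
conditionSpec <- function(name, phaseDrift = 0, amplitudeScale = 1,
                          tissue = "leaf", dayOfSeason = NA_real_) {
  list(name = name, phaseDrift = phaseDrift %% 24,
       amplitudeScale = amplitudeScale, tissue = tissue,
       dayOfSeason = dayOfSeason)
}

## Default bimodal phase distribution: cycling genes pile up at relative
## dawn (ZT-label 0) and dusk (ZT-label 12), as diurnal transcriptomes do.
.defaultPhaseDistribution <- function() {
  h <- 0:23
  w <- 1 + 3 * exp(-(circularDistance(h, 0) / 2.5)^2) +
           3 * exp(-(circularDistance(h, 12) / 2.5)^2)
  w / sum(w)
}

#' Configuration of the synthetic diurnal time-course study
#'
#' Builds a validated \linkS4class{SimConfig}.  The defaults define the
#' synthetic study conditions used throughout the package's recovery tests:
#' 1000 genes sampled every 2 h over two days (ZT6--ZT54, 25 timepoints) in
#' three developmental conditions with planted phase drifts of 0, +2 and
#' +6 h; 60\% of genes cycling with a dawn/dusk-enriched phase
#' distribution; 20\% of genes not expressed; Gaussian noise of sd 0.5 on
#' log2 intensity (placing the median best template correlation of cycling
#' genes near 0.9); the Evening Element \code{AAATATCT} planted in 80\% of
#' the promoters of phase-bin-12 genes; and two GO terms enriched at dawn
#' and dusk with odds 8.
#'
#' @param nGenes number of genes.
#' @param ztGrid sampling grid in ZT-label hours.
#' @param conditions list of \code{\link{conditionSpec}} entries.
#' @param cyclingFraction fraction of all genes that cycle (applied
#'   deterministically by rounding).
#' @param notExpressedFraction fraction of genes drawn at background level.
#' @param phaseDistribution 24 hourly mixture weights for base phases.
#' @param waveformMix named weights over waveform shapes; shapes outside
#'   the detection library (e.g. \code{"trapezoid"}) may be included to
#'   test robustness to off-library waveforms.
#' @param noiseSd Gaussian sd on log2 intensity.
#' @param baselineLogMean,baselineLogSd lognormal baseline of expressed
#'   genes (log2 scale).
#' @param backgroundLogMean log2 level of not-expressed genes.
#' @param amplitudeRange range of log2 peak-to-trough amplitudes
#'   (uniformly drawn).
#' @param phaseJitterSd per-gene, per-condition phase jitter sd in hours
#'   (0 = the drift is exactly constant per condition).
#' @param plantedKmers list of \code{list(kmer=, bin=, fraction=)} entries.
#' @param goTerms list of \code{list(term=, bin=, odds=)} phase-enriched
#'   terms; \code{odds = Inf} makes the term exclusive to its bin.
#' @param nGoBackgroundTerms number of uniformly assigned background terms.
#' @param goBaseProb background per-(gene, term) carriage probability.
#' @param seed integer seed; all generator randomness derives from it.
#' @return a \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 200, seed = 11)
#' cfg
#' @export
simConfig <- function(nGenes = 1000,
                      ztGrid = seq(6, 54, by = 2),
                      conditions = list(
                        conditionSpec("leaf_15d", phaseDrift = 0,
                                      dayOfSeason = 15),
                        conditionSpec("leaf_29d", phaseDrift = 2,
                                      dayOfSeason = 29),
                        conditionSpec("leaf_43d", phaseDrift = 6,
                                      dayOfSeason = 43)),
                      cyclingFraction = 0.6,
                      notExpressedFraction = 0.2,
                      phaseDistribution = .defaultPhaseDistribution(),
                      waveformMix = c(cosine = 0.5, sharp_cosine = 0.2,
                                      box = 0.1, spike = 0.05,
                                      ramp_up = 0.075, ramp_down = 0.075),
                      noiseSd = 0.5,
                      baselineLogMean = 7, baselineLogSd = 1,
                      backgroundLogMean = 2,
                      amplitudeRange = c(2, 4),
                      phaseJitterSd = 0,
                      plantedKmers = list(
                        list(kmer = "AAATATCT", bin = 12, fraction = 0.8)),
                      goTerms = list(
                        list(term = "GO:0000101", bin = 0, odds = 8),
                        list(term = "GO:0000102", bin = 12, odds = 8)),
                      nGoBackgroundTerms = 40L,
                      goBaseProb = 0.05,
                      seed = 1L) {
  new("SimConfig", nGenes = as.integer(nGenes), ztGrid = as.numeric(ztGrid),
      cyclingFraction = cyclingFraction,
      notExpressedFraction = notExpressedFraction,
      phaseDistribution = phaseDistribution, waveformMix = waveformMix,
      noiseSd = noiseSd, baselineLogMean = baselineLogMean,
      baselineLogSd = baselineLogSd, backgroundLogMean = backgroundLogMean,
      amplitudeRange = amplitudeRange, phaseJitterSd = phaseJitterSd,
      conditions = conditions, plantedKmers = plantedKmers,
      goTerms = goTerms, nGoBackgroundTerms = as.integer(nGoBackgroundTerms),
      goBaseProb = goBaseProb, seed = as.integer(seed))
}

#' Simulate a multi-condition diurnal expression study
#'
#' Generates one linear-scale \linkS4class{TimeCourse} per configured
#' condition, all over the same gene set and ZT grid, plus the
#' \linkS4class{GroundTruth} of what was planted.  Signals are built on
#' log2 scale -- lognormal baseline, plus amplitude times the gene's raw
#' waveform evaluated at the condition-drifted phase, plus Gaussian noise
#' -- and mapped to linear intensities by inverting the
#' \code{log2(x + 1)} analysis transform.  Cycling status, waveforms, amplitudes and base
#' phases are shared across conditions; only the phase drift (and fresh
#' noise) differs, so planted drifts are exactly recoverable.  The number
#' of cycling genes is \code{round(nGenes * cyclingFraction)}, drawn from
#' the expressed genes.  Deterministic given \code{cfg@seed}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return \code{list(timecourses = <named list of TimeCourse>,
#'   truth = <GroundTruth>)}.
#' @examples
#' sim <- simulateTimecourses(simConfig(nGenes = 100, seed = 3))
#' sim$timecourses[[1]]
#' sim$truth
#' @export
simulateTimecourses <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@nGenes
  genes <- sprintf("gene_%05d", seq_len(n))
  condNames <- vapply(cfg@conditions, `[[`, "", "name")

  nNotExpr <- round(n * cfg@notExpressedFraction)
  nCycling <- round(n * cfg@cyclingFraction)
  if (nCycling > n - nNotExpr)
    stop("cyclingFraction + notExpressedFraction exceed 1 gene pool")
  notExpr <- sample(genes, nNotExpr)
  expressed <- !(genes %in% notExpr)
  cycling <- rep(FALSE, n)
  cycling[sample(which(expressed), nCycling)] <- TRUE

  basePhase <- rep(NA_real_, n)
  basePhase[cycling] <- sample(0:23, nCycling, replace = TRUE,
                               prob = cfg@phaseDistribution)
  waveform <- rep(NA_character_, n)
  waveform[cycling] <- sample(names(cfg@waveformMix), nCycling,
                              replace = TRUE, prob = cfg@waveformMix)
  amplitude <- rep(0, n)
  amplitude[cycling] <- runif(nCycling, cfg@amplitudeRange[1],
                              cfg@amplitudeRange[2])
  baseline <- rep(cfg@backgroundLogMean, n)
  baseline[expressed] <- rnorm(sum(expressed), cfg@baselineLogMean,
                               cfg@baselineLogSd)

  phaseMat <- matrix(NA_real_, n, length(condNames),
                     dimnames = list(genes, condNames))
  tcs <- vector("list", length(cfg@conditions))
  names(tcs) <- condNames
  for (ci in seq_along(cfg@conditions)) {
    cs <- cfg@conditions[[ci]]
    ph <- basePhase + cs$phaseDrift
    if (cfg@phaseJitterSd > 0)
      ph <- ph + rnorm(n, 0, cfg@phaseJitterSd)
    ph <- ph %% 24
    phaseMat[cycling, ci] <- ph[cycling]
    log2m <- matrix(baseline, n, length(cfg@ztGrid))
    for (g in which(cycling)) {
      w <- waveformValue(waveform[g], cfg@ztGrid, ph[g])
      log2m[g, ] <- baseline[g] + amplitude[g] * cs$amplitudeScale * w
    }
    if (cfg@noiseSd > 0)
      log2m <- log2m + matrix(rnorm(length(log2m), 0, cfg@noiseSd),
                              nrow = n)
    ## invert the log2(x + 1) analysis transform exactly, so noiseless
    ## waveforms round-trip to correlation 1 with their template
    m <- pmax(2^log2m - 1, 0)
    rownames(m) <- genes
    tcs[[ci]] <- TimeCourse(m, zt = cfg@ztGrid, condition = cs$name,
                            tissue = cs$tissue,
                            dayOfSeason = cs$dayOfSeason)
  }

  truth <- new("GroundTruth",
    genes = S4Vectors::DataFrame(
      gene = genes, expressed = expressed, cycling = cycling,
      waveform = waveform, amplitude = amplitude, baseline = baseline,
      basePhase = basePhase),
    phases = phaseMat,
    plantedKmers = S4Vectors::DataFrame(
      kmer = vapply(cfg@plantedKmers, `[[`, "", "kmer"),
      bin = vapply(cfg@plantedKmers, function(x) as.numeric(x$bin), 0),
      fraction = vapply(cfg@plantedKmers, `[[`, 0, "fraction")),
    goTruth = S4Vectors::DataFrame(
      term = vapply(cfg@goTerms, `[[`, "", "term"),
      bin = vapply(cfg@goTerms, function(x) as.numeric(x$bin), 0),
      odds = vapply(cfg@goTerms, function(x) as.numeric(x$odds), 0)),
    conditions = condNames)
  list(timecourses = tcs, truth = truth)
}

#' Simulate promoters with planted phase-specific kmers
#'
#' Uniform-random A/C/G/T background sequences of the stated length, one
#' per gene, with each planted kmer inserted once at a random position into
#' the stated fraction (rounded) of the genes whose true base phase falls
#' in its target hourly bin.  The realized carrier sets are recorded in
#' \code{S4Vectors::metadata()} of the returned set, under
#' \code{$carriers}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param length promoter length in bp (default 500, the upstream window
#'   conventionally used for TOD element discovery).
#' @param seed integer seed.
#' @return a named \link[Biostrings]{DNAStringSet}, one promoter per gene.
#' @export
simulatePromoters <- function(truth, length = 500, seed = 1L) {
  stopifnot(is(truth, "GroundTruth"))
  set.seed(as.integer(seed))
  genes <- truth@genes$gene
  n <- base::length(genes)
  chars <- sample(c("A", "C", "G", "T"), n * length, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i)
    paste(chars[((i - 1) * length + 1):(i * length)], collapse = ""), "")
  names(seqs) <- genes
  carriers <- list()
  pk <- truth@plantedKmers
  for (i in seq_len(nrow(pk))) {
    kmer <- pk$kmer[i]
    if (!grepl("^[ACGT]+$", kmer))
      stop("planted kmer alphabet must be A/C/G/T: ", kmer)
    k <- nchar(kmer)
    if (k > length) stop("planted kmer longer than the promoter")
    binGenes <- genes[!is.na(truth@genes$basePhase) &
                      floor(truth@genes$basePhase) %% 24 == pk$bin[i] %% 24]
    nCarry <- round(pk$fraction[i] * base::length(binGenes))
    carry <- if (nCarry > 0) sample(binGenes, nCarry) else character()
    for (g in carry) {
      pos <- sample.int(length - k + 1L, 1L)
      substr(seqs[g], pos, pos + k - 1L) <- kmer
    }
    carriers[[kmer]] <- carry
  }
  ps <- Biostrings::DNAStringSet(seqs)
  S4Vectors::metadata(ps)$carriers <- carriers
  ps
}

#' Simulate a gene-to-GO annotation map with phase-enriched terms
#'
#' Background terms (\code{GO:0000001} ...) are assigned to genes
#' independently with probability \code{baseProb}; each phase-enriched term
#' from the ground truth is carried with a probability raised, on the odds
#' scale, by its odds ratio for genes whose base phase falls in the target
#' bin.  An infinite odds ratio makes the term exclusive to (and complete
#' over) its bin.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param nTerms number of background terms (0 gives a map containing only
#'   the enriched terms; if there are none, an empty map).
#' @param seed integer seed.
#' @param baseProb background carriage probability.
#' @return \code{data.frame} with columns \code{gene}, \code{term}.
#' @export
simulateGOMap <- function(truth, nTerms = 40L, seed = 1L,
                          baseProb = 0.05) {
  stopifnot(is(truth, "GroundTruth"))
  set.seed(as.integer(seed))
  genes <- truth@genes$gene
  n <- length(genes)
  rows <- list()
  if (nTerms > 0) {
    bgTerms <- sprintf("GO:%07d", seq_len(nTerms))
    bgTerms <- setdiff(bgTerms, truth@goTruth$term)
    for (term in bgTerms) {
      carry <- genes[runif(n) < baseProb]
      if (length(carry))
        rows[[term]] <- data.frame(gene = carry, term = term)
    }
  }
  gt <- truth@goTruth
  inOdds <- baseProb / (1 - baseProb)
  for (i in seq_len(nrow(gt))) {
    bin <- gt$bin[i] %% 24
    inBin <- !is.na(truth@genes$basePhase) &
      floor(truth@genes$basePhase) %% 24 == bin
    if (is.infinite(gt$odds[i])) {
      pIn <- 1; pOut <- 0
    } else {
      o <- inOdds * gt$odds[i]
      pIn <- o / (1 + o); pOut <- baseProb
    }
    p <- ifelse(inBin, pIn, pOut)
    carry <- genes[runif(n) < p]
    if (length(carry))
      rows[[gt$term[i]]] <- data.frame(gene = carry, term = gt$term[i])
  }
  if (!length(rows))
    return(data.frame(gene = character(), term = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
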