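#' TimeCourse: one condition's diurnal expression matrix
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one developmental
#' condition's gene-by-timepoint intensity matrix (linear scale) together
#' with its sampling metadata: the Zeitgeber-time (ZT) grid of the samples
#' (default ZT6 to ZT54 every 2 h, i.e. 25 samples over two days), the
#' tissue, and the day of the season the course was collected.
#'
#' @slot condition character(1), condition label (e.g. \code{"leaf_15d"}).
#' @slot tissue character(1).
#' @slot dayOfSeason numeric(1), days after sowing (may be \code{NA}).
#'
#' @param intensity numeric matrix, genes as rows (rownames = gene ids),
#'   one column per sample; linear-scale intensities, non-negative.
#' @param zt numeric vector of ZT labels (hours), strictly increasing, one
#'   per column.
#' @param condition,tissue,dayOfSeason sampling metadata.
#' @param x a \code{TimeCourse}.
#' @return \code{TimeCourse()} returns a validated object; \code{ztGrid}
#'   the ZT label vector; \code{intensities} the linear intensity matrix.
#' @aliases ztGrid conditionName tissueType dayOfSeason intensities
#' @examples
#' m <- matrix(runif(3 * 25, 10, 100), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), NULL))
#' tc <- TimeCourse(m, zt = seq(6, 54, by = 2), condition = "leaf_15d")
#' ztGrid(tc)
#' @export TimeCourse
#' @exportClass TimeCourse
setClass("TimeCourse",
  contains = "SummarizedExperiment",
  representation(condition = "character", tissue = "character",
                 dayOfSeason = "numeric"))

setValidity("TimeCourse", function(object) {
  msg <- character()
  zt <- SummarizedExperiment::colData(object)$zt
  if (is.null(zt)) msg <- c(msg, "colData must contain a 'zt' column")
  else if (any(diff(zt) <= 0)) msg <- c(msg, "zt grid must be strictly increasing")
  a <- SummarizedExperiment::assay(object)
  if (anyNA(a)) msg <- c(msg, "intensity matrix must not contain NA")
  else if (any(a < 0)) msg <- c(msg, "intensities must be non-negative")
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  if (length(object@condition) != 1L)
    msg <- c(msg, "condition must be a single label")
  if (length(msg)) msg else TRUE
})

TimeCourse <- function(intensity, zt, condition, tissue = "leaf",
                       dayOfSeason = NA_real_) {
  intensity <- as.matrix(intensity)
  colnames(intensity) <- paste0("ZT", zt)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    colData = S4Vectors::DataFrame(zt = zt,
                                   row.names = colnames(intensity)))
  new("TimeCourse", se, condition = condition, tissue = tissue,
      dayOfSeason = as.numeric(dayOfSeason))
}

#' @rdname TimeCourse-class
setMethod("ztGrid", "TimeCourse", function(x)
  SummarizedExperiment::colData(x)$zt)

#' @rdname TimeCourse-class
setMethod("conditionName", "TimeCourse", function(x) x@condition)

#' @rdname TimeCourse-class
setMethod("tissueType", "TimeCourse", function(x) x@tissue)

#' @rdname TimeCourse-class
setMethod("dayOfSeason", "TimeCourse", function(x) x@dayOfSeason)

#' @rdname TimeCourse-class
setMethod("intensities", "TimeCourse", function(x)
  SummarizedExperiment::assay(x, "intensity"))

setMethod("show", "TimeCourse", function(object) {
  cat("TimeCourse:", object@condition, sprintf("(%s", object@tissue),
      if (!is.na(object@dayOfSeason))
        sprintf(", day %g)", object@dayOfSeason) else ")", "\n")
  cat(" ", nrow(object), "genes x", ncol(object), "samples, ZT",
      min(ztGrid(object)), "-", max(ztGrid(object)), "\n")
})

#' ModelLibrary: phased waveform templates for rhythmicity detection
#'
#' A library of period-24 h waveform templates evaluated on the sampling
#' grid, one per (shape, phase-offset) combination, each standardized to
#' zero mean and unit (sample) variance.  A gene is called rhythmic when its
#' log2 profile correlates at least \code{rMin} with some template, and its
#' phase is the phase offset of the best template (time of peak expression).
#'
#' @slot templates numeric matrix, one standardized template per row.
#' @slot shape,phase per-template shape id and phase offset (hours).
#' @slot zt the ZT grid the templates were evaluated on.
#' @aliases templates
#' @seealso \code{\link{buildModelLibrary}}
#' @exportClass ModelLibrary
setClass("ModelLibrary",
  representation(templates = "matrix", shape = "character",
                 phase = "numeric", zt = "numeric"))

setValidity("ModelLibrary", function(object) {
  msg <- character()
  if (nrow(object@templates) != length(object@shape) ||
      nrow(object@templates) != length(object@phase))
    msg <- c(msg, "templates, shape and phase lengths disagree")
  if (ncol(object@templates) != length(object@zt))
    msg <- c(msg, "template width must match zt grid")
  m <- rowMeans(object@templates)
  v <- apply(object@templates, 1L, stats::var)
  if (any(abs(m) > 1e-9) || any(abs(v - 1) > 1e-9))
    msg <- c(msg, "templates must be standardized (mean 0, variance 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname ModelLibrary-class
setMethod("templates", "ModelLibrary", function(x) x@templates)

setMethod("show", "ModelLibrary", function(object) {
  cat("ModelLibrary:", nrow(object@templates), "templates (",
      length(unique(object@shape)), "shapes x",
      length(unique(object@phase)), "phases ) on",
      length(object@zt), "timepoints\n")
})

#' CyclingCallSet: per-gene expressed/rhythmic calls for one condition
#'
#' Per-gene rhythmicity calls for one condition: whether the gene is
#' expressed, whether it is rhythmic (best template correlation
#' \eqn{R \ge R_{min}}), the best-fitting shape, the phase (time of peak
#' expression, hours in ZT-label space, defined only for rhythmic genes),
#' the best correlation \eqn{R} and the fitted log2 amplitude.
#'
#' @slot condition character(1).
#' @slot calls a \link[S4Vectors]{DataFrame} with columns \code{gene},
#'   \code{expressed}, \code{rhythmic}, \code{shape}, \code{phase},
#'   \code{R}, \code{amplitude}.
#' @slot rMin the correlation threshold used.
#' @aliases calls rhythmicGenes expressedGenes phases
#' @seealso \code{\link{detectCycling}}, \code{\link{cyclingSummary}}
#' @exportClass CyclingCallSet
setClass("CyclingCallSet",
  representation(condition = "character", calls = "DFrame",
                 rMin = "numeric"))

setValidity("CyclingCallSet", function(object) {
  cl <- object@calls
  need <- c("gene", "expressed", "rhythmic", "shape", "phase", "R",
            "amplitude")
  if (!all(need %in% colnames(cl)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  msg <- character()
  if (any(cl$rhythmic & !cl$expressed))
    msg <- c(msg, "rhythmic implies expressed")
  if (any(cl$rhythmic & is.na(cl$phase)) ||
      any(!cl$rhythmic & !is.na(cl$phase)))
    msg <- c(msg, "phase must be defined exactly for rhythmic genes")
  ok <- !is.na(cl$R)
  if (any(cl$rhythmic[ok] != (cl$expressed[ok] & cl$R[ok] >= object@rMin)))
    msg <- c(msg, "rhythmic flag inconsistent with R >= rMin")
  if (length(msg)) msg else TRUE
})

#' @rdname CyclingCallSet-class
setMethod("calls", "CyclingCallSet", function(x) x@calls)

#' @rdname CyclingCallSet-class
setMethod("conditionName", "CyclingCallSet", function(x) x@condition)

#' @rdname CyclingCallSet-class
setMethod("rhythmicGenes", "CyclingCallSet", function(x)
  x@calls$gene[x@calls$rhythmic])

#' @rdname CyclingCallSet-class
setMethod("expressedGenes", "CyclingCallSet", function(x)
  x@calls$gene[x@calls$expressed])

#' @rdname CyclingCallSet-class
setMethod("phases", "CyclingCallSet", function(x) {
  r <- x@calls$rhythmic
  stats::setNames(x@calls$phase[r], x@calls$gene[r])
})

setMethod("show", "CyclingCallSet", function(object) {
  s <- cyclingSummary(object)
  cat("CyclingCallSet:", object@condition, "\n")
  cat(sprintf("  total %d | not expressed %d (%d%%) | not rhythmic %d (%d%%) | rhythmic %d (%d%% of expressed)\n",
      s$total, s$notExpressed, s$pctNotExpressed, s$notRhythmic,
      s$pctNotRhythmic, s$rhythmic, s$pctRhythmic))
})

#' PhaseShiftTable: circular phase differences between two conditions
#'
#' Per-gene circular phase shifts between a reference and a target
#' condition, restricted to the genes rhythmic in both.  \code{forward} is
#' the mod-24 shift in \eqn{[0,24)} (the primary convention: the 6--19 h
#' shift class is a forward window); \code{signed} the equivalent value in
#' \eqn{[-12,12)}.
#'
#' @slot reference,target condition names.
#' @slot shifts \link[S4Vectors]{DataFrame} with columns \code{gene},
#'   \code{phaseRef}, \code{phaseTarget}, \code{forward}, \code{signed}.
#' @aliases shifts
#' @seealso \code{\link{baselineAnalysis}}, \code{\link{incrementalAnalysis}}
#' @exportClass PhaseShiftTable
setClass("PhaseShiftTable",
  representation(reference = "character", target = "character",
                 shifts = "DFrame"))

setValidity("PhaseShiftTable", function(object) {
  s <- object@shifts
  msg <- character()
  if (any(s$forward < 0 | s$forward >= 24))
    msg <- c(msg, "forward shifts must lie in [0, 24)")
  if (any(s$signed < -12 | s$signed >= 12))
    msg <- c(msg, "signed shifts must lie in [-12, 12)")
  if (any(abs((s$forward - s$signed) %% 24) > 1e-9))
    msg <- c(msg, "forward and signed shifts must be congruent mod 24")
  if (length(msg)) msg else TRUE
})

#' @rdname PhaseShiftTable-class
setMethod("shifts", "PhaseShiftTable", function(x) x@shifts)

setMethod("show", "PhaseShiftTable", function(object) {
  cat("PhaseShiftTable:", object@reference, "->", object@target, ":",
      nrow(object@shifts), "genes rhythmic in both\n")
})

#' KmerDictionary: background promoter-presence counts for all 3-8 bp kmers
#'
#' Presence counts (number of promoters containing the word at least once,
#' forward strand) for every DNA kmer of length 3 to 8 over a promoter
#' universe.  The dictionary has \eqn{\sum_{k=3}^{8} 4^k = 87360} entries.
#'
#' @slot counts named integer vector of per-kmer presence counts.
#' @slot kRange integer(2), kmer length range.
#' @slot universeSize number of promoters counted.
#' @slot genes promoter (gene) ids of the universe.
#' @seealso \code{\link{buildKmerDictionary}}, \code{\link{enrichKmers}}
#' @exportClass KmerDictionary
setClass("KmerDictionary",
  representation(counts = "integer", kRange = "integer",
                 universeSize = "integer", genes = "character"))

setValidity("KmerDictionary", function(object) {
  kk <- seq(object@kRange[1], object@kRange[2])
  if (length(object@counts) != sum(4^kk))
    return("dictionary must cover all 4^k kmers for each k")
  if (any(object@counts > object@universeSize))
    return("presence counts cannot exceed the universe size")
  TRUE
})

setMethod("show", "KmerDictionary", function(object) {
  cat("KmerDictionary:", length(object@counts), "kmers (k =",
      object@kRange[1], "-", object@kRange[2], ") over",
      object@universeSize, "promoters\n")
})

#' @rdname enrichment-accessors
#' @name enrichment-accessors
#' @aliases enrichmentTable
#' @title Accessors for enrichment result containers
#' @param x a \linkS4class{KmerEnrichment} or \linkS4class{GOEnrichment}.
#' @return \code{enrichmentTable} returns the underlying result
#'   \link[S4Vectors]{DataFrame}.
NULL

#' KmerEnrichment: ELEMENT-style per-list kmer overrepresentation results
#'
#' Hypergeometric overrepresentation of promoter kmers in phase-binned gene
#' lists, one BH family per list, with rows kept for every kmer significant
#' (\eqn{q < \alpha}) in at least one list plus any explicitly tracked
#' kmers (e.g. the Evening Element) so their full TOD profile is available.
#'
#' @slot results \link[S4Vectors]{DataFrame}: \code{condition}, \code{bin},
#'   \code{kmer}, \code{foreground}, \code{listSize}, \code{background},
#'   \code{universeSize}, \code{p}, \code{q}, \code{significant}.
#' @slot alpha FDR threshold.
#' @slot bins phase-bin labels tested.
#' @slot conditions condition names in developmental order.
#' @slot universeSize promoter universe size.
#' @slot nLists number of scheduled (condition x bin) lists.
#' @slot listSizes named integer vector of list sizes
#'   (\code{"condition|bin"}).
#' @slot tracked kmers whose rows are always retained.
#' @seealso \code{\link{runElement}}, \code{\link{todProfile}}
#' @exportClass KmerEnrichment
setClass("KmerEnrichment",
  representation(results = "DFrame", alpha = "numeric", bins = "character",
                 conditions = "character", universeSize = "integer",
                 nLists = "integer", listSizes = "integer",
                 tracked = "character"))

#' @rdname enrichment-accessors
setMethod("enrichmentTable", "KmerEnrichment", function(x) x@results)

setMethod("show", "KmerEnrichment", function(object) {
  cat("KmerEnrichment:", object@nLists, "phase lists over",
      length(object@conditions), "conditions;",
      sum(object@results$significant), "significant (kmer, list) pairs at q <",
      object@alpha, "\n")
})

#' MotifClusterSet: significant kmers grouped into motifs
#'
#' Significant kmers clustered by ungapped sequence similarity
#' (single linkage), each cluster aligned to a common frame with a
#' position-frequency matrix and consensus, the ELEMENT-style motif
#' summarization from which sequence logos are drawn.
#'
#' @slot clusters list; each element has \code{members}, \code{offsets}
#'   (0-based within the frame), \code{pfm} (4 x width count matrix) and
#'   \code{consensus}.
#' @aliases clusters
#' @seealso \code{\link{clusterKmers}}, \code{\link{summarizeClusters}}
#' @exportClass MotifClusterSet
setClass("MotifClusterSet", representation(clusters = "list"))

#' @rdname MotifClusterSet-class
setMethod("clusters", "MotifClusterSet", function(x) x@clusters)

setMethod("show", "MotifClusterSet", function(object) {
  cat("MotifClusterSet:", length(object@clusters), "motif clusters;",
      sum(vapply(object@clusters, function(cl) length(cl$members), 1L)),
      "kmers\n")
})

#' GOEnrichment: phase-binned GO term overrepresentation
#'
#' Hypergeometric GO term overrepresentation of phase-binned rhythmic gene
#' lists against a per-condition universe (expressed genes by default),
#' BH-adjusted within each list.
#'
#' @slot results \link[S4Vectors]{DataFrame}: \code{condition}, \code{bin},
#'   \code{term}, \code{studyCount}, \code{studySize}, \code{popCount},
#'   \code{popSize}, \code{p}, \code{q}, \code{significant}.
#' @slot alpha FDR threshold.
#' @slot bins,conditions tested labels.
#' @slot universePolicy \code{"expressed"} or \code{"all"}.
#' @slot tracked GO terms whose rows are always retained.
#' @seealso \code{\link{runGoTOD}}, \code{\link{goSummary}}
#' @exportClass GOEnrichment
setClass("GOEnrichment",
  representation(results = "DFrame", alpha = "numeric", bins = "character",
                 conditions = "character", universePolicy = "character",
                 tracked = "character"))

#' @rdname enrichment-accessors
setMethod("enrichmentTable", "GOEnrichment", function(x) x@results)

setMethod("show", "GOEnrichment", function(object) {
  sig <- object@results[object@results$significant, , drop = FALSE]
  cat("GOEnrichment:", length(unique(sig$term)), "terms significant at q <",
      object@alpha, "across", length(object@conditions), "conditions\n")
})

#' SimConfig: parameters of the synthetic diurnal time-course generator
#'
#' Holds every knob of the generator; see \code{\link{simConfig}} for the
#' defaults, which define the study conditions the package's recovery tests
#' run under.
#'
#' @seealso \code{\link{simConfig}}, \code{\link{simulateTimecourses}}
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nGenes = "integer", ztGrid = "numeric",
                 cyclingFraction = "numeric",
                 notExpressedFraction = "numeric",
                 phaseDistribution = "numeric", waveformMix = "numeric",
                 noiseSd = "numeric", baselineLogMean = "numeric",
                 baselineLogSd = "numeric", backgroundLogMean = "numeric",
                 amplitudeRange = "numeric", phaseJitterSd = "numeric",
                 conditions = "list", plantedKmers = "list",
                 goTerms = "list", nGoBackgroundTerms = "integer",
                 goBaseProb = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (length(object@phaseDistribution) != 24)
    msg <- c(msg, "phaseDistribution must have 24 hourly weights")
  if (abs(sum(object@phaseDistribution) - 1) > 1e-9 ||
      any(object@phaseDistribution < 0))
    msg <- c(msg, "phaseDistribution must be a probability vector")
  if (abs(sum(object@waveformMix) - 1) > 1e-9 || any(object@waveformMix < 0))
    msg <- c(msg, "waveformMix must be a probability vector")
  if (!all(names(object@waveformMix) %in% .allSimShapes()))
    msg <- c(msg, "unknown waveform shape in waveformMix")
  zt <- object@ztGrid
  if (any(diff(zt) <= 0)) msg <- c(msg, "ztGrid must be strictly increasing")
  if (length(unique(round(diff(zt), 9))) != 1L)
    msg <- c(msg, "ztGrid must be uniformly spaced")
  fr <- c(object@cyclingFraction, object@notExpressedFraction)
  if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
  for (pk in object@plantedKmers) {
    if (!grepl("^[ACGT]+$", pk$kmer))
      msg <- c(msg, "planted kmers must use the A/C/G/T alphabet")
    if (nchar(pk$kmer) < 3 || nchar(pk$kmer) > 8)
      msg <- c(msg, "planted kmer lengths must be in 3-8")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes x", length(object@ztGrid),
      "timepoints x", length(object@conditions), "conditions\n")
  cat("  cycling", object@cyclingFraction, "| not expressed",
      object@notExpressedFraction, "| noise sd", object@noiseSd,
      "| seed", object@seed, "\n")
})

#' GroundTruth: the simulator's planted truth
#'
#' What the generator planted, for parameter-recovery testing: per-gene
#' expressed/cycling flags, waveform, amplitude and baseline; the true
#' phase of every cycling gene in every condition (base phase plus the
#' condition's drift, mod 24); the planted promoter kmers and the
#' phase-enriched GO terms.
#'
#' @slot genes \link[S4Vectors]{DataFrame}: \code{gene}, \code{expressed},
#'   \code{cycling}, \code{waveform}, \code{amplitude}, \code{baseline},
#'   \code{basePhase}.
#' @slot phases gene x condition matrix of true phases (NA when not
#'   cycling).
#' @slot plantedKmers \link[S4Vectors]{DataFrame}: \code{kmer}, \code{bin},
#'   \code{fraction}.
#' @slot goTruth \link[S4Vectors]{DataFrame}: \code{term}, \code{bin},
#'   \code{odds}.
#' @slot conditions condition names.
#' @aliases truthTable truePhases
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(genes = "DFrame", phases = "matrix",
                 plantedKmers = "DFrame", goTruth = "DFrame",
                 conditions = "character"))

setValidity("GroundTruth", function(object) {
  ph <- object@phases[object@genes$cycling, , drop = FALSE]
  if (length(ph) && (anyNA(ph) || any(ph < 0 | ph >= 24)))
    return("every cycling gene needs a true phase in [0, 24) per condition")
  TRUE
})

#' @rdname GroundTruth-class
setMethod("truthTable", "GroundTruth", function(x) x@genes)

#' @rdname GroundTruth-class
setMethod("truePhases", "GroundTruth", function(x) x@phases)

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@genes), "genes;",
      sum(object@genes$cycling), "cycling,",
      sum(!object@genes$expressed), "not expressed;",
      nrow(object@plantedKmers), "planted kmers;",
      nrow(object@goTruth), "enriched GO terms\n")
})
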