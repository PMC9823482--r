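#' @rdname TimeCourse-class
#' @export
setGeneric("ztGrid", function(x) standardGeneric("ztGrid"))

#' @rdname TimeCourse-class
#' @export
setGeneric("conditionName", function(x) standardGeneric("conditionName"))

#' @rdname TimeCourse-class
#' @export
setGeneric("tissueType", function(x) standardGeneric("tissueType"))

#' @rdname TimeCourse-class
#' @export
setGeneric("dayOfSeason", function(x) standardGeneric("dayOfSeason"))

#' @rdname TimeCourse-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname CyclingCallSet-class
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname CyclingCallSet-class
#' @export
setGeneric("rhythmicGenes", function(x) standardGeneric("rhythmicGenes"))

#' @rdname CyclingCallSet-class
#' @export
setGeneric("expressedGenes", function(x) standardGeneric("expressedGenes"))

#' @rdname CyclingCallSet-class
#' @export
setGeneric("phases", function(x) standardGeneric("phases"))

#' Summarize cycling calls with the mixed-denominator percentage convention
#'
#' @param x a \linkS4class{CyclingCallSet} (or see \code{\link{todSummary}}
#'   for the count-level worked form).
#' @return one-row \code{data.frame}; see \code{\link{todSummary}}.
#' @export
setGeneric("cyclingSummary", function(x) standardGeneric("cyclingSummary"))

#' @rdname PhaseShiftTable-class
#' @export
setGeneric("shifts", function(x) standardGeneric("shifts"))

#' @rdname enrichment-accessors
#' @export
setGeneric("enrichmentTable", function(x) standardGeneric("enrichmentTable"))

#' @rdname MotifClusterSet-class
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname ModelLibrary-class
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))

#' @rdname GroundTruth-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname GroundTruth-class
#' @export
setGeneric("truePhases", function(x) standardGeneric("truePhases"))

#' Time-of-day significance profile of a kmer, motif cluster or GO term
#'
#' Returns a condition-by-phase-bin matrix of \eqn{-\log_{10}(q)} values
#' (capped), the standard way ELEMENT-class and GO-by-phase results are
#' displayed: a dusk-specific element shows a ridge at the dusk bins across
#' every developmental stage.
#'
#' @param x a \linkS4class{KmerEnrichment} or \linkS4class{GOEnrichment}.
#' @param features character vector of kmers (possibly a motif cluster's
#'   members, whose per-cell best \eqn{q} is then used) or GO term ids.
#' @param cap maximum \eqn{-\log_{10}(q)} reported (default 10).
#' @return numeric matrix, conditions as rows, phase bins as columns.
#' @export
setGeneric("todProfile", function(x, features, cap = 10)
  standardGeneric("todProfile"))
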