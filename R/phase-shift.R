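#' Per-gene circular phase shifts between two conditions
#'
#' Builds a \linkS4class{PhaseShiftTable} over exactly the genes rhythmic
#' in both conditions (phase is undefined otherwise, so arrhythmic genes
#' are excluded rather than imputed).
#'
#' @param ref,target \linkS4class{CyclingCallSet}s.
#' @return a \linkS4class{PhaseShiftTable}.
#' @export
phaseShiftTable <- function(ref, target) {
  stopifnot(is(ref, "CyclingCallSet"), is(target, "CyclingCallSet"))
  pr <- phases(ref); pt <- phases(target)
  common <- intersect(names(pr), names(pt))
  sh <- circularShift(pr[common], pt[common])
  new("PhaseShiftTable", reference = conditionName(ref),
      target = conditionName(target),
      shifts = S4Vectors::DataFrame(
        gene = common, phaseRef = unname(pr[common]),
        phaseTarget = unname(pt[common]),
        forward = sh$forward, signed = sh$signed))
}

#' Baseline (anchor) phase-shift analysis
#'
#' Compares every non-anchor condition against a fixed anchor (the first
#' developmental stage, in the original design), yielding one
#' \linkS4class{PhaseShiftTable} per comparison.  The fraction of genes
#' holding their phase (forward shift 0, same 1 h bin, by default) is the
#' headline statistic of this analysis; genes shifting progressively later
#' over the season indicate the entrainment cue drifting relative to the
#' fixed clock-time sampling.
#'
#' @param callsets list of \linkS4class{CyclingCallSet}s in developmental
#'   order.
#' @param anchor condition name of the anchor; default the first.
#' @return named list of \linkS4class{PhaseShiftTable}s (one per
#'   non-anchor condition, in input order).
#' @seealso \code{\link{samePhaseFraction}}, \code{\link{shiftHistogram}}
#' @export
baselineAnalysis <- function(callsets, anchor = NULL) {
  stopifnot(length(callsets) >= 2L)
  nms <- unname(vapply(callsets, conditionName, ""))
  if (is.null(anchor)) anchor <- nms[1L]
  ai <- match(anchor, nms)
  if (is.na(ai)) stop("anchor condition not present: ", anchor)
  others <- setdiff(seq_along(callsets), ai)
  out <- lapply(others, function(i)
    phaseShiftTable(callsets[[ai]], callsets[[i]]))
  names(out) <- nms[others]
  out
}

#' Incremental (proximal-pairwise) phase-shift analysis
#'
#' Phase shifts between each pair of consecutive conditions in
#' developmental order: constant entrainment drift shows up as a constant
#' modal shift across pairs, while a localized developmental transition
#' produces a single pair with an outsized shift.
#'
#' @param callsets list of \linkS4class{CyclingCallSet}s in developmental
#'   order.
#' @return named list of \linkS4class{PhaseShiftTable}s, one per proximal
#'   pair (\code{"a->b"}); empty list for a single condition.
#' @export
incrementalAnalysis <- function(callsets) {
  if (length(callsets) < 2L) return(list())
  nms <- unname(vapply(callsets, conditionName, ""))
  out <- lapply(seq_len(length(callsets) - 1L), function(i)
    phaseShiftTable(callsets[[i]], callsets[[i + 1L]]))
  names(out) <- paste0(nms[-length(nms)], "->", nms[-1L])
  out
}

#' Histogram of forward phase shifts
#'
#' @param pst a \linkS4class{PhaseShiftTable}.
#' @param bins number of 1 h bins (default 24).
#' @return named integer vector of counts over forward-shift bins; counts
#'   sum to the rhythmic-in-both intersection size.
#' @export
shiftHistogram <- function(pst, bins = 24L) {
  stopifnot(is(pst, "PhaseShiftTable"))
  f <- floor(shifts(pst)$forward * bins / 24) %% bins
  tab <- table(factor(f, levels = 0:(bins - 1L)))
  stats::setNames(as.integer(tab), names(tab))
}

#' Fraction of genes keeping the same phase
#'
#' @param pst a \linkS4class{PhaseShiftTable}.
#' @param tolerance circular tolerance in hours; 0 (default) requires the
#'   exact same 1 h bin.
#' @return numeric fraction in [0, 1] (NaN for an empty table).
#' @export
samePhaseFraction <- function(pst, tolerance = 0) {
  stopifnot(is(pst, "PhaseShiftTable"))
  f <- shifts(pst)$forward
  mean(pmin(f, 24 - f) <= tolerance)
}

#' Select genes in a forward phase-shift window
#'
#' Genes whose forward shift lies in \code{[lo, hi]} (inclusive).  The
#' window of interest for late-season shifts is 6--19 h -- a range only
#' expressible on the forward, mod-24 scale -- and the selected list is
#' what feeds GO enrichment of the shifting class.
#'
#' @param pst a \linkS4class{PhaseShiftTable}.
#' @param lo,hi window bounds in forward-shift hours, \code{lo < hi}.
#' @return character vector of genes (possibly empty); idempotent and
#'   order-independent.
#' @export
selectShiftWindow <- function(pst, lo, hi) {
  stopifnot(is(pst, "PhaseShiftTable"), lo < hi)
  s <- shifts(pst)
  sort(s$gene[s$forward >= lo & s$forward <= hi])
}
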