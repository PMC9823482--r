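#' @importFrom methods new validObject is show slot
#' @importFrom stats quantile rnorm runif phyper p.adjust cmdscale
#'   chisq.test approx dist setNames
#' @importFrom utils read.delim write.table count.fields combn
#' @import S4Vectors
#' @import SummarizedExperiment
NULL

## Shapes available to the rhythm-template library.  Peak ("phase") is the
## time of maximum; all are period-24 in hours.
.todShapes <- c("cosine", "sharp_cosine", "box", "spike", "ramp_up",
                "ramp_down")

## Extra shapes the simulator may use that are deliberately absent from the
## default template library (robustness of detection to off-library waves).
.offLibraryShapes <- c("trapezoid")

.allSimShapes <- function() c(.todShapes, .offLibraryShapes)

## Raw (unstandardized) waveform value in [0, 1] at hours t for a peak at
## `phase` hours; period 24 h.
waveformValue <- function(shape, t, phase) {
  d <- (t - phase) %% 24
  switch(shape,
    cosine = 0.5 + 0.5 * cos(2 * pi * d / 24),
    sharp_cosine = (0.5 + 0.5 * cos(2 * pi * d / 24))^2,
    box = as.numeric(pmin(d, 24 - d) < 6),
    spike = as.numeric(pmin(d, 24 - d) <= 1),
    ramp_up = 1 - ((phase - t) %% 24) / 24,
    ramp_down = 1 - d / 24,
    trapezoid = {
      dd <- pmin(d, 24 - d)
      pmin(1, pmax(0, (8 - dd) / 6))
    },
    stop("unknown waveform shape: ", shape)
  )
}

#' Circular phase difference between two time-of-day phases
#'
#' Computes the forward (mod-24, in \eqn{[0,24)}) and signed (in
#' \eqn{[-12,12)}) circular difference \code{pTarget - pRef}.  The forward
#' convention is the primary one for reporting developmental phase shifts: a
#' shift window such as 6--19 h only makes sense on the forward scale.
#'
#' @param pRef,pTarget numeric vectors of phases in hours, each in
#'   \eqn{[0,24)}.  Recycled to a common length.
#' @return A \code{data.frame} with columns \code{forward} and \code{signed}.
#' @examples
#' circularShift(8, 8)    # 0, 0
#' circularShift(22, 4)   # 6, 6
#' circularShift(4, 22)   # 18, -6
#' @export
circularShift <- function(pRef, pTarget) {
  if (any(pRef < 0 | pRef >= 24, na.rm = TRUE) ||
      any(pTarget < 0 | pTarget >= 24, na.rm = TRUE))
    stop("phases must lie in [0, 24)")
  forward <- (pTarget - pRef) %% 24
  signed <- ifelse(forward >= 12, forward - 24, forward)
  data.frame(forward = forward, signed = signed)
}

## Circular distance in [0, 12].
circularDistance <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

## Percent helpers for Table-1-style summaries: integer rounding of a ratio.
.pct <- function(num, den) as.integer(round(100 * num / den))

## Validate that a vector of mixture weights is a probability vector.
.checkWeights <- function(w, what) {
  if (any(w < 0)) stop(what, " weights must be non-negative")
  if (abs(sum(w) - 1) > 1e-9)
    stop(what, " weights must sum to 1 (got ", format(sum(w)), ")")
  invisible(TRUE)
}

## md5 of a set of files, named by relative path (for run manifests).
.fileChecksums <- function(files, root) {
  sums <- tools::md5sum(files)
  names(sums) <- sub(paste0("^", root, "/?"), "", files)
  sums
}
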