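#' Quantile-normalize the samples of a time course
#'
#' Forces every sample (timepoint) of the course onto the same empirical
#' distribution: after normalization each sample's sorted value vector
#' equals the per-rank mean of the input samples' sorted vectors, while the
#' rank order within each sample is preserved.  Ties receive the mean of
#' the reference values at their tied ranks.  Applied per condition; the
#' downstream cross-condition comparisons are made on phases, not
#' intensities.
#'
#' The computation is delegated to \code{limma::normalizeQuantiles} (ties
#' averaged), the standard implementation of this normalization.
#'
#' @param tc a \linkS4class{TimeCourse} with at least 2 samples and no
#'   negative intensities.
#' @return a \linkS4class{TimeCourse} with the normalized intensity
#'   matrix; metadata and row flags preserved.
#' @examples
#' m <- rbind(a = c(1, 4), b = c(2, 5), c = c(3, 6))
#' tc <- TimeCourse(m, zt = c(0, 2), condition = "toy")
#' intensities(quantileNormalize(tc))  # both columns become 2.5, 3.5, 4.5
#' @export
quantileNormalize <- function(tc) {
  stopifnot(is(tc, "TimeCourse"))
  m <- intensities(tc)
  if (ncol(m) < 2L) stop("quantile normalization needs >= 2 samples")
  if (any(m < 0)) stop("negative intensities")
  constCol <- apply(m, 2L, function(x) diff(range(x)) == 0)
  if (any(constCol))
    message("all-constant sample(s): ",
            paste(colnames(m)[constCol], collapse = ", "),
            " (ties averaged)")
  nm <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(nm) <- dimnames(m)
  SummarizedExperiment::assay(tc, "intensity") <- nm
  tc
}
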