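#' Sample-by-sample correlation matrix across conditions
#'
#' Product-moment correlation between every pair of samples over all
#' conditions, computed on \code{log2(intensity + 1)} of the common gene
#' set (all common genes by default; the correlation structure over a
#' developmental series is the first-line QC -- leaf samples should
#' correlate highly with neighbouring stages and poorly with root).
#'
#' @param tcs list of \linkS4class{TimeCourse}s.
#' @return symmetric correlation matrix with unit diagonal; sample names
#'   \code{"<condition>.ZT<h>"}.
#' @export
correlationMatrix <- function(tcs) {
  if (is(tcs, "TimeCourse")) tcs <- list(tcs)
  common <- Reduce(intersect, lapply(tcs, rownames))
  if (length(common) < 3L) stop("fewer than 3 genes common to all courses")
  blocks <- lapply(tcs, function(tc) {
    m <- log2(intensities(tc)[common, , drop = FALSE] + 1)
    colnames(m) <- paste0(conditionName(tc), ".", colnames(m))
    m
  })
  stats::cor(do.call(cbind, blocks))
}

#' Classical MDS embedding of samples
#'
#' Torgerson (classical) multidimensional scaling on the distance
#' \eqn{1 - r} (the sign of the correlation is informative between
#' tissues, hence not \eqn{1 - r^2}).  Deterministic up to rotation and
#' reflection.  A metric stress value
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}} is reported so the quality
#' of the 2-D view can be judged.
#'
#' @param corrMatrix a correlation matrix, e.g. from
#'   \code{\link{correlationMatrix}}.
#' @param dims embedding dimension (default 2).
#' @return list with \code{points} (samples x dims coordinate matrix),
#'   \code{eig} (eigenvalues) and \code{stress}.
#' @export
mdsEmbed <- function(corrMatrix, dims = 2L) {
  d <- 1 - corrMatrix
  fit <- cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < dims)   # degenerate inputs can yield fewer axes
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  dhat <- as.matrix(dist(pts))
  stress <- sqrt(sum((d - dhat)^2) / sum(d^2))
  list(points = pts, eig = fit$eig, stress = stress)
}

#' Overlaps of cycling gene sets across conditions
#'
#' Exact set-intersection counts of the rhythmic gene sets: the pairwise
#' overlap matrix, the exclusive Venn cells over all (or a chosen subset
#' of) conditions, and the genes cycling under every condition.
#'
#' @param callsets list of \linkS4class{CyclingCallSet}s.
#' @param subset optional character vector of condition names to restrict
#'   to.
#' @return list with \code{pairwise} (condition x condition overlap-count
#'   matrix; diagonal = set sizes), \code{venn} (named exclusive cell
#'   counts, names are membership patterns like \code{"110"} in condition
#'   order; cells sum to the union size) and \code{sharedAll} (character
#'   vector of genes rhythmic everywhere).
#' @export
cyclingOverlaps <- function(callsets, subset = NULL) {
  nms <- unname(vapply(callsets, conditionName, ""))
  names(callsets) <- nms
  if (!is.null(subset)) {
    missing <- setdiff(subset, nms)
    if (length(missing)) stop("unknown condition(s): ",
                              paste(missing, collapse = ", "))
    callsets <- callsets[subset]
    nms <- subset
  }
  sets <- lapply(callsets, rhythmicGenes)
  k <- length(sets)
  pairwise <- matrix(0L, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) for (j in seq_len(k))
    pairwise[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  allGenes <- unique(unlist(sets))
  member <- vapply(sets, function(s) allGenes %in% s,
                   logical(length(allGenes)))
  if (length(allGenes) == 1L) member <- matrix(member, nrow = 1L)
  pat <- apply(member, 1L, function(b) paste(as.integer(b), collapse = ""))
  venn <- table(pat)
  venn <- stats::setNames(as.integer(venn), names(venn))
  list(pairwise = pairwise, venn = venn,
       sharedAll = sort(Reduce(intersect, sets)))
}
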