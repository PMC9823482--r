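#' GO term overrepresentation in one gene list
#'
#' Upper-tail hypergeometric test per term annotated in the universe, BH
#' adjusted across the tested terms (one family per list).  The annotation
#' map is used as-is -- no propagation of terms to ontology ancestors --
#' matching the direct use of an extracted gene-to-GO table.
#'
#' @param genes character vector, the study list (subset of the universe).
#' @param universe character vector, the population of genes the list was
#'   drawn from.
#' @param goMap \code{data.frame} with columns \code{gene}, \code{term}.
#' @param alpha FDR threshold for the \code{significant} flag.
#' @return \link[S4Vectors]{DataFrame}: \code{term}, \code{studyCount},
#'   \code{studySize}, \code{popCount}, \code{popSize}, \code{p},
#'   \code{q}, \code{significant}; zero rows when no term is annotated in
#'   the universe.
#' @examples
#' map <- data.frame(gene = paste0("g", 1:4), term = "GO:0000001")
#' enrichGO(paste0("g", c(1:4, 9)), paste0("g", 1:10), map)  # p = 6/252
#' @export
enrichGO <- function(genes, universe, goMap, alpha = 0.05) {
  if (!all(genes %in% universe))
    stop("study list contains genes outside the universe")
  empty <- S4Vectors::DataFrame(
    term = character(), studyCount = integer(), studySize = integer(),
    popCount = integer(), popSize = integer(), p = numeric(),
    q = numeric(), significant = logical())
  map <- goMap[goMap$gene %in% universe, , drop = FALSE]
  if (nrow(map) == 0L || length(genes) == 0L) return(empty)
  popCount <- table(map$term)
  inList <- map[map$gene %in% genes, , drop = FALSE]
  studyCount <- table(factor(inList$term, levels = names(popCount)))
  N <- length(universe); n <- length(genes)
  K <- as.integer(popCount); k <- as.integer(studyCount)
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  S4Vectors::DataFrame(
    term = names(popCount), studyCount = k, studySize = n,
    popCount = K, popSize = N, p = unname(p), q = unname(q),
    significant = unname(q < alpha))
}

#' Phase-binned GO enrichment across all conditions
#'
#' Runs \code{\link{enrichGO}} on every phase-binned rhythmic gene list of
#' every condition.  The universe defaults to the expressed genes of the
#' condition -- enrichment of a phase list is judged against the genes
#' that could have been phased -- with \code{universe = "all"} available
#' to use every gene.  Significant rows are retained, plus any
#' \code{track}ed terms in every list.
#'
#' @param callsets list of \linkS4class{CyclingCallSet}s in developmental
#'   order.
#' @param goMap \code{data.frame} with columns \code{gene}, \code{term}.
#' @param alpha per-list FDR threshold (default 0.05, applied to the BH
#'   q-value).
#' @param bins 24 (default) or 23 phase bins.
#' @param universe \code{"expressed"} (default) or \code{"all"}.
#' @param track GO term ids always retained.
#' @return a \linkS4class{GOEnrichment}.
#' @export
runGoTOD <- function(callsets, goMap, alpha = 0.05, bins = 24L,
                     universe = c("expressed", "all"),
                     track = character()) {
  universe <- match.arg(universe)
  if (is(callsets, "CyclingCallSet")) callsets <- list(callsets)
  condNames <- unname(vapply(callsets, conditionName, ""))
  res <- list(); binLabels <- NULL
  for (ci in seq_along(callsets)) {
    ccs <- callsets[[ci]]
    uni <- if (universe == "expressed") expressedGenes(ccs) else
      calls(ccs)$gene
    lists <- phaseGeneLists(ccs, bins = bins)
    if (is.null(binLabels)) binLabels <- names(lists)
    for (b in names(lists)) {
      gl <- intersect(lists[[b]], uni)
      if (length(gl) == 0L) next
      r <- enrichGO(gl, uni, goMap, alpha = alpha)
      keep <- r$significant | r$term %in% track
      if (any(keep))
        res[[length(res) + 1L]] <- cbind(
          S4Vectors::DataFrame(condition = condNames[ci], bin = b),
          r[keep, , drop = FALSE])
    }
  }
  results <- if (length(res)) do.call(rbind, res) else
    cbind(S4Vectors::DataFrame(condition = character(), bin = character()),
          enrichGO(character(), character(),
                   data.frame(gene = character(), term = character())))
  new("GOEnrichment", results = results, alpha = alpha, bins = binLabels,
      conditions = condNames, universePolicy = universe,
      tracked = as.character(track))
}

#' Summarize GO-by-phase significance
#'
#' Per condition, the number of distinct terms significant at one or more
#' time-of-day bins; per (term, condition), the number of bins at which
#' the term is significant ("occurrences per day", the ranking statistic
#' for broadly regulated processes).
#'
#' @param goe a \linkS4class{GOEnrichment}.
#' @return list with \code{perCondition} (\code{data.frame}:
#'   \code{condition}, \code{nSigTerms}), \code{occurrences} (term x
#'   condition integer matrix of significant-bin counts) and
#'   \code{sigTerms} (named list of per-condition significant term sets).
#' @export
goSummary <- function(goe) {
  stopifnot(is(goe, "GOEnrichment"))
  sig <- goe@results[goe@results$significant, , drop = FALSE]
  sets <- lapply(goe@conditions, function(cn)
    sort(unique(sig$term[sig$condition == cn])))
  names(sets) <- goe@conditions
  perCondition <- data.frame(condition = goe@conditions,
                             nSigTerms = lengths(sets))
  terms <- sort(unique(sig$term))
  occ <- matrix(0L, length(terms), length(goe@conditions),
                dimnames = list(terms, goe@conditions))
  if (nrow(sig))
    for (r in seq_len(nrow(sig)))
      occ[sig$term[r], sig$condition[r]] <-
        occ[sig$term[r], sig$condition[r]] + 1L
  list(perCondition = perCondition, occurrences = occ, sigTerms = sets)
}

#' @rdname todProfile
setMethod("todProfile", "GOEnrichment",
  function(x, features, cap = 10) {
    .profileFromResults(x@results, "term", features, x@conditions,
                        x@bins, cap)
  })

#' Cross-condition overlap of significant GO terms
#'
#' Intersections of the per-condition significant term sets: across all
#' conditions, in a sliding developmental window, and (optionally) as a
#' three-way Venn over developmental phase groups (e.g. vegetative /
#' reproductive / ripening).
#'
#' @param goe a \linkS4class{GOEnrichment} (or the list returned by
#'   \code{\link{goSummary}}).
#' @param window sliding-window width in conditions (default 2).
#' @param phaseGroups optional named list mapping each of three group
#'   labels to a vector of condition names; term sets are unioned within a
#'   group.
#' @return list with \code{sharedAll} (character vector),
#'   \code{slidingWindow} (named list of intersections over consecutive
#'   windows) and, if requested, \code{venn} (named counts of the 7
#'   exclusive three-set cells, names like \code{"100"}, \code{"110"} in
#'   group order).
#' @export
overlapAnalysis <- function(goe, window = 2L, phaseGroups = NULL) {
  summ <- if (is(goe, "GOEnrichment")) goSummary(goe) else goe
  sets <- summ$sigTerms
  k <- length(sets)
  sharedAll <- if (k) sort(Reduce(intersect, sets)) else character()
  sw <- list()
  if (k >= window)
    for (i in seq_len(k - window + 1L)) {
      idx <- i:(i + window - 1L)
      sw[[paste(names(sets)[idx], collapse = "+")]] <-
        sort(Reduce(intersect, sets[idx]))
    }
  out <- list(sharedAll = sharedAll, slidingWindow = sw)
  if (!is.null(phaseGroups)) {
    stopifnot(length(phaseGroups) == 3L)
    gsets <- lapply(phaseGroups, function(cns)
      sort(unique(unlist(sets[cns]))))
    allTerms <- unique(unlist(gsets))
    member <- vapply(gsets, function(s) allTerms %in% s,
                     logical(length(allTerms)))
    if (length(allTerms) == 1L) member <- matrix(member, nrow = 1L)
    pat <- apply(member, 1L, function(b) paste(as.integer(b),
                                               collapse = ""))
    cells <- c("100", "010", "001", "110", "101", "011", "111")
    venn <- stats::setNames(integer(7L), cells)
    tab <- table(pat)
    venn[names(tab)] <- as.integer(tab)
    out$venn <- venn
  }
  out
}
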