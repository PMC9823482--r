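## Per-promoter presence counts of all length-k DNA words, forward strand.
## Chunked so the dense oligonucleotide count matrix never exceeds a few
## hundred promoters at a time (4^8 columns).  Windows containing N match
## no A/C/G/T word and are effectively skipped.
.kmerPresence <- function(promoters, k, chunkSize = 256L) {
  n <- length(promoters)
  acc <- NULL
  for (start in seq(1L, n, by = chunkSize)) {
    idx <- start:min(start + chunkSize - 1L, n)
    of <- Biostrings::oligonucleotideFrequency(promoters[idx], width = k)
    pres <- colSums(of > 0L)
    acc <- if (is.null(acc)) pres else acc + pres
  }
  as.integer(acc) |> stats::setNames(names(acc))
}

#' Build the background kmer dictionary over a promoter universe
#'
#' Counts, for every DNA word of length \code{kRange[1]} to
#' \code{kRange[2]} (3--8 by default, \eqn{\sum 4^k = 87360} words), the
#' number of promoters of the universe containing it at least once --
#' presence, not occurrence, on the forward strand of the stored promoter.
#' These background counts are the reference for the per-phase-list
#' hypergeometric tests.
#'
#' @param promoters named \link[Biostrings]{DNAStringSet} (the promoter
#'   universe, conventionally 500 bp upstream windows).
#' @param kRange integer(2), kmer length range (default \code{c(3, 8)}).
#' @param chunkSize promoters per counting chunk (memory knob).
#' @return a \linkS4class{KmerDictionary}.
#' @export
buildKmerDictionary <- function(promoters, kRange = c(3L, 8L),
                                chunkSize = 256L) {
  stopifnot(is(promoters, "DNAStringSet"), length(promoters) > 0L)
  if (is.null(names(promoters))) stop("promoters must be named by gene")
  kk <- seq(kRange[1], kRange[2])
  counts <- unlist(lapply(kk, function(k)
    .kmerPresence(promoters, k, chunkSize)))
  new("KmerDictionary", counts = counts,
      kRange = as.integer(kRange),
      universeSize = length(promoters), genes = names(promoters))
}

#' Kmer overrepresentation in one gene list
#'
#' Hypergeometric upper-tail test per kmer: drawing \code{length(genes)}
#' promoters from the universe, the probability of observing at least the
#' foreground number of carriers, given the dictionary's background
#' presence counts.  \eqn{q} is Benjamini-Hochberg adjusted across all
#' kmers of the dictionary (one BH family per list).  A kmer absent from
#' the list has \eqn{p = P(X \ge 0) = 1}.
#'
#' @param dict a \linkS4class{KmerDictionary} built on the universe.
#' @param promoters the universe \link[Biostrings]{DNAStringSet} the
#'   dictionary was built from.
#' @param genes character vector, the gene list (must be a subset of the
#'   universe).
#' @param alpha FDR threshold for the \code{significant} flag.
#' @return \link[S4Vectors]{DataFrame} with one row per kmer:
#'   \code{kmer}, \code{k}, \code{foreground}, \code{listSize},
#'   \code{background}, \code{universeSize}, \code{p}, \code{q},
#'   \code{significant}; zero rows for an empty list.
#' @examples
#' ps <- Biostrings::DNAStringSet(c(a = "AAATATCTGG", b = "CCGGTTAACC",
#'                                  c = "AAATATCTTT", d = "GGCCGGAATT"))
#' d <- buildKmerDictionary(ps)
#' res <- enrichKmers(d, ps, c("a", "c"))
#' res[res$kmer == "AAATATCT", ]
#' @export
enrichKmers <- function(dict, promoters, genes, alpha = 0.05) {
  stopifnot(is(dict, "KmerDictionary"))
  if (!all(genes %in% dict@genes))
    stop("gene list contains genes outside the promoter universe")
  empty <- S4Vectors::DataFrame(
    kmer = character(), k = integer(), foreground = integer(),
    listSize = integer(), background = integer(),
    universeSize = integer(), p = numeric(), q = numeric(),
    significant = logical())
  if (length(genes) == 0L) return(empty)
  kk <- seq(dict@kRange[1], dict@kRange[2])
  fg <- unlist(lapply(kk, function(k)
    .kmerPresence(promoters[genes], k)))
  bg <- dict@counts
  stopifnot(identical(names(fg), names(bg)))
  N <- dict@universeSize
  nList <- length(genes)
  p <- phyper(fg - 1L, bg, N - bg, nList, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  S4Vectors::DataFrame(
    kmer = names(bg), k = nchar(names(bg)), foreground = fg,
    listSize = nList, background = bg, universeSize = N,
    p = unname(p), q = unname(q), significant = unname(q < alpha))
}

#' Run the TOD element analysis over all (condition x phase bin) lists
#'
#' Schedules one kmer-overrepresentation test family per phase-binned
#' rhythmic gene list of every condition (with 11 conditions and the
#' 23-bin option this is the canonical 253 lists), skipping empty bins
#' with a message.  To keep the result compact, only rows significant at
#' \eqn{q < \alpha} are retained, plus the rows of any \code{track}ed
#' kmers (canonical TOD elements by default) in every list so that their
#' full TOD profile can be drawn.
#'
#' @param callsets list of \linkS4class{CyclingCallSet}s in developmental
#'   order.
#' @param promoters the promoter universe
#'   (\link[Biostrings]{DNAStringSet}); genes without promoters are
#'   dropped from the lists.
#' @param alpha per-list FDR threshold (default 0.05).
#' @param bins 24 (default) or 23 phase bins; see
#'   \code{\link{phaseGeneLists}}.
#' @param track kmers always retained; defaults to the canonical Morning
#'   Element, Evening Element, CCA1-binding site and Telobox words.
#' @param dict optional precomputed \linkS4class{KmerDictionary}.
#' @return a \linkS4class{KmerEnrichment}.
#' @export
runElement <- function(callsets, promoters, alpha = 0.05, bins = 24L,
                       track = c("CCACAC", "AAATATCT", "AAAATCT",
                                 "AAACCCT"),
                       dict = NULL) {
  if (is(callsets, "CyclingCallSet")) callsets <- list(callsets)
  if (is.null(dict)) dict <- buildKmerDictionary(promoters)
  condNames <- unname(vapply(callsets, conditionName, ""))
  res <- list(); sizes <- integer(); nLists <- 0L
  binLabels <- NULL
  for (ci in seq_along(callsets)) {
    lists <- phaseGeneLists(callsets[[ci]], bins = bins)
    if (is.null(binLabels)) binLabels <- names(lists)
    for (b in names(lists)) {
      nLists <- nLists + 1L
      gl <- intersect(lists[[b]], dict@genes)
      sizes[paste0(condNames[ci], "|", b)] <- length(gl)
      if (length(gl) == 0L) {
        message("empty phase bin skipped: ", condNames[ci], " bin ", b)
        next
      }
      r <- enrichKmers(dict, promoters, gl, alpha = alpha)
      keep <- r$significant | r$kmer %in% track
      if (any(keep)) {
        r <- r[keep, , drop = FALSE]
        res[[length(res) + 1L]] <- cbind(
          S4Vectors::DataFrame(condition = condNames[ci], bin = b), r)
      }
    }
  }
  results <- if (length(res)) do.call(rbind, res) else
    cbind(S4Vectors::DataFrame(condition = character(), bin = character()),
          enrichKmers(dict, promoters, character()))
  new("KmerEnrichment", results = results, alpha = alpha,
      bins = binLabels, conditions = condNames,
      universeSize = dict@universeSize, nLists = nLists,
      listSizes = sizes, tracked = as.character(track))
}

## Best ungapped alignment of two kmers; returns the linking offset set.
## Offset o places b at position o relative to a (0 = left-aligned; may be
## negative).  Two kmers link when some offset with overlap >= 3 matches
## at >= min(nchar) - 1 positions.
.kmerOffsets <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  out <- list()
  for (o in seq(-(nb - 1L), na - 1L)) {
    aIdx <- max(1L, 1L + o):min(na, nb + o)
    if (length(aIdx) < 3L) next
    bIdx <- aIdx - o
    out[[length(out) + 1L]] <- list(
      offset = o, overlap = length(aIdx),
      matches = sum(av[aIdx] == bv[bIdx]))
  }
  out
}

.kmersLinked <- function(a, b, minOverlap = 3L) {
  need <- min(nchar(a), nchar(b)) - 1L
  for (al in .kmerOffsets(a, b))
    if (al$overlap >= minOverlap && al$matches >= need) return(TRUE)
  FALSE
}

#' Cluster significant kmers into motifs
#'
#' Greedy single-linkage clustering by ungapped sequence similarity: two
#' kmers link when some offset alignment matches at
#' \eqn{\ge \min(\mathrm{len}) - 1} positions with an overlap of at least
#' 3 bp (so a kmer always links its one-mismatch neighbours and its
#' contained sub-words).  Each cluster is aligned to a common frame --
#' members placed at their best offset against the longest member -- and
#' summarized as a position-frequency matrix from which a consensus (and a
#' sequence logo) can be drawn.
#'
#' @param kmers character vector of (significant) kmers.
#' @param minOverlap minimum alignment overlap in bp (default 3).
#' @return a \linkS4class{MotifClusterSet}; every input kmer belongs to
#'   exactly one cluster.
#' @examples
#' clusters(clusterKmers(c("AAATATCT", "AATATCT", "GGGCCC")))
#' @export
clusterKmers <- function(kmers, minOverlap = 3L) {
  kmers <- unique(as.character(kmers))
  m <- length(kmers)
  if (m == 0L) return(new("MotifClusterSet", clusters = list()))
  parent <- seq_len(m)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    ri <- findRoot(i); rj <- findRoot(j)
    if (ri != rj && .kmersLinked(kmers[i], kmers[j], minOverlap))
      parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(m), findRoot, 1L)
  groups <- split(kmers, roots)
  cl <- lapply(unname(groups), function(members) {
    lens <- nchar(members)
    seed <- members[order(-lens, members)][1L]
    offsets <- vapply(members, function(k) {
      if (k == seed) return(0L)
      als <- .kmerOffsets(seed, k)
      sc <- vapply(als, function(a) a$matches, 1L)
      as.integer(als[[which.max(sc)]]$offset)
    }, 1L)
    offsets <- offsets - min(offsets)
    width <- max(offsets + nchar(members))
    pfm <- matrix(0L, 4L, width,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    for (ki in seq_along(members)) {
      ch <- strsplit(members[ki], "")[[1L]]
      for (p in seq_along(ch))
        pfm[ch[p], offsets[ki] + p] <- pfm[ch[p], offsets[ki] + p] + 1L
    }
    consensus <- paste(rownames(pfm)[apply(pfm, 2L, which.max)],
                       collapse = "")
    list(members = members, offsets = unname(offsets), pfm = pfm,
         consensus = consensus)
  })
  ## deterministic order: by first member's appearance in the input
  first <- vapply(cl, function(x) match(x$members[1L], kmers), 1L)
  new("MotifClusterSet", clusters = cl[order(first)])
}

#' Rank motif clusters by their best enrichment
#'
#' @param mcs a \linkS4class{MotifClusterSet}.
#' @param enr the \linkS4class{KmerEnrichment} the member kmers came from.
#' @return \code{data.frame} sorted by minimum member \eqn{q}: cluster
#'   index, consensus, member count, \code{minQ} and the (condition, bin)
#'   where it is attained.
#' @export
summarizeClusters <- function(mcs, enr) {
  stopifnot(is(mcs, "MotifClusterSet"), is(enr, "KmerEnrichment"))
  tab <- enr@results
  rows <- lapply(seq_along(mcs@clusters), function(i) {
    cl <- mcs@clusters[[i]]
    hit <- tab[tab$kmer %in% cl$members, , drop = FALSE]
    if (nrow(hit) == 0L)
      return(data.frame(cluster = i, consensus = cl$consensus,
                        nMembers = length(cl$members), minQ = NA_real_,
                        bestCondition = NA_character_,
                        bestBin = NA_character_))
    b <- which.min(hit$q)
    data.frame(cluster = i, consensus = cl$consensus,
               nMembers = length(cl$members), minQ = hit$q[b],
               bestCondition = hit$condition[b], bestBin = hit$bin[b])
  })
  out <- do.call(rbind, rows)
  out[order(out$minQ), , drop = FALSE]
}

#' @rdname todProfile
setMethod("todProfile", "KmerEnrichment",
  function(x, features, cap = 10) {
    .profileFromResults(x@results, "kmer", features, x@conditions,
                        x@bins, cap)
  })

.profileFromResults <- function(tab, col, features, conds, bins, cap) {
  prof <- matrix(0, length(conds), length(bins),
                 dimnames = list(conds, bins))
  hit <- tab[tab[[col]] %in% features, , drop = FALSE]
  if (nrow(hit)) {
    v <- pmin(-log10(pmax(hit$q, .Machine$double.xmin)), cap)
    for (r in seq_len(nrow(hit))) {
      i <- hit$condition[r]; j <- hit$bin[r]
      prof[i, j] <- max(prof[i, j], v[r])
    }
  }
  prof
}
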