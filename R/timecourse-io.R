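#' Read a gene-by-timepoint expression table
#'
#' Reads a tab-delimited intensity table (first column gene ids, remaining
#' columns one sample each, header parseable to ZT hours such as
#' \code{ZT6 ... ZT54}) into a validated \linkS4class{TimeCourse}.
#'
#' Malformed input fails loudly: ragged rows, duplicated gene ids and
#' non-numeric cells raise errors naming the offending line or id.  Empty
#' cells are treated as missing values: a gene with a single missing sample
#' is linearly interpolated from its flanking timepoints (nearest value at
#' the boundary); a gene with two or more missing samples is retained but
#' flagged in \code{rowData()$naExcluded} and is treated as not expressed
#' by \code{\link{callExpressed}}.
#'
#' @param path file path.
#' @param condition,tissue,dayOfSeason sampling metadata for the course.
#' @param log2Input if \code{TRUE} the file stores log2 intensities, which
#'   are converted back to linear scale on load.
#' @return a \linkS4class{TimeCourse}.
#' @seealso \code{\link{writeExpressionTable}}
#' @export
readExpressionTable <- function(path, condition, tissue = "leaf",
                                dayOfSeason = NA_real_, log2Input = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop("ragged rows in ", path, " at line(s): ",
         paste(which(nf != nf[1]), collapse = ", "))
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 3L) stop("expected a gene column plus >= 2 samples")
  geneIds <- raw[[1L]]
  dup <- unique(geneIds[duplicated(geneIds)])
  if (length(dup))
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  ztLab <- colnames(raw)[-1L]
  zt <- suppressWarnings(as.numeric(sub("^ZT", "", ztLab)))
  if (anyNA(zt)) stop("header not parseable to ZT hours: ",
                      paste(ztLab[is.na(zt)], collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  missing <- cells == "" | toupper(cells) == "NA"
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) & !missing, arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell(s) at line(s) ",
         paste(unique(bad[, 1L] + 1L), collapse = ", "),
         " (gene ", paste(unique(geneIds[bad[, 1L]]), collapse = ", "), ")")
  num[missing] <- NA_real_
  naPerGene <- rowSums(is.na(num))
  excluded <- naPerGene >= 2L
  interp <- which(naPerGene >= 1L)
  for (i in interp) {
    ok <- !is.na(num[i, ])
    num[i, ] <- approx(zt[ok], num[i, ok], xout = zt, rule = 2)$y
  }
  if (length(interp))
    message(sum(naPerGene == 1L), " gene(s) interpolated; ",
            sum(excluded), " gene(s) with >= 2 missing values flagged ",
            "as not expressed")
  if (log2Input) num <- 2^num
  rownames(num) <- geneIds
  tc <- TimeCourse(num, zt = zt, condition = condition, tissue = tissue,
                   dayOfSeason = dayOfSeason)
  SummarizedExperiment::rowData(tc)$naExcluded <- excluded
  tc
}

#' Write a TimeCourse as a tab-delimited expression table
#'
#' @param tc a \linkS4class{TimeCourse}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpressionTable <- function(tc, path) {
  m <- intensities(tc)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("gene", paste0("ZT", ztGrid(tc)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Standard FASTA parsing (via Biostrings); lowercase is coerced to
#' uppercase; the alphabet must be within \code{A/C/G/T/N}.
#'
#' @param path FASTA file.
#' @param expectedLength if non-\code{NULL}, every record must have this
#'   length (strict mode; the conventional promoter window is 500 bp).
#' @return a named \link[Biostrings]{DNAStringSet}.
#' @export
readPromoters <- function(path, expectedLength = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ## readDNAStringSet drops invalid letters with a warning; surface that
  ## as the format error it is rather than silently shortening sequences
  ps <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w)
      stop("non-DNA characters in FASTA: ", conditionMessage(w),
           call. = FALSE))
  if (length(ps) == 0L) stop("empty FASTA: ", path)
  ps <- Biostrings::DNAStringSet(toupper(ps))
  freq <- Biostrings::alphabetFrequency(ps)
  extra <- colSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                        drop = FALSE])
  if (any(extra > 0))
    stop("non-DNA characters (beyond N) in promoters: ",
         paste(names(extra)[extra > 0], collapse = ", "))
  if (!is.null(expectedLength)) {
    badLen <- Biostrings::width(ps) != expectedLength
    if (any(badLen))
      stop("promoter length != ", expectedLength, " for: ",
           paste(utils::head(names(ps)[badLen], 5L), collapse = ", "))
  }
  if (anyDuplicated(names(ps))) stop("duplicated promoter names")
  ps
}

#' @rdname readPromoters
#' @param promoters a named \link[Biostrings]{DNAStringSet}.
#' @export
writePromoters <- function(promoters, path) {
  Biostrings::writeXStringSet(promoters, path)
  invisible(path)
}

#' Read a gene-to-GO annotation map
#'
#' Accepts either a two-column headerless \code{gene<TAB>GO:ID} TSV or a
#' GAF file (\code{!}-prefixed comment lines; object id and term taken
#' from columns 2 and 5).  Term ids must match \code{GO:} plus seven
#' digits.  Genes absent from any expression data are retained (the
#' annotation is independent of the arrays); callers subset at enrichment
#' time.
#'
#' @param path file path.
#' @return \code{data.frame} with columns \code{gene}, \code{term},
#'   duplicates removed.
#' @export
readGeneGO <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty annotation file: ", path)
  gaf <- startsWith(lines[1L], "!") ||
    length(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]) >= 15L
  lines <- lines[!startsWith(lines, "!")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (gaf) {
    gene <- vapply(parts, `[`, "", 2L)
    term <- vapply(parts, `[`, "", 5L)
  } else {
    nfld <- lengths(parts)
    if (any(nfld != 2L))
      stop("expected two tab-separated columns; offending line(s): ",
           paste(which(nfld != 2L), collapse = ", "))
    gene <- vapply(parts, `[`, "", 1L)
    term <- vapply(parts, `[`, "", 2L)
  }
  badTerm <- !grepl("^GO:[0-9]{7}$", term)
  if (any(badTerm))
    stop("malformed GO id(s): ", paste(unique(term[badTerm]), collapse = ", "))
  unique(data.frame(gene = gene, term = term))
}

#' @rdname readGeneGO
#' @param goMap \code{data.frame} with columns \code{gene}, \code{term}.
#' @export
writeGeneGO <- function(goMap, path) {
  write.table(goMap[, c("gene", "term")], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read back cycling call tables
#'
#' Plain TSV serialization of a \linkS4class{CyclingCallSet} (columns
#' gene, expressed, rhythmic, shape, phase, R, amplitude), the exchange
#' format between the detection stage and the downstream phase-shift,
#' element and GO stages.
#'
#' @param ccs a \linkS4class{CyclingCallSet}.
#' @param path file path.
#' @param condition condition label of the stored calls.
#' @param rMin the threshold the calls were made at.
#' @return \code{writeCallsTable}: \code{path} invisibly;
#'   \code{readCallsTable}: a \linkS4class{CyclingCallSet}.
#' @export
writeCallsTable <- function(ccs, path) {
  df <- as.data.frame(calls(ccs))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCallsTable
#' @export
readCallsTable <- function(path, condition, rMin = 0.8) {
  df <- read.delim(path)
  new("CyclingCallSet", condition = condition,
      calls = S4Vectors::DataFrame(
        gene = as.character(df$gene),
        expressed = as.logical(df$expressed),
        rhythmic = as.logical(df$rhythmic),
        shape = as.character(df$shape),
        phase = as.numeric(df$phase),
        R = as.numeric(df$R),
        amplitude = as.numeric(df$amplitude)),
      rMin = rMin)
}

#' Write a ground-truth table
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param path file path.
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  df <- as.data.frame(truthTable(truth))
  ph <- truePhases(truth)
  colnames(ph) <- paste0("phase_", colnames(ph))
  write.table(cbind(df, ph), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
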