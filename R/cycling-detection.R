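#' Build the phased waveform template library
#'
#' Evaluates each shape at each phase offset on the sampling grid and
#' standardizes the resulting template to zero mean and unit variance.
#' With the default six shapes and 1 h phase steps the library holds
#' 6 x 24 = 144 templates.  Templates are ordered phase-major (all shapes
#' at phase 0, then phase 1, ...), which fixes the deterministic tie-break
#' of \code{\link{detectCycling}}: earlier phase first, then shape order.
#'
#' @param zt sampling grid in hours; must span at least two full 24 h
#'   cycles with spacing of at most 6 h.
#' @param shapes character vector of shape ids; the default set
#'   \{cosine, sharpened cosine, 50\%-duty box, one-sample spike, rising
#'   ramp, falling ramp\} spans the waveform diversity of diurnal
#'   transcripts.
#' @param phaseStep phase offset step in hours (default 1).
#' @return a \linkS4class{ModelLibrary}.
#' @examples
#' lib <- buildModelLibrary(seq(6, 54, by = 2))
#' lib
#' @export
buildModelLibrary <- function(zt, shapes = .todShapes, phaseStep = 1) {
  zt <- as.numeric(zt)
  if (max(zt) - min(zt) < 48)
    stop("grid must cover at least 2 full 24 h cycles")
  if (max(diff(zt)) > 6)
    stop("grid spacing > 6 h: insufficient sampling for 24 h rhythms")
  bad <- setdiff(shapes, .allSimShapes())
  if (length(bad)) stop("unknown shape(s): ", paste(bad, collapse = ", "))
  phs <- seq(0, 24 - phaseStep, by = phaseStep)
  n <- length(shapes) * length(phs)
  tmpl <- matrix(NA_real_, n, length(zt))
  shapeId <- character(n); phaseId <- numeric(n)
  i <- 0L
  for (ph in phs) {
    for (sh in shapes) {
      i <- i + 1L
      w <- waveformValue(sh, zt, ph)
      s <- stats::sd(w)
      if (s == 0)
        stop("constant template (shape ", sh, ", phase ", ph,
             ") on this grid")
      tmpl[i, ] <- (w - mean(w)) / s
      shapeId[i] <- sh; phaseId[i] <- ph
    }
  }
  rownames(tmpl) <- paste0(shapeId, "_", phaseId)
  new("ModelLibrary", templates = tmpl, shape = shapeId, phase = phaseId,
      zt = zt)
}

#' Flag expressed genes
#'
#' A gene is called expressed when at least \code{minPoints} (consecutive,
#' by default) samples exceed a background threshold, taken as the
#' \code{bgQuantile} quantile of all values of the matrix.  Genes flagged
#' \code{naExcluded} at load time (two or more missing samples) are never
#' called expressed.
#'
#' @param tc a (normalized) \linkS4class{TimeCourse}.
#' @param bgQuantile quantile of all matrix values used as the background
#'   threshold (default 0.2).
#' @param minPoints minimum number of above-threshold samples (default 2).
#' @param consecutive if \code{TRUE} (default) the \code{minPoints}
#'   samples must be consecutive.
#' @return named logical vector over genes.
#' @export
callExpressed <- function(tc, bgQuantile = 0.2, minPoints = 2L,
                          consecutive = TRUE) {
  stopifnot(is(tc, "TimeCourse"))
  m <- intensities(tc)
  thr <- quantile(m, bgQuantile, names = FALSE)
  above <- m > thr
  flag <- if (consecutive) {
    apply(above, 1L, function(x) {
      r <- rle(x)
      any(r$values & r$lengths >= minPoints)
    })
  } else rowSums(above) >= minPoints
  excl <- SummarizedExperiment::rowData(tc)$naExcluded
  if (!is.null(excl)) flag <- flag & !excl
  stats::setNames(flag, rownames(m))
}

#' Detect cycling genes by template correlation
#'
#' HAYSTACK-style rhythmicity detection: each expressed gene's
#' \code{log2(intensity + 1)} profile is correlated (product-moment)
#' against every template of the library; the gene is called rhythmic when
#' the best correlation \eqn{R} reaches \code{rMin} (default 0.8, the
#' empirically defined threshold for two-day, 2 h-resolution courses), and
#' its phase -- the time of day of peak expression -- is the best
#' template's phase offset in ZT-label space.  Exact correlation ties are
#' broken deterministically toward the earlier phase, then shape order.
#' Genes with constant profiles have undefined correlation and are called
#' not rhythmic (with a message).
#'
#' @param tc a (normalized) \linkS4class{TimeCourse}.
#' @param lib a \linkS4class{ModelLibrary} built on the same ZT grid.
#' @param rMin correlation threshold; rhythmic iff \eqn{R \ge rMin}.
#' @param expressed optional named logical vector overriding
#'   \code{\link{callExpressed}} (e.g. to score every gene).
#' @param ... passed to \code{\link{callExpressed}}.
#' @return a \linkS4class{CyclingCallSet} covering every gene of \code{tc}.
#' @examples
#' sim <- simulateTimecourses(simConfig(nGenes = 50, noiseSd = 0, seed = 7))
#' tc <- sim$timecourses[[1]]
#' lib <- buildModelLibrary(ztGrid(tc))
#' ccs <- detectCycling(tc, lib)
#' ccs
#' @export
detectCycling <- function(tc, lib, rMin = 0.8, expressed = NULL, ...) {
  stopifnot(is(tc, "TimeCourse"), is(lib, "ModelLibrary"))
  if (!isTRUE(all.equal(as.numeric(ztGrid(tc)), lib@zt)))
    stop("library was built on a different ZT grid")
  genes <- rownames(tc)
  if (is.null(expressed)) expressed <- callExpressed(tc, ...)
  expressed <- expressed[genes]
  X <- log2(intensities(tc) + 1)
  npts <- ncol(X)
  mu <- rowMeans(X)
  cen <- X - mu
  sdx <- sqrt(rowSums(cen^2) / (npts - 1))
  shape <- rep(NA_character_, length(genes))
  phase <- rep(NA_real_, length(genes))
  R <- rep(NA_real_, length(genes))
  amplitude <- rep(NA_real_, length(genes))
  scor <- which(expressed & sdx > 1e-12)
  nConst <- sum(expressed & sdx <= 1e-12)
  if (nConst > 0)
    message(nConst, " expressed gene(s) with constant profiles: ",
            "correlation undefined, called not rhythmic")
  if (length(scor)) {
    ## correlation of each centered profile with each standardized template
    Rmat <- (cen[scor, , drop = FALSE] %*% t(lib@templates)) /
      ((npts - 1) * sdx[scor])
    best <- max.col(Rmat, ties.method = "first")
    R[scor] <- Rmat[cbind(seq_along(scor), best)]
    shape[scor] <- lib@shape[best]
    tplRange <- apply(lib@templates, 1L, function(r) diff(range(r)))
    amplitude[scor] <- R[scor] * sdx[scor] * tplRange[best]
    phase[scor] <- lib@phase[best]
  }
  rhythmic <- !is.na(R) & expressed & R >= rMin
  phase[!rhythmic] <- NA_real_
  new("CyclingCallSet", condition = conditionName(tc),
      calls = S4Vectors::DataFrame(
        gene = genes, expressed = unname(expressed), rhythmic = rhythmic,
        shape = shape, phase = phase, R = R, amplitude = amplitude),
      rMin = rMin)
}

#' Summary counts and percentages under the mixed-denominator convention
#'
#' Summarizes expressed/rhythmic calls the way developmental cycling
#' tables are conventionally printed: \emph{not expressed} and \emph{not
#' rhythmic} as integer-rounded percentages of the \emph{total} gene
#' count, but \emph{rhythmic} as a percentage of the \emph{expressed}
#' genes.  The three counts always partition the total
#' (\code{notExpressed + notRhythmic + rhythmic == total}).
#'
#' @param total,notExpressed,notRhythmic,rhythmic integer counts; exactly
#'   one of \code{notRhythmic}/\code{rhythmic} may be omitted and is
#'   filled from the partition.
#' @return one-row \code{data.frame} with the four counts, the expressed
#'   count and \code{pctNotExpressed}, \code{pctNotRhythmic},
#'   \code{pctRhythmic}.
#' @examples
#' todSummary(27648, notExpressed = 4735, rhythmic = 15615)$pctRhythmic  # 68
#' @export
todSummary <- function(total, notExpressed, notRhythmic = NULL,
                       rhythmic = NULL) {
  if (is.null(notRhythmic) && is.null(rhythmic))
    stop("supply notRhythmic or rhythmic")
  if (is.null(notRhythmic)) notRhythmic <- total - notExpressed - rhythmic
  if (is.null(rhythmic)) rhythmic <- total - notExpressed - notRhythmic
  if (notExpressed + notRhythmic + rhythmic != total)
    stop("counts do not partition the total")
  expressed <- total - notExpressed
  data.frame(total = total, notExpressed = notExpressed,
             expressed = expressed, notRhythmic = notRhythmic,
             rhythmic = rhythmic,
             pctNotExpressed = .pct(notExpressed, total),
             pctNotRhythmic = .pct(notRhythmic, total),
             pctRhythmic = .pct(rhythmic, expressed))
}

#' @rdname cyclingSummary
setMethod("cyclingSummary", "CyclingCallSet", function(x) {
  cl <- x@calls
  s <- todSummary(nrow(cl), notExpressed = sum(!cl$expressed),
                  rhythmic = sum(cl$rhythmic))
  cbind(data.frame(condition = x@condition), s)
})

#' Split rhythmic genes into phase-binned gene lists
#'
#' Returns the per-phase-bin gene lists that feed the element and GO
#' enrichment stages: 24 hourly bins by default, or 23 bins, in which case
#' the two adjacent (circularly) bins with the smallest combined
#' membership are merged -- so eleven conditions yield the canonical
#' 11 x 23 = 253 lists.  Empty bins are retained (and skipped, with a
#' message, at enrichment time).
#'
#' @param ccs a \linkS4class{CyclingCallSet}.
#' @param bins 24 (default) or 23.
#' @return named list of character vectors (bin label -> genes).
#' @export
phaseGeneLists <- function(ccs, bins = 24L) {
  stopifnot(is(ccs, "CyclingCallSet"))
  ph <- phases(ccs)
  bin <- factor(floor(ph) %% 24, levels = 0:23)
  lists <- split(names(ph), bin)
  names(lists) <- as.character(0:23)
  if (bins == 24L) return(lists)
  if (bins != 23L) stop("bins must be 24 or 23")
  cnt <- lengths(lists)
  pairSum <- cnt + cnt[c(2:24, 1)]           # (i, i+1 mod 24)
  i <- which.min(pairSum)                    # first minimum: deterministic
  j <- if (i == 24L) 1L else i + 1L
  merged <- c(lists[[i]], lists[[j]])
  out <- lists[-c(i, j)]
  nm <- paste0(names(lists)[i], "+", names(lists)[j])
  ## keep bin order, merged bin in place of its first member
  out <- append(out, stats::setNames(list(merged), nm),
                after = min(i - 1L, length(out)))
  out
}
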