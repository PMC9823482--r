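#' Pipeline configuration
#'
#' Assembles the full-run configuration: either a synthetic study (a
#' \code{\link{simConfig}}) or, in file mode, paths to expression tables,
#' promoters and a gene-to-GO map on disk.  Every default that fills a
#' methodological gap (the correlation threshold, the expressed-gating
#' policy, the strandedness of the kmer counts, the bin count) is recorded
#' in the run manifest so any divergence between runs is auditable.
#'
#' @param sim a \linkS4class{SimConfig} (ignored when \code{inputFiles}
#'   is given).
#' @param inputFiles optional named list for file mode:
#'   \code{expression} (named character vector of per-condition TSV
#'   paths), \code{promoters} (FASTA path, optional), \code{goMap} (TSV
#'   path, optional), and optionally \code{tissue}, \code{dayOfSeason}
#'   vectors aligned with \code{expression}.
#' @param rMin rhythmicity correlation threshold (default 0.8).
#' @param bins phase bins, 24 or 23 (the 23-bin profile gives the
#'   conventional 253-list schedule over eleven conditions).
#' @param alphaElement,alphaGO per-list FDR thresholds.
#' @param goUniverse \code{"expressed"} or \code{"all"}.
#' @param anchor baseline-analysis anchor condition (default: first).
#' @param doElement,doGO stage switches.
#' @param bgQuantile,minPoints expressed-gating policy.
#' @param seed integer seed governing all pipeline randomness.
#' @return a validated configuration list of class
#'   \code{"todPipelineConfig"}.
#' @export
pipelineConfig <- function(sim = simConfig(), inputFiles = NULL,
                           rMin = 0.8, bins = 24L, alphaElement = 0.05,
                           alphaGO = 0.05,
                           goUniverse = c("expressed", "all"),
                           anchor = NULL, doElement = TRUE, doGO = TRUE,
                           bgQuantile = 0.2, minPoints = 2L,
                           seed = 1L) {
  goUniverse <- match.arg(goUniverse)
  stopifnot(rMin > 0, rMin <= 1, bins %in% c(23L, 24L),
            alphaElement > 0, alphaElement < 1, alphaGO > 0, alphaGO < 1)
  if (!is.null(inputFiles)) {
    stopifnot(is.list(inputFiles), !is.null(inputFiles$expression))
    paths <- unlist(inputFiles[c("expression", "promoters", "goMap")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(sim = sim, inputFiles = inputFiles, rMin = rMin,
                 bins = as.integer(bins), alphaElement = alphaElement,
                 alphaGO = alphaGO, goUniverse = goUniverse,
                 anchor = anchor, doElement = doElement, doGO = doGO,
                 bgQuantile = bgQuantile, minPoints = as.integer(minPoints),
                 seed = as.integer(seed)),
            class = "todPipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full TOD analysis pipeline
#'
#' Orchestrates simulate/load, quantile normalization, cycling detection,
#' baseline and incremental phase-shift analyses, element discovery, GO
#' enrichment and the similarity report, writing every stage's output as
#' tab-delimited text under \code{outDir} plus a machine-readable
#' \code{manifest.json} (package version, all parameters, md5 checksum of
#' every written file).  Deterministic given the configured seed:
#' re-running with the same seed reproduces identical checksums.  With
#' \code{resume = TRUE}, a per-condition calls table already on disk is
#' validated and reused instead of re-detecting.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @param resume reuse validated intermediates already in \code{outDir}.
#' @return invisibly, a list with the in-memory stage results
#'   (\code{timecourses}, \code{truth} (synthetic mode), \code{callsets},
#'   \code{baseline}, \code{incremental}, \code{element}, \code{go},
#'   \code{report}, \code{manifest}).
#' @export
runPipeline <- function(config, outDir, resume = FALSE) {
  stopifnot(inherits(config, "todPipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("matrices", "normalized", "calls", "shifts", "element",
              "go", "report"))
    dir.create(file.path(outDir, d), showWarnings = FALSE)

  truth <- NULL; promoters <- NULL; goMap <- NULL
  if (is.null(config$inputFiles)) {
    sim <- .stage("simulate", {
      cfg <- config$sim
      cfg@seed <- config$seed
      simulateTimecourses(cfg)
    })
    tcs <- sim$timecourses
    truth <- sim$truth
    promoters <- .stage("simulate_promoters",
      simulatePromoters(truth, seed = config$seed + 1L))
    goMap <- .stage("simulate_go",
      simulateGOMap(truth, nTerms = config$sim@nGoBackgroundTerms,
                    seed = config$seed + 2L,
                    baseProb = config$sim@goBaseProb))
    .stage("write_inputs", {
      for (tc in tcs)
        writeExpressionTable(tc, file.path(outDir, "matrices",
          paste0(conditionName(tc), ".tsv")))
      writePromoters(promoters, file.path(outDir, "promoters.fasta"))
      writeGeneGO(goMap, file.path(outDir, "gene2go.tsv"))
      writeGroundTruth(truth, file.path(outDir, "ground_truth.tsv"))
    })
  } else {
    inf <- config$inputFiles
    tcs <- .stage("load", {
      nms <- names(inf$expression)
      if (is.null(nms)) nms <- sub("\\.tsv$", "", basename(inf$expression))
      out <- lapply(seq_along(inf$expression), function(i)
        readExpressionTable(inf$expression[[i]], condition = nms[i],
          tissue = if (!is.null(inf$tissue)) inf$tissue[[i]] else "leaf",
          dayOfSeason = if (!is.null(inf$dayOfSeason))
            inf$dayOfSeason[[i]] else NA_real_))
      names(out) <- nms
      out
    })
    if (!is.null(inf$promoters))
      promoters <- .stage("load_promoters", readPromoters(inf$promoters))
    if (!is.null(inf$goMap))
      goMap <- .stage("load_go", readGeneGO(inf$goMap))
  }

  normed <- .stage("normalize", {
    out <- lapply(tcs, quantileNormalize)
    for (tc in out)
      writeExpressionTable(tc, file.path(outDir, "normalized",
        paste0(conditionName(tc), ".tsv")))
    out
  })

  lib <- .stage("model_library",
    buildModelLibrary(ztGrid(normed[[1L]])))
  callsets <- .stage("detect", lapply(normed, function(tc) {
    path <- file.path(outDir, "calls", paste0(conditionName(tc), ".tsv"))
    if (resume && file.exists(path)) {
      ccs <- readCallsTable(path, condition = conditionName(tc),
                            rMin = config$rMin)
      validObject(ccs)
      return(ccs)
    }
    ccs <- detectCycling(tc, lib, rMin = config$rMin,
                         bgQuantile = config$bgQuantile,
                         minPoints = config$minPoints)
    writeCallsTable(ccs, path)
    ccs
  }))

  shiftsOut <- .stage("shift", {
    base <- baselineAnalysis(callsets, anchor = config$anchor)
    incr <- incrementalAnalysis(callsets)
    writeShift <- function(pst, path) {
      write.table(as.data.frame(shifts(pst)), path, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    for (nm in names(base))
      writeShift(base[[nm]], file.path(outDir, "shifts",
        paste0("baseline_", nm, ".tsv")))
    for (nm in names(incr))
      writeShift(incr[[nm]], file.path(outDir, "shifts",
        paste0("incremental_", gsub("->", "_vs_", nm, fixed = TRUE),
               ".tsv")))
    hists <- do.call(rbind, lapply(names(incr), function(nm)
      data.frame(pair = nm, bin = 0:23,
                 count = shiftHistogram(incr[[nm]]))))
    if (!is.null(hists))
      write.table(hists, file.path(outDir, "shifts", "histograms.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    list(baseline = base, incremental = incr)
  })

  element <- NULL
  if (config$doElement && !is.null(promoters)) {
    element <- .stage("element", {
      enr <- runElement(callsets, promoters, alpha = config$alphaElement,
                        bins = config$bins)
      sig <- enr@results[enr@results$significant, , drop = FALSE]
      write.table(as.data.frame(sig),
                  file.path(outDir, "element", "significant_kmers.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      mcs <- clusterKmers(unique(sig$kmer))
      if (length(clusters(mcs))) {
        summ <- summarizeClusters(mcs, enr)
        write.table(summ, file.path(outDir, "element", "clusters.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        for (i in seq_along(clusters(mcs)))
          write.table(clusters(mcs)[[i]]$pfm,
                      file.path(outDir, "element",
                                sprintf("pfm_%03d.tsv", i)),
                      sep = "\t", quote = FALSE, row.names = TRUE,
                      col.names = NA)
      }
      list(enrichment = enr, clusters = mcs)
    })
  }

  go <- NULL
  if (config$doGO && !is.null(goMap)) {
    go <- .stage("go", {
      goe <- runGoTOD(callsets, goMap, alpha = config$alphaGO,
                      bins = config$bins, universe = config$goUniverse)
      sig <- goe@results[goe@results$significant, , drop = FALSE]
      write.table(as.data.frame(sig),
                  file.path(outDir, "go", "significant_terms.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summ <- goSummary(goe)
      write.table(summ$perCondition,
                  file.path(outDir, "go", "summary_per_condition.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(summ$occurrences,
                  file.path(outDir, "go", "occurrences.tsv"),
                  sep = "\t", quote = FALSE, col.names = NA)
      goe
    })
  }

  report <- .stage("report", {
    cm <- correlationMatrix(tcs)
    write.table(cm, file.path(outDir, "report", "correlation.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    mds <- mdsEmbed(cm)
    write.table(mds$points, file.path(outDir, "report", "mds.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    ov <- cyclingOverlaps(callsets)
    write.table(ov$pairwise,
                file.path(outDir, "report", "overlaps_pairwise.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    summ <- do.call(rbind, lapply(callsets, cyclingSummary))
    write.table(summ, file.path(outDir, "report", "summary_table.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(correlation = cm, mds = mds, overlaps = ov, summary = summ)
  })

  manifest <- .stage("manifest", {
    files <- list.files(outDir, recursive = TRUE, full.names = TRUE)
    files <- files[basename(files) != "manifest.json"]
    man <- list(
      package = "todcourse",
      version = as.character(utils::packageVersion("todcourse")),
      mode = if (is.null(config$inputFiles)) "synthetic" else "files",
      parameters = list(
        rMin = config$rMin, bins = config$bins,
        alphaElement = config$alphaElement, alphaGO = config$alphaGO,
        goUniverse = config$goUniverse,
        expressedGating = list(bgQuantile = config$bgQuantile,
                               minPoints = config$minPoints,
                               consecutive = TRUE),
        kmerStrand = "forward", kmerStatistic = "hypergeometric-presence",
        seed = config$seed),
      checksums = as.list(.fileChecksums(sort(files), outDir)))
    jsonlite::write_json(man, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    man
  })

  invisible(list(timecourses = tcs, truth = truth, callsets = callsets,
                 baseline = shiftsOut$baseline,
                 incremental = shiftsOut$incremental, element = element,
                 go = go, report = report, manifest = manifest))
}
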