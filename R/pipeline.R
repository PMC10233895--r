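# End-to-end composition of the analysis stages, in memory and file-to-file.

.logStage <- function(verbose, ...) if (verbose) message("[lpiscreen] ", ...)

#' Analyse a screen in memory
#'
#' Chains calibrate -> smooth -> QC -> doubling time -> spatial
#' normalization -> slow-grower exclusion -> LPI -> phenotype calls on a
#' \linkS4class{GrowthCurveSet} plus its layouts, logging counts at each
#' stage.
#'
#' @param curves a \linkS4class{GrowthCurveSet}.
#' @param layouts named list of \linkS4class{PlateLayout} objects.
#' @param calibration calibration spec for \code{\link{calibrateIntensity}}
#'   (default \code{"identity"}: inputs already in cells).
#' @param medianWindow,meanWindow smoothing windows
#'   (\code{\link{smoothCurves}}).
#' @param window,minR2 estimation parameters
#'   (\code{\link{estimateDoublingTimes}}).
#' @param bandwidth control-surface kernel scale
#'   (\code{\link{fitControlSurface}}).
#' @param config a \linkS4class{CallConfig}.
#' @param background background condition label.
#' @param blacklist strains (e.g. dubious ORFs) dropped before calling.
#' @param verbose log stage counts to stderr (default TRUE).
#' @return list with \code{estimates}, \code{phenotypes} (normalized table),
#'   \code{calls}, \code{lpi}, \code{excluded}, \code{backgroundMeans} and
#'   \code{counts} (per-stage tallies).
#' @export
analyzeScreen <- function(curves, layouts, calibration = "identity",
                          medianWindow = 5, meanWindow = 5,
                          window = 7, minR2 = 0.95, bandwidth = 0.8,
                          config = callConfig(), background = "background",
                          blacklist = character(0), verbose = TRUE) {
  counts <- list(curves = nrow(curves))
  .logStage(verbose, "curves: ", counts$curves)
  if (!identical(calibration, "identity")) {
    Y <- curveValues(curves)
    assay(curves, "value") <- matrix(calibrateIntensity(as.vector(Y), calibration),
                                     nrow = nrow(Y))
  }
  curves <- smoothCurves(curves, medianWindow, meanWindow)
  curves <- qcCurves(curves)
  counts$qc_rejected <- sum(!rowData(curves)$qc_pass)
  .logStage(verbose, "QC rejected: ", counts$qc_rejected)
  estimates <- estimateDoublingTimes(curves, window = window, minR2 = minR2)
  counts$estimated <- sum(estimates$qc_pass)
  phenotypes <- normalizeScreen(estimates, layouts, bandwidth = bandwidth)
  scored <- scoreScreen(phenotypes, config, background, blacklist)
  counts$excluded <- length(scored$excluded)
  .logStage(verbose, "slow growers excluded: ", counts$excluded)
  hits <- table(factor(scored$calls$call,
                       c("sensitive", "resistant", "none", "excluded")),
                scored$calls$condition)
  counts$hits <- hits
  if (verbose) {
    for (cond in colnames(hits))
      .logStage(verbose, cond, ": ", hits["sensitive", cond], " sensitive, ",
                hits["resistant", cond], " resistant")
  }
  c(list(estimates = estimates, phenotypes = phenotypes, counts = counts),
    scored)
}

#' Run the full pipeline file-to-file
#'
#' Reads curves and layouts from TSV, runs \code{\link{analyzeScreen}}, and
#' writes all stage outputs (doubling-time TSV, normalized TSV, call table
#' TSV and one hit-list text file per stressor condition) plus optional
#' gene-set overlap reports into \code{outDir}. Deterministic: identical
#' inputs and parameters give byte-identical outputs.
#'
#' @param curvesFile long-format curves TSV (see \code{\link{readCurves}}).
#' @param layoutsFile layouts TSV (see \code{\link{readLayouts}}).
#' @param outDir output directory, created if absent.
#' @param geneSetFiles optional named character vector of gene-set files to
#'   overlap with each condition's sensitive hit list.
#' @param universeN universe size for the overlap tests.
#' @param blacklistFile optional file of strains to drop (one per line).
#' @param ... further parameters passed to \code{\link{analyzeScreen}}.
#' @return invisibly, the \code{\link{analyzeScreen}} result list.
#' @export
runPipeline <- function(curvesFile, layoutsFile, outDir,
                        geneSetFiles = NULL, universeN = 4308,
                        blacklistFile = NULL, ...) {
  for (f in c(curvesFile, layoutsFile, blacklistFile, geneSetFiles))
    if (!file.exists(f)) stop("input file not found: ", f)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  curves <- readCurves(curvesFile)
  layouts <- readLayouts(layoutsFile)
  blacklist <- if (is.null(blacklistFile)) character(0) else
    geneSetMembers(readGeneSet(blacklistFile))
  res <- analyzeScreen(curves, layouts, blacklist = blacklist, ...)
  writeTSV(res$estimates, file.path(outDir, "doubling_times.tsv"),
           meta = "stage: doubling-time estimation")
  writeTSV(res$phenotypes, file.path(outDir, "normalized.tsv"),
           meta = "stage: spatial normalization")
  writeTSV(res$calls, file.path(outDir, "calls.tsv"),
           meta = "stage: phenotype calls")
  overlaps <- list()
  for (cond in unique(res$calls$condition)) {
    hitIds <- res$calls$strain_id[res$calls$condition == cond &
                                    res$calls$call == "sensitive"]
    hitSet <- geneSet(paste0(cond, "_sensitive"), hitIds)
    writeGeneSet(hitSet, file.path(outDir, paste0("hits_", cond, ".txt")))
    if (length(geneSetFiles)) {
      for (i in seq_along(geneSetFiles)) {
        other <- readGeneSet(geneSetFiles[i])
        key <- paste(cond, geneSetLabel(other), sep = "_vs_")
        overlaps[[key]] <- overlapReport(
          overlapSets(hitSet, other, universeN))
      }
    }
  }
  if (length(overlaps)) {
    jsonlite::write_json(overlaps, file.path(outDir, "overlaps.json"),
                         digits = NA, auto_unbox = TRUE)
    txt <- vapply(names(overlaps), function(k) {
      o <- overlaps[[k]]
      sprintf("%s: %d of %d shared (%d%%), P = %.3g",
              k, o$n_intersection, o$n_union, o$pct_overlap, o$p_upper)
    }, character(1))
    writeLines(txt, file.path(outDir, "overlaps.txt"))
  }
  invisible(res)
}
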