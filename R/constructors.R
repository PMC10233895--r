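# Constructors and accessors.

#' Build a screen simulation configuration
#'
#' @param rows,cols plate dimensions; default the 1536 format (32 x 48).
#' @param controlOffset parity pair (row mod 2, col mod 2) of the control
#'   sub-grid; the default \code{c(0, 0)} places a control at every fourth
#'   position starting at the top-left corner.
#' @param nReplicates replicate plates per condition (default 3).
#' @param conditions condition labels, background first.
#' @param samplingInterval sampling interval in hours (default 1/3, i.e. 20
#'   minutes).
#' @param duration assay duration in hours (default 72).
#' @param baselineD wild-type doubling time in hours (default 2.5).
#' @param K carrying capacity in cells per colony (default 1e7).
#' @param N0 inoculum in cells per colony (default 1e5).
#' @param biasAmplitude amplitude of the smooth spatial bias on log2(D)
#'   (default 0.25 log2 units).
#' @param noiseSd colony-to-colony noise on log2(D) (default 0.05 log2 units).
#' @param effects strains x conditions numeric matrix of additive effects on
#'   log2(D), or a long data.frame with columns strain_id, condition, effect;
#'   unlisted strains/conditions have effect 0.
#' @param corruptionRate probability a curve is replaced by noise
#'   (default 0.003).
#' @param seed integer RNG seed.
#' @return a validated \linkS4class{ScreenConfig}.
#' @examples
#' cfg <- screenConfig(rows = 8, cols = 12, duration = 24, seed = 7)
#' @export
screenConfig <- function(rows = 32, cols = 48, controlOffset = c(0L, 0L),
                         nReplicates = 3, conditions = c("background", "stressor"),
                         samplingInterval = 1 / 3, duration = 72,
                         baselineD = 2.5, K = 1e7, N0 = 1e5,
                         biasAmplitude = 0.25, noiseSd = 0.05,
                         effects = NULL, corruptionRate = 0.003, seed = 1) {
  eff <- .effectMatrix(effects, conditions)
  new("ScreenConfig",
    rows = as.integer(rows), cols = as.integer(cols),
    controlOffset = as.integer(controlOffset),
    nReplicates = as.integer(nReplicates), conditions = as.character(conditions),
    samplingInterval = samplingInterval, duration = duration,
    baselineD = baselineD, K = K, N0 = N0,
    biasAmplitude = biasAmplitude, noiseSd = noiseSd,
    effects = eff, corruptionRate = corruptionRate, seed = as.integer(seed)
  )
}

# Normalize the user-supplied effect specification to a strains x conditions
# matrix. NULL -> 0-row matrix (all effects zero).
.effectMatrix <- function(effects, conditions) {
  if (is.null(effects)) {
    return(matrix(numeric(0), nrow = 0, ncol = length(conditions),
                  dimnames = list(character(0), conditions)))
  }
  if (is.data.frame(effects)) {
    need <- c("strain_id", "condition", "effect")
    if (!all(need %in% names(effects)))
      stop("effects data.frame needs columns strain_id, condition, effect")
    bad <- setdiff(unique(effects$condition), conditions)
    if (length(bad))
      stop("effects reference unknown conditions: ", paste(bad, collapse = ", "))
    strains <- unique(effects$strain_id)
    m <- matrix(0, nrow = length(strains), ncol = length(conditions),
                dimnames = list(strains, conditions))
    m[cbind(match(effects$strain_id, strains),
            match(effects$condition, conditions))] <- effects$effect
    return(m)
  }
  if (is.matrix(effects)) {
    if (is.null(rownames(effects)) || is.null(colnames(effects)))
      stop("effects matrix must carry strain rownames and condition colnames")
    bad <- setdiff(colnames(effects), conditions)
    if (length(bad))
      stop("effects reference unknown conditions: ", paste(bad, collapse = ", "))
    m <- matrix(0, nrow = nrow(effects), ncol = length(conditions),
                dimnames = list(rownames(effects), conditions))
    m[, colnames(effects)] <- effects
    return(m)
  }
  stop("effects must be NULL, a matrix or a data.frame")
}

#' Build a phenotype-calling configuration
#'
#' Defaults implement the dual calling criterion: Benjamini-Hochberg FDR at
#' alpha = 0.01 combined with a strong-effect gate |mean LPI| >= 2.5 (a
#' 5.6-fold change in doubling time), with slow growers on the background
#' medium excluded beforehand.
#'
#' @param alpha FDR level (default 0.01).
#' @param effectThreshold strong-effect gate in log2 units (default 2.5).
#' @param nReplicates nominal replicates (default 3).
#' @param slowGrowerCutoff exclusion cutoff on mean background log2(D)_norm
#'   (default 1.5 log2 units, about 2.8-fold slower than the controls).
#' @param symmetricResistance also call resistance at mean LPI <=
#'   -effectThreshold (default TRUE).
#' @return a validated \linkS4class{CallConfig}.
#' @export
callConfig <- function(alpha = 0.01, effectThreshold = 2.5, nReplicates = 3,
                       slowGrowerCutoff = 1.5, symmetricResistance = TRUE) {
  new("CallConfig",
    alpha = alpha, effectThreshold = effectThreshold,
    nReplicates = as.integer(nReplicates),
    slowGrowerCutoff = slowGrowerCutoff,
    symmetricResistance = symmetricResistance
  )
}

#' Construct a growth curve set
#'
#' @param values colonies x timepoints numeric matrix of population sizes or
#'   intensities.
#' @param times sampling times in hours, strictly increasing, one per column.
#' @param colonyInfo data.frame with one row per colony; must contain
#'   plate_id, row, col (0-based coordinates).
#' @return a \linkS4class{GrowthCurveSet}.
#' @export
GrowthCurveSet <- function(values, times, colonyInfo) {
  stopifnot(is.matrix(values), nrow(values) == nrow(colonyInfo),
            ncol(values) == length(times))
  info <- as.data.frame(colonyInfo)
  rownames(info) <- NULL
  dimnames(values) <- NULL
  se <- SummarizedExperiment(
    assays = list(value = values),
    rowData = DataFrame(info, row.names = NULL),
    colData = DataFrame(time_h = as.numeric(times))
  )
  new("GrowthCurveSet", se)
}

#' @describeIn GrowthCurveSet sampling times (hours).
#' @param x a \code{GrowthCurveSet}.
#' @export
curveTimes <- function(x) colData(x)$time_h

#' @describeIn GrowthCurveSet the colonies x timepoints value matrix.
#' @export
curveValues <- function(x) assay(x, "value")

#' @describeIn GrowthCurveSet per-colony metadata as a data.frame.
#' @export
colonyInfo <- function(x) as.data.frame(rowData(x))

#' Construct a gene set
#'
#' Identifiers are upper-cased and de-duplicated (matching on systematic gene
#' names is case-insensitive; no alias resolution is attempted).
#'
#' @param label set label.
#' @param members character vector of gene identifiers.
#' @return a \linkS4class{GeneSet}.
#' @examples
#' geneSet("ca", c("pmr1", "CCH1", "cnb1"))
#' @export
geneSet <- function(label, members) {
  m <- unique(toupper(as.character(members)))
  m <- m[nzchar(m)]
  new("GeneSet", label = as.character(label), members = m)
}

#' @describeIn geneSet the member identifiers.
#' @param x a \code{GeneSet}.
#' @export
geneSetMembers <- function(x) x@members

#' @describeIn geneSet the set label.
#' @export
geneSetLabel <- function(x) x@label

# --- accessors for SimulatedScreen and PlateLayout ---

#' @describeIn simulateScreen growth curves of a simulated screen.
#' @param x a \code{SimulatedScreen}.
#' @export
screenCurves <- function(x) x@curves

#' @describeIn simulateScreen per-plate layouts (named list).
#' @export
screenLayouts <- function(x) x@layouts

#' @describeIn simulateScreen simulation ground truth.
#' @export
screenTruth <- function(x) x@truth

#' @describeIn makeLayout strain matrix of a layout.
#' @param x a \code{PlateLayout}.
#' @export
layoutStrains <- function(x) x@strains

#' @describeIn makeLayout logical control mask of a layout.
#' @export
layoutControls <- function(x) x@isControl

#' Flatten a plate layout to a long table
#'
#' @param x a \linkS4class{PlateLayout}.
#' @param row.names,optional,... ignored; present for method compatibility.
#' @return data.frame with plate_id, row, col (0-based), strain_id,
#'   is_control, condition, replicate; empty positions are dropped.
#' @export
as.data.frame.PlateLayout <- function(x, row.names = NULL, optional = FALSE, ...) {
  nr <- nrow(x@strains); nc <- ncol(x@strains)
  df <- data.frame(
    plate_id = x@plateId,
    row = rep(seq_len(nr) - 1L, times = nc),
    col = rep(seq_len(nc) - 1L, each = nr),
    strain_id = as.vector(x@strains),
    is_control = as.vector(x@isControl),
    condition = x@condition,
    replicate = x@replicate,
    stringsAsFactors = FALSE
  )
  df <- df[!is.na(df$strain_id), , drop = FALSE]
  df <- df[order(df$row, df$col), , drop = FALSE]
  rownames(df) <- NULL
  df
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig:", object@rows, "x", object@cols, "plate,",
      sum(.controlMask(object@rows, object@cols, object@controlOffset)),
      "controls\n")
  cat("  conditions:", paste(object@conditions, collapse = ", "),
      "| replicates:", object@nReplicates, "\n")
  cat("  sampling:", signif(object@samplingInterval, 3), "h for",
      object@duration, "h | baseline D:", object@baselineD, "h\n")
  cat("  bias:", object@biasAmplitude, "| noise:", object@noiseSd,
      "| corruption:", object@corruptionRate,
      "| seed:", object@seed, "\n")
})

setMethod("show", "PlateLayout", function(object) {
  cat("PlateLayout", object@plateId, ":", nrow(object@strains), "x",
      ncol(object@strains), "|", sum(object@isControl), "controls |",
      sum(!is.na(object@strains) & !object@isControl), "strains |",
      object@condition, "r", object@replicate, "\n")
})

setMethod("show", "SimulatedScreen", function(object) {
  cat("SimulatedScreen:", length(object@layouts), "plates,",
      nrow(object@curves), "curves,", ncol(object@curves), "timepoints\n")
  cat("  seed:", object@truth$seed, "| corrupted:",
      nrow(object@truth$corrupted), "\n")
})

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet", object@label, ":", length(object@members), "genes\n")
})

setMethod("show", "OverlapResult", function(object) {
  cat(sprintf("Overlap %s (n=%d) vs %s (n=%d): %d shared (%d%% of union %d)\n",
              object@labelA, object@nA, object@labelB, object@nB,
              object@nIntersection, round(object@pctOverlap), object@nUnion))
  cat(sprintf("  hypergeometric P(X >= %d) = %.3g (universe %d)\n",
              object@nIntersection, object@pUpper, object@universeN))
})
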