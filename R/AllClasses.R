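# S4 classes for screen configuration, plate data and results.

#' Screen simulation configuration
#'
#' Parameters of the synthetic screen generator. Defaults describe the screen
#' design the pipeline targets: 1536-colony plates (32 x 48) with 384
#' interleaved control colonies at every fourth position, three replicates per
#' condition, logistic colony growth sampled every 20 minutes for 72 hours
#' from an inoculum of ~1e5 cells, a smooth spatial bias on the log2 doubling
#' time, and a small rate of corrupted curves.
#'
#' @slot rows,cols plate dimensions (rows x cols colonies).
#' @slot controlOffset integer parity pair (row mod 2, col mod 2) selecting
#'   which of the four interleaved sub-grids carries the controls.
#' @slot nReplicates replicate plates per condition.
#' @slot conditions condition labels; the first is the background medium.
#' @slot samplingInterval,duration sampling interval and total time, hours.
#' @slot baselineD wild-type (control) doubling time, hours.
#' @slot K,N0 logistic carrying capacity and inoculum, cells per colony.
#' @slot biasAmplitude amplitude of the spatial bias surface, log2(D) units.
#' @slot noiseSd colony-to-colony noise on log2(D), log2 units.
#' @slot effects numeric matrix (strains x conditions) of additive effects on
#'   log2(D); positive = slower growth = sensitivity.
#' @slot corruptionRate probability that a colony's curve is corrupted.
#' @slot seed integer RNG seed.
#' @aliases ScreenConfig
#' @exportClass ScreenConfig
setClass("ScreenConfig",
  representation(
    rows = "integer", cols = "integer", controlOffset = "integer",
    nReplicates = "integer", conditions = "character",
    samplingInterval = "numeric", duration = "numeric",
    baselineD = "numeric", K = "numeric", N0 = "numeric",
    biasAmplitude = "numeric", noiseSd = "numeric",
    effects = "matrix", corruptionRate = "numeric", seed = "integer"
  )
)

setValidity("ScreenConfig", function(object) {
  msg <- character()
  if ((object@rows * object@cols) %% 4L != 0L)
    msg <- c(msg, "rows * cols must be divisible by 4")
  if (object@samplingInterval <= 0) msg <- c(msg, "samplingInterval must be > 0")
  if (object@duration <= 0) msg <- c(msg, "duration must be > 0")
  if (object@N0 >= object@K) msg <- c(msg, "N0 must be < K")
  if (object@N0 <= 0 || object@K <= 0) msg <- c(msg, "N0 and K must be positive")
  if (object@baselineD <= 0) msg <- c(msg, "baselineD must be > 0")
  if (object@corruptionRate < 0 || object@corruptionRate >= 1)
    msg <- c(msg, "corruptionRate must be in [0, 1)")
  if (length(object@conditions) < 2L || anyDuplicated(object@conditions))
    msg <- c(msg, "conditions must hold a background plus >= 1 distinct stressor")
  if (length(object@controlOffset) != 2L ||
      !all(object@controlOffset %in% c(0L, 1L)))
    msg <- c(msg, "controlOffset must be a parity pair in {0,1} x {0,1}")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Phenotype-calling configuration
#'
#' @slot alpha FDR level for the Benjamini-Hochberg step-up procedure.
#' @slot effectThreshold strong-effect gate on |mean LPI|, log2 units.
#' @slot nReplicates nominal replicates per condition.
#' @slot slowGrowerCutoff exclusion cutoff on mean background log2(D)_norm.
#' @slot symmetricResistance call resistance at mean LPI <= -effectThreshold.
#' @aliases CallConfig
#' @exportClass CallConfig
setClass("CallConfig",
  representation(
    alpha = "numeric", effectThreshold = "numeric", nReplicates = "integer",
    slowGrowerCutoff = "numeric", symmetricResistance = "logical"
  )
)

setValidity("CallConfig", function(object) {
  msg <- character()
  if (object@alpha <= 0 || object@alpha >= 1) msg <- c(msg, "alpha must be in (0, 1)")
  if (object@effectThreshold <= 0) msg <- c(msg, "effectThreshold must be > 0")
  if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Plate layout
#'
#' Geometry and annotation of one plate: which strain sits at each (row, col)
#' position, which positions carry the interleaved reference (control)
#' colonies, and the condition/replicate labels of the plate. Coordinates are
#' 0-based, row-major.
#'
#' @slot plateId plate identifier.
#' @slot strains character matrix (rows x cols) of strain identifiers; NA for
#'   empty positions.
#' @slot isControl logical matrix marking control positions.
#' @slot condition,replicate condition label and replicate index of the plate.
#' @aliases PlateLayout
#' @exportClass PlateLayout
setClass("PlateLayout",
  representation(
    plateId = "character", strains = "matrix", isControl = "matrix",
    condition = "character", replicate = "integer"
  )
)

setValidity("PlateLayout", function(object) {
  msg <- character()
  if (!identical(dim(object@strains), dim(object@isControl)))
    msg <- c(msg, "strains and isControl must have identical dimensions")
  if (!is.logical(object@isControl)) msg <- c(msg, "isControl must be logical")
  if (any(is.na(object@strains[object@isControl])))
    msg <- c(msg, "control positions must carry the control strain id")
  if (length(msg)) msg else TRUE
})

#' Growth curve set
#'
#' A \linkS4class{SummarizedExperiment} holding one screen's growth curves:
#' the \code{"value"} assay is a colonies x timepoints matrix of population
#' sizes (cells) or calibrated intensities, \code{rowData} carries the colony
#' coordinates (\code{plate_id}, \code{row}, \code{col}) plus QC annotation,
#' and \code{colData$time_h} holds the shared sampling times in hours.
#'
#' @aliases GrowthCurveSet
#' @exportClass GrowthCurveSet
setClass("GrowthCurveSet", contains = "SummarizedExperiment")

setValidity("GrowthCurveSet", function(object) {
  msg <- character()
  cd <- colData(object)
  if (!("time_h" %in% colnames(cd))) {
    msg <- c(msg, "colData must contain time_h")
  } else {
    t <- cd$time_h
    if (length(t) > 1L && any(diff(t) <= 0))
      msg <- c(msg, "time_h must be strictly increasing")
  }
  rd <- rowData(object)
  need <- c("plate_id", "row", "col")
  if (!all(need %in% colnames(rd)))
    msg <- c(msg, "rowData must contain plate_id, row, col")
  if (length(msg)) msg else TRUE
})

#' Simulated screen
#'
#' Bundle returned by \code{\link{simulateScreen}}: the growth curves, the
#' per-plate layouts and the simulation ground truth (realized bias surface,
#' per-strain effects, corrupted colonies, seed).
#'
#' @slot curves a \linkS4class{GrowthCurveSet}.
#' @slot layouts named list of \linkS4class{PlateLayout} objects.
#' @slot truth list with elements \code{effects} (strains x conditions
#'   matrix), \code{bias} (rows x cols matrix), \code{corrupted} (data.frame
#'   plate_id/row/col) and \code{seed}.
#' @aliases SimulatedScreen
#' @exportClass SimulatedScreen
setClass("SimulatedScreen",
  representation(curves = "GrowthCurveSet", layouts = "list", truth = "list")
)

#' Gene set
#'
#' A labelled set of unique, upper-cased gene identifiers.
#'
#' @slot label set label.
#' @slot members unique upper-case identifiers.
#' @aliases GeneSet
#' @exportClass GeneSet
setClass("GeneSet", representation(label = "character", members = "character"))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (!nzchar(object@label)) msg <- c(msg, "label must be non-empty")
  if (anyDuplicated(object@members)) msg <- c(msg, "members must be unique")
  if (any(object@members != toupper(object@members)))
    msg <- c(msg, "members must be upper-case")
  if (length(msg)) msg else TRUE
})

#' Overlap of two gene sets
#'
#' Counts, union-based overlap percentage and hypergeometric upper-tail
#' probability for the intersection of two gene sets drawn from a finite
#' universe.
#'
#' @slot labelA,labelB set labels.
#' @slot nA,nB,nIntersection,nUnion set and overlap sizes.
#' @slot pctOverlap 100 * intersection / union, rounded to nearest integer.
#' @slot universeN assumed universe size.
#' @slot pUpper P(X >= intersection) under the hypergeometric null.
#' @aliases OverlapResult
#' @exportClass OverlapResult
setClass("OverlapResult",
  representation(
    labelA = "character", labelB = "character",
    nA = "integer", nB = "integer", nIntersection = "integer",
    nUnion = "integer", pctOverlap = "numeric", universeN = "integer",
    pUpper = "numeric"
  )
)

setValidity("OverlapResult", function(object) {
  msg <- character()
  if (object@nUnion != object@nA + object@nB - object@nIntersection)
    msg <- c(msg, "union count inconsistent")
  if (object@nIntersection < 0L || object@nIntersection > min(object@nA, object@nB))
    msg <- c(msg, "intersection exceeds set sizes")
  if (object@nUnion > object@universeN)
    msg <- c(msg, "universe smaller than the union")
  if (object@pUpper < 0 || object@pUpper > 1) msg <- c(msg, "pUpper outside [0, 1]")
  if (length(msg)) msg else TRUE
})
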