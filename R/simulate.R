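# Synthetic screen generator: plate layouts, logistic colony growth, smooth
# spatial bias on log2 doubling time, replicate structure, curve corruption.

#' Logistic population growth
#'
#' Evaluates \eqn{N(t) = K N_0 e^{rt} / (K + N_0 (e^{rt} - 1))}, the
#' three-parameter logistic without lag. In exponential phase the doubling
#' time is \eqn{D = \ln 2 / r}.
#'
#' @param n0 inoculum (cells), > 0.
#' @param k carrying capacity (cells), >= n0.
#' @param r per-hour growth rate, >= 0.
#' @param times non-negative times in hours.
#' @return population sizes at \code{times}; monotone non-decreasing and
#'   bounded by \code{k}.
#' @examples
#' logisticCurve(1e5, 1e7, log(2) / 2.5, c(0, 1, 2))
#' @export
logisticCurve <- function(n0, k, r, times) {
  if (n0 <= 0 || k <= 0) stop("invalid parameter: n0 and k must be positive")
  if (k < n0) stop("invalid parameter: k must be >= n0")
  if (r < 0) stop("invalid parameter: r must be >= 0")
  if (any(times < 0)) stop("invalid parameter: times must be non-negative")
  # overflow-safe form of K N0 e^{rt} / (K + N0 (e^{rt} - 1))
  k / (1 + (k / n0 - 1) * exp(-r * times))
}

# Logical rows x cols mask of the interleaved control sub-grid at a parity
# offset: every fourth position.
.controlMask <- function(rows, cols, offset) {
  r <- (seq_len(rows) - 1L) %% 2L == offset[1]
  c <- (seq_len(cols) - 1L) %% 2L == offset[2]
  outer(r, c, `&`)
}

#' Lay out strains and interleaved controls on a plate
#'
#' Controls occupy every fourth position (one of the four parity sub-grids),
#' as in 1536-colony screens where 384 fixed reference colonies are
#' interleaved among 1152 experimental colonies. Experimental strains fill
#' the remaining positions deterministically in row-major order; surplus
#' positions stay empty.
#'
#' @param config a \linkS4class{ScreenConfig} (only geometry fields are used).
#' @param strainIds experimental strain identifiers, at most
#'   \code{rows * cols * 3/4}.
#' @param plateId,condition,replicate plate annotation.
#' @param controlId identifier used for control colonies.
#' @return a \linkS4class{PlateLayout}.
#' @examples
#' lay <- makeLayout(screenConfig(), sprintf("strain%04d", 1:1152))
#' sum(layoutControls(lay))  # 384
#' @export
makeLayout <- function(config, strainIds, plateId = "plate1",
                       condition = config@conditions[1], replicate = 1L,
                       controlId = "his3d_control") {
  rows <- config@rows; cols <- config@cols
  ctrl <- .controlMask(rows, cols, config@controlOffset)
  capacity <- rows * cols - sum(ctrl)
  if (length(strainIds) > capacity)
    stop("capacity error: ", length(strainIds), " strains exceed ",
         capacity, " experimental positions")
  if (anyDuplicated(strainIds)) stop("strainIds must be unique")
  strains <- matrix(NA_character_, rows, cols)
  strains[ctrl] <- controlId
  # row-major fill of experimental positions
  open <- which(t(!ctrl))                       # t(): row-major order
  openRM <- arrayInd(open, c(cols, rows))       # (col, row) pairs
  take <- seq_along(strainIds)
  strains[cbind(openRM[take, 2], openRM[take, 1])] <- strainIds
  new("PlateLayout", plateId = plateId, strains = strains, isControl = ctrl,
      condition = condition, replicate = as.integer(replicate))
}

# Smooth spatial bias surface on log2(D): linear gradient plus one
# low-frequency sinusoid, scaled so that max|bias| = amplitude.
.biasSurface <- function(rows, cols, amplitude) {
  if (amplitude == 0) return(matrix(0, rows, cols))
  r <- (seq_len(rows) - 1) / max(rows - 1, 1)
  c <- (seq_len(cols) - 1) / max(cols - 1, 1)
  lin <- outer(r - 0.5, c - 0.5, `+`)
  sin2d <- outer(sin(pi * r), cos(pi * c))
  raw <- 0.5 * lin + 0.5 * sin2d
  amplitude * raw / max(abs(raw))
}

#' Simulate a complete chemical-genomic screen
#'
#' For every condition x replicate, generates one plate of logistic growth
#' curves. Each colony's log2 doubling time is
#' \code{log2(baselineD) + bias(position) + effect(strain, condition) +
#' noise}; control colonies have effect 0 in every condition, the bias
#' surface is shared by all plates (so control interpolation can remove it),
#' and a small fraction of curves is replaced by high-variance noise around
#' the inoculum (corrupted curves, designed to fail QC). Fully reproducible
#' from \code{config@seed}.
#'
#' @param config a \linkS4class{ScreenConfig}.
#' @param strainIds experimental strain identifiers.
#' @param controlId identifier for control colonies.
#' @return a \linkS4class{SimulatedScreen}.
#' @examples
#' cfg <- screenConfig(rows = 4, cols = 4, duration = 12, seed = 3)
#' sim <- simulateScreen(cfg, sprintf("s%02d", 1:12))
#' @export
simulateScreen <- function(config, strainIds, controlId = "his3d_control") {
  validObject(config)
  set.seed(config@seed)
  times <- seq(0, config@duration, by = config@samplingInterval)
  bias <- .biasSurface(config@rows, config@cols, config@biasAmplitude)
  conditions <- config@conditions
  eff <- config@effects

  layouts <- list()
  valueBlocks <- list()
  infoBlocks <- list()
  corrupted <- list()
  effectAt <- function(strain, condition) {
    if (strain %in% rownames(eff)) eff[strain, condition] else 0
  }
  for (cond in conditions) {
    for (rep in seq_len(config@nReplicates)) {
      plateId <- sprintf("%s_r%d", cond, rep)
      lay <- makeLayout(config, strainIds, plateId = plateId,
                        condition = cond, replicate = rep,
                        controlId = controlId)
      layouts[[plateId]] <- lay
      df <- as.data.frame(lay)
      pos <- cbind(df$row + 1L, df$col + 1L)
      strainEff <- vapply(df$strain_id, effectAt, numeric(1), condition = cond)
      strainEff[df$is_control] <- 0
      log2D <- log2(config@baselineD) + bias[pos] + strainEff +
        rnorm(nrow(df), 0, config@noiseSd)
      r <- log(2) / 2^log2D
      values <- config@K /
        (1 + (config@K / config@N0 - 1) * exp(-outer(r, times)))
      corrupt <- runif(nrow(df)) < config@corruptionRate
      if (any(corrupt)) {
        nT <- length(times)
        values[corrupt, ] <- config@N0 *
          exp(matrix(rnorm(sum(corrupt) * nT, 0, 0.5), ncol = nT))
        corrupted[[plateId]] <- df[corrupt, c("plate_id", "row", "col")]
      }
      valueBlocks[[plateId]] <- values
      infoBlocks[[plateId]] <- df[, c("plate_id", "row", "col")]
    }
  }
  curves <- GrowthCurveSet(
    do.call(rbind, valueBlocks), times, do.call(rbind, infoBlocks)
  )
  corruptedDf <- if (length(corrupted)) do.call(rbind, corrupted) else
    data.frame(plate_id = character(0), row = integer(0), col = integer(0))
  rownames(corruptedDf) <- NULL
  truthEff <- matrix(0, nrow = length(strainIds), ncol = length(conditions),
                     dimnames = list(strainIds, conditions))
  shared <- intersect(rownames(eff), strainIds)
  truthEff[shared, ] <- eff[shared, conditions]
  new("SimulatedScreen", curves = curves, layouts = layouts,
      truth = list(effects = truthEff, bias = bias, corrupted = corruptedDf,
                   seed = config@seed))
}

#' Simulate normalized phenotypes directly
#'
#' Generates the per-strain, per-condition, per-replicate normalized log2
#' doubling times that the calling stage consumes, bypassing curve
#' simulation: \code{log2D_norm = effect(strain, condition) + N(0,
#' noiseSd)}. Useful for large calibration experiments (e.g. null false-call
#' rates over many seeds) where the curve and normalization stages are not
#' under study.
#'
#' @param strainIds strain identifiers.
#' @param conditions condition labels, background first.
#' @param nReplicates replicates per condition.
#' @param noiseSd replicate noise on log2(D)_norm, log2 units.
#' @param effects effect specification as in \code{\link{screenConfig}}.
#' @param seed integer RNG seed.
#' @return data.frame with strain_id, condition, replicate, log2D_norm,
#'   is_control = FALSE, qc_pass = TRUE (the format \code{\link{scoreScreen}}
#'   expects).
#' @export
simulatePhenotypes <- function(strainIds, conditions = c("background", "stressor"),
                               nReplicates = 3, noiseSd = 0.05,
                               effects = NULL, seed = 1) {
  set.seed(seed)
  eff <- .effectMatrix(effects, conditions)
  grid <- expand.grid(strain_id = strainIds, condition = conditions,
                      replicate = seq_len(nReplicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- ifelse(grid$strain_id %in% rownames(eff),
               eff[cbind(match(grid$strain_id, rownames(eff)),
                         match(grid$condition, colnames(eff)))], 0)
  mu[is.na(mu)] <- 0
  grid$log2D_norm <- mu + rnorm(nrow(grid), 0, noiseSd)
  grid$is_control <- FALSE
  grid$qc_pass <- TRUE
  grid
}
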