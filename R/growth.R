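# Curve processing: intensity calibration, smoothing, quality control and
# doubling-time extraction.

#' Calibrate raw intensities to cell counts
#'
#' Applies a monotone calibration function element-wise. Negative raw values
#' (possible after background subtraction upstream) are clamped to 0 before
#' calibration.
#'
#' @param values numeric series of background-subtracted intensities.
#' @param calibration either the string \code{"identity"} or a data.frame
#'   with columns \code{intensity} and \code{cells} giving monotone
#'   non-decreasing calibration knots; intermediate values are interpolated
#'   with a monotone (Hyman-filtered) cubic spline.
#' @return numeric series of cell counts.
#' @export
calibrateIntensity <- function(values, calibration = "identity") {
  v <- pmax(values, 0)
  if (identical(calibration, "identity")) return(v)
  if (!is.data.frame(calibration) ||
      !all(c("intensity", "cells") %in% names(calibration)))
    stop("invalid calibration: need 'identity' or a data.frame with ",
         "columns intensity, cells")
  x <- calibration$intensity; y <- calibration$cells
  if (is.unsorted(x, strictly = TRUE))
    stop("invalid calibration: intensity knots must be strictly increasing")
  if (any(diff(y) < 0))
    stop("invalid calibration: cells must be monotone non-decreasing")
  f <- splinefun(x, y, method = "hyman")
  f(v)
}

# Edge-truncated rolling median of each row of a matrix. Interior positions
# use stats::runmed (C); the (w-1)/2 positions at each edge are recomputed
# with shrunken windows.
.rollMedianRows <- function(Y, w) {
  if (w == 1L) return(Y)
  h <- (w - 1L) %/% 2L
  n <- ncol(Y)
  out <- t(apply(Y, 1, function(y) runmed(y, w, endrule = "keep")))
  for (i in c(seq_len(min(h, n)), seq.int(max(n - h + 1L, 1L), n))) {
    idx <- max(1L, i - h):min(n, i + h)
    out[, i] <- apply(Y[, idx, drop = FALSE], 1, median)
  }
  out
}

# Edge-truncated rolling mean of each row, via cumulative sums.
.rollMeanRows <- function(Y, w) {
  if (w == 1L) return(Y)
  h <- (w - 1L) %/% 2L
  n <- ncol(Y)
  cs <- cbind(0, t(apply(Y, 1, cumsum)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(Y))
}

#' Smooth growth curves
#'
#' Median filter followed by a moving average, both with edge-truncated
#' (shrinking) windows, so the series length is preserved. The median pass
#' removes isolated spikes; the mean pass damps residual jitter.
#'
#' @param x a \linkS4class{GrowthCurveSet}, or a numeric vector (one curve).
#' @param medianWindow,meanWindow odd window widths in points (defaults 5).
#' @return object of the same kind as \code{x} with smoothed values.
#' @export
smoothCurves <- function(x, medianWindow = 5, meanWindow = 5) {
  for (w in c(medianWindow, meanWindow)) {
    if (w < 1 || w %% 2 == 0) stop("invalid parameter: windows must be odd and >= 1")
  }
  vec <- is.numeric(x) && is.null(dim(x))
  Y <- if (vec) matrix(x, nrow = 1) else curveValues(x)
  if (min(medianWindow, meanWindow) > ncol(Y))
    stop("invalid parameter: window exceeds series length")
  Y <- .rollMeanRows(.rollMedianRows(Y, as.integer(medianWindow)),
                     as.integer(meanWindow))
  if (vec) return(as.vector(Y))
  assay(x, "value") <- Y
  x
}

#' Quality-control growth curves
#'
#' Flags curves with (i) insufficient dynamic range (max/min fold change
#' below \code{minFold}), (ii) excessive non-monotonicity (fraction of
#' strictly decreasing steps above \code{maxDecreasingFrac}; a genuine
#' growth curve rises then plateaus, whereas a corrupted one jitters), or
#' (iii) too few time points. An empty flag set means pass.
#'
#' @param x a \linkS4class{GrowthCurveSet} (calibrated, smoothed), or a
#'   numeric vector (one curve).
#' @param minFold minimum max/min fold change (default 2).
#' @param maxDecreasingFrac maximum tolerated fraction of decreasing steps
#'   (default 0.25).
#' @param minPoints minimum number of time points (default 10).
#' @return for a vector, a character vector of flags (empty = pass); for a
#'   \code{GrowthCurveSet}, the object with \code{qc_flags} (";"-separated)
#'   and \code{qc_pass} added to its \code{rowData}.
#' @export
qcCurves <- function(x, minFold = 2, maxDecreasingFrac = 0.25, minPoints = 10) {
  flagRow <- function(y) {
    flags <- character(0)
    if (length(y) < minPoints) flags <- c(flags, "too_few_points")
    mx <- max(y); mn <- min(y)
    if (mx <= 0 || (mn > 0 && mx / mn < minFold))
      flags <- c(flags, "dynamic_range")
    if (length(y) >= 2 && mean(diff(y) < 0) > maxDecreasingFrac)
      flags <- c(flags, "non_monotone")
    flags
  }
  if (is.numeric(x) && is.null(dim(x))) return(flagRow(x))
  Y <- curveValues(x)
  flags <- apply(Y, 1, function(y) paste(flagRow(y), collapse = ";"))
  rowData(x)$qc_flags <- unname(flags)
  rowData(x)$qc_pass <- !nzchar(flags)
  x
}

# Rolling-window least-squares of log2(value) on time for every row of a
# value matrix. Returns per-row slope (doublings/hour), r2 and start index of
# the best (steepest, adequately fitting) window.
.maxSlopeFit <- function(Y, times, window, minR2) {
  n <- ncol(Y)
  w <- as.integer(window)
  L <- log2(Y)
  bad <- !is.finite(L)
  L0 <- ifelse(bad, 0, L)
  rc <- function(M) cbind(0, t(apply(M, 1, cumsum)))
  csY <- rc(L0); csY2 <- rc(L0^2)
  csXY <- rc(sweep(L0, 2, times, `*`))
  csBad <- rc(matrix(as.numeric(bad), nrow = nrow(Y)))
  cx <- c(0, cumsum(times)); cx2 <- c(0, cumsum(times^2))
  starts <- seq_len(n - w + 1L)
  ends <- starts + w - 1L
  Sx <- cx[ends + 1L] - cx[starts]
  Sxx <- cx2[ends + 1L] - cx2[starts]
  dxx <- w * Sxx - Sx^2
  win <- function(cs) cs[, ends + 1L, drop = FALSE] - cs[, starts, drop = FALSE]
  Sy <- win(csY); Syy <- win(csY2); Sxy <- win(csXY); nBad <- win(csBad)
  num <- w * Sxy - outer(rep(1, nrow(Y)), Sx) * Sy
  slope <- num / rep(dxx, each = nrow(Y))
  dyy <- w * Syy - Sy^2
  r2 <- num^2 / (rep(dxx, each = nrow(Y)) * dyy)
  ok <- nBad == 0 & is.finite(slope) & slope > 0 & is.finite(r2) & r2 >= minR2
  slope[!ok] <- NA_real_
  best <- apply(slope, 1, function(s) if (all(is.na(s))) NA_integer_
                else which.max(s))
  idx <- cbind(seq_len(nrow(Y)), best)
  list(slope = ifelse(is.na(best), NA_real_, slope[idx]),
       r2 = ifelse(is.na(best), NA_real_, r2[idx]),
       window_start = best)
}

#' Estimate the doubling time of one curve
#'
#' Slides a fixed-width window along the curve, regresses log2(value) on
#' time within each window (slope in doublings per hour), and takes the
#' steepest window whose coefficient of determination reaches \code{minR2}.
#' The doubling time is the reciprocal of that maximal slope, i.e. growth is
#' scored in the fastest (exponential) phase.
#'
#' @param times sampling times in hours.
#' @param values positive population sizes, same length.
#' @param window window width in points (default 7, about 2 h at 20-minute
#'   sampling).
#' @param minR2 minimum within-window r-squared (default 0.95).
#' @return list with \code{D} (hours), \code{log2D}, \code{r2},
#'   \code{window_start} (1-based index) and \code{window_length}.
#' @examples
#' estimateDoublingTime(0:5, 2^(0:5))$D  # exactly 1 hour
#' @export
estimateDoublingTime <- function(times, values, window = 7, minR2 = 0.95) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (window < 3) stop("invalid parameter: window must be >= 3")
  if (length(values) < window) stop("invalid parameter: window exceeds series")
  fit <- .maxSlopeFit(matrix(values, nrow = 1), times, window, minR2)
  if (is.na(fit$slope))
    stop("no-growth error: no window with positive slope and r2 >= ", minR2)
  list(D = 1 / fit$slope, log2D = log2(1 / fit$slope), r2 = fit$r2,
       window_start = fit$window_start, window_length = as.integer(window))
}

#' Estimate doubling times for a whole curve set
#'
#' Vectorized form of \code{\link{estimateDoublingTime}} over all colonies of
#' a \linkS4class{GrowthCurveSet}. Colonies that failed QC (see
#' \code{\link{qcCurves}}) or yield no acceptable growth window are reported
#' with \code{NA} estimates and \code{qc_pass = FALSE} (flag
#' \code{no_growth}).
#'
#' @param x a \linkS4class{GrowthCurveSet}, ideally QC-annotated.
#' @param window,minR2 as in \code{\link{estimateDoublingTime}}.
#' @return data.frame with plate_id, row, col, D_hours, log2D, r2,
#'   window_start, qc_pass, flags.
#' @export
estimateDoublingTimes <- function(x, window = 7, minR2 = 0.95) {
  info <- colonyInfo(x)
  if (is.null(info$qc_pass)) {
    info$qc_pass <- TRUE
    info$qc_flags <- ""
  }
  Y <- curveValues(x)
  out <- data.frame(info[, c("plate_id", "row", "col")],
                    D_hours = NA_real_, log2D = NA_real_, r2 = NA_real_,
                    window_start = NA_integer_,
                    qc_pass = info$qc_pass, flags = info$qc_flags,
                    stringsAsFactors = FALSE)
  use <- which(info$qc_pass)
  if (length(use)) {
    fit <- .maxSlopeFit(Y[use, , drop = FALSE], curveTimes(x), window, minR2)
    out$D_hours[use] <- 1 / fit$slope
    out$log2D[use] <- log2(out$D_hours[use])
    out$r2[use] <- fit$r2
    out$window_start[use] <- fit$window_start
    noGrowth <- use[is.na(fit$slope)]
    out$qc_pass[noGrowth] <- FALSE
    out$flags[noGrowth] <- ifelse(nzchar(out$flags[noGrowth]),
                                  paste0(out$flags[noGrowth], ";no_growth"),
                                  "no_growth")
  }
  rownames(out) <- NULL
  out
}
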