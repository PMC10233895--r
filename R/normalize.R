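# Spatial normalization: interpolate the control-colony log2(D) surface and
# subtract it from every colony.

#' Fit the control log2(D) surface of a plate
#'
#' Gaussian-kernel locally weighted mean (Nadaraya-Watson) of the control
#' values, evaluated at every plate position: the estimate at position p is
#' \eqn{\sum_i w_i v_i / \sum_i w_i} with \eqn{w_i = \exp(-d(p, i)^2 / (2
#' b^2))} over the usable controls. Being a convex combination, the surface
#' is defined everywhere and bounded by the range of the control values; the
#' kernel average is robust to individual noisy controls, unlike exact
#' interpolation.
#'
#' @param positions integer matrix (n x 2) of 0-based (row, col) control
#'   coordinates.
#' @param values control log2 doubling times, one per position; NA values
#'   are dropped from the fit.
#' @param dims plate dimensions c(rows, cols).
#' @param bandwidth Gaussian kernel scale in grid units (default 0.8; controls
#'   sit 2 grid units apart, so each position still averages over many
#'   controls while keeping the smoothing bias of the kernel mean small).
#' @return rows x cols numeric matrix of interpolated control log2(D).
#' @export
fitControlSurface <- function(positions, values, dims, bandwidth = 0.8) {
  if (bandwidth <= 0) stop("invalid parameter: bandwidth must be > 0")
  positions <- as.matrix(positions)
  keep <- is.finite(values)
  positions <- positions[keep, , drop = FALSE]
  values <- values[keep]
  if (length(values) < 4)
    stop("insufficient controls: need >= 4 usable control values, have ",
         length(values))
  rows <- dims[1]; cols <- dims[2]
  gr <- rep(seq_len(rows) - 1L, times = cols)
  gc <- rep(seq_len(cols) - 1L, each = rows)
  d2 <- outer(gr, positions[, 1], `-`)^2 + outer(gc, positions[, 2], `-`)^2
  W <- exp(-d2 / (2 * bandwidth^2))
  matrix(as.vector(W %*% values) / rowSums(W), rows, cols)
}

#' Normalize one plate against its control surface
#'
#' Subtracts the interpolated control value at each colony's position from
#' its log2 doubling time, yielding the normalized relative log2 doubling
#' time log2(D)_norm. Colonies with missing estimates (QC failures)
#' propagate as NA.
#'
#' @param phenotypes data.frame with columns row, col (0-based) and log2D.
#' @param surface rows x cols matrix from \code{\link{fitControlSurface}}.
#' @return \code{phenotypes} with columns \code{control_surface} and
#'   \code{log2D_norm} appended.
#' @export
normalizePlate <- function(phenotypes, surface) {
  if (any(phenotypes$row >= nrow(surface)) || any(phenotypes$col >= ncol(surface)))
    stop("dimension error: colony positions fall outside the surface")
  sv <- surface[cbind(phenotypes$row + 1L, phenotypes$col + 1L)]
  phenotypes$control_surface <- sv
  phenotypes$log2D_norm <- phenotypes$log2D - sv
  phenotypes
}

#' Normalize a whole screen
#'
#' Joins doubling-time estimates with the plate layouts, fits a control
#' surface per plate from the QC-passed control colonies, and subtracts it.
#' Normalization is strictly per plate; no information is shared across
#' plates.
#'
#' @param estimates per-colony doubling-time table from
#'   \code{\link{estimateDoublingTimes}}.
#' @param layouts named list of \linkS4class{PlateLayout} objects (one per
#'   plate_id present in \code{estimates}).
#' @param bandwidth kernel scale passed to \code{\link{fitControlSurface}}.
#' @return data.frame with plate_id, condition, replicate, row, col,
#'   strain_id, is_control, log2D, control_surface, log2D_norm, qc_pass,
#'   flags.
#' @export
normalizeScreen <- function(estimates, layouts, bandwidth = 0.8) {
  layoutDf <- do.call(rbind, lapply(layouts, as.data.frame))
  merged <- merge(layoutDf, estimates, by = c("plate_id", "row", "col"),
                  sort = FALSE)
  out <- lapply(split(merged, merged$plate_id), function(pl) {
    lay <- layouts[[pl$plate_id[1]]]
    dims <- dim(layoutStrains(lay))
    ctrl <- pl[pl$is_control & pl$qc_pass & is.finite(pl$log2D), , drop = FALSE]
    surface <- fitControlSurface(as.matrix(ctrl[, c("row", "col")]),
                                 ctrl$log2D, dims, bandwidth)
    normalizePlate(pl, surface)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$plate_id, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  cols <- c("plate_id", "condition", "replicate", "row", "col", "strain_id",
            "is_control", "log2D", "control_surface", "log2D_norm",
            "qc_pass", "flags")
  out[, intersect(cols, names(out)), drop = FALSE]
}
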