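# LPI computation and phenotype calling: slow-grower exclusion, replicate
# LPIs, one-sample t-test, Benjamini-Hochberg FDR, dual-criterion calls.

#' Exclude slow growers on the background medium
#'
#' Strains whose mean normalized log2 doubling time on the background medium
#' is at or above the cutoff grow too slowly for a reliable stressor
#' phenotype and receive no call.
#'
#' @param backgroundMeans named numeric vector, strain -> mean background
#'   log2(D)_norm.
#' @param cutoff exclusion cutoff in log2 units (default 1.5, about 2.8-fold
#'   slower than the controls).
#' @return character vector of excluded strain identifiers.
#' @export
excludeSlowGrowers <- function(backgroundMeans, cutoff = 1.5) {
  names(backgroundMeans)[is.finite(backgroundMeans) & backgroundMeans >= cutoff]
}

#' Compute the Logarithmic Phenotypic Index
#'
#' The LPI of a strain under a stressor is its mean normalized log2 doubling
#' time on the stressor medium minus that on the background medium. For the
#' per-strain t-test, replicate-level LPIs are defined as each stressor
#' replicate minus the background mean (the background mean is a shared
#' offset, so the replicate spread reflects stressor-plate variation).
#' A positive LPI means slower growth under the stressor than the controls,
#' i.e. sensitivity; a negative LPI means resistance.
#'
#' @param stressorValues replicate log2(D)_norm values on the stressor
#'   medium (>= 2 usable).
#' @param backgroundValues replicate log2(D)_norm values on the background
#'   medium (>= 1 usable).
#' @return list with \code{replicates} (stressor replicate minus background
#'   mean) and \code{mean} (difference of condition means).
#' @examples
#' computeLPI(c(2.0, 2.2, 2.4), c(0.1, 0, -0.1))$mean  # 2.2
#' @export
computeLPI <- function(stressorValues, backgroundValues) {
  s <- stressorValues[is.finite(stressorValues)]
  b <- backgroundValues[is.finite(backgroundValues)]
  if (length(s) < 2 || length(b) < 1)
    stop("missing data: need >= 2 stressor and >= 1 background replicates")
  reps <- s - mean(b)
  list(replicates = reps, mean = mean(reps))
}

#' Benjamini-Hochberg false discovery control
#'
#' Step-up procedure: q for the i-th p-value is the smallest
#' \eqn{p_{(j)} m / j} over sorted p-values at or above it, capped at 1.
#' Input order is preserved.
#'
#' @param p p-values in [0, 1].
#' @param alpha FDR level for the rejection flags (default 0.05).
#' @return list with \code{q} (adjusted p-values) and \code{rejected}
#'   (\code{q <= alpha}).
#' @export
bhFDR <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("invalid input: p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, rejected = q <= alpha)
}

# One-sample two-sided t-test of x against 0 with the zero-variance
# convention: sd 0 with nonzero mean -> p = 0; sd 0 with mean 0 -> p = 1.
.oneSampleT <- function(x) {
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf,
                p = if (m == 0) 1 else 0))
  }
  ht <- t.test(x, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Call sensitive and resistant phenotypes
#'
#' For each strain x stressor record, tests the replicate LPIs against 0 with
#' a two-sided one-sample t-test (df = n - 1), adjusts p-values per condition
#' with Benjamini-Hochberg, and applies the dual criterion: \emph{sensitive}
#' requires q <= alpha and mean LPI >= effectThreshold; \emph{resistant}
#' (when enabled) requires q <= alpha and mean LPI <= -effectThreshold.
#' Strains listed in \code{excluded} are reported with call
#' \code{"excluded"}; replicate sets of fewer than two values are reported
#' uncalled (\code{"none"} with NA statistics).
#'
#' @param lpi long data.frame with columns strain_id, condition and lpi
#'   (one row per replicate).
#' @param config a \linkS4class{CallConfig}.
#' @param excluded strain identifiers excluded as slow growers.
#' @return data.frame with strain_id, condition, n_replicates, lpi_mean,
#'   t_stat, p_value, q_value, call.
#' @export
callPhenotypes <- function(lpi, config = callConfig(), excluded = character(0)) {
  validObject(config)
  stopifnot(all(c("strain_id", "condition", "lpi") %in% names(lpi)))
  recs <- lapply(split(lpi, lpi[c("condition", "strain_id")], drop = TRUE),
    function(d) {
      x <- d$lpi[is.finite(d$lpi)]
      data.frame(strain_id = d$strain_id[1], condition = d$condition[1],
                 n_replicates = length(x),
                 lpi_mean = if (length(x)) mean(x) else NA_real_,
                 t_stat = NA_real_, p_value = NA_real_,
                 stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  testable <- out$n_replicates >= 2 & !(out$strain_id %in% excluded)
  if (any(testable)) {
    byRec <- split(lpi, lpi[c("condition", "strain_id")], drop = TRUE)
    key <- paste(out$condition, out$strain_id, sep = ".")
    for (i in which(testable)) {
      x <- byRec[[key[i]]]$lpi
      x <- x[is.finite(x)]
      tt <- .oneSampleT(x)
      out$t_stat[i] <- tt$t
      out$p_value[i] <- tt$p
    }
  }
  out$q_value <- NA_real_
  for (cond in unique(out$condition)) {
    sel <- which(out$condition == cond & testable & !is.na(out$p_value))
    if (length(sel)) out$q_value[sel] <- bhFDR(out$p_value[sel])$q
  }
  out$call <- "none"
  sig <- !is.na(out$q_value) & out$q_value <= config@alpha
  out$call[sig & out$lpi_mean >= config@effectThreshold] <- "sensitive"
  if (config@symmetricResistance)
    out$call[sig & out$lpi_mean <= -config@effectThreshold] <- "resistant"
  out$call[out$strain_id %in% excluded] <- "excluded"
  out[order(out$condition, out$strain_id), , drop = FALSE]
}

#' Score a normalized screen: exclusion, LPI and calls
#'
#' End-to-end calling stage. From a normalized phenotype table
#' (experimental, QC-passed colonies), computes per-strain background means,
#' excludes slow growers, forms replicate LPIs for every stressor condition
#' and calls phenotypes with the dual criterion.
#'
#' @param phenotypes data.frame with columns strain_id, condition, replicate,
#'   log2D_norm and optionally is_control, qc_pass (as produced by
#'   \code{\link{normalizeScreen}} or \code{\link{simulatePhenotypes}}).
#' @param config a \linkS4class{CallConfig}.
#' @param background label of the background condition (default
#'   \code{"background"}).
#' @param blacklist strain identifiers (e.g. dubious ORFs) removed before
#'   scoring.
#' @return list with \code{calls} (see \code{\link{callPhenotypes}}),
#'   \code{lpi} (replicate-level long table), \code{excluded} and
#'   \code{backgroundMeans}.
#' @export
scoreScreen <- function(phenotypes, config = callConfig(),
                        background = "background", blacklist = character(0)) {
  ph <- phenotypes
  if (!is.null(ph$is_control)) ph <- ph[!ph$is_control, , drop = FALSE]
  if (!is.null(ph$qc_pass)) ph <- ph[ph$qc_pass, , drop = FALSE]
  ph <- ph[is.finite(ph$log2D_norm) & !(ph$strain_id %in% blacklist), ,
           drop = FALSE]
  if (!(background %in% ph$condition))
    stop("background condition '", background, "' absent from phenotypes")
  bg <- ph[ph$condition == background, , drop = FALSE]
  bgMeans <- tapply(bg$log2D_norm, bg$strain_id, mean)
  bgMeans <- setNames(as.numeric(bgMeans), names(bgMeans))
  excluded <- excludeSlowGrowers(bgMeans, config@slowGrowerCutoff)
  stressors <- setdiff(unique(ph$condition), background)
  bgBy <- split(bg$log2D_norm, bg$strain_id)
  lpiRows <- list()
  for (cond in stressors) {
    st <- ph[ph$condition == cond, , drop = FALSE]
    stBy <- split(st$log2D_norm, st$strain_id)
    for (strain in names(stBy)) {
      reps <- tryCatch(
        computeLPI(stBy[[strain]], bgBy[[strain]])$replicates,
        error = function(e) numeric(0))
      lpiRows[[paste(cond, strain)]] <- data.frame(
        strain_id = strain, condition = cond,
        lpi = if (length(reps)) reps else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  lpiLong <- do.call(rbind, lpiRows)
  rownames(lpiLong) <- NULL
  calls <- callPhenotypes(lpiLong, config, excluded)
  list(calls = calls, lpi = lpiLong, excluded = excluded,
       backgroundMeans = bgMeans)
}
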