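# Hit-list set algebra: overlaps with hypergeometric significance, 3-set
# Venn decomposition, LPI/fold conversion.

#' Overlap statistics from counts
#'
#' Core overlap computation when only the set sizes are known (e.g. published
#' hit-list tallies). The overlap percentage uses the union as denominator
#' and is rounded to the nearest integer; significance is the exact
#' hypergeometric upper tail P(X >= intersection) for drawing \code{nA}
#' genes from a universe of \code{universeN} containing \code{nB} successes
#' (evaluated in log space by \code{stats::phyper}).
#'
#' @param nA,nB set sizes.
#' @param nIntersection observed intersection.
#' @param universeN universe size (default 4308, a scored deletion
#'   collection).
#' @param labelA,labelB set labels.
#' @return an \linkS4class{OverlapResult}.
#' @examples
#' overlapFromCounts(171, 133, 62)  # 26% of the union of Al and Ga hits
#' @export
overlapFromCounts <- function(nA, nB, nIntersection, universeN = 4308,
                              labelA = "A", labelB = "B") {
  nA <- as.integer(nA); nB <- as.integer(nB)
  nInt <- as.integer(nIntersection); N <- as.integer(universeN)
  union <- nA + nB - nInt
  if (union > N)
    stop("invalid universe: union (", union, ") exceeds universe (", N, ")")
  pUpper <- if (nInt == 0L) 1 else
    phyper(nInt - 1L, nB, N - nB, nA, lower.tail = FALSE)
  new("OverlapResult",
    labelA = labelA, labelB = labelB, nA = nA, nB = nB,
    nIntersection = nInt, nUnion = union,
    pctOverlap = round(100 * nInt / union), universeN = N, pUpper = pUpper)
}

#' Overlap of two gene sets
#'
#' @param a,b \linkS4class{GeneSet} objects.
#' @param universeN assumed universe size (default 4308).
#' @return an \linkS4class{OverlapResult}.
#' @export
overlapSets <- function(a, b, universeN = 4308) {
  overlapFromCounts(length(a@members), length(b@members),
                    length(intersect(a@members, b@members)),
                    universeN, a@label, b@label)
}

#' @describeIn overlapFromCounts the union-based overlap percentage.
#' @param x an \code{OverlapResult}.
#' @export
pctOverlap <- function(x) x@pctOverlap

#' @describeIn overlapFromCounts the hypergeometric upper-tail probability.
#' @export
pUpper <- function(x) x@pUpper

#' Three-set Venn decomposition
#'
#' @param a,b,c \linkS4class{GeneSet} objects.
#' @return named integer vector of the 7 disjoint region counts
#'   (\code{a_only}, \code{b_only}, \code{c_only}, \code{ab}, \code{ac},
#'   \code{bc}, \code{abc}); the regions sum to |a U b U c|.
#' @export
venn3 <- function(a, b, c) {
  all <- union(union(a@members, b@members), c@members)
  inA <- all %in% a@members
  inB <- all %in% b@members
  inC <- all %in% c@members
  c(a_only = sum(inA & !inB & !inC),
    b_only = sum(!inA & inB & !inC),
    c_only = sum(!inA & !inB & inC),
    ab = sum(inA & inB & !inC),
    ac = sum(inA & !inB & inC),
    bc = sum(!inA & inB & inC),
    abc = sum(inA & inB & inC))
}

#' Convert an LPI to a fold change
#'
#' The LPI is a log2 ratio of doubling times, so \code{2^lpi} is the fold
#' change in doubling time relative to the controls; e.g. the strong-effect
#' gate LPI >= 2.5 corresponds to a 5.6-fold slower-growing mutant.
#'
#' @param lpi finite LPI in log2 units.
#' @return fold change \code{2^lpi}.
#' @examples
#' lpiFold(2.5)
#' @export
lpiFold <- function(lpi) {
  stopifnot(all(is.finite(lpi)))
  2^lpi
}

#' @describeIn lpiFold report formatting: fold change truncated (not
#'   rounded) to one decimal, as a character string. Full precision is kept
#'   by \code{lpiFold} itself.
#' @param fold numeric fold change.
#' @export
foldLabel <- function(fold) sprintf("%.1f", trunc(fold * 10) / 10)

#' Percentage of a count ratio
#'
#' @param k,n numerator and denominator counts.
#' @param digits decimals to round to (default 0).
#' @return \code{round(100 * k / n, digits)}.
#' @examples
#' ratePercent(18, 19)        # 95, a validation true-positive rate
#' ratePercent(287, 4308, 1)  # 6.7, a slow-grower exclusion rate
#' @export
ratePercent <- function(k, n, digits = 0) round(100 * k / n, digits)

#' Read a gene-set file
#'
#' Plain text, one identifier per line; blank lines and \code{#} comments
#' are ignored.
#'
#' @param path file path.
#' @param label set label (default the file name without extension).
#' @return a \linkS4class{GeneSet}.
#' @export
readGeneSet <- function(path, label = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  geneSet(label, lines[nzchar(lines)])
}

#' Write a gene set to a file
#'
#' @param x a \linkS4class{GeneSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGeneSet <- function(x, path) {
  writeLines(c(paste0("# gene set: ", x@label), x@members), path)
  invisible(path)
}

#' Overlap report as a plain list
#'
#' JSON-ready summary of an \linkS4class{OverlapResult}.
#'
#' @param x an \code{OverlapResult}.
#' @return named list of all overlap fields.
#' @export
overlapReport <- function(x) {
  list(set_a = x@labelA, set_b = x@labelB, n_a = x@nA, n_b = x@nB,
       n_intersection = x@nIntersection, n_union = x@nUnion,
       pct_overlap = x@pctOverlap, universe_n = x@universeN,
       p_upper = x@pUpper)
}
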