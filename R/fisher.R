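# Two-sided Fisher's exact test by hypergeometric tail summation, and the
# interval co-occurrence test built on it.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p is the sum of hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (with a 1 + 1e-7 relative tolerance, the standard
#' convention).  The odds ratio is the simple cross-product ratio;
#' zero-cell tables report an unbounded (Inf) or zero ratio.
#'
#' @param x11,x12,x21,x22 table cells (row 1: in set A; column 1: in set B)
#' @return list(p = two-sided p value, odds_ratio)
#' @export
fisherExactTwoSided <- function(x11, x12, x21, x22) {
  m <- x11 + x12   # row 1 total
  n <- x21 + x22   # row 2 total
  k <- x11 + x21   # column 1 total
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(x11, m, n, k)
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  orat <- if (x12 == 0 || x21 == 0) {
    if (x11 == 0 || x22 == 0) NaN else Inf
  } else (x11 * x22) / (x12 * x21)
  list(p = p, odds_ratio = orat)
}

#' Interval co-occurrence by Fisher's exact test
#'
#' Intervals of set A are expanded by \code{flank} bp on both sides
#' (clipped to the sequence bounds); the genome's base pairs are then
#' cross-classified by membership in expanded-A and in B, and the 2x2
#' table tested two-sided.
#'
#' @param setA,setB GRanges interval sets
#' @param genomeLengths named sequence lengths in bp
#' @param flank expansion of set A in bp on each side
#' @return list(odds_ratio, p, table = 2x2 matrix of bp counts)
#' @export
intervalCooccurrenceFisher <- function(setA, setB, genomeLengths,
                                       flank = 500000L) {
  sl <- genomeLengths
  gwide <- GenomicRanges::GRanges(names(sl), IRanges::IRanges(1L, unname(sl)))
  expand <- function(gr) {
    GenomicRanges::start(gr) <- pmax(1L, GenomicRanges::start(gr) - flank)
    len <- sl[as.character(GenomicRanges::seqnames(gr))]
    GenomicRanges::end(gr) <- pmin(unname(len), GenomicRanges::end(gr) + flank)
    GenomicRanges::reduce(gr, ignore.strand = TRUE)
  }
  a <- expand(setA)
  b <- GenomicRanges::reduce(setB, ignore.strand = TRUE)
  ab <- GenomicRanges::intersect(a, b, ignore.strand = TRUE)
  total <- sum(as.numeric(sl))
  aBp <- sum(GenomicRanges::width(a))
  bBp <- sum(GenomicRanges::width(b))
  abBp <- sum(GenomicRanges::width(ab))
  x11 <- abBp; x12 <- aBp - abBp
  x21 <- bBp - abBp; x22 <- total - aBp - bBp + abBp
  ft <- fisherExactTwoSided(x11, x12, x21, x22)
  list(odds_ratio = ft$odds_ratio, p = ft$p,
       table = matrix(c(x11, x21, x12, x22), 2, 2,
                      dimnames = list(c("inA", "outA"), c("inB", "outB"))))
}
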