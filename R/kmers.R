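# K-mer uniqueness (effective genome size) and depth-track interval calls.

#' Effective genome fraction (unique k-mer fraction)
#'
#' Fraction of k-mer positions whose canonical (strand-folded) N-free k-mer
#' occurs exactly once genome-wide.  Counting uses a rolling strand-aware
#' 64-bit hash fold; at genome scales where every canonical k-mer maps to a
#' distinct hash value with overwhelming probability, the count is exact.
#'
#' @param genome named list of \linkS4class{SeqRecord} (or character vector)
#' @param k k-mer length (default 150, the unique 150-mer convention)
#' @return fraction in [0, 1]
#' @export
effectiveGenomeFraction <- function(genome, k = 150L) {
  seqs <- if (is.character(genome)) genome else vapply(genome, seqString, "")
  if (all(nchar(seqs) < k)) stop("all sequences shorter than k")
  res <- cpp_canonical_kmer_uniqueness(unname(seqs), as.integer(k))
  res$fraction
}

#' Mappability classes from a self-coverage depth track
#'
#' Positions with depth at most \code{low} or at least \code{high} are
#' non-uniquely mappable; non-unique runs separated by at most
#' \code{mergeGap} bp are merged into islands, and the complement is the
#' uniquely mappable fraction.
#'
#' @param depth named list of integer per-bp depth vectors (or one vector,
#'   named "seq")
#' @param low,high depth bounds for the non-unique class
#' @param mergeGap maximum merge interval in bp
#' @return list(unique = GRanges, non_unique = GRanges)
#' @export
mappabilityClasses <- function(depth, low = 2L, high = 101L, mergeGap = 1000L) {
  if (!is.list(depth)) depth <- list(seq = depth)
  nu <- list(); uq <- list()
  for (sid in names(depth)) {
    d <- depth[[sid]]
    mask <- d <= low | d >= high
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ir <- IRanges::IRanges(start = starts[r$values], end = ends[r$values])
    ir <- IRanges::reduce(ir, min.gapwidth = mergeGap + 1L)
    nu[[length(nu) + 1L]] <- GenomicRanges::GRanges(rep(sid, length(ir)), ir)
    comp <- IRanges::setdiff(IRanges::IRanges(1L, length(d)), ir)
    uq[[length(uq) + 1L]] <- GenomicRanges::GRanges(rep(sid, length(comp)), comp)
  }
  list(unique = do.call(c, uq), non_unique = do.call(c, nu))
}

#' Low-coverage regions of a depth track
#'
#' Maximal runs with depth strictly below \code{minReads} (e.g. fewer than
#' 3 reads for accurate profiles, fewer than 2 for the long-noisy profile).
#'
#' @param depth named list of integer per-bp depth vectors (or one vector)
#' @param minReads depth threshold (exclusive)
#' @return GRanges of low-coverage intervals
#' @export
lowCoverageRegions <- function(depth, minReads) {
  if (!is.list(depth)) depth <- list(seq = depth)
  out <- list()
  for (sid in names(depth)) {
    d <- depth[[sid]]
    mask <- d < minReads
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ir <- IRanges::IRanges(start = starts[r$values], end = ends[r$values])
    out[[length(out) + 1L]] <- GenomicRanges::GRanges(rep(sid, length(ir)), ir)
  }
  do.call(c, out)
}
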