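# CENH3 ChIP enrichment: broad island calling on binned counts and
# RPKM enrichment ratios over features.

#' Call broad enrichment islands (CENH3 domains)
#'
#' Reads are binned; each bin's ChIP count is tested against an
#' input-scaled Poisson background (lambda floored at
#' \code{effectiveFraction} times the mean input, which keeps poorly
#' mappable bins from producing spurious enrichment).  Bins with
#' -log10 p above \code{-log10(pThresh)} are merged into islands allowing
#' up to \code{gapBins} non-significant bins between; the island score is
#' the sum of its bins' -log10 Poisson p.  Islands are kept when score
#' exceeds \code{minScore} and the depth-normalized ChIP/input fold change
#' exceeds \code{minFC}.
#'
#' @param chip,input named lists of read start positions per sequence (or
#'   single numeric vectors, named "seq")
#' @param seqLengths named sequence lengths in bp
#' @param bin bin size in bp (default 5000)
#' @param gapBins non-significant bins tolerated inside an island
#' @param minScore island score cutoff (strictly greater)
#' @param minFC fold-change cutoff (strictly greater)
#' @param effectiveFraction effective (uniquely mappable) genome fraction
#' @param pThresh per-bin significance threshold
#' @return GRanges of islands with mcols \code{score}, \code{fold_change},
#'   \code{label}
#' @export
callCenh3Domains <- function(chip, input, seqLengths, bin = 5000L,
                             gapBins = 0L, minScore = 250, minFC = 4,
                             effectiveFraction = 1, pThresh = 0.01) {
  if (!is.list(chip)) chip <- list(seq = chip)
  if (!is.list(input)) input <- list(seq = input)
  tC <- sum(lengths(chip)); tI <- sum(lengths(input))
  if (tI == 0) stop("zero-depth input track")
  out <- list()
  for (sid in names(chip)) {
    n <- seqLengths[[sid]]
    nb <- ceiling(n / bin)
    cb <- tabulate(pmin(nb, (chip[[sid]] - 1) %/% bin + 1L), nbins = nb)
    ib <- tabulate(pmin(nb, (input[[sid]] - 1) %/% bin + 1L), nbins = nb)
    lam <- pmax(ib, effectiveFraction * mean(ib)) * (tC / tI)
    logp <- -stats::ppois(cb - 1L, lam, lower.tail = FALSE, log.p = TRUE) / log(10)
    sig <- logp > -log10(pThresh)
    if (!any(sig)) next
    # merge significant bins allowing gaps of <= gapBins non-significant bins
    idx <- which(sig)
    grp <- cumsum(c(1, diff(idx) > gapBins + 1L))
    for (g in unique(grp)) {
      bidx <- idx[grp == g]
      lo <- min(bidx); hi <- max(bidx)
      score <- sum(logp[lo:hi][sig[lo:hi]])
      chipSum <- sum(cb[lo:hi]); inSum <- sum(ib[lo:hi])
      fc <- (chipSum / tC) / (max(inSum, effectiveFraction * mean(ib) * length(lo:hi)) / tI)
      if (score > minScore && fc > minFC) {
        gr <- GenomicRanges::GRanges(sid, IRanges::IRanges(
          start = (lo - 1L) * bin + 1L, end = min(n, hi * bin)))
        S4Vectors::mcols(gr)$score <- score
        S4Vectors::mcols(gr)$fold_change <- fc
        S4Vectors::mcols(gr)$label <- "CENH3"
        out[[length(out) + 1L]] <- gr
      }
    }
  }
  if (!length(out))
    return(GenomicRanges::GRanges(score = numeric(0), fold_change = numeric(0),
                                  label = character(0)))
  sort(do.call(c, out))
}

#' RPKM enrichment ratio over features
#'
#' Ratio of RPKM(ChIP, feature) to RPKM(input, feature); the depth
#' normalization is exact (doubling all ChIP counts leaves ratios
#' unchanged).  Features with zero input reads get NA, never infinity.
#'
#' @param chip,input named lists of read start positions per sequence
#' @param features GRanges of features
#' @return features with mcols \code{chip_rpkm}, \code{input_rpkm},
#'   \code{ratio}
#' @export
rpkmEnrichment <- function(chip, input, features) {
  if (!is.list(chip)) chip <- list(seq = chip)
  if (!is.list(input)) input <- list(seq = input)
  tC <- sum(lengths(chip)); tI <- sum(lengths(input))
  if (tC == 0 || tI == 0) stop("total mapped counts must be positive")
  countIn <- function(track, f) {
    sid <- as.character(GenomicRanges::seqnames(f))
    p <- track[[sid]]
    if (is.null(p)) return(0L)
    sum(p >= GenomicRanges::start(f) & p <= GenomicRanges::end(f))
  }
  cc <- ii <- numeric(length(features))
  for (i in seq_along(features)) {
    cc[i] <- countIn(chip, features[i])
    ii[i] <- countIn(input, features[i])
  }
  wkb <- GenomicRanges::width(features) / 1e3
  chipR <- cc / wkb / (tC / 1e6)
  inR <- ii / wkb / (tI / 1e6)
  S4Vectors::mcols(features)$chip_rpkm <- chipR
  S4Vectors::mcols(features)$input_rpkm <- inR
  S4Vectors::mcols(features)$ratio <- ifelse(ii == 0, NA_real_, chipR / inR)
  features
}
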