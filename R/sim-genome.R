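# Synthetic genome generation with exact truth tables.

#' Simulate a truth-annotated repeat-rich genome
#'
#' Each chromosome carries telomere tracts at both ends, subtelomeric
#' knob180 blocks, a CentC centromere array with TE-like interruptions,
#' knob/TR-1/rDNA arrays per the configuration, and unique background.
#' One designated heterozygous region has an alternate haplotype (emitted
#' as a full alternate chromosome) with the configured divergence and a
#' deletion.  Truth tables cover every feature, interruption and the
#' haplotype.  Deterministic per (config, seed).
#'
#' @param config a \code{\link{simConfig}}
#' @return list(genome = named list of \linkS4class{SeqRecord},
#'   alt = named list with the alternate haplotype chromosome,
#'   truth = list(features = GRanges, het, monomers, config))
#' @export
simulateGenome <- function(config = simConfig()) {
  set.seed(config$seed + 101L)
  mons <- simMonomers(config)
  len <- config$chromosomeLength
  telU <- config$telomereUnit
  feats <- list()
  genome <- list()
  addF <- function(chrom, start0, end0, family, label) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
    S4Vectors::mcols(gr)$family <- family
    S4Vectors::mcols(gr)$label <- label
    S4Vectors::mcols(gr)$score <- NA_real_
    feats[[length(feats) + 1L]] <<- gr
  }
  for (ci in seq_len(config$nChromosomes)) {
    chrom <- paste0("chr", ci)
    s <- randomDNA(len)
    # telomeres
    tl <- config$telomereLen
    substr(s, 1, tl) <- tandemFill(revComp(telU), tl)
    substr(s, len - tl + 1, len) <- tandemFill(telU, tl)
    addF(chrom, 0L, tl, "telomere", "telomere")
    addF(chrom, len - tl, len, "telomere", "telomere")
    # subtelomeric knob180 blocks
    st <- config$subtelomere
    for (off in c(st$offset, len - st$offset - st$span)) {
      blk <- buildArray(mons$knob180, st$span, st$divergence, 0, config$teLen)
      substr(s, off + 1, off + st$span) <- blk$seq
      addF(chrom, off, off + st$span, "knob180", "subtelomere")
    }
    # arrays
    aa <- config$arrays[config$arrays$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(aa))) {
      a <- aa[i, ]
      if (a$start + a$span > len) stop("array overflows chromosome length")
      arr <- buildArray(mons[[a$family]], a$span, a$divergence, a$teRate, config$teLen)
      substr(s, a$start + 1, a$start + a$span) <- arr$seq
      addF(chrom, a$start, a$start + a$span, a$family, "array")
      if (a$family == "CentC")
        addF(chrom, a$start, a$start + a$span, "CentC", "centromere")
      teFam <- if (a$family == "CentC") "CRM-like" else "Cinful-Zeon-like"
      for (j in seq_len(nrow(arr$te)))
        addF(chrom, a$start + arr$te$start[j], a$start + arr$te$end[j], teFam, "TE")
    }
    genome[[chrom]] <- seqRecord(chrom, s)
  }
  # heterozygous region: alternate haplotype with divergence + deletion
  alt <- list()
  het <- config$het
  if (!is.null(het) && het$chrom %in% names(genome)) {
    s <- genome[[het$chrom]]@seq
    seg <- substr(s, het$start + 1, het$end)
    seg2 <- mutateSequence(seg, subRate = het$divergence)
    mid <- nchar(seg2) %/% 2
    delLo <- mid - het$indelLen %/% 2          # 0-based within segment
    seg2 <- paste0(substr(seg2, 1, delLo), substr(seg2, delLo + het$indelLen + 1, nchar(seg2)))
    altSeq <- paste0(substr(s, 1, het$start), seg2, substr(s, het$end + 1, nchar(s)))
    altId <- paste0(het$chrom, "_hap2")
    alt[[het$chrom]] <- seqRecord(altId, altSeq)
    addF(het$chrom, het$start, het$end, "het", "heterozygous")
    het$delStart <- het$start + delLo           # hap1 coords of the deleted bp
    het$delEnd <- het$start + delLo + het$indelLen
  }
  features <- suppressWarnings(sort(do.call(c, feats)))
  list(genome = genome, alt = alt,
       truth = list(features = features, het = het, monomers = mons,
                    config = config))
}

# Build a tandem array of `span` bp: mutated monomer copies with TE-like
# interruption blocks.  Returns list(seq, te = data.frame(start, end)
# 0-based within the array).
buildArray <- function(monomer, span, divergence, teRate, teLen) {
  L <- nchar(monomer)
  nTe <- if (teRate > 0) max(0L, round(span * teRate / teLen)) else 0L
  nCopies <- ceiling((span - nTe * teLen) / L) + 2L
  pieces <- character(0)
  teAt <- if (nTe > 0) sort(sample(seq_len(nCopies - 1L), nTe)) else integer(0)
  te <- list()
  off <- 0L
  for (i in seq_len(nCopies)) {
    cp <- if (divergence > 0) mutateSequence(monomer, subRate = divergence) else monomer
    pieces <- c(pieces, cp)
    off <- off + nchar(cp)
    if (i %in% teAt && off + teLen < span) {
      tb <- randomDNA(teLen)
      pieces <- c(pieces, tb)
      te[[length(te) + 1L]] <- data.frame(start = off, end = off + teLen)
      off <- off + teLen
    }
    if (off >= span) break
  }
  seq <- substr(paste(pieces, collapse = ""), 1, span)
  te <- if (length(te)) do.call(rbind, te) else data.frame(start = integer(0), end = integer(0))
  te <- te[te$end <= span, , drop = FALSE]
  list(seq = seq, te = te)
}
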