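# Simulated observations: optical maps, long reads, ChIP tracks, markers.

#' Simulate noisy optical maps
#'
#' Truth label positions (in-silico digest of the chromosome) are perturbed
#' with interval-proportional Gaussian sizing noise (sd = sdCoeff *
#' sqrt(interval)), labels are dropped at the miss rate, false labels are
#' inserted at a rate per 100 kb, and maps are split at unlabeled stretches
#' longer than the configured limit.  A minimum emitted map length is
#' enforced.  Replicate maps per chromosome provide the independent
#' evidence used for junction support and zygosity adjudication; for the
#' heterozygous chromosome one replicate is drawn from the alternate
#' haplotype.
#'
#' @param sim result of \code{\link{simulateGenome}}
#' @param config a \code{\link{simConfig}}
#' @return list(maps = named list of \linkS4class{LabelMap}, truth =
#'   data.frame(map_id, chrom, hap, offset, n_labels))
#' @export
simulateOpticalMaps <- function(sim, config = sim$truth$config) {
  set.seed(config$seed + 303L)
  mc <- config$maps
  maps <- list(); truth <- list()
  digestCache <- list()
  for (chrom in names(sim$genome)) {
    for (r in seq_len(mc$replicates)) {
      useAlt <- r == mc$altHapReplicate && !is.null(sim$alt[[chrom]])
      key <- paste0(chrom, if (useAlt) "_hap2" else "")
      if (is.null(digestCache[[key]])) {
        src <- if (useAlt) sim$alt[[chrom]] else sim$genome[[chrom]]
        digestCache[[key]] <- insilicoDigest(src, config$digestion$motif,
                                             config$digestion$minLabelSpacing)
      }
      dg <- digestCache[[key]]
      len <- dg@length
      p <- dg@labels
      d <- diff(c(0, p))
      d2 <- pmax(10, d + stats::rnorm(length(d), 0, mc$sdCoeff * sqrt(d)))
      p2 <- cumsum(d2)
      p2 <- p2[stats::runif(length(p2)) >= mc$missRate]
      nf <- stats::rpois(1, len / 1e5 * mc$falsePer100kb)
      if (nf > 0) p2 <- c(p2, stats::runif(nf, 1, len))
      p2 <- sort(p2)
      p2 <- p2[p2 >= 1 & p2 <= len]
      if (length(p2) < 5L) next
      # split at unlabeled stretches
      grp <- cumsum(c(1, diff(p2) > mc$splitUnlabeled))
      pi_ <- 0L
      for (g in unique(grp)) {
        lab <- p2[grp == g]
        if (length(lab) < 5L) next
        start <- max(0, min(lab[1] - 1, lab[1] - mc$pad))
        end <- min(len, lab[length(lab)] + mc$pad)
        if (end - start < mc$minMapLen) next
        pi_ <- pi_ + 1L
        mid <- sprintf("om_%s_r%d_p%d", chrom, r, pi_)
        maps[[mid]] <- labelMap(mid, end - start, lab - start, source = "optical")
        truth[[length(truth) + 1L]] <- data.frame(map_id = mid, chrom = chrom,
          hap = if (useAlt) 2L else 1L, offset = start, n_labels = length(lab),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(maps = maps, truth = do.call(rbind, truth))
}

#' Simulate long (or accurate) reads
#'
#' Read start positions are uniform over the chromosomes; lengths are
#' log-normal tuned so the emitted N50 matches the profile preset (the
#' length-biased median of a log-normal(mu, sigma) is exp(mu + sigma^2)).
#' Errors follow the profile; reads over the heterozygous chromosome come
#' from either haplotype with equal probability; half the reads are
#' reverse complemented.
#'
#' @param sim result of \code{\link{simulateGenome}}
#' @param profile "long" or "accurate"
#' @param depth target genome coverage
#' @param config a \code{\link{simConfig}}
#' @return list(seqs = named character vector, truth = data.frame(read_id,
#'   chrom, hap, start, end, strand, length))
#' @export
simulateReads <- function(sim, profile = "long", depth = NULL,
                          config = sim$truth$config) {
  set.seed(config$seed + 404L + match(profile, c("accurate", "long", "short")))
  prof <- config$profiles[[if (profile == "long") "long" else "accurate"]]
  if (is.null(depth)) depth <- config$reads$depthLong
  if (depth <= 0) stop("depth must be positive")
  sdlog <- config$reads$sdlog
  meanlog <- log(prof$readN50) - sdlog^2
  srcSeq <- lapply(sim$genome, seqString)
  altSeq <- lapply(sim$alt, seqString)
  lens <- vapply(srcSeq, nchar, 0)
  altLens <- vapply(altSeq, nchar, 0)
  target <- depth * sum(lens)
  expLen <- exp(meanlog + sdlog^2 / 2)
  n <- ceiling(1.3 * target / expLen)
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens)
  useAlt <- chrom %in% names(altSeq) & stats::runif(n) < 0.5
  L <- pmax(config$reads$minReadLen, round(stats::rlnorm(n, meanlog, sdlog)))
  srcLen <- ifelse(useAlt, altLens[chrom], lens[chrom])
  # reads may overhang either chromosome end (clipped), so coverage piles
  # up symmetrically at both termini
  st <- floor(stats::runif(n, 2 - L + config$reads$minReadLen, srcLen + 1))
  en <- pmin(srcLen, st + L - 1)
  st <- pmax(1, st)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  keep <- which(en - st + 1 >= config$reads$minReadLen)
  keep <- keep[cumsum(en[keep] - st[keep] + 1) <= target * 1.02]
  seqs <- character(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    src <- if (useAlt[i]) altSeq[[chrom[i]]] else srcSeq[[chrom[i]]]
    s <- substr(src, st[i], en[i])
    seqs[j] <- mutateSequence(s, prof$readSubRate, prof$readIndelRate)
  }
  ids <- sprintf("rd_%s_%d", profile, seq_along(keep))
  names(seqs) <- ids
  tr <- data.frame(read_id = ids, chrom = chrom[keep],
                   hap = ifelse(useAlt[keep], 2L, 1L), start = st[keep] - 1L,
                   end = en[keep], strand = strand[keep],
                   length = nchar(seqs), stringsAsFactors = FALSE)
  flip <- which(tr$strand == "-")
  if (length(flip)) {
    rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[flip]))
    seqs[flip] <- as.character(rc)
  }
  list(seqs = seqs, truth = tr)
}

#' Simulate CENH3 ChIP and input read positions
#'
#' Input reads are uniform; ChIP reads sample centromere truth intervals
#' at \code{fold} times the background rate.  Deterministic per seed.
#'
#' @param sim result of \code{\link{simulateGenome}}
#' @param fold ChIP enrichment fold inside centromeres (>= 1)
#' @param depth sequencing depth of each track
#' @param readLen nominal read length (depth / readLen sets read counts)
#' @param config a \code{\link{simConfig}}
#' @return list(chip, input = named lists of read start positions,
#'   read_len)
#' @export
simulateChip <- function(sim, fold = NULL, depth = NULL, readLen = NULL,
                         config = sim$truth$config) {
  set.seed(config$seed + 505L)
  if (is.null(fold)) fold <- config$chip$fold
  if (is.null(depth)) depth <- config$chip$depth
  if (is.null(readLen)) readLen <- config$chip$readLen
  if (depth <= 0) stop("depth must be positive")
  if (fold < 1) stop("fold must be >= 1")
  fx <- sim$truth$features
  cents <- fx[S4Vectors::mcols(fx)$label == "centromere"]
  chip <- list(); input <- list()
  for (chrom in names(sim$genome)) {
    len <- seqLen(sim$genome[[chrom]])
    n <- round(depth * len / readLen)
    input[[chrom]] <- sort(sample.int(len, n, replace = TRUE))
    cc <- cents[GenomicRanges::seqnames(cents) == chrom]
    centLen <- sum(GenomicRanges::width(cc))
    pCent <- fold * centLen / (fold * centLen + (len - centLen))
    nc <- stats::rbinom(1, n, pCent)
    inC <- if (centLen > 0 && nc > 0) {
      offs <- sample.int(centLen, nc, replace = TRUE)
      starts <- GenomicRanges::start(cc); widths <- GenomicRanges::width(cc)
      cum <- cumsum(widths)
      idx <- findInterval(offs - 1L, c(0, cum[-length(cum)]))
      starts[idx] + (offs - c(0, cum)[idx] - 1L)
    } else integer(0)
    outC <- integer(0)
    nOut <- n - nc
    while (length(outC) < nOut) {
      cand <- sample.int(len, nOut - length(outC) + 100L, replace = TRUE)
      bad <- rep(FALSE, length(cand))
      for (k in seq_along(cc))
        bad <- bad | (cand >= GenomicRanges::start(cc)[k] &
                      cand <= GenomicRanges::end(cc)[k])
      outC <- c(outC, cand[!bad])
    }
    chip[[chrom]] <- sort(c(inC, outC[seq_len(nOut)]))
  }
  list(chip = chip, input = input, read_len = readLen)
}

#' Simulate genetic markers
#'
#' Marker physical positions are uniform per chromosome; genetic positions
#' are a monotone map of physical position plus Gaussian noise.  A
#' configured fraction is flagged non-unique or low-mapq to exercise the
#' marker filters.  Each marker carries its 50 bp up/downstream flanked
#' sequence for re-anchoring onto assemblies.
#'
#' @param sim result of \code{\link{simulateGenome}}
#' @param perGroup markers per chromosome (>= 2)
#' @param noiseSd genetic-position noise in cM
#' @param config a \code{\link{simConfig}}
#' @return marker data.frame (see \code{\link{readMarkers}})
#' @export
simulateMarkers <- function(sim, perGroup = NULL, noiseSd = NULL,
                            config = sim$truth$config) {
  set.seed(config$seed + 606L)
  mk <- config$markers
  if (is.null(perGroup)) perGroup <- mk$perGroup
  if (is.null(noiseSd)) noiseSd <- mk$noiseSd
  if (perGroup < 2L) stop("perGroup must be >= 2")
  rows <- list()
  mi <- 0L
  for (chrom in names(sim$genome)) {
    len <- seqLen(sim$genome[[chrom]])
    pos <- sort(sample(seq(mk$flank + 1L, len - mk$flank - 1L), perGroup))
    gen <- pos / len * mk$cmLength + stats::rnorm(perGroup, 0, noiseSd)
    nonUnique <- stats::runif(perGroup) < mk$fracNonUnique
    lowQ <- stats::runif(perGroup) < mk$fracLowMapq
    for (j in seq_len(perGroup)) {
      mi <- mi + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = sprintf("mk%d", mi), scaffold_id = chrom,
        physical_bp = pos[j], linkage_group = chrom, genetic_pos = gen[j],
        mapq = if (lowQ[j]) 20L else 60L, unique = !nonUnique[j],
        source = "sim", seq = substr(sim$genome[[chrom]]@seq,
                                     pos[j] - mk$flank, pos[j] + mk$flank),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate the full default input bundle
#'
#' @param config a \code{\link{simConfig}}
#' @return list(sim, assemblies, maps, reads, markers)
#' @export
simulateBundle <- function(config = simConfig()) {
  sim <- simulateGenome(config)
  assemblies <- simulateAssemblies(sim, config)
  maps <- simulateOpticalMaps(sim, config)
  reads <- simulateReads(sim, "long", config$reads$depthLong, config)
  markers <- simulateMarkers(sim, config = config)
  list(sim = sim, assemblies = assemblies, maps = maps, reads = reads,
       markers = markers)
}
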