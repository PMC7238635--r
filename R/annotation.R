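# Tandem-repeat monomer scanning and rule-based array calling.

#' Scan a genome for monomer copies of a repeat consensus
#'
#' Seed-and-extend: exact seed k-mers shared between the consensus (both
#' strands) and the genome vote for candidate monomer placements; candidate
#' placements are verified by global pairwise alignment against the
#' consensus and accepted when percent identity reaches
#' \code{minIdentity}.  Accepted units are non-overlapping (greedy by vote
#' count); adjacent units are merged into hit blocks carrying unit counts.
#'
#' @param genome named list of \linkS4class{SeqRecord}
#' @param consensus consensus monomer (\linkS4class{SeqRecord} or string)
#' @param minIdentity minimum fractional identity of an accepted unit
#' @param family family label stored on the hits
#' @param seedK seed k-mer length
#' @param minVotes minimum seed votes for a candidate placement
#' @return \link[GenomicRanges]{GRanges} of hit blocks with mcols
#'   \code{family}, \code{units}, \code{identity} (mean), \code{label}
#' @export
scanRepeatMonomers <- function(genome, consensus, minIdentity = 0.7,
                               family = "repeat", seedK = 12L, minVotes = 3L) {
  if (is(consensus, "SeqRecord")) consensus <- consensus@seq
  L <- nchar(consensus)
  if (L < 50) stop("consensus must be at least 50 bp")
  if (is(genome, "SeqRecord")) genome <- list(genome)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  grs <- list()
  for (rec in genome) {
    h <- cpp_anchor_hits(rec@seq, c(consensus, revComp(consensus)),
                         as.integer(seedK), 100000L, 1L)
    if (!length(h$qpos)) next
    # candidate unit start implied by each seed, per strand
    strand <- ifelse(h$query == 1L, "+", "-")
    cand <- h$tpos - h$qpos   # implied unit start (query is already oriented)
    keyv <- paste(strand, round(cand / 8))          # 8 bp vote tolerance
    votes <- table(keyv)
    votes <- votes[votes >= minVotes]
    if (!length(votes)) next
    ord <- order(-as.integer(votes), names(votes))
    accepted <- list()
    occ <- integer(0)  # accepted starts for overlap checks
    for (kv in names(votes)[ord]) {
      parts <- strsplit(kv, " ")[[1]]
      st <- as.integer(parts[2]) * 8L
      sd <- parts[1]
      if (st < 0 || st + L > seqLen(rec)) next
      if (length(occ) && any(abs(occ - st) < 0.8 * L)) next
      win <- substr(rec@seq, st + 1, st + L)
      if (grepl("N", win, fixed = TRUE)) next
      subj <- if (sd == "+") consensus else revComp(consensus)
      pa <- Biostrings::pairwiseAlignment(win, subj, type = "global",
              substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
      idf <- Biostrings::pid(pa) / 100
      if (idf < minIdentity) next
      occ <- c(occ, st)
      accepted[[length(accepted) + 1L]] <- data.frame(start = st, strand = sd,
                                                      identity = idf)
    }
    if (!length(accepted)) next
    u <- do.call(rbind, accepted)
    u <- u[order(u$start), , drop = FALSE]
    # merge adjacent units (gap <= 2 monomer lengths) into blocks
    grp <- cumsum(c(1, diff(u$start) > 3 * L))
    for (g in unique(grp)) {
      ug <- u[grp == g, , drop = FALSE]
      strands <- unique(ug$strand)
      gr <- GenomicRanges::GRanges(rec@id,
              IRanges::IRanges(start = min(ug$start) + 1L, end = max(ug$start) + L),
              strand = if (length(strands) == 1L) strands else "*")
      S4Vectors::mcols(gr)$family <- family
      S4Vectors::mcols(gr)$units <- nrow(ug)
      S4Vectors::mcols(gr)$identity <- mean(ug$identity)
      S4Vectors::mcols(gr)$label <- family
      grs[[length(grs) + 1L]] <- gr
    }
  }
  if (!length(grs))
    return(GenomicRanges::GRanges(family = character(0), units = integer(0),
                                  identity = numeric(0), label = character(0)))
  sort(do.call(c, grs))
}

#' Call repeat arrays from monomer hit blocks
#'
#' Single-linkage clustering of hit blocks with inter-block spacing at most
#' \code{maxSpacing}; a cluster is an array when its span reaches the class
#' minimum (knob class: 500 kb over knob180 + TR-1 hits; CentC class:
#' 100 kb) and at least \code{minDensity} of the span is covered by repeat
#' hits.  Knob calls drop clusters overlapping the configured subtelomeric
#' windows (the outermost \code{subtelomereWin} bp of each sequence when
#' \code{seqLengths} is given).
#'
#' @param hits GRanges from \code{\link{scanRepeatMonomers}} (mcols
#'   \code{family}, \code{units})
#' @param familyClass "knob" or "centc"
#' @param knobSpan,centcSpan class span minima in bp
#' @param minDensity minimum repeat coverage of the span
#' @param maxSpacing maximum spacing between clustered hit blocks in bp
#' @param seqLengths named lengths for subtelomeric exclusion
#' @param subtelomereWin subtelomeric window at each sequence end in bp
#' @param subtelomericWindows explicit exclusion GRanges (overrides
#'   \code{seqLengths})
#' @return GRanges of arrays with mcols \code{family}, \code{density},
#'   \code{units}, \code{label}, \code{score}
#' @export
callRepeatArrays <- function(hits, familyClass = c("knob", "centc"),
                             knobSpan = 500000L, centcSpan = 100000L,
                             minDensity = 0.10, maxSpacing = 100000L,
                             seqLengths = NULL, subtelomereWin = 200000L,
                             subtelomericWindows = NULL) {
  familyClass <- match.arg(familyClass)
  fams <- if (familyClass == "knob") c("knob180", "TR-1") else "CentC"
  minSpan <- if (familyClass == "knob") knobSpan else centcSpan
  hh <- hits[S4Vectors::mcols(hits)$family %in% fams]
  if (!length(hh))
    return(GenomicRanges::GRanges(family = character(0), density = numeric(0),
                                  units = integer(0), label = character(0),
                                  score = numeric(0)))
  cl <- GenomicRanges::reduce(hh, min.gapwidth = maxSpacing + 1L, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(cl, hh, ignore.strand = TRUE)
  dens <- units <- numeric(length(cl))
  for (i in seq_along(cl)) {
    sub <- hh[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
    cov <- sum(GenomicRanges::width(GenomicRanges::reduce(sub, ignore.strand = TRUE)))
    dens[i] <- cov / GenomicRanges::width(cl)[i]
    units[i] <- sum(S4Vectors::mcols(sub)$units)
  }
  keep <- GenomicRanges::width(cl) >= minSpan & dens >= minDensity
  cl <- cl[keep]; dens <- dens[keep]; units <- units[keep]
  if (familyClass == "knob") {
    excl <- subtelomericWindows
    if (is.null(excl) && !is.null(seqLengths)) {
      excl <- GenomicRanges::GRanges(rep(names(seqLengths), 2),
        IRanges::IRanges(start = c(rep(1, length(seqLengths)),
                                   pmax(1, seqLengths - subtelomereWin + 1)),
                         end = c(pmin(seqLengths, subtelomereWin), seqLengths)))
    }
    if (!is.null(excl) && length(cl)) {
      drop <- S4Vectors::queryHits(GenomicRanges::findOverlaps(cl, excl,
                                                               ignore.strand = TRUE))
      if (length(drop)) { cl <- cl[-unique(drop)]; dens <- dens[-unique(drop)]
                          units <- units[-unique(drop)] }
    }
  }
  S4Vectors::mcols(cl)$family <- rep(familyClass, length(cl))
  S4Vectors::mcols(cl)$density <- dens
  S4Vectors::mcols(cl)$units <- as.integer(units)
  S4Vectors::mcols(cl)$label <- rep(familyClass, length(cl))
  S4Vectors::mcols(cl)$score <- dens
  cl
}

#' Per-array repeat-family composition
#'
#' For each array, the fraction of its span covered by each annotation
#' family, with overlapping annotations flattened per family (each bp
#' counted once per family).
#'
#' @param arrays GRanges of arrays
#' @param annotations GRanges with an mcols \code{family} (or \code{label})
#' @return data.frame: array, family, fraction
#' @export
repeatComposition <- function(arrays, annotations) {
  fam <- S4Vectors::mcols(annotations)$family
  if (is.null(fam)) fam <- S4Vectors::mcols(annotations)$label
  rows <- list()
  for (i in seq_along(arrays)) {
    a <- arrays[i]
    aid <- sprintf("%s:%d-%d", GenomicRanges::seqnames(a),
                   GenomicRanges::start(a), GenomicRanges::end(a))
    for (f in unique(fam)) {
      flat <- GenomicRanges::reduce(annotations[fam == f], ignore.strand = TRUE)
      ov <- GenomicRanges::intersect(flat, a, ignore.strand = TRUE)
      frac <- sum(GenomicRanges::width(ov)) / GenomicRanges::width(a)
      rows[[length(rows) + 1L]] <- data.frame(array = aid, family = f,
                                              fraction = frac,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame(array = character(0), family = character(0),
                                       fraction = numeric(0)))
  do.call(rbind, rows)
}
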