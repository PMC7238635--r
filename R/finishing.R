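# Iterative long-read gap filling and telomere extension.
#
# Reads carry no prior alignment: anchoring is internal, by exact k-mer
# seeding against the gap flanks followed by collinear chaining.  A read
# anchored to both flanks (with at least anchorLen of chained match per
# flank, reaching the flank edges) patches the gap with its interior when
# the implied span is compatible with the estimated gap size; single-flank
# anchors shrink the gap by extension but never close it (a minimum
# residual of 13 N is kept, junctions are only closed by spanning reads).

#' Fill scaffold N-gaps with long reads
#'
#' @param scaffolds named list of \linkS4class{SeqRecord}
#' @param reads named character vector of read sequences
#' @param nIter number of fill iterations
#' @param anchorLen minimum chained match per flank in bp
#' @param maxGapDelta accept a spanning read when its implied interior is at
#'   most \code{maxGapDelta} times the estimated gap (plus \code{slack} bp)
#' @param k anchor k-mer size
#' @param flankWin flank window length in bp
#' @param slack additive slack on the implied-span guard in bp
#' @param minResidual minimum N residual left by single-flank extension
#' @return list(scaffolds, report = data.frame of per-gap outcomes)
#' @export
fillGaps <- function(scaffolds, reads, nIter = 3L, anchorLen = 300L,
                     maxGapDelta = 2, k = 21L, flankWin = 3000L,
                     slack = 1000L, minResidual = 13L) {
  report <- list()
  nReads <- length(reads)
  rcReads <- revCompVec(reads)
  candidates <- seq_len(nReads)
  for (iter in seq_len(nIter)) {
    # collect gaps and flank windows
    gapTab <- list()
    flanks <- character(0)
    for (sid in names(scaffolds)) {
      g <- findNGaps(scaffolds[[sid]], minExcludedRun = 0L)
      for (i in seq_len(nrow(g))) {
        lw0 <- max(0, g$start[i] - flankWin)
        rw1 <- min(seqLen(scaffolds[[sid]]), g$end[i] + flankWin)
        gi <- length(gapTab) + 1L
        gapTab[[gi]] <- list(sid = sid, gs = g$start[i], ge = g$end[i],
                             lw0 = lw0, rw1 = rw1)
        flanks <- c(flanks,
                    substr(scaffolds[[sid]]@seq, lw0 + 1, g$start[i]),
                    substr(scaffolds[[sid]]@seq, g$end[i] + 1, rw1))
      }
    }
    if (!length(gapTab)) break
    h <- cpp_anchor_hits(flanks, unname(reads)[candidates], as.integer(k), 4L, 3L)
    hrc <- cpp_anchor_hits(flanks, unname(rcReads)[candidates], as.integer(k), 4L, 3L)
    hits <- data.frame(read = candidates[c(h$query, hrc$query)],
                       strand = rep(c("+", "-"), c(length(h$query), length(hrc$query))),
                       qpos = c(h$qpos, hrc$qpos),
                       flank = c(h$target, hrc$target),
                       tpos = c(h$tpos, hrc$tpos))
    if (iter == 1L) candidates <- sort(unique(hits$read))
    hits$gap <- (hits$flank + 1L) %/% 2L
    hits$side <- ifelse(hits$flank %% 2L == 1L, "L", "R")
    # evaluate gaps right-to-left per scaffold so coordinates stay valid
    ord <- order(vapply(gapTab, function(x) x$sid, ""),
                 -vapply(gapTab, function(x) x$gs, 0))
    for (gi in ord) {
      gp <- gapTab[[gi]]
      hh <- hits[hits$gap == gi, , drop = FALSE]
      outcome <- list(scaffold = gp$sid, gap_start = gp$gs,
                      gap_len = gp$ge - gp$gs, iteration = iter,
                      action = "none", read_id = NA_character_,
                      bases_added = 0, n_removed = 0)
      if (nrow(hh)) {
        cand <- evaluateGapReads(hh, gp, reads, rcReads, anchorLen, k,
                                 maxGapDelta, slack)
        rec <- scaffolds[[gp$sid]]
        if (!is.null(cand$span)) {
          cs <- cand$span
          seg <- seqRecord(cs$read_id, cs$seg)
          rec <- concatRecords(gp$sid, list(sliceRecord(rec, 0L, cs$sL), seg,
                                            sliceRecord(rec, cs$sR, seqLen(rec))))
          outcome$action <- "closed"; outcome$read_id <- cs$read_id
          outcome$bases_added <- nchar(cs$seg)
          outcome$n_removed <- gp$ge - gp$gs
          scaffolds[[gp$sid]] <- rec
        } else if (!is.null(cand$extL) || !is.null(cand$extR)) {
          gapN <- gp$ge - gp$gs
          extL <- cand$extL; extR <- cand$extR
          room <- gapN - minResidual
          eL <- if (!is.null(extL)) substr(extL$seg, 1, min(nchar(extL$seg), room)) else ""
          room <- room - nchar(eL)
          eR <- if (!is.null(extR)) substr(extR$seg, max(1, nchar(extR$seg) - room + 1),
                                           nchar(extR$seg)) else ""
          if (nchar(eL) + nchar(eR) > 0) {
            parts <- list(sliceRecord(rec, 0L, gp$gs))
            if (nchar(eL)) parts <- c(parts, list(seqRecord(extL$read_id, eL)))
            parts <- c(parts, list(list(gap = gapN - nchar(eL) - nchar(eR),
                                        kind = "estimated")))
            if (nchar(eR)) parts <- c(parts, list(seqRecord(extR$read_id, eR)))
            parts <- c(parts, list(sliceRecord(rec, gp$ge, seqLen(rec))))
            scaffolds[[gp$sid]] <- concatRecords(gp$sid, parts)
            outcome$action <- "shrunk"
            outcome$bases_added <- nchar(eL) + nchar(eR)
            outcome$n_removed <- nchar(eL) + nchar(eR)
          }
        }
      }
      report[[length(report) + 1L]] <- as.data.frame(outcome, stringsAsFactors = FALSE)
    }
  }
  list(scaffolds = scaffolds,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(scaffold = character(0), gap_start = numeric(0),
                    gap_len = numeric(0), iteration = integer(0),
                    action = character(0), read_id = character(0),
                    bases_added = numeric(0), n_removed = numeric(0)))
}

# Chain per-flank hits for each read/strand over one gap and pick the best
# spanning read (or flank extensions).  Coordinates: sL/sR are scaffold
# cut positions, seg the replacement sequence.
evaluateGapReads <- function(hh, gp, reads, rcReads, anchorLen, k, maxGapDelta,
                             slack, stride = 3L) {
  est <- gp$ge - gp$gs
  lFlankLen <- gp$gs - gp$lw0
  best <- NULL; bestScore <- -Inf
  extL <- NULL; extR <- NULL; extLBp <- 0; extRBp <- 0
  for (keyRead in unique(hh$read)) {
    for (st in c("+", "-")) {
      hr <- hh[hh$read == keyRead & hh$strand == st, , drop = FALSE]
      if (!nrow(hr)) next
      seqR <- if (st == "+") reads[[keyRead]] else rcReads[[keyRead]]
      chL <- chainFlank(hr[hr$side == "L", , drop = FALSE], k, stride)
      chR <- chainFlank(hr[hr$side == "R", , drop = FALSE], k, stride)
      okL <- !is.null(chL) && chL$span >= anchorLen && chL$tEnd >= lFlankLen - 150
      okR <- !is.null(chR) && chR$span >= anchorLen && chR$tStart <= 150
      if (okL && okR && chR$qStart > chL$qEnd - 2 * k) {
        sL <- gp$lw0 + chL$tEnd; sR <- gp$ge + chR$tStart
        implied <- (chR$qStart - chL$qEnd) - (gp$gs - sL) - (sR - gp$ge)
        # implied interior must sit inside the symmetric size window around
        # the map-estimated gap (within a factor of maxGapDelta, plus slack)
        if (implied <= maxGapDelta * est + slack &&
            implied >= est / maxGapDelta - slack && implied >= -(est + slack) &&
            chR$qStart > chL$qEnd) {
          score <- chL$n + chR$n
          if (score > bestScore) {
            bestScore <- score
            best <- list(read_id = names(reads)[keyRead], sL = sL, sR = sR,
                         seg = substr(seqR, chL$qEnd + 1, chR$qStart))
          }
        }
      } else if (okL && chL$tEnd >= lFlankLen - 60) {
        avail <- nchar(seqR) - (chL$qEnd + (gp$gs - (gp$lw0 + chL$tEnd)))
        if (avail > extLBp) {
          start <- chL$qEnd + (gp$gs - (gp$lw0 + chL$tEnd))
          if (start >= 0 && start < nchar(seqR)) {
            extLBp <- avail
            extL <- list(read_id = names(reads)[keyRead],
                         seg = substr(seqR, start + 1, nchar(seqR)))
          }
        }
      } else if (okR && chR$tStart <= 60) {
        avail <- chR$qStart - chR$tStart - (gp$ge - gp$ge)
        if (avail > extRBp) {
          end <- chR$qStart - chR$tStart
          if (end > 0) {
            extRBp <- avail
            extR <- list(read_id = names(reads)[keyRead],
                         seg = substr(seqR, 1, end))
          }
        }
      }
    }
  }
  list(span = best, extL = extL, extR = extR)
}

# Chain hits of one read on one flank: dominant diagonal, monotone, return
# read/flank coordinates of the chain (0-based; *End are exclusive).  A
# genuine match has dense anchors (most sampled k-mer positions hit);
# sparse chains of conserved repeat k-mers are rejected.
chainFlank <- function(hf, k, stride = 3L) {
  if (nrow(hf) < 2L) return(NULL)
  ch <- chainAnchors(hf$qpos, hf$tpos)
  if (is.null(ch) || ch$n < 2L) return(NULL)
  if (ch$n < 0.3 * (ch$tmax - ch$tmin + k) / stride) return(NULL)
  list(n = ch$n, span = ch$tmax - ch$tmin + k,
       qStart = ch$qmin, qEnd = ch$qmax + k,
       tStart = ch$tmin, tEnd = ch$tmax + k)
}

#' Extend scaffold ends with telomere-bearing long reads
#'
#' A candidate read carries a terminal tandem tract of the telomere unit
#' (TTTAGGG, or CCCTAAA on the other strand) of at least \code{minTract} bp
#' at >= 90 percent unit coverage, and anchors uniquely (a single
#' qualifying locus across all scaffold ends) to a scaffold terminus with
#' at least \code{anchorLen} of chained exact match.  Among candidates per
#' end the longest read wins.  Tract orientation must be
#' telomere-consistent: CCCTAAA tracts extend 5' ends, TTTAGGG tracts 3'
#' ends.
#'
#' @param scaffolds named list of \linkS4class{SeqRecord}
#' @param reads named character vector of read sequences
#' @param minTract minimum tract length in bp
#' @param unit telomere repeat unit
#' @param anchorLen minimum chained anchor span in bp
#' @param k anchor k-mer size
#' @param window scaffold terminal window searched for anchors
#' @param unitIdentity minimum unit coverage of the tract
#' @return list(scaffolds, report)
#' @export
extendTelomeres <- function(scaffolds, reads, minTract = 1000L,
                            unit = "TTTAGGG", anchorLen = 300L, k = 21L,
                            window = 20000L, unitIdentity = 0.9) {
  pre <- strrep(unit, 3)
  cand <- which(vapply(reads, function(s)
    grepl(pre, s, fixed = TRUE) || grepl(revComp(pre), s, fixed = TRUE), TRUE))
  report <- list()
  if (!length(cand))
    return(list(scaffolds = scaffolds, report = data.frame()))
  # oriented candidates with a 3'-terminal unit tract
  oriented <- list()
  for (i in cand) {
    for (st in c("+", "-")) {
      s <- if (st == "+") reads[[i]] else revComp(reads[[i]])
      tl <- terminalTractLen(s, unit, unitIdentity)
      if (tl >= minTract)
        oriented[[length(oriented) + 1L]] <- list(read_id = names(reads)[i],
                                                  seq = s, tract = tl)
    }
  }
  if (!length(oriented))
    return(list(scaffolds = scaffolds, report = data.frame()))
  # scaffold terminal windows: suffix of each scaffold ("3p") and suffix of
  # the reverse complement ("5p"); an oriented read extends exactly one kind
  ends <- list()
  for (sid in names(scaffolds)) {
    n <- seqLen(scaffolds[[sid]])
    w <- min(window, n)
    ends[[paste0(sid, ":3p")]] <- substr(scaffolds[[sid]]@seq, n - w + 1, n)
    ends[[paste0(sid, ":5p")]] <- substr(revComp(scaffolds[[sid]]@seq), n - w + 1, n)
  }
  qs <- vapply(oriented, function(x) x$seq, "")
  h <- cpp_anchor_hits(unlist(ends), qs, as.integer(k), 4L, 1L)
  assign <- list()  # per scaffold end: best candidate
  endNames <- names(ends)
  for (ci in unique(h$query)) {
    sel <- h$query == ci
    loci <- list()
    for (ti in unique(h$target[sel])) {
      s2 <- sel & h$target == ti
      ch <- chainAnchors(h$qpos[s2], h$tpos[s2])
      if (is.null(ch) || ch$n < 2L) next
      wlen <- nchar(ends[[ti]])
      tractStart <- nchar(qs[ci]) - oriented[[ci]]$tract
      if (ch$tmax + k < wlen - 1000) next     # must reach near the scaffold tip
      if (ch$qmax + k > tractStart + 200) next # anchor must be pre-tract
      if (ch$tmax - ch$tmin + k < anchorLen) next
      if (ch$n < 0.3 * (ch$tmax - ch$tmin + k)) next  # sparse repeat chain
      loci[[length(loci) + 1L]] <- list(target = ti, ch = ch)
    }
    if (length(loci) != 1L) next  # not uniquely mapped
    l <- loci[[1]]
    key <- endNames[l$target]
    prev <- assign[[key]]
    if (is.null(prev) || nchar(qs[ci]) > nchar(qs[prev$ci]))
      assign[[key]] <- list(ci = ci, ch = l$ch)
  }
  for (key in names(assign)) {
    parts <- strsplit(key, ":")[[1]]
    sid <- parts[1]; endKind <- parts[2]
    a <- assign[[key]]
    rec <- scaffolds[[sid]]
    if (endKind == "5p") rec <- revCompRecord(rec)
    n <- seqLen(rec)
    w <- min(window, n)
    off <- n - w  # window offset on oriented scaffold
    cut <- off + a$ch$tmax + k
    readSeq <- qs[a$ci]
    ext <- substr(readSeq, a$ch$qmax + k + 1, nchar(readSeq))
    if (!nchar(ext)) next
    rec <- concatRecords(sid, list(sliceRecord(rec, 0L, cut),
                                   seqRecord(oriented[[a$ci]]$read_id, ext)))
    if (endKind == "5p") rec <- revCompRecord(rec)
    rec@id <- sid
    added <- seqLen(rec) - seqLen(scaffolds[[sid]])
    scaffolds[[sid]] <- rec
    report[[length(report) + 1L]] <- data.frame(
      scaffold = sid, end = endKind, read_id = oriented[[a$ci]]$read_id,
      added_bp = added, tract_len = oriented[[a$ci]]$tract,
      stringsAsFactors = FALSE)
  }
  list(scaffolds = scaffolds,
       report = if (length(report)) do.call(rbind, report) else data.frame())
}

# Length of the terminal (suffix) tandem tract of `unit` at >= identity
# unit coverage; 0 if none.
terminalTractLen <- function(s, unit, identity) {
  m <- gregexpr(unit, s, fixed = TRUE)[[1]]
  if (m[1] == -1) return(0L)
  m <- as.integer(m)
  n <- nchar(s); u <- nchar(unit)
  if (n - (m[length(m)] + u - 1L) > 50L) return(0L)  # tract must reach the end
  # the tract is the terminal run of unit matches without large holes
  # (an isolated unit far upstream does not extend it)
  gaps <- diff(m)
  brk <- which(gaps > 15L * u)
  first <- if (length(brk)) m[max(brk) + 1L] else m[1]
  mm <- m[m >= first]
  tlen <- n - first + 1L
  cover <- length(mm) * u
  # invert unit coverage through the unit survival model: a single error
  # voids a whole unit, so per-base identity ~ coverage^(1/u)
  if (pmin(1, cover / tlen)^(1 / u) < identity) return(0L)
  tlen
}
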