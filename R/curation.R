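# Step-2 error curation: insertion/deletion discrepancies between contigs
# and rescaled maps, adjudicated across covering maps and patched from the
# alternate assembly where a concordant donor exists.

#' Call insertion/deletion discrepancies from a map alignment
#'
#' For each adjacent matched label pair, the contig span and the map span
#' are compared; a difference larger than \code{minSize} bp is a
#' discrepancy (insertion when the contig span is larger, deletion
#' otherwise).  Call confidence is the mean per-pair transition quality of
#' up to \code{flankPairs} flanking pairs on each side, normalized to
#' [0, 1]; calls below \code{minConfidence} are suppressed.  Zygosity is
#' "unknown" here; cross-map adjudication happens in
#' \code{\link{mergeDiscrepancies}}.
#'
#' @param alignment \linkS4class{MapAlignment} (query = contig digest,
#'   ref = rescaled map)
#' @param query,ref the aligned label maps
#' @param minSize minimum span difference in bp (the "> 1 Kb" rule)
#' @param minConfidence confidence floor (the "at least 0.1" rule)
#' @param params \code{\link{alignParams}} used for flank quality
#' @param flankPairs flanking pairs per side entering the confidence
#' @return data.frame: contig_id, map_id, kind, contig_start, contig_end,
#'   map_start, map_end, size, confidence, zygosity
#' @export
callDiscrepancies <- function(alignment, query, ref, minSize = 1000,
                              minConfidence = 0.1, params = alignParams(),
                              flankPairs = 3L) {
  p <- alignment@pairs
  empty <- data.frame(contig_id = character(0), map_id = character(0),
                      kind = character(0), contig_start = numeric(0),
                      contig_end = numeric(0), map_start = numeric(0),
                      map_end = numeric(0), size = numeric(0),
                      confidence = numeric(0), zygosity = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(p) < 2L) return(empty)
  qpos <- query@labels[p[, 1]]
  rpos <- ref@labels[p[, 2]]
  dq <- abs(diff(qpos)); dr <- diff(rpos)
  # per-transition quality in [0, 1]: 1 when the sizing penalty is zero
  delta <- dq - dr
  meanInt <- pmax((dq + dr) / 2, 1)
  pen <- pmin(delta^2 / (params$sdCoeff^2 * meanInt), params$svCap)
  qual <- pmax(0, pmin(1, 1 - pen / params$svCap))
  rows <- list()
  for (t in which(abs(delta) > minSize)) {
    flank <- setdiff(c(max(1, t - flankPairs):min(length(delta), t + flankPairs)), t)
    conf <- if (length(flank)) mean(qual[flank]) else 0
    if (conf < minConfidence) next
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = alignment@queryId, map_id = alignment@refId,
      kind = if (delta[t] > 0) "insertion" else "deletion",
      contig_start = min(qpos[t], qpos[t + 1L]),
      contig_end = max(qpos[t], qpos[t + 1L]),
      map_start = rpos[t], map_end = rpos[t + 1L],
      size = abs(delta[t]), confidence = conf, zygosity = "unknown",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Merge per-map discrepancy calls and adjudicate zygosity
#'
#' Calls on the same contig whose intervals lie within one median label
#' interval are grouped as one locus.  A locus is homozygous when at least
#' \code{minMaps} maps cover it (their alignment brackets the interval) and
#' every covering map shows a matching call (same kind, size within
#' \code{sizeTol} or half the size); heterozygous when covering maps
#' disagree; unknown with fewer than \code{minMaps} covering maps.
#'
#' @param calls rbind of \code{\link{callDiscrepancies}} outputs across maps
#' @param alignments all alignments of the assembly to the maps
#' @param digests named list of contig digests
#' @param minMaps minimum covering maps for an adjudication
#' @param sizeTol absolute size agreement tolerance in bp
#' @return merged call table with zygosity and \code{n_maps_covering},
#'   \code{n_maps_agree} columns
#' @export
mergeDiscrepancies <- function(calls, alignments, digests, minMaps = 2L,
                               sizeTol = 2000) {
  if (!nrow(calls)) { calls$n_maps_covering <- integer(0); calls$n_maps_agree <- integer(0); return(calls) }
  out <- list()
  for (ctg in unique(calls$contig_id)) {
    cc <- calls[calls$contig_id == ctg, , drop = FALSE]
    cc <- cc[order(cc$contig_start), , drop = FALSE]
    lab <- digests[[ctg]]@labels
    tol <- if (length(lab) > 1) 2 * stats::median(diff(lab)) else 10000
    # cluster calls whose contig intervals overlap (within tol)
    grp <- integer(nrow(cc)); g <- 0L; hi <- -Inf
    for (i in seq_len(nrow(cc))) {
      if (cc$contig_start[i] > hi + tol) { g <- g + 1L; hi <- cc$contig_end[i] }
      else hi <- max(hi, cc$contig_end[i])
      grp[i] <- g
    }
    for (gg in unique(grp)) {
      gcalls <- cc[grp == gg, , drop = FALSE]
      rep_ <- gcalls[which.max(gcalls$confidence), , drop = FALSE]
      covering <- character(0)
      for (a in alignments) {
        if (a@queryId != ctg) next
        qpos <- digests[[ctg]]@labels[a@pairs[, 1]]
        if (min(qpos) <= rep_$contig_start && max(qpos) >= rep_$contig_end)
          covering <- unique(c(covering, a@refId))
      }
      # a covering map agrees when it contributes a matching call
      agree <- unique(gcalls$map_id[gcalls$kind == rep_$kind &
                 abs(gcalls$size - rep_$size) <= pmax(sizeTol, 0.5 * rep_$size)])
      nCov <- length(covering); nAgr <- sum(covering %in% agree)
      rep_$zygosity <- if (nCov < minMaps) "unknown"
                       else if (nAgr == nCov) "homozygous" else "heterozygous"
      rep_$n_maps_covering <- nCov
      rep_$n_maps_agree <- nAgr
      out[[length(out) + 1L]] <- rep_
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Patch a discrepancy with the alternate assembly
#'
#' If an alternate contig aligns to the same map across the call's label
#' interval with no discrepancy of its own, the primary contig's
#' inter-label segment is replaced by the alternate's segment.  Replacement
#' boundaries snap to the matched label positions and are then refined to
#' the nearest exact 20-mer shared by donor and recipient within
#' \code{refineWin} bp, to avoid junction artifacts.  Only homozygous calls
#' above the size and confidence floors are patched; otherwise the contig
#' is returned unchanged with a note.
#'
#' @param primary the primary-assembly \linkS4class{SeqRecord}
#' @param call one merged discrepancy call (see
#'   \code{\link{mergeDiscrepancies}})
#' @param alternates named list of alternate-assembly records
#' @param altAlignments alignments of alternate digests to the maps
#' @param altDigests named list of alternate digests
#' @param maps named list of optical maps
#' @param minSize,minConfidence patching floors
#' @param params \code{\link{alignParams}} for donor discrepancy screening
#' @param refineWin junction refinement window in bp
#' @param primaryOrientation orientation of the primary contig's alignment
#'   to the call's map; a donor whose alignment orientation differs is
#'   reverse complemented before splicing
#' @return list(record, patched, note, donor_id, bases_removed, bases_added)
#' @export
patchWithAlternate <- function(primary, call, alternates, altAlignments,
                               altDigests, maps, minSize = 1000,
                               minConfidence = 0.1, params = alignParams(),
                               refineWin = 500L, primaryOrientation = "+") {
  unchanged <- function(note) list(record = primary, patched = FALSE, note = note,
                                   donor_id = NA_character_, bases_removed = 0,
                                   bases_added = 0)
  if (call$contig_start < 0 || call$contig_end > seqLen(primary))
    stop("call coordinates outside contig")
  if (call$zygosity != "homozygous") return(unchanged("not homozygous"))
  if (call$size <= minSize) return(unchanged("below size floor"))
  if (call$confidence < minConfidence) return(unchanged("below confidence floor"))

  ref <- maps[[call$map_id]]
  for (a in altAlignments) {
    if (a@refId != call$map_id) next
    donor <- alternates[[a@queryId]]
    if (is.null(donor)) next
    dq <- altDigests[[a@queryId]]
    rpos <- ref@labels[a@pairs[, 2]]
    if (min(rpos) > call$map_start || max(rpos) < call$map_end) next
    # donor must be clean across the interval
    dcalls <- callDiscrepancies(a, dq, ref, minSize = minSize,
                                minConfidence = 0, params = params)
    if (nrow(dcalls) && any(dcalls$map_start < call$map_end &
                            dcalls$map_end > call$map_start)) next
    # donor label positions bracketing the call's map interval
    if (!any(rpos <= call$map_start) || !any(rpos >= call$map_end)) next
    iL <- max(which(rpos <= call$map_start))
    iR <- min(which(rpos >= call$map_end))
    dposL <- dq@labels[a@pairs[iL, 1]]; dposR <- dq@labels[a@pairs[iR, 1]]
    flip <- a@orientation != primaryOrientation
    dseg <- sort(c(dposL, dposR))
    # pad: map interval may extend past the call's labels on the primary
    dstart <- max(0, dseg[1] - 1); dend <- min(seqLen(donor), dseg[2])
    donorOri <- if (flip) revCompRecord(donor) else donor
    if (flip) { tmp <- seqLen(donor) - c(dend, dstart); dstart <- tmp[1]; dend <- tmp[2] }
    pstart <- call$contig_start - 1; pend <- call$contig_end
    # refine both junctions to shared exact 20-mers
    refL <- refineJunction(primary@seq, donorOri@seq, pstart, dstart, refineWin)
    refR <- refineJunction(primary@seq, donorOri@seq, pend, dend, refineWin)
    pstart <- refL$a; dstart <- refL$b; pend <- refR$a; dend <- refR$b
    if (dend <= dstart || pend <= pstart) next
    slice <- sliceRecord(donorOri, dstart, dend)
    rec <- replaceSegment(primary, pstart, pend, slice)
    return(list(record = rec, patched = TRUE, note = "patched",
                donor_id = donor@id, bases_removed = pend - pstart,
                bases_added = dend - dstart))
  }
  unchanged("no concordant donor")
}

# Find an exact shared k-mer near positions (posA on a, posB on b) and return
# refined cut coordinates; falls back to the input positions.
refineJunction <- function(a, b, posA, posB, win = 500L, k = 20L) {
  aw <- c(max(0, posA - win), min(nchar(a), posA + win))
  bw <- c(max(0, posB - win), min(nchar(b), posB + win))
  if (diff(aw) < k || diff(bw) < k) return(list(a = posA, b = posB))
  sa <- substr(a, aw[1] + 1, aw[2]); sb <- substr(b, bw[1] + 1, bw[2])
  h <- cpp_anchor_hits(sa, sb, as.integer(k), 4L, 1L)
  if (!length(h$qpos)) return(list(a = posA, b = posB))
  pa <- aw[1] + h$tpos; pb <- bw[1] + h$qpos
  drift <- abs((pa - posA) - (pb - posB))
  near <- abs(pa - posA) + abs(pb - posB)
  i <- order(drift, near)[1]
  list(a = pa[i], b = pb[i])
}
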