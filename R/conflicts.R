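# Map-vs-sequence conflict detection and chimeric contig cutting.
#
# A chimeric contig joins two regions that do not belong together; aligned
# against an optical map, the alignment terminates inside the contig with
# substantial unaligned label/sequence overhang on both the contig and the
# map.  Junctions are scored by how many independent maps align contiguously
# through a window around them, and junctions with insufficient support are
# cut.  The map is always trusted over the sequence.

#' Detect conflicts between contig digests and optical maps
#'
#' A conflict is emitted where an alignment terminates with at least
#' \code{minOverhangLabels} unaligned labels and \code{minOverhangBp}
#' unaligned bp beyond the terminus on \emph{both} the contig and the map.
#' The junction is placed at the contig position of the terminal paired
#' label (only label positions are evidence-bearing).
#'
#' @param alignments list of \linkS4class{MapAlignment} (query = contig
#'   digest, ref = optical map)
#' @param digests named list of contig digest \linkS4class{LabelMap}s
#' @param maps named list of optical \linkS4class{LabelMap}s
#' @param minOverhangLabels,minOverhangBp overhang thresholds
#' @return data.frame: contig_id, junction_bp, junction_label_idx, map_id,
#'   side, overhang_labels_contig, overhang_bp_contig, overhang_labels_map,
#'   overhang_bp_map, support_score (NA until scored)
#' @export
detectConflicts <- function(alignments, digests, maps,
                            minOverhangLabels = 5L, minOverhangBp = 50000L) {
  rows <- list()
  for (a in alignments) {
    q <- digests[[a@queryId]]; r <- maps[[a@refId]]
    if (is.null(q) || is.null(r)) next
    p <- a@pairs
    nq <- length(q@labels); nr <- length(r@labels)
    for (side in c("start", "end")) {
      if (side == "start") { qi <- p[1, 1]; ri <- p[1, 2] }
      else { qi <- p[nrow(p), 1]; ri <- p[nrow(p), 2] }
      rpos <- r@labels[ri]; qpos <- q@labels[qi]
      if (side == "start") { mapLab <- ri - 1L; mapBp <- rpos - 0 }
      else { mapLab <- nr - ri; mapBp <- r@length - rpos }
      # which contig side extends beyond this terminus
      qLow <- (a@orientation == "+") == (side == "start")
      if (qLow) { ctgLab <- qi - 1L; ctgBp <- qpos - 0 }
      else { ctgLab <- nq - qi; ctgBp <- q@length - qpos }
      if (ctgLab >= minOverhangLabels && ctgBp >= minOverhangBp &&
          mapLab >= minOverhangLabels && mapBp >= minOverhangBp) {
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = a@queryId, junction_bp = qpos, junction_label_idx = qi,
          map_id = a@refId, side = side,
          overhang_labels_contig = ctgLab, overhang_bp_contig = ctgBp,
          overhang_labels_map = mapLab, overhang_bp_map = mapBp,
          support_score = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = character(0), junction_bp = numeric(0),
                      junction_label_idx = integer(0), map_id = character(0),
                      side = character(0), overhang_labels_contig = integer(0),
                      overhang_bp_contig = numeric(0), overhang_labels_map = integer(0),
                      overhang_bp_map = numeric(0), support_score = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Score junction support from independent map alignments
#'
#' Among alignments of the conflict's contig whose paired labels span a
#' window of +/- \code{window} contig labels around the junction, the
#' support score is 100 times the fraction that align contiguously through
#' the window (every contig label inside the window is paired).  No
#' spanning map gives score 0.
#'
#' @param conflict one row of the \code{\link{detectConflicts}} table
#' @param alignments all contig-vs-map alignments of the assembly
#' @param digests named list of contig digests
#' @param window half-width of the label window
#' @return numeric support score in [0, 100]
#' @export
scoreJunctionSupport <- function(conflict, alignments, digests, window = 3L) {
  ctg <- conflict$contig_id
  ji <- conflict$junction_label_idx
  nq <- length(digests[[ctg]]@labels)
  lo <- max(1L, ji - window); hi <- min(nq, ji + window)
  spanning <- 0L; contiguous <- 0L
  for (a in alignments) {
    if (a@queryId != ctg) next
    qi <- a@pairs[, 1]
    if (min(qi) <= lo && max(qi) >= hi) {
      spanning <- spanning + 1L
      if (all(lo:hi %in% qi)) contiguous <- contiguous + 1L
    }
  }
  if (spanning == 0L) return(0)
  100 * contiguous / spanning
}

#' Cut contigs at unsupported junctions
#'
#' Junctions with \code{support_score < supportCut} are cut at
#' \code{junction_bp}.  Junctions closer than \code{clusterBp} are collapsed
#' to their median position first (several maps typically report the same
#' junction within sizing noise).  Fragments are suffixed ".1", ".2", ... in
#' coordinate order, provenance is preserved, and fragments shorter than
#' \code{shortFloor} are kept but flagged in the ledger.
#'
#' @param contigs named list of \linkS4class{SeqRecord}
#' @param conflicts scored conflict table
#' @param supportCut cut when support is strictly below this value
#' @param clusterBp junction clustering distance
#' @param shortFloor flag fragments shorter than this many bp
#' @return list(contigs = named list of records after cutting,
#'   ledger = data.frame(fragment_id, source_id, start, end, flagged_short))
#' @export
cutContigs <- function(contigs, conflicts, supportCut = 35, clusterBp = 5000L,
                       shortFloor = 20000L) {
  ledger <- list()
  out <- list()
  toCut <- conflicts[!is.na(conflicts$support_score) &
                     conflicts$support_score < supportCut, , drop = FALSE]
  for (id in names(contigs)) {
    rec <- contigs[[id]]
    n <- seqLen(rec)
    tc <- toCut[toCut$contig_id == id, , drop = FALSE]
    tc <- tc[order(tc$junction_bp), , drop = FALSE]
    cuts <- numeric(0)
    if (nrow(tc)) {
      if (any(tc$junction_bp <= 0 | tc$junction_bp >= n))
        stop(sprintf("junction outside contig '%s'", id))
      grp <- cumsum(c(1, diff(tc$junction_bp) > clusterBp))
      # within a cluster, alignments ending at the junction ("end" side)
      # under-reach it and those starting there over-reach: take the
      # innermost terminal label per side, then their midpoint
      cuts <- round(vapply(split(seq_len(nrow(tc)), grp), function(ix) {
        jb <- tc$junction_bp[ix]; sd_ <- tc$side[ix]
        reps <- c(if (any(sd_ == "end")) max(jb[sd_ == "end"]),
                  if (any(sd_ == "start")) min(jb[sd_ == "start"]))
        mean(reps)
      }, 0))
    }
    bounds <- unique(c(0, cuts, n))
    if (length(bounds) == 2L) {
      out[[id]] <- rec
      ledger[[length(ledger) + 1L]] <- data.frame(
        fragment_id = id, source_id = id, start = 0, end = n,
        flagged_short = n < shortFloor, stringsAsFactors = FALSE)
      next
    }
    for (i in seq_len(length(bounds) - 1L)) {
      fid <- sprintf("%s.%d", id, i)
      out[[fid]] <- sliceRecord(rec, bounds[i], bounds[i + 1L], newId = fid)
      ledger[[length(ledger) + 1L]] <- data.frame(
        fragment_id = fid, source_id = id, start = bounds[i], end = bounds[i + 1L],
        flagged_short = (bounds[i + 1L] - bounds[i]) < shortFloor,
        stringsAsFactors = FALSE)
    }
  }
  list(contigs = out, ledger = do.call(rbind, ledger))
}
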