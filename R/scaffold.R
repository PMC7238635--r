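# Hybrid scaffolding: placing contigs along optical maps, estimating gaps
# from map coordinates, annotating placement overlaps as 13N junctions, and
# resolving those junctions by sequence-level merging.

#' Best map placements for contigs
#'
#' Each contig takes its best-scoring alignment; the placement interval on
#' the map is the aligned span extended by the unaligned contig tails.  A
#' contig whose two best alignments score equally (on different maps or
#' positions) is reported as ambiguous and left unplaced.
#'
#' @param alignments list of \linkS4class{MapAlignment} (query = contig)
#' @param digests named list of contig digests
#' @param maps named list of optical maps
#' @param restrictMaps optional map ids to consider
#' @return list(placements = data.frame(contig_id, map_id, orientation,
#'   map_start, map_end, score), ambiguous = character vector)
#' @export
contigPlacements <- function(alignments, digests, maps, restrictMaps = NULL) {
  rows <- list()
  for (a in alignments) {
    if (!is.null(restrictMaps) && !a@refId %in% restrictMaps) next
    q <- digests[[a@queryId]]; r <- maps[[a@refId]]
    if (is.null(q) || is.null(r)) next
    p <- a@pairs
    qposF <- q@labels[p[1, 1]]; qposL <- q@labels[p[nrow(p), 1]]
    rposF <- r@labels[p[1, 2]]; rposL <- r@labels[p[nrow(p), 2]]
    if (a@orientation == "+") { tailL <- qposF - 1; tailR <- q@length - qposL }
    else { tailL <- q@length - qposF; tailR <- qposL - 1 }
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = a@queryId, map_id = a@refId, orientation = a@orientation,
      map_start = rposF - tailL, map_end = rposL + tailR, score = a@score,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(placements = data.frame(contig_id = character(0), map_id = character(0),
                orientation = character(0), map_start = numeric(0),
                map_end = numeric(0), score = numeric(0)), ambiguous = character(0)))
  d <- do.call(rbind, rows)
  placements <- list(); ambiguous <- character(0)
  for (ctg in unique(d$contig_id)) {
    di <- d[d$contig_id == ctg, , drop = FALSE]
    di <- di[order(-di$score), , drop = FALSE]
    if (nrow(di) > 1 && abs(di$score[1] - di$score[2]) < 1e-9 &&
        (di$map_id[1] != di$map_id[2] ||
         abs(di$map_start[1] - di$map_start[2]) > 1)) {
      ambiguous <- c(ambiguous, ctg)
      next
    }
    placements[[length(placements) + 1L]] <- di[1, ]
  }
  list(placements = if (length(placements)) do.call(rbind, placements) else d[0, ],
       ambiguous = ambiguous)
}

#' Map-guided adjacency and gap estimation
#'
#' Consecutive contigs placed on the same map yield an estimated gap equal
#' to the map distance between their facing aligned ends.  A negative gap
#' whose magnitude is at least \code{minDetectableOverlap} marks a large
#' overlap that should be merged at the sequence level immediately; smaller
#' negatives are deferred to hybrid scaffolding (13N junctions).
#'
#' @param placements placement table from \code{\link{contigPlacements}}
#' @param minDetectableOverlap detectability floor in bp (map-level overlap
#'   resolution; roughly 200 kb at full scale)
#' @return data.frame: map_id, left_contig, right_contig, estimated_gap_bp,
#'   action ("gap", "overlap13N" or "merge")
#' @export
mapGuidedAdjacency <- function(placements, minDetectableOverlap = 200000L) {
  rows <- list()
  for (m in unique(placements$map_id)) {
    pm <- placements[placements$map_id == m, , drop = FALSE]
    pm <- pm[order(pm$map_start), , drop = FALSE]
    if (nrow(pm) < 2) next
    for (i in seq_len(nrow(pm) - 1L)) {
      gp <- pm$map_start[i + 1L] - pm$map_end[i]
      action <- if (gp > 0) "gap" else if (-gp >= minDetectableOverlap) "merge" else "overlap13N"
      rows[[length(rows) + 1L]] <- data.frame(
        map_id = m, left_contig = pm$contig_id[i],
        right_contig = pm$contig_id[i + 1L], estimated_gap_bp = gp,
        action = action, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(map_id = character(0), left_contig = character(0),
                      right_contig = character(0), estimated_gap_bp = numeric(0),
                      action = character(0)))
  do.call(rbind, rows)
}

#' Hybrid scaffolding along optical maps
#'
#' Contigs are ordered and oriented by their placements on each anchor map.
#' Positive inter-contig gaps become N runs of the estimated size (minimum
#' 100 N); junctions whose placements overlap get exactly 13 N annotated as
#' kind \code{overlap13N}.  Contigs without a placement (or with ambiguous
#' placements) are returned as leftovers.
#'
#' @param contigs named list of \linkS4class{SeqRecord}
#' @param maps named list of optical maps
#' @param alignments contig-vs-map alignments
#' @param digests named list of contig digests
#' @param anchorMaps map ids to scaffold along (default: all maps with
#'   placements; with replicate maps pass a non-redundant cover, see
#'   \code{\link{selectAnchorMaps}})
#' @param minGap minimum emitted N-gap size
#' @return list(scaffolds = named record list, agp, placements, leftover =
#'   named record list, notes)
#' @export
hybridScaffold <- function(contigs, maps, alignments, digests,
                           anchorMaps = NULL, minGap = 100L, minRel = 0.5) {
  # a contig may only be placed on an anchor map if that alignment is
  # comparable to its best alignment anywhere (weak off-target alignments
  # must not steal a contig whose true map was not selected as an anchor)
  alignments <- filterStrongAlignments(alignments, minRel)
  pl <- contigPlacements(alignments, digests, maps, restrictMaps = anchorMaps)
  placements <- pl$placements
  notes <- if (length(pl$ambiguous))
    sprintf("ambiguous placement: %s", paste(pl$ambiguous, collapse = ",")) else character(0)
  scaffolds <- list()
  sn <- 0L
  placedIds <- character(0)
  scMap <- list()
  for (m in unique(placements$map_id)) {
    pm <- placements[placements$map_id == m, , drop = FALSE]
    pm <- pm[order(pm$map_start, -(pm$map_end - pm$map_start)), , drop = FALSE]
    # drop placements contained within an already accepted placement
    # (redundant duplicates of sequence another contig already provides)
    keep <- logical(nrow(pm)); hi <- -Inf
    for (i in seq_len(nrow(pm))) {
      if (pm$map_end[i] <= hi + 1000) {
        notes <- c(notes, sprintf("redundant placement: %s within %s on %s",
                                  pm$contig_id[i], pm$contig_id[which(keep)[sum(keep)]], m))
      } else { keep[i] <- TRUE; hi <- max(hi, pm$map_end[i]) }
    }
    pm <- pm[keep, , drop = FALSE]
    sn <- sn + 1L
    sid <- sprintf("scf%d", sn)
    parts <- list()
    for (i in seq_len(nrow(pm))) {
      if (i > 1L) {
        gp <- pm$map_start[i] - pm$map_end[i - 1L]
        if (gp > 0) parts[[length(parts) + 1L]] <- list(gap = max(round(gp), minGap),
                                                        kind = "estimated")
        else parts[[length(parts) + 1L]] <- list(gap = 13L, kind = "overlap13N")
      }
      parts[[length(parts) + 1L]] <-
        orientRecord(contigs[[pm$contig_id[i]]], pm$orientation[i])
    }
    scaffolds[[sid]] <- concatRecords(sid, parts)
    scMap[[sid]] <- m
    placedIds <- c(placedIds, pm$contig_id)
  }
  leftover <- contigs[setdiff(names(contigs), placedIds)]
  list(scaffolds = scaffolds, agp = agpFromRecords(scaffolds),
       placements = placements, leftover = leftover,
       scaffold_map = unlist(scMap), notes = notes)
}

#' Derive AGP from record provenance
#'
#' Provenance blocks become W rows (with component sub-ranges and
#' orientation); \code{gap:*} blocks become N rows carrying the gap kind in
#' the gap-type column.  Adjacent blocks from the same source are coalesced
#' when contiguous.
#'
#' @param records named list of \linkS4class{SeqRecord}
#' @return AGP data.frame (see \code{\link{writeAGP}})
#' @export
agpFromRecords <- function(records) {
  rows <- list()
  for (rec in records) {
    p <- coalesceProvenance(rec@provenance)
    for (i in seq_len(nrow(p))) {
      isGap <- startsWith(p$source_id[i], "gap:")
      rows[[length(rows) + 1L]] <- if (isGap)
        data.frame(object = rec@id, object_beg = p$start[i] + 1, object_end = p$end[i],
                   part_number = i, component_type = "N", component_id = NA_character_,
                   component_beg = NA_real_, component_end = NA_real_,
                   orientation = NA_character_, gap_length = p$end[i] - p$start[i],
                   gap_type = sub("^gap:", "", p$source_id[i]), stringsAsFactors = FALSE)
      else
        data.frame(object = rec@id, object_beg = p$start[i] + 1, object_end = p$end[i],
                   part_number = i, component_type = "W", component_id = p$source_id[i],
                   component_beg = p$src_start[i] + 1, component_end = p$src_end[i],
                   orientation = p$strand[i], gap_length = NA_real_,
                   gap_type = NA_character_, stringsAsFactors = FALSE)
    }
  }
  agp <- do.call(rbind, rows)
  validateAGP(agp)
  agp
}

# Keep only alignments scoring at least minRel of their contig's best.
filterStrongAlignments <- function(alignments, minRel = 0.5) {
  if (!length(alignments)) return(alignments)
  best <- tapply(vapply(alignments, function(a) a@score, 0),
                 vapply(alignments, function(a) a@queryId, ""), max)
  Filter(function(a) a@score >= minRel * best[[a@queryId]], alignments)
}

# Merge consecutive provenance blocks with the same source, strand and
# contiguous source coordinates.
coalesceProvenance <- function(p) {
  if (nrow(p) < 2L) return(p)
  p <- p[order(p$start), , drop = FALSE]
  out <- p[1, , drop = FALSE]
  for (i in 2:nrow(p)) {
    j <- nrow(out)
    contiguous <- p$source_id[i] == out$source_id[j] &&
      p$strand[i] == out$strand[j] && p$start[i] == out$end[j] &&
      !startsWith(p$source_id[i], "gap:") &&
      ((p$strand[i] == "+" && p$src_start[i] == out$src_end[j]) ||
       (p$strand[i] == "-" && p$src_end[i] == out$src_start[j]))
    if (contiguous) {
      out$end[j] <- p$end[i]
      if (p$strand[i] == "+") out$src_end[j] <- p$src_end[i]
      else out$src_start[j] <- p$src_start[i]
    } else out <- rbind(out, p[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

#' Reconstruct object sequences from an AGP and component records
#'
#' @param agp AGP data.frame
#' @param components named list of component \linkS4class{SeqRecord}s
#' @return named list of reconstructed records
#' @export
sequenceFromAGP <- function(agp, components) {
  out <- list()
  for (obj in unique(agp$object)) {
    a <- agp[agp$object == obj, , drop = FALSE]
    a <- a[order(a$part_number), , drop = FALSE]
    parts <- list()
    for (i in seq_len(nrow(a))) {
      if (a$component_type[i] == "W") {
        comp <- components[[a$component_id[i]]]
        if (is.null(comp)) stop(sprintf("missing component '%s'", a$component_id[i]))
        sl <- sliceRecord(comp, a$component_beg[i] - 1, a$component_end[i])
        parts[[length(parts) + 1L]] <- orientRecord(sl, a$orientation[i])
      } else {
        parts[[length(parts) + 1L]] <- list(gap = a$gap_length[i],
                                            kind = ifelse(is.na(a$gap_type[i]), "unknown", a$gap_type[i]))
      }
    }
    out[[obj]] <- concatRecords(obj, parts)
  }
  out
}

#' Resolve 13N overlap junctions by sequence merging
#'
#' For every 13N junction (kind \code{overlap13N}) the flanking scaffold
#' windows are searched for a dovetail overlap; on success the junction is
#' spliced into continuous sequence (the gap disappears from the AGP), on
#' failure the 13N gap is retained.  Junctions adjacent to contigs listed
#' in \code{skipContigs} (regions flagged unmergeable, e.g. an rDNA/NOR
#' analogue) are skipped.
#'
#' @param bundle result of \code{\link{hybridScaffold}}
#' @param k,minOverlap,minIdentity,maxOverhang overlap detection parameters
#' @param window flanking window searched on each side of a junction
#' @param skipContigs component ids whose junctions are never merged
#' @param junctionTail tolerated foreign-remnant length between the
#'   overlap and the junction on either side
#' @return updated bundle; \code{$resolved} counts merged junctions
#' @export
resolve13NOverlaps <- function(bundle, k = 21L, minOverlap = 2000L,
                               minIdentity = 0.9, maxOverhang = 500L,
                               window = 300000L, skipContigs = character(0),
                               junctionTail = 15000L) {
  resolved <- 0L; retained <- 0L
  for (sid in names(bundle$scaffolds)) {
    rec <- bundle$scaffolds[[sid]]
    repeat {
      p <- rec@provenance
      gidx <- which(p$source_id == "gap:overlap13N")
      done <- TRUE
      for (g in gidx) {
        gs <- p$start[g]; ge <- p$end[g]
        flankIds <- c(if (g > 1) p$source_id[g - 1L], if (g < nrow(p)) p$source_id[g + 1L])
        if (any(flankIds %in% skipContigs)) next
        lw <- c(max(0, gs - window), gs)
        rw <- c(ge, min(seqLen(rec), ge + window))
        ls <- substr(rec@seq, lw[1] + 1, lw[2])
        rs <- substr(rec@seq, rw[1] + 1, rw[2])
        ov <- findSequenceOverlaps(list(seqRecord("L", ls)), list(seqRecord("R", rs)),
                                   k = k, minOverlap = minOverlap,
                                   minIdentity = minIdentity,
                                   maxOverhang = maxOverhang)
        # the overlap must reach the junction on both sides, allowing a
        # short foreign remnant (e.g. left by a label-resolution chimera
        # cut) to sit between the overlap and the junction
        ov <- ov[ov$orientation == "+" &
                 ov$a_end >= nchar(ls) - junctionTail &
                 ov$b_start <= junctionTail, , drop = FALSE]
        if (!nrow(ov)) next
        ref <- refineJunction(ls, rs, ov$a_end[1], ov$b_end[1], win = 2000L)
        rec <- concatRecords(sid, list(sliceRecord(rec, 0L, lw[1] + ref$a),
                                       sliceRecord(rec, rw[1] + ref$b, seqLen(rec))))
        resolved <- resolved + 1L
        done <- FALSE
        break  # provenance indices changed; rescan
      }
      if (done) break
    }
    retained <- retained + sum(rec@provenance$source_id == "gap:overlap13N")
    bundle$scaffolds[[sid]] <- rec
  }
  bundle$agp <- agpFromRecords(bundle$scaffolds)
  bundle$resolved <- resolved
  bundle$retained13N <- retained
  bundle
}

#' Select a non-redundant set of anchor maps
#'
#' With replicate optical maps covering the same region, scaffolding along
#' every map would place each contig several times.  Greedy set cover picks
#' maps in order of how many not-yet-covered contigs they place; remaining
#' maps still contribute to junction support and zygosity evidence.
#'
#' @param alignments contig-vs-map alignments
#' @param digests named list of contig digests
#' @param maps named list of optical maps
#' @return character vector of map ids
#' @export
selectAnchorMaps <- function(alignments, digests, maps, minRel = 0.5) {
  alignments <- filterStrongAlignments(alignments, minRel)
  byMap <- list()
  for (a in alignments)
    byMap[[a@refId]] <- unique(c(byMap[[a@refId]], a@queryId))
  chosen <- character(0)
  covered <- character(0)
  repeat {
    gain <- vapply(byMap, function(x) length(setdiff(x, covered)), 0L)
    if (!length(gain) || max(gain) == 0L) break
    # deterministic tie-break: most labels, then id
    best <- names(gain)[gain == max(gain)]
    if (length(best) > 1L) {
      nl <- vapply(best, function(m) length(maps[[m]]@labels), 0L)
      best <- best[order(-nl, best)]
    }
    chosen <- c(chosen, best[1])
    covered <- unique(c(covered, byMap[[best[1]]]))
    byMap[[best[1]]] <- NULL
  }
  chosen
}
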