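# Sequence overlap detection (k-mer anchors + collinear chaining) and
# unbranched unitig merging.
#
# Identity is estimated from the fraction s of sampled k-mer start positions
# inside the overlap that carry a chained exact anchor, inverted through the
# k-mer survival model: identity ~ s^(1/k).  Raw anchor coverage would
# systematically underestimate identity in the presence of read error.

#' Find overlaps between two contig sets
#'
#' Exact k-mer anchors between every pair (one set is indexed, the other
#' streamed in both orientations) are chained collinearly on the dominant
#' diagonal; chains shorter than \code{minOverlap} bp or with estimated
#' identity below \code{minIdentity} are discarded.  Each retained overlap
#' is classified as dovetail (both overlap ends within \code{maxOverhang}
#' of the respective contig ends), containment, or internal.
#'
#' @param setA,setB named lists of \linkS4class{SeqRecord}
#' @param k anchor k-mer size (15-32)
#' @param minOverlap minimum overlap span in bp
#' @param minIdentity minimum estimated identity
#' @param maxOverhang dovetail slack in bp
#' @param stride anchor sampling stride on the query side
#' @param maxOcc k-mers occurring more often than this in the index are
#'   ignored (repeat masking)
#' @return data.frame: a_id, b_id, a_start, a_end, b_start, b_end (0-based
#'   half-open, original coordinates), orientation, identity, kind,
#'   n_anchors
#' @export
findSequenceOverlaps <- function(setA, setB, k = 21L, minOverlap = 5000L,
                                 minIdentity = 0.9, maxOverhang = 500L,
                                 stride = 10L, maxOcc = 8L) {
  if (k < 15L) stop("k must be >= 15")
  emptyOv <- data.frame(a_id = character(0), b_id = character(0),
                        a_start = numeric(0), a_end = numeric(0),
                        b_start = numeric(0), b_end = numeric(0),
                        orientation = character(0), identity = numeric(0),
                        kind = character(0), n_anchors = integer(0),
                        stringsAsFactors = FALSE)
  if (!length(setA) || !length(setB)) return(emptyOv)
  aSeq <- vapply(setA, seqString, "")
  bSeq <- vapply(setB, seqString, "")
  aIds <- vapply(setA, seqId, ""); bIds <- vapply(setB, seqId, "")
  aLen <- nchar(aSeq); bLen <- nchar(bSeq)
  rows <- list()
  nb <- length(bSeq)
  h <- cpp_anchor_hits(unname(aSeq), c(unname(bSeq), unname(revCompVec(bSeq))),
                       as.integer(k), as.integer(maxOcc), as.integer(stride))
  if (length(h$qpos)) {
    strandV <- ifelse(h$query > nb, "-", "+")
    h$query <- ((h$query - 1L) %% nb) + 1L
    key <- (h$target * (nb + 1) + h$query) * 2 + (strandV == "-")
    byPair <- split(seq_along(key), key)
    for (sel in byPair) {
      strand <- strandV[sel][1]
      ti <- h$target[sel][1]; qi <- h$query[sel][1]
      if (aIds[ti] == bIds[qi]) next  # same record present in both sets
      ch <- chainAnchors(h$qpos[sel], h$tpos[sel])
      if (is.null(ch) || ch$n < 3L) next
      spanQ <- ch$qmax - ch$qmin + k
      spanT <- ch$tmax - ch$tmin + k
      span <- max(spanQ, spanT)
      if (span < minOverlap) next
      s <- min(1, ch$n / (spanQ / stride))
      identity <- s^(1 / k)
      if (identity < minIdentity) next
      # back to original b coordinates
      if (strand == "+") { b0 <- ch$qmin; b1 <- ch$qmax + k }
      else { b0 <- bLen[qi] - (ch$qmax + k); b1 <- bLen[qi] - ch$qmin }
      a0 <- ch$tmin; a1 <- ch$tmax + k
      kind <- classifyOverlap(a0, a1, aLen[ti], b0, b1, bLen[qi], strand, maxOverhang)
      rows[[length(rows) + 1L]] <- data.frame(
        a_id = aIds[ti], b_id = bIds[qi], a_start = a0, a_end = a1,
        b_start = b0, b_end = b1, orientation = strand,
        identity = identity, kind = kind, n_anchors = ch$n,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyOv)
  out <- do.call(rbind, rows)
  out[order(out$a_id, out$b_id, -out$n_anchors), , drop = FALSE]
}

# Dominant-diagonal collinear chaining of (qpos, tpos) anchor pairs.
chainAnchors <- function(qpos, tpos, diagBin = 2000L) {
  d <- tpos - qpos
  bin <- floor(d / diagBin)
  tb <- table(bin)
  top <- as.integer(names(tb)[which.max(tb)])
  sel <- bin >= top - 1L & bin <= top + 1L
  q <- qpos[sel]; t <- tpos[sel]
  o <- order(q, t)
  q <- q[o]; t <- t[o]
  keep <- logical(length(q))
  last <- -Inf
  for (i in seq_along(q)) {        # greedy monotone filter on target side
    if (t[i] > last) { keep[i] <- TRUE; last <- t[i] }
  }
  q <- q[keep]; t <- t[keep]
  if (!length(q)) return(NULL)
  list(n = length(q), qmin = min(q), qmax = max(q), tmin = min(t), tmax = max(t))
}

classifyOverlap <- function(a0, a1, aL, b0, b1, bL, strand, slack) {
  aAtStart <- a0 <= slack; aAtEnd <- a1 >= aL - slack
  bAtStart <- b0 <= slack; bAtEnd <- b1 >= bL - slack
  if (bAtStart && bAtEnd) return("containment")   # b inside a
  if (aAtStart && aAtEnd) return("containment")   # a inside b
  if (strand == "+") {
    if ((aAtEnd && bAtStart) || (bAtEnd && aAtStart)) return("dovetail")
  } else {
    if ((aAtEnd && bAtEnd) || (aAtStart && bAtStart)) return("dovetail")
  }
  "internal"
}

#' Drop contigs contained in another contig
#'
#' @param contigs named list of records
#' @param overlaps overlap table from \code{\link{findSequenceOverlaps}}
#' @return list(contigs, dropped = character vector of contained ids)
#' @export
dropContained <- function(contigs, overlaps, maxTail = 5000L) {
  dropped <- character(0)
  for (i in seq_len(nrow(overlaps))) {
    r <- overlaps[i, ]
    aL <- seqLen(contigs[[r$a_id]]); bL <- seqLen(contigs[[r$b_id]])
    inner <- if (bL <= aL) "b" else "a"
    iL <- min(aL, bL)
    i0 <- if (inner == "a") r$a_start else r$b_start
    i1 <- if (inner == "a") r$a_end else r$b_end
    # containment proper, or an overlap leaving only short unmatched tails
    # on the shorter contig (tolerates chimeric/cut remnants at its ends)
    if (r$kind == "containment" || max(i0, iL - i1) <= maxTail)
      dropped <- unique(c(dropped, if (inner == "a") r$a_id else r$b_id))
  }
  list(contigs = contigs[setdiff(names(contigs), dropped)], dropped = dropped)
}

#' Merge dovetailing contigs into unitigs
#'
#' Builds the oriented overlap graph from dovetail overlaps, keeps only
#' unambiguous edges (a contig end with more than one dovetail partner is a
#' branch and merges nothing), and merges maximal unbranched paths into
#' unitigs.  At each junction the retained bases follow the donor policy:
#' where both contigs cover the overlap, bases come from the
#' primary-assembly contig if exactly one side is primary, otherwise from
#' the left contig.  Junctions are spliced at an exact shared 20-mer.
#' A circular unbranched path is reported and left unmerged.
#'
#' @param contigs named list of records
#' @param overlaps overlap table (only dovetail rows are used)
#' @param primaryIds ids considered primary-assembly for the donor policy
#' @return list(records = named list after merging, info = data.frame of
#'   unitig composition, branches = ids of branching ends,
#'   circular = logical)
#' @export
mergeOverlapping <- function(contigs, overlaps, primaryIds = character(0)) {
  dt <- overlaps[overlaps$kind == "dovetail", , drop = FALSE]
  mkNode <- function(id, o) paste0(id, o)
  edges <- list()  # from oriented node -> list(to, row)
  addEdge <- function(from, to, row) {
    edges[[from]] <<- c(edges[[from]], list(list(to = to, row = row)))
  }
  for (i in seq_len(nrow(dt))) {
    r <- dt[i, ]
    aL <- seqLen(contigs[[r$a_id]]); bL <- seqLen(contigs[[r$b_id]])
    slack <- max(1000, 0.05 * min(r$a_end - r$a_start, r$b_end - r$b_start))
    aAtEnd <- r$a_end >= aL - slack; aAtStart <- r$a_start <= slack
    bAtEnd <- r$b_end >= bL - slack; bAtStart <- r$b_start <= slack
    if (r$orientation == "+") {
      if (aAtEnd && bAtStart) { addEdge(mkNode(r$a_id, "+"), mkNode(r$b_id, "+"), i)
                                addEdge(mkNode(r$b_id, "-"), mkNode(r$a_id, "-"), i) }
      else if (bAtEnd && aAtStart) { addEdge(mkNode(r$b_id, "+"), mkNode(r$a_id, "+"), i)
                                     addEdge(mkNode(r$a_id, "-"), mkNode(r$b_id, "-"), i) }
    } else {
      if (aAtEnd && bAtEnd) { addEdge(mkNode(r$a_id, "+"), mkNode(r$b_id, "-"), i)
                              addEdge(mkNode(r$b_id, "+"), mkNode(r$a_id, "-"), i) }
      else if (aAtStart && bAtStart) { addEdge(mkNode(r$a_id, "-"), mkNode(r$b_id, "+"), i)
                                       addEdge(mkNode(r$b_id, "-"), mkNode(r$a_id, "+"), i) }
    }
  }
  # unique out-edges only; count in-degrees
  branches <- character(0)
  outEdge <- list()
  inDeg <- integer(0)
  for (from in names(edges)) {
    es <- edges[[from]]
    tos <- unique(vapply(es, function(e) e$to, ""))
    if (length(tos) > 1L) { branches <- c(branches, from); next }
    outEdge[[from]] <- es[[1]]
  }
  for (from in names(outEdge)) {
    to <- outEdge[[from]]$to
    inDeg[to] <- (if (is.na(inDeg[to])) 0L else inDeg[to]) + 1L
  }
  usable <- function(from) {
    !is.null(outEdge[[from]]) &&
      (is.na(inDeg[outEdge[[from]]$to]) || inDeg[outEdge[[from]]$to] == 1L)
  }
  consumed <- character(0)
  records <- list()
  info <- list()
  circular <- FALSE
  un <- 0L
  ids <- names(contigs)
  revNode <- function(v) {
    id <- substr(v, 1, nchar(v) - 1L)
    o <- substr(v, nchar(v), nchar(v))
    paste0(id, if (o == "+") "-" else "+")
  }
  nodeId <- function(v) substr(v, 1, nchar(v) - 1L)
  nodeOri <- function(v) substr(v, nchar(v), nchar(v))
  for (id in ids) {
    if (id %in% consumed) next
    # find a chain through this contig: walk backwards from id+ then forward
    start <- mkNode(id, "+")
    seen <- character(0)
    repeat {
      prev <- revNode(start)
      if (!usable(prev)) break
      cand <- revNode(outEdge[[prev]]$to)
      if (cand %in% seen || nodeId(cand) %in% consumed) { circular <- TRUE; break }
      seen <- c(seen, start)
      start <- cand
    }
    chain <- list(start)
    rowsUsed <- integer(0)
    v <- start
    cyc <- FALSE
    while (usable(v)) {
      nxt <- outEdge[[v]]$to
      if (nodeId(nxt) %in% vapply(chain, nodeId, "")) { cyc <- TRUE; break }
      rowsUsed <- c(rowsUsed, outEdge[[v]]$row)
      chain <- c(chain, list(nxt))
      v <- nxt
    }
    if (cyc) { circular <- TRUE; warning("circular unitig left unmerged") }
    if (length(chain) == 1L || cyc) {
      records[[id]] <- contigs[[id]]
      consumed <- c(consumed, id)
      next
    }
    un <- un + 1L
    uid <- sprintf("u%d", un)
    merged <- mergeChain(contigs, chain, dt[rowsUsed, , drop = FALSE],
                         vapply(chain, nodeId, ""), primaryIds, uid)
    records[[uid]] <- merged
    consumed <- c(consumed, vapply(chain, nodeId, ""))
    info[[length(info) + 1L]] <- data.frame(
      unitig = uid, n_contigs = length(chain),
      members = paste(vapply(chain, identity, ""), collapse = ","),
      length = seqLen(merged), stringsAsFactors = FALSE)
  }
  list(records = records,
       info = if (length(info)) do.call(rbind, info) else
         data.frame(unitig = character(0), n_contigs = integer(0),
                    members = character(0), length = numeric(0)),
       branches = unique(branches), circular = circular)
}

# Merge an oriented chain of contigs using the dovetail rows that connect
# consecutive members.
mergeChain <- function(contigs, chain, rows, memberIds, primaryIds, uid) {
  nodeOri <- function(v) substr(v, nchar(v), nchar(v))
  cur <- orientRecord(contigs[[memberIds[1]]], nodeOri(chain[[1]]))
  for (i in seq_len(length(chain) - 1L)) {
    nxtId <- memberIds[i + 1L]
    nxt <- orientRecord(contigs[[nxtId]], nodeOri(chain[[i + 1L]]))
    r <- rows[i, ]
    # overlap length on each side in oriented coordinates
    if (r$a_id == nxtId) { ovNext <- r$a_end - r$a_start; ovCur <- r$b_end - r$b_start }
    else { ovNext <- r$b_end - r$b_start; ovCur <- r$a_end - r$a_start }
    curPrimary <- memberIds[i] %in% primaryIds
    nxtPrimary <- nxtId %in% primaryIds
    keepCur <- !(nxtPrimary && !curPrimary)
    if (keepCur) { cutCur <- seqLen(cur); cutNxt <- ovNext }
    else { cutCur <- seqLen(cur) - ovCur; cutNxt <- 0L }
    ref <- refineJunction(cur@seq, nxt@seq, cutCur, cutNxt, win = 2000L)
    cutCur <- ref$a; cutNxt <- ref$b
    cur <- concatRecords(uid, list(sliceRecord(cur, 0L, cutCur),
                                   sliceRecord(nxt, cutNxt, seqLen(nxt))))
  }
  cur@id <- uid
  cur
}
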