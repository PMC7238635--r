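# Pseudomolecule construction: marker filtering, scaffold ordering and
# orientation by weighted rank concordance with genetic maps, and AGP
# emission.

#' Anchor marker sequences onto scaffolds
#'
#' Markers arrive with a flanked sequence (50 bp up/downstream); each is
#' placed by exact full-length matching on both strands across all
#' scaffolds.  A marker is uniquely mapped when it has exactly one hit
#' genome-wide (and was flagged unique at the source); markers with no hit
#' are dropped.
#'
#' @param markers marker data.frame with a \code{seq} column
#' @param scaffolds named list of \linkS4class{SeqRecord}
#' @return marker data.frame re-anchored to scaffold coordinates
#' @export
anchorMarkers <- function(markers, scaffolds, k = 21L, minAnchors = 3L) {
  if (!nrow(markers)) return(markers)
  w <- nchar(markers$seq[1])
  stopifnot(all(nchar(markers$seq) == w))
  targets <- vapply(scaffolds, seqString, "")
  nm <- nrow(markers)
  h <- cpp_anchor_hits(unname(targets),
                       c(markers$seq, vapply(markers$seq, revComp, "")),
                       as.integer(k), 8L, 1L)
  nLoci <- integer(nm)
  hitScaffold <- rep(NA_character_, nm)
  hitPos <- rep(NA_real_, nm)
  if (length(h$qpos)) {
    mi <- ((h$query - 1L) %% nm) + 1L
    start <- h$tpos - h$qpos      # implied marker start on the target
    tab <- data.frame(mi = mi, target = h$target, start = start)
    tab <- tab[order(tab$mi, tab$target, tab$start), , drop = FALSE]
    for (m in unique(tab$mi)) {
      tm <- tab[tab$mi == m, , drop = FALSE]
      cl <- cumsum(c(1, diff(tm$start) > 200 | diff(tm$target) != 0))
      sizes <- table(cl)
      good <- as.integer(names(sizes)[sizes >= minAnchors])
      nLoci[m] <- length(good)
      if (length(good)) {
        bestCl <- good[which.max(sizes[as.character(good)])]
        sel <- tm[cl == bestCl, , drop = FALSE]
        hitScaffold[m] <- names(scaffolds)[sel$target[1]]
        hitPos[m] <- round(stats::median(sel$start)) + (w - 1) / 2
      }
    }
  }
  keep <- nLoci > 0
  out <- markers[keep, , drop = FALSE]
  out$scaffold_id <- hitScaffold[keep]
  out$physical_bp <- round(hitPos[keep])
  out$unique <- out$unique & (nLoci[keep] == 1L)
  rownames(out) <- NULL
  out
}

#' Filter markers for pseudomolecule construction
#'
#' Keeps uniquely mapped markers with mapping quality strictly above 30
#' (\code{minMapq = 31}); drops scaffolds with 20 or fewer surviving
#' markers; caps each scaffold at \code{cap} markers chosen evenly spaced
#' by physical position (the first and last markers are always retained).
#'
#' @param markers marker data.frame
#' @param minPerScaffold minimum surviving markers to keep a scaffold
#'   (strictly more than 20 means \code{minPerScaffold = 21})
#' @param cap maximum markers per scaffold
#' @param minMapq minimum mapping quality (inclusive)
#' @return filtered marker data.frame
#' @export
filterMarkers <- function(markers, minPerScaffold = 21L, cap = 100L,
                          minMapq = 31L) {
  m <- markers[markers$unique & markers$mapq >= minMapq, , drop = FALSE]
  out <- list()
  for (sid in unique(m$scaffold_id)) {
    ms <- m[m$scaffold_id == sid, , drop = FALSE]
    # a scaffold joins exactly one linkage group: its majority group
    lg <- names(which.max(table(ms$linkage_group)))
    ms <- ms[ms$linkage_group == lg, , drop = FALSE]
    if (nrow(ms) < minPerScaffold) next
    ms <- ms[order(ms$physical_bp), , drop = FALSE]
    if (nrow(ms) > cap) {
      idx <- unique(round(seq(1L, nrow(ms), length.out = cap)))
      ms <- ms[idx, , drop = FALSE]
    }
    out[[length(out) + 1L]] <- ms
  }
  if (!length(out)) return(m[0, , drop = FALSE])
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Order and orient scaffolds within linkage groups
#'
#' Maximizes the weighted sum over marker sources of the absolute Spearman
#' rank correlation between genetic position and assembled physical order.
#' Groups with at most \code{exhaustiveLimit} scaffolds are solved by
#' exhaustive search over orders and orientations; larger groups use a
#' deterministic greedy construction followed by single-flip, adjacent-swap
#' and segment-reversal (2-opt) passes to a local optimum.  The overall
#' direction is canonicalized so genetic positions ascend.
#'
#' @param markers filtered marker data.frame (optionally with a
#'   \code{source} column)
#' @param weights named weights per source (default equal)
#' @param exhaustiveLimit exhaustive search cutoff
#' @return list(orders = list per linkage group of data.frame(scaffold_id,
#'   orientation), objective = named numeric, method = named character)
#' @export
orderOrient <- function(markers, weights = NULL, exhaustiveLimit = 8L) {
  if (!nrow(markers)) stop("orderOrient: empty marker table")
  if (is.null(markers$source)) markers$source <- "map1"
  orders <- list(); objective <- c(); method <- c()
  for (lg in unique(markers$linkage_group)) {
    ml <- markers[markers$linkage_group == lg, , drop = FALSE]
    if (!nrow(ml)) stop(sprintf("empty linkage group '%s'", lg))
    sc <- unique(ml$scaffold_id)
    srcs <- unique(ml$source)
    w <- if (is.null(weights)) stats::setNames(rep(1, length(srcs)), srcs) else weights
    # per scaffold, per orientation, per source: genetic ranks in physical order
    ml$grank <- stats::ave(ml$genetic_pos, ml$source, FUN = rank)
    seqs <- list()
    for (s in sc) for (o in c("+", "-")) for (src in srcs) {
      ms <- ml[ml$scaffold_id == s & ml$source == src, , drop = FALSE]
      ms <- ms[order(ms$physical_bp, decreasing = (o == "-")), , drop = FALSE]
      seqs[[paste(s, o, src)]] <- ms$grank
    }
    obj <- function(perm, flips) {
      tot <- 0
      for (src in srcs) {
        g <- unlist(lapply(seq_along(perm), function(i)
          seqs[[paste(sc[perm[i]], if (flips[i]) "-" else "+", src)]]),
          use.names = FALSE)
        if (length(g) > 2) {
          r <- suppressWarnings(stats::cor(g, seq_along(g)))
          if (!is.na(r)) tot <- tot + w[[src]] * abs(r)
        }
      }
      tot
    }
    n <- length(sc)
    if (n <= exhaustiveLimit) {
      best <- NULL; bestV <- -Inf
      for (perm in permList(n)) {
        for (mask in 0:(2^n - 1)) {
          flips <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1L)), 1L))
          v <- obj(perm, flips)
          if (v > bestV + 1e-12) { bestV <- v; best <- list(perm = perm, flips = flips) }
        }
      }
      meth <- "exhaustive"
    } else {
      best <- greedyOrder(sc, ml, seqs, srcs, w, obj)
      bestV <- obj(best$perm, best$flips)
      meth <- "heuristic"
    }
    # canonical direction: genetic positions ascend along the group
    gAll <- unlist(lapply(seq_along(best$perm), function(i)
      seqs[[paste(sc[best$perm[i]], if (best$flips[i]) "-" else "+", srcs[1])]]),
      use.names = FALSE)
    if (length(gAll) > 2 && !is.na(stats::cor(gAll, seq_along(gAll))) &&
        stats::cor(gAll, seq_along(gAll)) < 0) {
      best$perm <- rev(best$perm); best$flips <- rev(!best$flips)
    }
    orders[[as.character(lg)]] <- data.frame(
      scaffold_id = sc[best$perm],
      orientation = ifelse(best$flips, "-", "+"), stringsAsFactors = FALSE)
    objective[as.character(lg)] <- bestV
    method[as.character(lg)] <- meth
  }
  list(orders = orders, objective = objective, method = method)
}

# All permutations of 1..n in lexicographic order.
permList <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permList(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# Deterministic greedy + local search for large groups.
greedyOrder <- function(sc, ml, seqs, srcs, w, obj) {
  n <- length(sc)
  gm <- vapply(sc, function(s) mean(ml$genetic_pos[ml$scaffold_id == s]), 0)
  perm <- order(gm)
  flips <- vapply(sc[perm], function(s) {
    ms <- ml[ml$scaffold_id == s, , drop = FALSE]
    if (nrow(ms) > 2) {
      r <- suppressWarnings(stats::cor(ms$physical_bp, ms$genetic_pos))
      !is.na(r) && r < 0
    } else FALSE
  }, TRUE)
  v <- obj(perm, flips)
  improved <- TRUE; it <- 0L
  while (improved && it < 100L) {
    improved <- FALSE; it <- it + 1L
    for (i in seq_len(n)) {            # single flips
      f2 <- flips; f2[i] <- !f2[i]
      v2 <- obj(perm, f2)
      if (v2 > v + 1e-12) { flips <- f2; v <- v2; improved <- TRUE }
    }
    if (n > 1) for (i in seq_len(n - 1L)) {  # adjacent swaps
      p2 <- perm; p2[c(i, i + 1L)] <- p2[c(i + 1L, i)]
      f2 <- flips; f2[c(i, i + 1L)] <- f2[c(i + 1L, i)]
      v2 <- obj(p2, f2)
      if (v2 > v + 1e-12) { perm <- p2; flips <- f2; v <- v2; improved <- TRUE }
    }
    if (n > 2) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {  # 2-opt
      p2 <- perm; p2[i:j] <- rev(p2[i:j])
      f2 <- flips; f2[i:j] <- rev(!f2[i:j])
      v2 <- obj(p2, f2)
      if (v2 > v + 1e-12) { perm <- p2; flips <- f2; v <- v2; improved <- TRUE }
    }
  }
  list(perm = perm, flips = flips)
}

#' Emit pseudomolecules from an ordering
#'
#' Scaffolds are concatenated in order with \code{interGap} N between
#' neighbors (AGP gap type "scaffold").  The AGP plus the component
#' scaffolds reconstruct the emitted FASTA exactly
#' (\code{\link{sequenceFromAGP}}).
#'
#' @param ordering result of \code{\link{orderOrient}} (or its
#'   \code{$orders} element)
#' @param scaffolds named list of \linkS4class{SeqRecord}
#' @param interGap inter-scaffold gap size in bp
#' @return list(records = named list of pseudomolecule records, agp)
#' @export
emitPseudomolecules <- function(ordering, scaffolds, interGap = 100L) {
  if (!is.null(ordering$orders)) ordering <- ordering$orders
  if (!length(ordering)) stop("empty ordering")
  records <- list()
  for (lg in names(ordering)) {
    od <- ordering[[lg]]
    if (!nrow(od)) stop(sprintf("empty ordering for group '%s'", lg))
    parts <- list()
    for (i in seq_len(nrow(od))) {
      if (i > 1L) parts[[length(parts) + 1L]] <- list(gap = interGap, kind = "scaffold")
      parts[[length(parts) + 1L]] <-
        orientRecord(scaffolds[[od$scaffold_id[i]]], od$orientation[i])
    }
    records[[lg]] <- concatRecords(lg, parts)
  }
  # pseudomolecule AGP references scaffolds, not deeper components
  rows <- list()
  for (lg in names(ordering)) {
    od <- ordering[[lg]]
    pos <- 1; pn <- 0L
    for (i in seq_len(nrow(od))) {
      if (i > 1L) {
        pn <- pn + 1L
        rows[[length(rows) + 1L]] <- data.frame(object = lg, object_beg = pos,
          object_end = pos + interGap - 1, part_number = pn, component_type = "N",
          component_id = NA_character_, component_beg = NA_real_,
          component_end = NA_real_, orientation = NA_character_,
          gap_length = interGap, gap_type = "scaffold", stringsAsFactors = FALSE)
        pos <- pos + interGap
      }
      sl <- seqLen(scaffolds[[od$scaffold_id[i]]])
      pn <- pn + 1L
      rows[[length(rows) + 1L]] <- data.frame(object = lg, object_beg = pos,
        object_end = pos + sl - 1, part_number = pn, component_type = "W",
        component_id = od$scaffold_id[i], component_beg = 1, component_end = sl,
        orientation = od$orientation[i], gap_length = NA_real_,
        gap_type = NA_character_, stringsAsFactors = FALSE)
      pos <- pos + sl
    }
  }
  agp <- do.call(rbind, rows)
  validateAGP(agp)
  list(records = records, agp = agp)
}
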