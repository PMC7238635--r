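# In-silico digestion and the label-map aligner.
#
# The aligner is a banded local dynamic programme over label index pairs.
# Matching a pair of labels earns a fixed bonus; the transition between
# consecutive matched pairs is penalized by the squared difference of the
# bounded interval lengths, scaled by the expected sizing variance
# (sd = sdCoeff * sqrt(interval)), and by a per-skipped-label miss penalty.
# The sizing penalty is capped (svCap) so that one large insertion/deletion
# can be bridged inside an alignment (the error-curation module reads these
# off adjacent matched pairs) while a chimeric junction, where every
# subsequent label mismatches, still terminates the alignment.

#' Alignment parameters for the label-map aligner
#'
#' @param sdCoeff sizing noise coefficient: the sd of an interval-length
#'   error is \code{sdCoeff * sqrt(interval bp)}
#' @param missPenalty score penalty per skipped (unmatched) label
#' @param minPairs minimum number of matched pairs for a reported alignment
#' @param minConfidence minimum confidence for a reported alignment
#' @param bandLabels width of the predecessor window, in labels
#' @param pairBonus score earned by each matched label pair
#' @param svCap cap on the per-pair sizing penalty (see module notes)
#' @param maxAlignments maximum number of local alignments reported per
#'   orientation
#' @return list of class \code{AlignParams}
#' @export
alignParams <- function(sdCoeff = 2.0, missPenalty = 3, minPairs = 6,
                        minConfidence = 12, bandLabels = 6, pairBonus = 5,
                        svCap = 12, maxAlignments = 1) {
  stopifnot(sdCoeff > 0, missPenalty > 0, minPairs >= 2, minConfidence >= 0,
            bandLabels >= 1, pairBonus > 0, svCap > 0)
  structure(list(sdCoeff = sdCoeff, missPenalty = missPenalty,
                 minPairs = minPairs, minConfidence = minConfidence,
                 bandLabels = bandLabels, pairBonus = pairBonus, svCap = svCap,
                 maxAlignments = maxAlignments), class = "AlignParams")
}

#' In-silico digestion of a sequence into a label map
#'
#' One label per motif occurrence (1-based start of the match).  The default
#' motif CTTAAG (DLE-1 recognition site) is its own reverse complement, so a
#' single-strand scan suffices; for non-palindromic motifs both strands are
#' scanned.  Occurrences closer than \code{minLabelSpacing} are collapsed to
#' their midpoint, emulating optical resolution.  N runs carry no labels.
#'
#' @param record a \linkS4class{SeqRecord} (or DNA string; id "seq")
#' @param motif recognition motif (ACGT only, length >= 4)
#' @param minLabelSpacing labels closer than this many bp are collapsed
#' @return a \linkS4class{LabelMap} with source "digest"
#' @export
insilicoDigest <- function(record, motif = "CTTAAG", minLabelSpacing = 800L) {
  if (grepl("[^ACGT]", motif) || nchar(motif) < 4)
    stop("motif must be ACGT-only and at least 4 bp")
  if (!is(record, "SeqRecord")) record <- seqRecord("seq", record)
  s <- record@seq
  m <- gregexpr(motif, s, fixed = TRUE)[[1]]
  pos <- if (m[1] == -1) numeric(0) else as.numeric(m)
  rc <- revComp(motif)
  if (rc != motif) {
    m2 <- gregexpr(rc, s, fixed = TRUE)[[1]]
    if (m2[1] != -1) pos <- sort(unique(c(pos, as.numeric(m2))))
  }
  pos <- collapseLabels(pos, minLabelSpacing)
  labelMap(record@id, nchar(s), pos, source = "digest")
}

# Collapse clusters of labels closer than `spacing` to their midpoints.
collapseLabels <- function(pos, spacing) {
  if (length(pos) < 2L || spacing <= 0) return(pos)
  grp <- cumsum(c(1, diff(pos) >= spacing))
  out <- vapply(split(pos, grp), function(p) round(mean(p)), 0)
  unname(out)
}

#' Align two label maps
#'
#' Runs the banded local DP in both orientations and returns all alignments
#' with at least \code{minPairs} pairs and confidence at least
#' \code{minConfidence}, best score first.  Confidence is score / ln(10)
#' (monotone in score; a perfect 10-pair alignment scores
#' \code{10 * pairBonus}, i.e. confidence >= 20 at the default bonus).
#' A map with fewer than \code{minPairs} labels yields an empty result.
#'
#' @param query,ref \linkS4class{LabelMap}s
#' @param params an \code{\link{alignParams}} object
#' @return list of \linkS4class{MapAlignment}, best first
#' @export
alignLabelMaps <- function(query, ref, params = alignParams()) {
  q <- query@labels; r <- ref@labels
  if (length(q) < params$minPairs || length(r) < params$minPairs) return(list())
  res <- list()
  for (ori in c("+", "-")) {
    qq <- if (ori == "+") q else sort(query@length - rev(q) + 1)
    hits <- cpp_align_labels(qq, r, params$sdCoeff, params$missPenalty,
                             params$pairBonus, params$svCap, params$bandLabels,
                             params$minPairs, params$maxAlignments,
                             params$minConfidence * log(10))
    for (h in hits) {
      conf <- h$score / log(10)
      if (conf < params$minConfidence) next
      pp <- h$pairs
      if (ori == "-") pp[, 1] <- length(q) - pp[, 1] + 1L  # back to original indexing
      colnames(pp) <- c("query", "ref")
      res[[length(res) + 1L]] <- new("MapAlignment",
        queryId = query@id, refId = ref@id, orientation = ori, pairs = pp,
        score = h$score, confidence = conf,
        querySpan = range(q[pp[, 1]]), refSpan = range(r[pp[, 2]]))
    }
  }
  res[order(vapply(res, function(a) a@score, 0), decreasing = TRUE)]
}

#' Least-squares rescaling factor from a map alignment
#'
#' Fits, through the origin, the reference matched-interval lengths on the
#' query matched-interval lengths.  Applying the returned slope to the query
#' map minimizes the summed squared interval deltas.
#'
#' @param alignment a \linkS4class{MapAlignment}
#' @param query,ref the aligned \linkS4class{LabelMap}s
#' @return scalar stretch factor
#' @export
fitStretch <- function(alignment, query, ref) {
  p <- alignment@pairs
  if (nrow(p) < 3L) stop("insufficient pairs for rescaling (need >= 3)")
  dq <- abs(diff(query@labels[p[, 1]]))
  dr <- diff(ref@labels[p[, 2]])
  sum(dq * dr) / sum(dq * dq)
}

#' Rescale a label map by a stretch factor
#'
#' @param map a \linkS4class{LabelMap}
#' @param stretch multiplicative factor applied to labels and length
#' @export
rescaleMap <- function(map, stretch) {
  labelMap(map@id, map@length * stretch, map@labels * stretch, source = map@source)
}
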