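#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib gapless, .registration = TRUE
NULL

#' SeqRecord: a named DNA sequence with provenance
#'
#' A contig, scaffold or read: an uppercase DNA string over \code{A,C,G,T,N}
#' together with provenance blocks that tile the sequence and point back to
#' intervals on the source object(s) it was derived from.  Provenance is the
#' backbone of coordinate liftover across cutting, patching, merging and
#' scaffolding.
#'
#' Provenance is a \code{data.frame} with columns \code{start}, \code{end}
#' (0-based half-open intervals on this record, tiling \code{[0, len)}),
#' \code{source_id}, \code{src_start}, \code{src_end} (0-based half-open on
#' the source; for synthetic blocks such as gaps, \code{source_id} may be
#' \code{"gap"} and the source interval is ignored) and \code{strand}
#' (\code{"+"} or \code{"-"}).
#'
#' @slot id single character identifier
#' @slot seq single character string over ACGTN
#' @slot provenance data.frame of provenance blocks (see Details)
#' @aliases SeqRecord
#' @exportClass SeqRecord
setClass("SeqRecord",
  representation(id = "character", seq = "character", provenance = "data.frame"))

setValidity("SeqRecord", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id)) return("id must be a single non-empty string")
  if (length(object@seq) != 1L || !nzchar(object@seq)) return(sprintf("record '%s' has an empty sequence", object@id))
  if (grepl("[^ACGTN]", object@seq)) return(sprintf("record '%s' contains characters outside ACGTN", object@id))
  p <- object@provenance
  if (nrow(p)) {
    need <- c("start", "end", "source_id", "src_start", "src_end", "strand")
    if (!all(need %in% names(p))) return("provenance lacks required columns")
    p <- p[order(p$start), , drop = FALSE]
    n <- nchar(object@seq)
    if (p$start[1] != 0 || p$end[nrow(p)] != n ||
        (nrow(p) > 1 && any(p$start[-1] != p$end[-nrow(p)])))
      return(sprintf("provenance of '%s' does not tile [0, %d)", object@id, n))
  }
  TRUE
})

#' LabelMap: ordered label positions on a molecule or contig
#'
#' The CMAP role: a molecule (optical map) or an in-silico digested sequence,
#' represented by its length and a strictly increasing vector of 1-based
#' label positions in bp.
#'
#' @slot id single character identifier
#' @slot length numeric molecule length in bp
#' @slot labels numeric vector of strictly increasing 1-based positions
#' @slot source "digest" (from sequence) or "optical"
#' @aliases LabelMap
#' @exportClass LabelMap
setClass("LabelMap",
  representation(id = "character", length = "numeric", labels = "numeric",
                 source = "character"))

setValidity("LabelMap", function(object) {
  if (length(object@id) != 1L) return("id must be a single string")
  if (length(object@length) != 1L || object@length <= 0) return("length must be a positive scalar")
  lb <- object@labels
  if (length(lb)) {
    if (any(lb < 1 | lb > object@length)) return(sprintf("map '%s': labels outside [1, length]", object@id))
    if (any(diff(lb) <= 0)) return(sprintf("map '%s': label positions not strictly increasing", object@id))
  }
  if (!object@source %in% c("digest", "optical")) return("source must be 'digest' or 'optical'")
  TRUE
})

#' MapAlignment: a monotone pairing of query and reference labels
#'
#' @slot queryId,refId identifiers of the aligned maps
#' @slot orientation "+" or "-"
#' @slot pairs integer matrix, columns \code{query}/\code{ref}, of 1-based
#'   label indices; strictly increasing in ref index, and increasing
#'   (orientation "+") or decreasing ("-") in query index
#' @slot score alignment score
#' @slot confidence non-negative confidence (score / ln 10)
#' @slot querySpan,refSpan numeric length-2 bp spans of the outermost paired labels
#' @aliases MapAlignment
#' @exportClass MapAlignment
setClass("MapAlignment",
  representation(queryId = "character", refId = "character",
                 orientation = "character", pairs = "matrix",
                 score = "numeric", confidence = "numeric",
                 querySpan = "numeric", refSpan = "numeric"))

setValidity("MapAlignment", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (!object@orientation %in% c("+", "-")) return("orientation must be '+' or '-'")
  if (nrow(p) > 1) {
    if (any(diff(p[, 2]) <= 0)) return("ref label indices must be strictly increasing")
    dq <- diff(p[, 1])
    if (object@orientation == "+" && any(dq <= 0)) return("query indices must increase for orientation '+'")
    if (object@orientation == "-" && any(dq >= 0)) return("query indices must decrease for orientation '-'")
  }
  if (object@confidence < 0) return("confidence must be non-negative")
  TRUE
})

setMethod("show", "SeqRecord", function(object) {
  n <- nchar(object@seq)
  gaps <- findNGaps(object)
  cat(sprintf("SeqRecord '%s': %s bp, %d N-gap(s) > 10 N, %d provenance block(s)\n",
              object@id, format(n, big.mark = ","), nrow(gaps), nrow(object@provenance)))
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap '%s' (%s): %s bp, %d label(s)\n", object@id, object@source,
              format(round(object@length), big.mark = ","), length(object@labels)))
})

setMethod("show", "MapAlignment", function(object) {
  cat(sprintf("MapAlignment %s -> %s (%s): %d pairs, score %.2f, confidence %.2f\n",
              object@queryId, object@refId, object@orientation,
              nrow(object@pairs), object@score, object@confidence))
})
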