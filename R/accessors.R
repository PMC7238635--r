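# Constructors and accessors for the core S4 containers.

#' Create a SeqRecord
#'
#' @param id record identifier
#' @param seq DNA string; folded to upper case.  By default any IUPAC
#'   ambiguity code other than N is an error; with \code{coerceAmbiguous =
#'   TRUE} such characters are converted to N.
#' @param provenance optional provenance data.frame (see
#'   \linkS4class{SeqRecord}); defaults to a single self-referential block
#' @param coerceAmbiguous coerce non-ACGTN IUPAC codes to N instead of erroring
#' @return a \linkS4class{SeqRecord}
#' @export
seqRecord <- function(id, seq, provenance = NULL, coerceAmbiguous = FALSE) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop(sprintf("record '%s' has an empty sequence", id))
  if (grepl("[^ACGTN]", seq)) {
    if (coerceAmbiguous) seq <- gsub("[^ACGTN]", "N", seq)
    else stop(sprintf("record '%s' contains non-ACGTN characters", id))
  }
  if (is.null(provenance))
    provenance <- data.frame(start = 0L, end = nchar(seq), source_id = id,
                             src_start = 0L, src_end = nchar(seq),
                             strand = "+", stringsAsFactors = FALSE)
  new("SeqRecord", id = id, seq = seq, provenance = provenance)
}

#' Create a LabelMap
#'
#' @param id map identifier
#' @param length molecule length in bp
#' @param labels strictly increasing 1-based label positions
#' @param source "digest" or "optical"
#' @return a \linkS4class{LabelMap}
#' @export
labelMap <- function(id, length, labels = numeric(0), source = "digest") {
  new("LabelMap", id = id, length = as.numeric(length),
      labels = as.numeric(labels), source = source)
}

#' @rdname seqRecord
#' @param x a SeqRecord
#' @export
seqId <- function(x) x@id

#' @rdname seqRecord
#' @export
seqString <- function(x) x@seq

#' @rdname seqRecord
#' @export
seqLen <- function(x) nchar(x@seq)

#' @rdname seqRecord
#' @export
provenance <- function(x) x@provenance

#' @rdname labelMap
#' @param x a LabelMap
#' @export
mapLabels <- function(x) x@labels

#' @rdname labelMap
#' @export
mapLength <- function(x) x@length

#' Accessors for MapAlignment
#'
#' @param x a \linkS4class{MapAlignment}
#' @return \code{alignmentPairs}: integer matrix of paired 1-based label
#'   indices (columns query, ref); \code{alignmentScore} /
#'   \code{alignmentConfidence}: scalars.
#' @export
alignmentPairs <- function(x) x@pairs

#' @rdname alignmentPairs
#' @export
alignmentScore <- function(x) x@score

#' @rdname alignmentPairs
#' @export
alignmentConfidence <- function(x) x@confidence
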