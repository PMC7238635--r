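# Coordinate liftover through provenance chains.
#
# Every record produced by the pipeline carries provenance blocks that
# bottom out at the original source coordinate systems (simulated truth
# chromosomes, or read ids for filled sequence).  Lifting an interval from
# one assembly version to another goes through that shared frame: forward
# through the source records' provenance, then inverted through the target
# records' provenance.  Portions of an interval falling in sequence absent
# from the target are flagged "deleted-in-target", never silently dropped.

#' Lift intervals between assembly versions
#'
#' @param intervals data.frame with \code{seq_id}, \code{start}, \code{end}
#'   (0-based half-open) on the source assembly
#' @param source named list of source \linkS4class{SeqRecord} (NULL if the
#'   intervals are already in base/truth coordinates)
#' @param target named list of target records
#' @return data.frame: seq_id, start, end, target_id, target_start,
#'   target_end, strand, status ("lifted" or "deleted-in-target")
#' @export
liftoverIntervals <- function(intervals, source, target) {
  base <- list()
  for (i in seq_len(nrow(intervals))) {
    iv <- intervals[i, ]
    if (is.null(source)) {
      base[[length(base) + 1L]] <- data.frame(idx = i, src = iv$seq_id,
        start = iv$start, end = iv$end, strand = "+", stringsAsFactors = FALSE)
    } else {
      rec <- source[[iv$seq_id]]
      if (is.null(rec)) stop(sprintf("unknown source id '%s'", iv$seq_id))
      pieces <- projectToSource(rec, iv$start, iv$end)
      if (nrow(pieces)) pieces$idx <- i
      base[[length(base) + 1L]] <- pieces
    }
  }
  base <- do.call(rbind, base)
  # invert target provenance: index blocks by bottom source id
  blocks <- list()
  for (tid in names(target)) {
    p <- target[[tid]]@provenance
    if (!nrow(p)) next
    p$target_id <- tid
    blocks[[length(blocks) + 1L]] <- p
  }
  blocks <- do.call(rbind, blocks)
  out <- list()
  for (i in seq_len(nrow(base))) {
    bi <- base[i, ]
    hit <- blocks[blocks$source_id == bi$src & blocks$src_end > bi$start &
                    blocks$src_start < bi$end, , drop = FALSE]
    orig <- intervals[bi$idx, ]
    if (!nrow(hit)) {
      out[[length(out) + 1L]] <- data.frame(seq_id = orig$seq_id,
        start = orig$start, end = orig$end, target_id = NA_character_,
        target_start = NA_real_, target_end = NA_real_, strand = NA_character_,
        status = "deleted-in-target", stringsAsFactors = FALSE)
      next
    }
    for (j in seq_len(nrow(hit))) {
      b <- hit[j, ]
      os <- max(b$src_start, bi$start); oe <- min(b$src_end, bi$end)
      if (b$strand == "+") {
        ts <- b$start + (os - b$src_start); te <- b$start + (oe - b$src_start)
        strand <- bi$strand
      } else {
        ts <- b$start + (b$src_end - oe); te <- b$start + (b$src_end - os)
        strand <- if (bi$strand == "+") "-" else "+"
      }
      out[[length(out) + 1L]] <- data.frame(seq_id = orig$seq_id,
        start = orig$start, end = orig$end, target_id = b$target_id,
        target_start = ts, target_end = te, strand = strand,
        status = "lifted", stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Project a record interval [start, end) through its own provenance onto
# the bottom source coordinate systems; returns one row per provenance
# block crossed.
projectToSource <- function(rec, start, end) {
  p <- rec@provenance
  keep <- p$end > start & p$start < end
  p <- p[keep, , drop = FALSE]
  if (!nrow(p))
    return(data.frame(idx = integer(0), src = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0)))
  os <- pmax(p$start, start); oe <- pmin(p$end, end)
  data.frame(idx = NA_integer_, src = p$source_id,
             start = ifelse(p$strand == "+", p$src_start + (os - p$start),
                            p$src_end - (oe - p$start)),
             end = ifelse(p$strand == "+", p$src_start + (oe - p$start),
                          p$src_end - (os - p$start)),
             strand = p$strand, stringsAsFactors = FALSE)
}
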