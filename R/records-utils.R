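# Provenance-preserving record surgery: slicing, reverse complement and
# concatenation.  All record-level coordinates are 0-based half-open.

# Slice a record to [start, end); provenance blocks are intersected and
# their source intervals adjusted (strand-aware).
sliceRecord <- function(record, start, end, newId = record@id) {
  n <- seqLen(record)
  if (start < 0 || end > n || end <= start)
    stop(sprintf("slice [%d,%d) outside record '%s' of length %d", start, end, record@id, n))
  seq <- substr(record@seq, start + 1L, end)
  p <- record@provenance
  keep <- p$end > start & p$start < end
  p <- p[keep, , drop = FALSE]
  if (nrow(p)) {
    os <- pmax(p$start, start); oe <- pmin(p$end, end)
    srcs <- ifelse(p$strand == "+", p$src_start + (os - p$start),
                   p$src_end - (oe - p$start))
    srce <- ifelse(p$strand == "+", p$src_start + (oe - p$start),
                   p$src_end - (os - p$start))
    p <- data.frame(start = os - start, end = oe - start,
                    source_id = p$source_id, src_start = srcs, src_end = srce,
                    strand = p$strand, stringsAsFactors = FALSE)
  }
  new("SeqRecord", id = newId, seq = seq, provenance = p)
}

# Reverse complement a record, flipping provenance blocks and strands.
revCompRecord <- function(record, newId = record@id) {
  n <- seqLen(record)
  p <- record@provenance
  if (nrow(p)) {
    p2 <- data.frame(start = n - p$end, end = n - p$start,
                     source_id = p$source_id, src_start = p$src_start,
                     src_end = p$src_end,
                     strand = ifelse(p$strand == "+", "-", "+"),
                     stringsAsFactors = FALSE)
    p <- p2[order(p2$start), , drop = FALSE]
    rownames(p) <- NULL
  }
  new("SeqRecord", id = newId, seq = revComp(record@seq), provenance = p)
}

# Orient a record: "+" returns it unchanged, "-" reverse complements.
orientRecord <- function(record, orientation) {
  if (orientation == "-") revCompRecord(record) else record
}

# Concatenate records and N-gap blocks into a new record.
# `parts` is a list whose elements are either SeqRecord or
# list(gap = <n>, kind = <chr>) gap specifications.
concatRecords <- function(id, parts) {
  seqs <- character(length(parts))
  provs <- vector("list", length(parts))
  off <- 0L
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (is(p, "SeqRecord")) {
      seqs[i] <- p@seq
      pr <- p@provenance
      if (nrow(pr)) { pr$start <- pr$start + off; pr$end <- pr$end + off }
      provs[[i]] <- pr
      off <- off + seqLen(p)
    } else {
      g <- p$gap
      seqs[i] <- strrep("N", g)
      provs[[i]] <- data.frame(start = off, end = off + g,
                               source_id = paste0("gap:", p$kind),
                               src_start = 0L, src_end = g, strand = "+",
                               stringsAsFactors = FALSE)
      off <- off + g
    }
  }
  new("SeqRecord", id = id, seq = paste(seqs, collapse = ""),
      provenance = do.call(rbind, provs))
}

# Replace record[start, end) by a donor record segment; provenance of the
# replaced window is taken from the donor slice.
replaceSegment <- function(record, start, end, donorSlice) {
  n <- seqLen(record)
  left <- if (start > 0) sliceRecord(record, 0L, start) else NULL
  right <- if (end < n) sliceRecord(record, end, n) else NULL
  parts <- Filter(Negate(is.null), list(left, donorSlice, right))
  concatRecords(record@id, parts)
}

# Total non-N bases of a record list (conservation bookkeeping).
nonNBases <- function(records) {
  if (is(records, "SeqRecord")) records <- list(records)
  sum(vapply(records, function(r) seqLen(r) - sum(charToRaw(r@seq) == charToRaw("N")), 0))
}
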