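# Readers and writers for every on-disk format the pipeline touches.
# Internal coordinates are 0-based half-open; conversions to each format's
# native convention (AGP 1-based inclusive, CMAP 1-based labels, BED 0-based
# half-open) happen only at these boundaries.

#' Read / write FASTA sequence sets
#'
#' Sequences are folded to upper case.  IUPAC ambiguity codes other than N
#' are rejected unless \code{coerceAmbiguous = TRUE}, in which case they are
#' coerced to N.  Duplicate or empty records are errors.
#'
#' @param path file path
#' @param coerceAmbiguous coerce non-ACGTN codes to N
#' @return named list of \linkS4class{SeqRecord}
#' @export
readSequences <- function(path, coerceAmbiguous = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate sequence id '%s' in %s", ids[duplicated(ids)][1], path))
  out <- vector("list", length(ss))
  for (i in seq_along(ss)) {
    s <- as.character(ss[[i]])
    if (!nzchar(s)) stop(sprintf("empty record '%s' in %s", ids[i], path))
    out[[i]] <- seqRecord(ids[i], s, coerceAmbiguous = coerceAmbiguous)
  }
  names(out) <- ids
  out
}

#' @rdname readSequences
#' @param records named list of SeqRecord (or a single SeqRecord)
#' @param wrap line width for sequence wrapping
#' @export
writeSequences <- function(records, path, wrap = 60L) {
  if (is(records, "SeqRecord")) records <- list(records)
  ids <- vapply(records, seqId, "")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  ss <- Biostrings::DNAStringSet(vapply(records, seqString, ""))
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path, width = as.integer(wrap))
  invisible(path)
}

#' Read / write label maps (CMAP-style TSV)
#'
#' The dialect is a tab-separated table with a header and one row per label,
#' plus one terminal row per map carrying the map length (channel 0), as in
#' CMAP.  Columns: \code{CMapId}, \code{ContigLength}, \code{NumSites},
#' \code{SiteID}, \code{LabelChannel}, \code{Position}.
#'
#' @param path file path
#' @return list of \linkS4class{LabelMap}
#' @export
readLabelMaps <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- list()
  for (id in unique(d$CMapId)) {
    di <- d[d$CMapId == id, , drop = FALSE]
    len <- di$ContigLength[1]
    lab <- di$Position[di$LabelChannel == 1]
    if (length(lab) > 1 && any(diff(lab) <= 0))
      stop(sprintf("map '%s': label positions not monotone", id))
    src <- if ("Source" %in% names(di)) di$Source[1] else "optical"
    out[[as.character(id)]] <- labelMap(as.character(id), len, lab, source = src)
  }
  out
}

#' @rdname readLabelMaps
#' @param maps list of LabelMap
#' @export
writeLabelMaps <- function(maps, path) {
  if (is(maps, "LabelMap")) maps <- list(maps)
  rows <- lapply(maps, function(m) {
    n <- length(m@labels)
    data.frame(CMapId = m@id, ContigLength = m@length, NumSites = n,
               SiteID = seq_len(n + 1L),
               LabelChannel = c(rep(1L, n), 0L),
               Position = c(m@labels, m@length),
               Source = m@source, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write AGP (v2.1 dialect)
#'
#' The in-memory representation is a data.frame with 1-based inclusive
#' object coordinates and the standard nine AGP columns: \code{object},
#' \code{object_beg}, \code{object_end}, \code{part_number},
#' \code{component_type} (W for sequence, N/U for gaps), then for W rows
#' \code{component_id}/\code{component_beg}/\code{component_end}/
#' \code{orientation} and for gap rows \code{gap_length}/\code{gap_type}/
#' \code{linkage}.  Parts must tile each object contiguously.
#'
#' @param agp AGP data.frame
#' @param path file path
#' @export
writeAGP <- function(agp, path) {
  validateAGP(agp)
  lines <- character(nrow(agp))
  for (i in seq_len(nrow(agp))) {
    r <- agp[i, ]
    if (r$component_type == "W") {
      lines[i] <- paste(r$object, r$object_beg, r$object_end, r$part_number,
                        "W", r$component_id, r$component_beg, r$component_end,
                        r$orientation, sep = "\t")
    } else {
      lines[i] <- paste(r$object, r$object_beg, r$object_end, r$part_number,
                        r$component_type, r$gap_length, r$gap_type, "yes",
                        "align_genus", sep = "\t")
    }
  }
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' @rdname writeAGP
#' @export
readAGP <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  f <- strsplit(ln, "\t")
  agp <- do.call(rbind, lapply(f, function(x) {
    if (x[5] == "W")
      data.frame(object = x[1], object_beg = as.numeric(x[2]),
                 object_end = as.numeric(x[3]), part_number = as.integer(x[4]),
                 component_type = "W", component_id = x[6],
                 component_beg = as.numeric(x[7]), component_end = as.numeric(x[8]),
                 orientation = x[9], gap_length = NA_real_, gap_type = NA_character_,
                 stringsAsFactors = FALSE)
    else
      data.frame(object = x[1], object_beg = as.numeric(x[2]),
                 object_end = as.numeric(x[3]), part_number = as.integer(x[4]),
                 component_type = x[5], component_id = NA_character_,
                 component_beg = NA_real_, component_end = NA_real_,
                 orientation = NA_character_, gap_length = as.numeric(x[6]),
                 gap_type = x[7], stringsAsFactors = FALSE)
  }))
  validateAGP(agp)
  agp
}

# Contiguity check shared by readAGP/writeAGP: parts must tile each object.
validateAGP <- function(agp) {
  for (obj in unique(agp$object)) {
    a <- agp[agp$object == obj, , drop = FALSE]
    a <- a[order(a$part_number), , drop = FALSE]
    pos <- 1
    for (i in seq_len(nrow(a))) {
      if (a$object_beg[i] != pos)
        stop(sprintf("AGP object '%s': part %d starts at %d, expected %d",
                     obj, a$part_number[i], a$object_beg[i], pos))
      span <- a$object_end[i] - a$object_beg[i] + 1
      expected <- if (a$component_type[i] == "W")
        a$component_end[i] - a$component_beg[i] + 1 else a$gap_length[i]
      if (span != expected)
        stop(sprintf("AGP object '%s' part %d: span %d does not match component (%d)",
                     obj, a$part_number[i], span, expected))
      pos <- a$object_end[i] + 1
    }
  }
  invisible(TRUE)
}

#' Read / write BED3+ feature intervals
#'
#' Features are held as \link[GenomicRanges]{GRanges} (1-based in memory);
#' BED files are 0-based half-open.  Column 4 maps to \code{label}, column 5
#' to \code{score}, column 6 to strand.  Output is sorted by (seqnames,
#' start).
#'
#' @param path file path
#' @return a GRanges with mcols \code{label} and \code{score}
#' @export
readBed <- function(path) {
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 3) stop("BED needs at least 3 columns")
  if (any(d[[3]] <= d[[2]])) stop("BED interval with end <= start")
  strand <- if (ncol(d) >= 6) d[[6]] else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(d[[1]],
          IRanges::IRanges(start = d[[2]] + 1L, end = d[[3]]),
          strand = strand)
  S4Vectors::mcols(gr)$label <- if (ncol(d) >= 4) as.character(d[[4]]) else NA_character_
  S4Vectors::mcols(gr)$score <- if (ncol(d) >= 5) suppressWarnings(as.numeric(d[[5]])) else NA_real_
  gr
}

#' @rdname readBed
#' @param features a GRanges (mcols \code{label}, \code{score} used if present)
#' @export
writeBed <- function(features, path) {
  if (length(features) && any(GenomicRanges::width(features) < 1))
    stop("feature with end <= start")
  o <- order(as.character(GenomicRanges::seqnames(features)),
             GenomicRanges::start(features))
  features <- features[o]
  mc <- S4Vectors::mcols(features)
  lab <- if ("label" %in% names(mc)) as.character(mc$label) else rep(".", length(features))
  sc <- if ("score" %in% names(mc)) mc$score else rep(0, length(features))
  sc[is.na(sc)] <- 0
  lab[is.na(lab)] <- "."
  d <- data.frame(as.character(GenomicRanges::seqnames(features)),
                  GenomicRanges::start(features) - 1L,
                  GenomicRanges::end(features), lab, sc,
                  as.character(GenomicRanges::strand(features)))
  d[[6]][d[[6]] == "*"] <- "."
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read / write marker tables (genetic-map CSV)
#'
#' Columns: \code{marker_id}, \code{scaffold_id}, \code{physical_bp}
#' (1-based), \code{linkage_group}, \code{genetic_pos}, \code{mapq},
#' \code{unique} (logical), and optionally \code{seq} (the 50 bp up/down
#' flanked marker sequence used for anchoring).
#'
#' @param path file path
#' @export
readMarkers <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$unique <- as.logical(d$unique)
  d
}

#' @rdname readMarkers
#' @param markers marker data.frame
#' @export
writeMarkers <- function(markers, path) {
  utils::write.csv(markers, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write map alignments (XMAP-like TSV)
#'
#' One row per alignment: query/ref ids, orientation, spans, score,
#' confidence, and the pair list serialized as \code{"q:r;q:r;..."} of
#' 1-based label indices.
#'
#' @param alignments list of \linkS4class{MapAlignment}
#' @param path file path
#' @export
writeAlignments <- function(alignments, path) {
  rows <- lapply(alignments, function(a) {
    data.frame(query_id = a@queryId, ref_id = a@refId, orientation = a@orientation,
               query_start = a@querySpan[1], query_end = a@querySpan[2],
               ref_start = a@refSpan[1], ref_end = a@refSpan[2],
               score = a@score, confidence = a@confidence,
               pairs = paste(sprintf("%d:%d", a@pairs[, 1], a@pairs[, 2]), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeAlignments
#' @export
readAlignments <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    pp <- do.call(rbind, lapply(strsplit(strsplit(d$pairs[i], ";")[[1]], ":"),
                                as.integer))
    colnames(pp) <- c("query", "ref")
    new("MapAlignment", queryId = d$query_id[i], refId = d$ref_id[i],
        orientation = d$orientation[i], pairs = pp, score = d$score[i],
        confidence = d$confidence[i],
        querySpan = c(d$query_start[i], d$query_end[i]),
        refSpan = c(d$ref_start[i], d$ref_end[i]))
  })
}
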