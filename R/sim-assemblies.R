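# Two simulated assembly profiles with planted failure modes.
#
# The accurate-short profile (the polished backbone) breaks inside arrays
# longer than its break threshold, collapses one configured tandem array,
# carries planted chimeric joins, breaks at the heterozygous region and has
# low substitution error.  The long-noisy profile breaks only above its
# (higher) threshold, assembles through the heterozygous region on the
# alternate haplotype, and has higher substitution/indel error.

#' Simulate the two contig assemblies
#'
#' @param sim result of \code{\link{simulateGenome}}
#' @param config a \code{\link{simConfig}}
#' @return list per profile (\code{accurate}, \code{long}): list(records =
#'   named list of contigs, events = data.frame of planted events)
#' @export
simulateAssemblies <- function(sim, config = sim$truth$config) {
  set.seed(config$seed + 202L)
  out <- list()
  for (pname in c("accurate", "long")) {
    prof <- config$profiles[[pname]]
    prefix <- if (pname == "accurate") "acc" else "lon"
    records <- list()
    events <- list()
    ev <- function(type, chrom, ts, te, cid = NA_character_, cpos = NA_real_) {
      events[[length(events) + 1L]] <<- data.frame(profile = pname, type = type,
        chrom = chrom, truth_start = ts, truth_end = te, contig_id = cid,
        contig_pos = cpos, stringsAsFactors = FALSE)
    }
    cn <- 0L
    for (chrom in names(sim$genome)) {
      useAlt <- pname == "long" && isTRUE(prof$useAltHap) &&
        !is.null(sim$alt[[chrom]])
      srcRec <- if (useAlt) sim$alt[[chrom]] else sim$genome[[chrom]]
      srcName <- srcRec@id
      len <- seqLen(srcRec)
      het <- sim$truth$het
      shiftHet <- function(x) {  # hap1 coords -> source coords
        if (!useAlt) return(x)
        ifelse(x >= het$delEnd, x - het$indelLen,
               ifelse(x > het$delStart, het$delStart, x))
      }
      aa <- config$arrays[config$arrays$chrom == chrom, , drop = FALSE]
      brk <- list()  # list of c(left, right) missing intervals in source coords
      for (i in seq_len(nrow(aa))) {
        if (aa$span[i] > prof$breakArraySpan) {
          a0 <- shiftHet(aa$start[i]); a1 <- shiftHet(aa$start[i] + aa$span[i])
          brk[[length(brk) + 1L]] <- c(a0 + prof$arrayEdgeKeep, a1 - prof$arrayEdgeKeep)
          ev("break_array", chrom, aa$start[i], aa$start[i] + aa$span[i])
        }
      }
      if (isTRUE(prof$breakAtHet) && !is.null(het) && chrom == het$chrom) {
        brk[[length(brk) + 1L]] <- c(het$start, het$end)
        ev("break_het", chrom, het$start, het$end)
      }
      # random clean breaks away from arrays/existing breaks/ends
      margin <- round(0.04 * len)
      occupied <- do.call(rbind, c(list(cbind(0, margin), cbind(len - margin, len)),
        lapply(brk, function(b) cbind(b[1] - margin, b[2] + margin)),
        lapply(seq_len(nrow(aa)), function(i)
          cbind(shiftHet(aa$start[i]) - margin,
                shiftHet(aa$start[i] + aa$span[i]) + margin))))
      nr <- prof$nRandomBreaks
      tries <- 0L
      while (nr > 0L && tries < 200L) {
        tries <- tries + 1L
        pos <- sample.int(len, 1L)
        if (any(pos > occupied[, 1] & pos < occupied[, 2])) next
        brk[[length(brk) + 1L]] <- c(pos, pos)
        occupied <- rbind(occupied, cbind(pos - margin, pos + margin))
        ev("break_random", chrom, pos, pos)
        nr <- nr - 1L
      }
      bounds <- if (length(brk)) {
        bmat <- do.call(rbind, brk)
        bmat <- bmat[order(bmat[, 1]), , drop = FALSE]
        c(prof$tipTrim, as.vector(t(bmat)), len - prof$tipTrim)
      } else c(prof$tipTrim, len - prof$tipTrim)
      for (i in seq(1, length(bounds) - 1, by = 2)) {
        lo <- bounds[i]; hi <- bounds[i + 1]
        if (hi - lo < 1000) next
        cn <- cn + 1L
        cid <- sprintf("%s_c%d", prefix, cn)
        records[[cid]] <- sliceRecord(srcRec, lo, hi, newId = cid)
      }
    }
    # planted collapse of a tandem array (accurate profile)
    if (pname == "accurate" && !is.null(config$collapse)) {
      cl <- config$collapse
      a <- config$arrays[config$arrays$chrom == cl$chrom &
                         config$arrays$start == cl$arrayStart, , drop = FALSE]
      if (nrow(a) == 1L) {
        for (cid in names(records)) {
          p <- records[[cid]]@provenance
          hitBlock <- p$source_id == cl$chrom & p$src_start <= a$start &
            p$src_end >= a$start + a$span
          if (any(hitBlock)) {
            b <- p[which(hitBlock)[1], ]
            delLen <- round(cl$fraction * a$span)
            d0 <- b$start + (a$start - b$src_start) + round((a$span - delLen) / 2)
            rec <- records[[cid]]
            records[[cid]] <- concatRecords(cid,
              list(sliceRecord(rec, 0L, d0), sliceRecord(rec, d0 + delLen, seqLen(rec))))
            ev("collapse", cl$chrom, a$start, a$start + a$span, cid, d0)
            break
          }
        }
      }
    }
    # planted chimeric joins between repeat-adjacent loci (accurate profile)
    if (pname == "accurate" && config$chimeras > 0L) {
      evSoFar <- do.call(rbind, events)
      collapseCid <- evSoFar$contig_id[evSoFar$type == "collapse"]
      endsAtArray <- function(cid, side) {
        p <- records[[cid]]@provenance
        src <- p$source_id[1]
        aa <- config$arrays[config$arrays$chrom == src, , drop = FALSE]
        edge <- if (side == "R") max(p$src_end) else min(p$src_start)
        any(abs(c(aa$start, aa$start + aa$span) - edge) <=
              config$profiles$accurate$arrayEdgeKeep + 1)
      }
      cids <- names(records)
      lefts <- cids[vapply(cids, endsAtArray, TRUE, side = "R")]
      rights <- cids[vapply(cids, endsAtArray, TRUE, side = "L")]
      lefts <- setdiff(lefts, collapseCid); rights <- setdiff(rights, collapseCid)
      made <- 0L; used <- character(0)
      for (lft in lefts) {
        if (made >= config$chimeras) break
        if (lft %in% used) next
        lChrom <- records[[lft]]@provenance$source_id[1]
        avail <- setdiff(rights, c(used, lft))
        cand <- avail[vapply(avail, function(r)
          records[[r]]@provenance$source_id[1] != lChrom, TRUE)]
        if (!length(cand)) next
        rgt <- cand[1]
        made <- made + 1L
        used <- c(used, lft, rgt)
        cidNew <- sprintf("acc_chim%d", made)
        junction <- seqLen(records[[lft]])
        chim <- concatRecords(cidNew, list(records[[lft]], records[[rgt]]))
        pl <- records[[lft]]@provenance; pr <- records[[rgt]]@provenance
        ev("chimera", pl$source_id[nrow(pl)], pl$src_end[nrow(pl)], pr$src_start[1],
           cidNew, junction)
        records[[cidNew]] <- chim
        records[[lft]] <- NULL; records[[rgt]] <- NULL
      }
    }
    # profile sequence error
    for (cid in names(records)) {
      r <- records[[cid]]
      s2 <- mutateSequence(r@seq, prof$subRate, prof$indelRate)
      if (nchar(s2) != seqLen(r)) {
        # indels: provenance collapses to one nominal block whose source
        # interval matches the new length (the mapping is approximate by
        # up to the net indel drift)
        p <- r@provenance
        records[[cid]] <- new("SeqRecord", id = cid, seq = s2,
          provenance = data.frame(start = 0L, end = nchar(s2),
            source_id = p$source_id[1], src_start = min(p$src_start),
            src_end = min(p$src_start) + nchar(s2), strand = "+",
            stringsAsFactors = FALSE))
      } else records[[cid]] <- new("SeqRecord", id = cid, seq = s2,
                                   provenance = r@provenance)
    }
    out[[pname]] <- list(records = records,
                         events = do.call(rbind, events))
  }
  out
}
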