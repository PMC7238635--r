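# Validation of a final assembly against simulator truth.

#' Validate an assembly against simulator truth
#'
#' Probes the truth genome with sampled 31-mers and reports: completeness
#' (fraction of truth probes present in the assembly, overall and excluding
#' the regions designed to be unresolvable: arrays above both break
#' thresholds, the heterozygous region and telomere tips), a sequence
#' identity estimate outside repeat arrays (probe survival inverted through
#' the k-mer model), N-gap counts per assembly object, per-chimera cut
#' distances (when a pipeline report is supplied), and whether the planted
#' collapse was restored to truth length.
#'
#' @param assembly named list of \linkS4class{SeqRecord} (pseudomolecules)
#' @param bundle the simulation bundle the pipeline consumed
#' @param report optional pipeline report (for cut-vs-chimera distances)
#' @param stride probe spacing in bp
#' @param k probe k-mer length (<= 31)
#' @return list of validation metrics
#' @export
validateAgainstTruth <- function(assembly, bundle, report = NULL,
                                 stride = 1000L, k = 31L) {
  sim <- bundle$sim
  config <- sim$truth$config
  fx <- sim$truth$features
  hardFam <- c("telomere", "het")
  unsolvable <- fx[(S4Vectors::mcols(fx)$label == "array" &
                    GenomicRanges::width(fx) >
                      config$profiles$long$breakArraySpan) |
                   S4Vectors::mcols(fx)$family %in% hardFam]
  repeatish <- fx[S4Vectors::mcols(fx)$label %in%
                    c("array", "subtelomere", "telomere", "centromere", "TE",
                      "heterozygous")]
  probes <- list(); meta <- list()
  for (chrom in names(sim$genome)) {
    s <- sim$genome[[chrom]]@seq
    pos <- seq(1L, nchar(s) - k, by = stride)
    probes[[chrom]] <- substring(s, pos, pos + k - 1L)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos + k - 1L))
    meta[[chrom]] <- data.frame(chrom = chrom, pos = pos,
      hard = IRanges::overlapsAny(gr, unsolvable),
      repeatish = IRanges::overlapsAny(gr, repeatish))
  }
  probeSeq <- unlist(probes, use.names = FALSE)
  meta <- do.call(rbind, meta)
  targets <- vapply(assembly, seqString, "")
  h <- cpp_anchor_hits(unname(targets),
                       c(probeSeq, revCompVec(probeSeq)),
                       as.integer(k), 5000L, 1L)
  n <- length(probeSeq)
  found <- logical(n)
  qi <- ((h$query - 1L) %% n) + 1L
  found[unique(qi)] <- TRUE
  # a probe is covered when found, or when probes just up- and downstream on
  # the same chromosome are found (the base pairs are present, merely
  # carrying sequence error; identity is reported separately below)
  covered <- found
  for (chrom in unique(meta$chrom)) {
    ix <- which(meta$chrom == chrom)
    f <- found[ix]
    prevF <- cummax(ifelse(f, seq_along(f), 0L))
    nextF <- rev(cummax(ifelse(rev(f), seq_along(f), 0L)))
    nextF <- length(f) + 1L - nextF
    gapOk <- prevF > 0 & nextF <= length(f) &
      (seq_along(f) - prevF <= 3L) & (nextF - seq_along(f) <= 3L)
    covered[ix] <- f | gapOk
  }
  completeness <- mean(covered)
  completeness_solvable <- mean(covered[!meta$hard])
  sNon <- mean(found[!meta$repeatish & !meta$hard])
  identity_estimate <- sNon^(1 / k)
  gaps <- vapply(assembly, function(r) nrow(findNGaps(r)), 0L)
  out <- list(completeness = completeness,
              completeness_solvable = completeness_solvable,
              identity_outside_repeats = identity_estimate,
              n_gaps = gaps, total_gap_bp = sum(vapply(assembly, function(r) {
                g <- findNGaps(r); sum(g$end - g$start) }, 0)))
  # chimera cut accuracy
  if (!is.null(report)) {
    ev <- report$events
    chim <- ev[ev$type == "chimera", , drop = FALSE]
    led <- report$conflicts$ledgerA
    dists <- numeric(0)
    for (i in seq_len(nrow(chim))) {
      frags <- led[led$source_id == chim$contig_id[i], , drop = FALSE]
      cuts <- setdiff(unique(c(frags$start, frags$end)),
                      c(0, max(frags$end)))
      dists <- c(dists, if (length(cuts))
        min(abs(cuts - chim$contig_pos[i])) else Inf)
    }
    out$chimera_cut_distance_bp <- dists
    # label-interval distance: number of digest labels on the chimeric
    # contig strictly between the cut and the planted junction (0 means
    # same label interval)
    lint <- numeric(0)
    for (i in seq_len(nrow(chim))) {
      rec <- bundle$assemblies$accurate$records[[chim$contig_id[i]]]
      frags <- led[led$source_id == chim$contig_id[i], , drop = FALSE]
      cuts <- setdiff(unique(c(frags$start, frags$end)), c(0, max(frags$end)))
      if (!length(cuts) || is.null(rec)) { lint <- c(lint, Inf); next }
      cut <- cuts[which.min(abs(cuts - chim$contig_pos[i]))]
      lab <- insilicoDigest(rec, config$digestion$motif,
                            config$digestion$minLabelSpacing)@labels
      lo <- min(cut, chim$contig_pos[i]); hi <- max(cut, chim$contig_pos[i])
      lint <- c(lint, sum(lab > lo & lab < hi))
    }
    out$chimera_cut_distance_labels <- lint
  }
  # collapse restoration: distance between unique flank probes
  cl <- config$collapse
  if (!is.null(cl)) {
    a <- config$arrays[config$arrays$chrom == cl$chrom &
                       config$arrays$start == cl$arrayStart, , drop = FALSE]
    if (nrow(a) == 1L) {
      s <- sim$genome[[cl$chrom]]@seq
      # unique flank probes at several offsets from the array bounds:
      # sequence error in the assembly can defeat any single exact probe
      probeAt <- function(off, side) {
        p0 <- if (side == "L") a$start - off else a$start + a$span + off - k
        substr(s, p0 + 1, p0 + k)
      }
      offs <- c(600, 1200, 2000, 3000, 5000)
      pl <- vapply(offs, probeAt, "", side = "L")
      pr <- vapply(offs, probeAt, "", side = "R")
      qsAll <- c(pl, pr, revCompVec(pl), revCompVec(pr))
      hp <- cpp_anchor_hits(unname(targets), qsAll, as.integer(k), 4L, 1L)
      no <- length(offs)
      probeIdx <- ((hp$query - 1L) %% (2L * no)) + 1L  # fold rc onto fw
      found <- NULL
      for (oL in seq_len(no)) {
        selL <- probeIdx == oL
        if (sum(selL) != 1L) next
        for (oR in seq_len(no)) {
          selR <- probeIdx == no + oR
          if (sum(selR) != 1L) next
          if (hp$target[selR] != hp$target[selL]) next
          found <- list(dist = abs(hp$tpos[selR] - hp$tpos[selL]),
                        truth = a$span + offs[oL] + offs[oR] - k)
          break
        }
        if (!is.null(found)) break
      }
      delLen <- round(cl$fraction * a$span)
      if (!is.null(found)) {
        out$collapse_span_error_bp <- abs(found$dist - found$truth)
        out$collapse_restored <- abs(found$dist - found$truth) < 0.5 * delLen
      } else {
        out$collapse_span_error_bp <- NA_real_
        out$collapse_restored <- FALSE
      }
    }
  }
  out
}
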