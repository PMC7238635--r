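# End-to-end driver: conflict cutting (step 1), error curation (step 2),
# overlap merging (step 3), hybrid scaffolding + 13N resolution (step 4),
# then gap filling, telomere extension and pseudomolecule construction.

# Digest every contig and align each digest against each map, with a cheap
# interval-sketch prefilter.  When `prev` is given, contigs whose id and
# sequence length are unchanged reuse their previous digest and alignments.
alignAssembly <- function(contigs, maps, config, params, prev = NULL) {
  reuse <- character(0)
  if (!is.null(prev)) {
    reuse <- names(contigs)[vapply(names(contigs), function(id)
      !is.null(prev$digests[[id]]) &&
        abs(prev$digests[[id]]@length - seqLen(contigs[[id]])) < 0.5, TRUE)]
  }
  digests <- list()
  for (id in names(contigs)) {
    digests[[id]] <- if (id %in% reuse) prev$digests[[id]] else
      insilicoDigest(contigs[[id]], motif = config$digestion$motif,
                     minLabelSpacing = config$digestion$minLabelSpacing)
  }
  sketch <- function(m) unique(round(diff(m@labels) / 1000))
  mapSketch <- lapply(maps, sketch)
  alignments <- list()
  if (length(reuse))
    alignments <- Filter(function(a) a@queryId %in% reuse, prev$alignments)
  for (cid in setdiff(names(contigs), reuse)) {
    dg <- digests[[cid]]
    if (length(dg@labels) < params$minPairs) next
    ds <- sketch(dg)
    for (mid in names(maps)) {
      if (length(intersect(ds, mapSketch[[mid]])) < 4L) next
      res <- alignLabelMaps(dg, maps[[mid]], params)
      alignments <- c(alignments, res)
    }
  }
  list(digests = digests, alignments = alignments)
}

# One round of map rescaling against the backbone digests.
rescaleMaps <- function(maps, alignments, digests, minPairsFit = 10L) {
  for (mid in names(maps)) {
    ss <- c()
    for (a in alignments) {
      if (a@refId != mid || nrow(a@pairs) < minPairsFit) next
      s <- fitStretch(a, digests[[a@queryId]], maps[[mid]])
      ss <- c(ss, s)
    }
    if (length(ss)) maps[[mid]] <- rescaleMap(maps[[mid]], 1 / stats::median(ss))
  }
  maps
}

#' Run the full assembly-merging pipeline
#'
#' Executes, in order: map rescaling, conflict detection and chimera
#' cutting (both assemblies), insertion/deletion curation of the primary
#' assembly with alternate-assembly patching, cross-assembly overlap
#' merging into unitigs, hybrid scaffolding with 13N overlap annotation and
#' resolution, iterative long-read gap filling, telomere extension, and
#' marker-driven pseudomolecule construction.  Every planted-event count,
#' per-step tally and base-conservation delta is returned in the report.
#'
#' @param config a \code{\link{simConfig}} (study conditions and seed)
#' @param bundle optional pre-simulated input bundle
#'   (\code{\link{simulateBundle}}); simulated from \code{config} if NULL
#' @param params label-map \code{\link{alignParams}}
#' @param rerunConflicts re-run conflict detection after step 3
#' @param outDir optional run directory for step artifacts
#' @param verbose print one summary line per step
#' @return list(pseudomolecules, agp, scaffolds, leftover, markers,
#'   ordering, report, bundle)
#' @export
runPipeline <- function(config = simConfig(), bundle = NULL,
                        params = alignParams(), rerunConflicts = TRUE,
                        outDir = NULL, verbose = TRUE) {
  if (is.null(bundle)) bundle <- simulateBundle(config)
  if (is.null(bundle$maps) || !length(bundle$maps$maps))
    stop("step 1 requires optical maps: none provided")
  sc <- config$scale
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  report <- list()
  A <- bundle$assemblies$accurate$records
  B <- bundle$assemblies$long$records
  maps <- bundle$maps$maps
  report$metrics_before <- assemblyMetrics(c(A, B))
  nonN0 <- nonNBases(c(A, B))

  # --- step 0: digest, align, rescale maps against the primary assembly
  alA <- alignAssembly(A, maps, config, params)
  maps <- rescaleMaps(maps, alA$alignments, alA$digests)
  alA <- alignAssembly(A, maps, config, params)
  alB <- alignAssembly(B, maps, config, params)
  say("step 0: %d + %d alignments on %d maps", length(alA$alignments),
      length(alB$alignments), length(maps))

  # --- step 1: conflicts and cutting
  cutOne <- function(contigs, al) {
    # only near-best alignments per contig are evidence for conflicts;
    # weak secondary hits still contribute to junction support
    bestBy <- tapply(vapply(al$alignments, alignmentScore, 0),
                     vapply(al$alignments, function(a) a@queryId, ""), max)
    strong <- Filter(function(a) a@score >= 0.5 * bestBy[[a@queryId]],
                     al$alignments)
    cf <- detectConflicts(strong, al$digests, maps,
                          minOverhangLabels = 5L,
                          minOverhangBp = round(50000 * sc))
    if (nrow(cf)) for (i in seq_len(nrow(cf)))
      cf$support_score[i] <- scoreJunctionSupport(cf[i, ], al$alignments, al$digests)
    cut <- cutContigs(contigs, cf, supportCut = 35,
                      shortFloor = round(20000 * sc))
    list(conflicts = cf, contigs = cut$contigs, ledger = cut$ledger)
  }
  s1A <- cutOne(A, alA); s1B <- cutOne(B, alB)
  A <- s1A$contigs; B <- s1B$contigs
  report$conflicts <- list(
    found = nrow(s1A$conflicts) + nrow(s1B$conflicts),
    cut_junctions = sum(s1A$conflicts$support_score < 35, na.rm = TRUE) +
      sum(s1B$conflicts$support_score < 35, na.rm = TRUE),
    tableA = s1A$conflicts, tableB = s1B$conflicts,
    ledgerA = s1A$ledger, ledgerB = s1B$ledger)
  say("step 1: %d conflicts, contigs now %d + %d", report$conflicts$found,
      length(A), length(B))
  stopifnot(nonNBases(c(A, B)) == nonN0)  # cutting conserves non-N bases
  alA <- alignAssembly(A, maps, config, params, prev = alA)
  alB <- alignAssembly(B, maps, config, params, prev = alB)

  # --- step 2: discrepancy calling and patching (primary = accurate)
  calls <- list()
  ori <- list()
  for (a in alA$alignments) {
    cc <- callDiscrepancies(a, alA$digests[[a@queryId]], maps[[a@refId]],
                            minSize = 1000, params = params)
    if (nrow(cc)) {
      calls[[length(calls) + 1L]] <- cc
      ori[[paste(a@queryId, a@refId)]] <- a@orientation
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    callDiscrepancies(new("MapAlignment", queryId = "x", refId = "y",
                          orientation = "+", pairs = matrix(integer(0), 0, 2),
                          score = 0, confidence = 0, querySpan = c(0, 0),
                          refSpan = c(0, 0)),
                      labelMap("x", 1), labelMap("y", 1))
  merged <- if (nrow(calls))
    mergeDiscrepancies(calls, alA$alignments, alA$digests) else calls
  patched <- 0L; patchAdded <- 0; patchRemoved <- 0
  patchNotes <- list()
  if (nrow(merged)) {
    merged <- merged[order(merged$contig_id, -merged$contig_start), , drop = FALSE]
    for (i in seq_len(nrow(merged))) {
      call <- merged[i, ]
      res <- patchWithAlternate(A[[call$contig_id]], call, B, alB$alignments,
                                alB$digests, maps,
                                minSize = 1000, params = params,
                                primaryOrientation =
                                  ori[[paste(call$contig_id, call$map_id)]] %||% "+")
      if (res$patched) {
        A[[call$contig_id]] <- res$record
        patched <- patched + 1L
        patchAdded <- patchAdded + res$bases_added
        patchRemoved <- patchRemoved + res$bases_removed
      }
      patchNotes[[length(patchNotes) + 1L]] <-
        data.frame(contig_id = call$contig_id, kind = call$kind,
                   size = call$size, zygosity = call$zygosity, note = res$note,
                   donor = res$donor_id, stringsAsFactors = FALSE)
    }
  }
  report$discrepancies <- list(called = nrow(calls), merged_loci = nrow(merged),
    homozygous = sum(merged$zygosity == "homozygous"),
    heterozygous = sum(merged$zygosity == "heterozygous"),
    patched = patched, bases_added = patchAdded, bases_removed = patchRemoved,
    table = merged,
    notes = if (length(patchNotes)) do.call(rbind, patchNotes) else data.frame())
  say("step 2: %d loci (%d hom, %d het), %d patched", nrow(merged),
      report$discrepancies$homozygous, report$discrepancies$heterozygous, patched)

  # --- step 3: cross-assembly overlap merging into unitigs
  contigs <- c(A, B)
  ov <- findSequenceOverlaps(contigs, contigs, k = 21L,
                             minOverlap = round(5000 * sc),
                             minIdentity = 0.9, maxOverhang = 500L)
  dc <- dropContained(contigs, ov, maxTail = max(2000, round(15000 * sc)))
  ov2 <- ov[ov$a_id %in% names(dc$contigs) & ov$b_id %in% names(dc$contigs), , drop = FALSE]
  mg <- mergeOverlapping(dc$contigs, ov2, primaryIds = names(A))
  contigs <- mg$records
  report$overlaps <- list(found = nrow(ov), dovetails = sum(ov$kind == "dovetail"),
    contained_dropped = length(dc$dropped), unitigs = nrow(mg$info),
    info = mg$info, branches = mg$branches)
  say("step 3: %d overlaps, %d contained dropped, %d unitigs, %d contigs remain",
      nrow(ov), length(dc$dropped), nrow(mg$info), length(contigs))

  alC <- alignAssembly(contigs, maps, config, params,
                       prev = list(digests = c(alA$digests, alB$digests),
                                   alignments = c(alA$alignments, alB$alignments)))
  if (rerunConflicts) {
    s3 <- cutOne(contigs, alC)
    if (nrow(s3$conflicts)) {
      contigs <- s3$contigs
      alC <- alignAssembly(contigs, maps, config, params, prev = alC)
    }
    report$conflicts$post_merge <- nrow(s3$conflicts)
  }

  # --- step 4: hybrid scaffolding + 13N resolution
  anchors <- selectAnchorMaps(alC$alignments, alC$digests, maps)
  hb <- hybridScaffold(contigs, maps, alC$alignments, alC$digests,
                       anchorMaps = anchors)
  n13 <- sum(hb$agp$gap_type == "overlap13N", na.rm = TRUE)
  adj <- mapGuidedAdjacency(hb$placements,
                            minDetectableOverlap = round(200000 * sc))
  hb <- resolve13NOverlaps(hb, minOverlap = round(2000 * sc),
                           junctionTail = max(2000, round(15000 * sc)))
  report$scaffolding <- list(scaffolds = length(hb$scaffolds),
    anchor_maps = anchors, junction13N = n13, resolved13N = hb$resolved,
    retained13N = hb$retained13N, leftover = names(hb$leftover),
    adjacency = adj, notes = hb$notes)
  say("step 4: %d scaffolds, %d x 13N (%d resolved), %d leftover contigs",
      length(hb$scaffolds), n13, hb$resolved, length(hb$leftover))

  # --- finishing: gap filling and telomere extension
  gapBefore <- sum(vapply(hb$scaffolds, function(r) {
    g <- findNGaps(r, 0L); sum(g$end - g$start) }, 0))
  fg <- fillGaps(hb$scaffolds, bundle$reads$seqs, nIter = 3L,
                 anchorLen = 300L, maxGapDelta = 2)
  scaffolds <- fg$scaffolds
  tl <- extendTelomeres(scaffolds, bundle$reads$seqs,
                        minTract = round(1000 * sc))
  scaffolds <- tl$scaffolds
  gapAfter <- sum(vapply(scaffolds, function(r) {
    g <- findNGaps(r, 0L); sum(g$end - g$start) }, 0))
  report$finishing <- list(
    gaps_closed = sum(fg$report$action == "closed"),
    gaps_shrunk = sum(fg$report$action == "shrunk"),
    gap_bp_before = gapBefore, gap_bp_after = gapAfter,
    fill_bases_added = sum(fg$report$bases_added),
    fill_report = fg$report,
    telomeres_extended = nrow(tl$report), telomere_report = tl$report)
  say("finishing: %d gaps closed, %d shrunk, %d telomeres extended",
      report$finishing$gaps_closed, report$finishing$gaps_shrunk,
      report$finishing$telomeres_extended)

  # --- AGP construction: markers -> ordering -> pseudomolecules
  mk <- anchorMarkers(bundle$markers, scaffolds)
  mkf <- filterMarkers(mk)
  pm <- NULL; ordering <- NULL
  if (nrow(mkf)) {
    ordering <- orderOrient(mkf)
    pm <- emitPseudomolecules(ordering, scaffolds, interGap = 100L)
  }
  placedScaffolds <- if (!is.null(ordering))
    unlist(lapply(ordering$orders, function(o) o$scaffold_id)) else character(0)
  leftover <- c(scaffolds[setdiff(names(scaffolds), placedScaffolds)],
                hb$leftover)
  report$agp_stage <- list(markers_anchored = nrow(mk),
    markers_kept = nrow(mkf), pseudomolecules = length(pm$records),
    unplaced = names(leftover))
  say("AGP: %d/%d markers kept, %d pseudomolecules, %d unplaced pieces",
      nrow(mkf), nrow(mk), length(pm$records), length(leftover))

  report$metrics_after <- if (!is.null(pm)) assemblyMetrics(pm$records) else
    assemblyMetrics(scaffolds)
  report$nonN_before <- nonN0
  report$nonN_after <- nonNBases(c(if (!is.null(pm)) pm$records else scaffolds,
                                   leftover))
  report$events <- rbind(bundle$assemblies$accurate$events,
                         bundle$assemblies$long$events)

  result <- list(pseudomolecules = if (!is.null(pm)) pm$records else NULL,
                 agp = if (!is.null(pm)) pm$agp else NULL,
                 scaffolds = scaffolds, scaffold_agp = agpFromRecords(scaffolds),
                 leftover = leftover, markers = mkf, ordering = ordering,
                 report = report, config = config)
  if (!is.null(outDir)) writeRunDir(result, outDir)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dump the principal artifacts of a run into a directory.
writeRunDir <- function(result, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(result$pseudomolecules)) {
    writeSequences(result$pseudomolecules, file.path(outDir, "pseudomolecules.fa"))
    writeAGP(result$agp, file.path(outDir, "pseudomolecules.agp"))
  }
  writeSequences(result$scaffolds, file.path(outDir, "scaffolds.fa"))
  writeAGP(result$scaffold_agp, file.path(outDir, "scaffolds.agp"))
  if (length(result$leftover))
    writeSequences(result$leftover, file.path(outDir, "leftover.fa"))
  if (!is.null(result$markers) && nrow(result$markers))
    writeMarkers(result$markers, file.path(outDir, "markers.csv"))
  wtsv <- function(d, f) if (!is.null(d) && nrow(d))
    utils::write.table(d, file.path(outDir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wtsv(rbind(result$report$conflicts$tableA, result$report$conflicts$tableB),
       "conflicts.tsv")
  wtsv(rbind(result$report$conflicts$ledgerA, result$report$conflicts$ledgerB),
       "cut_ledger.tsv")
  wtsv(result$report$discrepancies$table, "discrepancies.tsv")
  wtsv(result$report$overlaps$info, "unitigs.tsv")
  wtsv(result$report$finishing$fill_report, "gap_fill.tsv")
  rep <- result$report
  keep <- c("conflicts", "discrepancies", "overlaps", "scaffolding",
            "finishing", "agp_stage")
  slim <- lapply(rep[keep], function(x)
    x[!vapply(x, function(e) is.data.frame(e) || is.list(e), TRUE)])
  slim$metrics_before <- unclass(rep$metrics_before)
  slim$metrics_after <- unclass(rep$metrics_after)
  slim$nonN_before <- rep$nonN_before
  slim$nonN_after <- rep$nonN_after
  jsonlite::write_json(slim, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}
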