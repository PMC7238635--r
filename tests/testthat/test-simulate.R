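# The synthetic-data generator: determinism, truth self-consistency and
# the planted failure modes.

test_that("the generator is byte-reproducible from (config, seed)", {
  cfg <- simConfig(seed = 5, scale = 0.1, nChromosomes = 1L)
  s1 <- suppressWarnings(simulateGenome(cfg))
  s2 <- suppressWarnings(simulateGenome(cfg))
  expect_identical(seqString(s1$genome$chr1), seqString(s2$genome$chr1))
  m1 <- simulateOpticalMaps(s1, cfg); m2 <- simulateOpticalMaps(s2, cfg)
  expect_identical(lapply(m1$maps, mapLabels), lapply(m2$maps, mapLabels))
  r1 <- simulateReads(s1, "long", 2, cfg); r2 <- simulateReads(s2, "long", 2, cfg)
  expect_identical(r1$seqs, r2$seqs)
  k1 <- simulateMarkers(s1, config = cfg); k2 <- simulateMarkers(s2, config = cfg)
  expect_identical(k1, k2)
})

test_that("truth arrays re-scanned by the annotation module match the tables", {
  sim <- tinySim()
  fx <- sim$truth$features
  arr <- fx[S4Vectors::mcols(fx)$label == "array" &
            S4Vectors::mcols(fx)$family == "CentC"]
  hits <- scanRepeatMonomers(sim$genome, sim$truth$monomers$CentC,
                             family = "CentC")
  ov <- GenomicRanges::findOverlaps(arr, hits, ignore.strand = TRUE)
  expect_equal(length(unique(S4Vectors::queryHits(ov))), length(arr))
  # the recovered span agrees with truth within one monomer
  for (i in seq_along(arr)) {
    hh <- hits[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
    expect_lte(abs(min(GenomicRanges::start(hh)) - GenomicRanges::start(arr[i])), 160)
    expect_lte(abs(max(GenomicRanges::end(hh)) - GenomicRanges::end(arr[i])), 320)
  }
})

test_that("zero-interruption, zero-divergence arrays are pure tandem runs", {
  cfg <- simConfig(seed = 6, scale = 0.1, nChromosomes = 1L)
  cfg$arrays$divergence <- 0
  cfg$arrays$teRate <- 0
  sim <- suppressWarnings(simulateGenome(cfg))
  a <- cfg$arrays[cfg$arrays$family == "CentC", ][1, ]
  mono <- sim$truth$monomers$CentC
  arrSeq <- substr(seqString(sim$genome$chr1), a$start + 1, a$start + a$span)
  expect_equal(arrSeq, tandemFill(mono, a$span))
})

test_that("assembly profiles honour break thresholds and planted events", {
  b <- miniBundle()
  cfg <- b$sim$truth$config
  evA <- b$assemblies$accurate$events
  expect_equal(sum(evA$type == "chimera"), 2)
  expect_equal(sum(evA$type == "collapse"), 1)
  expect_equal(sum(evA$type == "break_het"), 1)
  # an array between the two break thresholds splits the accurate profile
  # but not the long-noisy one
  mid <- cfg$arrays[cfg$arrays$span > cfg$profiles$accurate$breakArraySpan &
                    cfg$arrays$span <= cfg$profiles$long$breakArraySpan, ]
  expect_gte(nrow(mid), 1)
  evL <- b$assemblies$long$events
  brkA <- evA[evA$type == "break_array", ]
  brkL <- evL[evL$type == "break_array", ]
  for (i in seq_len(nrow(mid)))
    expect_true(any(brkA$chrom == mid$chrom[i] & brkA$truth_start == mid$start[i]))
  expect_false(any(paste(brkL$chrom, brkL$truth_start) %in%
                   paste(mid$chrom, mid$start)))
  # the designed-unsolvable array breaks both profiles
  big <- cfg$arrays[cfg$arrays$span > cfg$profiles$long$breakArraySpan, ]
  expect_equal(nrow(big), 1)
  expect_true(any(brkL$chrom == big$chrom & brkL$truth_start == big$start))
})

test_that("an event-free, error-free profile tiles the genome exactly", {
  cfg <- simConfig(seed = 8, scale = 0.1, nChromosomes = 1L)
  cfg$profiles$accurate <- modifyList(cfg$profiles$accurate,
    list(subRate = 0, indelRate = 0, nRandomBreaks = 0L, breakAtHet = FALSE,
         tipTrim = 0, breakArraySpan = 1e9))
  cfg$chimeras <- 0L
  cfg$collapse <- NULL
  cfg$het <- NULL
  sim <- suppressWarnings(simulateGenome(cfg))
  asm <- simulateAssemblies(sim, cfg)
  tiled <- paste(vapply(asm$accurate$records, seqString, ""), collapse = "")
  expect_equal(tiled, seqString(sim$genome$chr1))
})

test_that("optical maps carry the configured noise processes", {
  cfg <- simConfig(seed = 9, scale = 0.1, nChromosomes = 1L)
  sim <- suppressWarnings(simulateGenome(cfg))
  # zero-noise maps equal the in-silico digest exactly (up to rebasing)
  cfg0 <- cfg
  cfg0$maps <- modifyList(cfg$maps, list(sdCoeff = 1e-9, missRate = 0,
                                         falsePer100kb = 0, replicates = 1L,
                                         pad = 0))
  mp <- simulateOpticalMaps(sim, cfg0)
  dg <- insilicoDigest(sim$genome$chr1, cfg$digestion$motif,
                       cfg$digestion$minLabelSpacing)
  off <- mp$truth$offset[1]
  expect_equal(mapLabels(mp$maps[[1]]) + off,
               mapLabels(dg)[mapLabels(dg) >= off &
                             mapLabels(dg) <= off + mapLength(mp$maps[[1]])],
               tolerance = 1e-6)
  # a 10 percent miss rate drops about 10 percent of labels
  cfgM <- cfg
  cfgM$maps <- modifyList(cfg$maps, list(missRate = 0.1, falsePer100kb = 0,
                                         replicates = 3L, splitUnlabeled = 1e12,
                                         minMapLen = 0))
  mpM <- simulateOpticalMaps(sim, cfgM)
  kept <- sum(mpM$truth$n_labels) / (3 * length(mapLabels(dg)))
  expect_lt(abs(kept - 0.9), 0.05)
})

test_that("read sets match their length and depth presets", {
  sim <- tinySim()
  cfg <- sim$truth$config
  rd <- simulateReads(sim, "long", 8, cfg)
  lens <- sort(rd$truth$length, decreasing = TRUE)
  n50 <- lens[which(cumsum(lens) >= 0.5 * sum(lens))[1]]
  expect_lt(abs(n50 - cfg$profiles$long$readN50) / cfg$profiles$long$readN50, 0.1)
  depth <- sum(rd$truth$length) / seqLen(sim$genome$chr1)
  expect_lt(abs(depth - 8) / 8, 0.05)
  # error-free reads are exact substrings
  cfg0 <- cfg
  cfg0$profiles$long$readSubRate <- 0
  cfg0$profiles$long$readIndelRate <- 0
  rd0 <- simulateReads(sim, "long", 1, cfg0)
  for (i in sample(length(rd0$seqs), 10)) {
    tr <- rd0$truth[i, ]
    src <- if (tr$hap == 2) sim$alt[[tr$chrom]] else sim$genome[[tr$chrom]]
    s <- substr(seqString(src), tr$start + 1, tr$end)
    if (tr$strand == "-") s <- revComp(s)
    expect_identical(rd0$seqs[[i]], s)
  }
})

test_that("ChIP simulation matches its enrichment fold", {
  sim <- tinySim()
  ch <- simulateChip(sim, fold = 10, depth = 20)
  fx <- sim$truth$features
  cent <- fx[S4Vectors::mcols(fx)$label == "centromere"]
  inC <- sum(ch$chip$chr1 >= GenomicRanges::start(cent) &
             ch$chip$chr1 <= GenomicRanges::end(cent))
  outC <- length(ch$chip$chr1) - inC
  centLen <- sum(GenomicRanges::width(cent))
  len <- seqLen(sim$genome$chr1)
  ratio <- (inC / centLen) / (outC / (len - centLen))
  expect_lt(abs(ratio - 10) / 10, 0.2)
  # fold 1 is statistically indistinguishable from input
  ch1 <- simulateChip(sim, fold = 1, depth = 20)
  ks <- suppressWarnings(stats::ks.test(ch1$chip$chr1, ch1$input$chr1))
  expect_gt(ks$p.value, 0.01)
  expect_error(simulateChip(sim, depth = 0), "positive")
})

test_that("markers are monotone up to noise and carry filter fodder", {
  sim <- tinySim()
  cfg <- sim$truth$config
  mkCfg <- cfg; mkCfg$markers$noiseSd <- 0
  mk0 <- simulateMarkers(sim, noiseSd = 0, config = mkCfg)
  expect_true(all(diff(order(mk0$genetic_pos)) > 0))
  mk <- simulateMarkers(sim, perGroup = 200, config = cfg)
  expect_lt(abs(mean(!mk$unique) - cfg$markers$fracNonUnique), 0.05)
  expect_true(all(nchar(mk$seq) == 2 * cfg$markers$flank + 1))
})
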