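# Hybrid scaffolding: placements, gap estimation, 13N annotation and
# resolution, AGP bookkeeping.

# Truth region with a noise-free optical map and two contigs placed on it.
scaffoldScenario <- function(seed, c1range, c2range, mutate2 = 0) {
  set.seed(seed)
  truth <- randomDNA(6e5)
  mp <- insilicoDigest(seqRecord("map", truth)); mp@source <- "optical"
  s2 <- substr(truth, c2range[1] + 1, c2range[2])
  if (mutate2 > 0) s2 <- mutateSequence(s2, mutate2)
  contigs <- list(c1 = seqRecord("c1", substr(truth, c1range[1] + 1, c1range[2])),
                  c2 = seqRecord("c2", s2))
  digests <- lapply(contigs, insilicoDigest)
  p <- alignParams()
  al <- c(alignLabelMaps(digests$c1, mp, p), alignLabelMaps(digests$c2, mp, p))
  list(truth = truth, maps = list(map = mp), contigs = contigs,
       digests = digests, alignments = al)
}

test_that("positive gaps get estimated N runs, bounded below at 100", {
  sc <- scaffoldScenario(51, c(0, 295000), c(305000, 600000))
  hb <- hybridScaffold(sc$contigs, sc$maps, sc$alignments, sc$digests)
  expect_length(hb$scaffolds, 1)
  g <- findNGaps(hb$scaffolds[[1]], 0)
  expect_equal(nrow(g), 1)
  expect_equal(g$end - g$start, 10000, tolerance = 0.01)  # noise-free estimate
  expect_equal(sum(hb$agp$gap_length, na.rm = TRUE), g$end - g$start)
  # scaffold length bookkeeping: contigs plus gaps exactly
  expect_equal(seqLen(hb$scaffolds[[1]]),
               sum(vapply(sc$contigs, seqLen, 0)) + (g$end - g$start))
})

test_that("overlapping placements are annotated with exactly 13 N", {
  sc <- scaffoldScenario(52, c(0, 310000), c(300000, 600000))
  hb <- hybridScaffold(sc$contigs, sc$maps, sc$alignments, sc$digests)
  g <- findNGaps(hb$scaffolds[[1]], 0)
  expect_equal(g$end - g$start, 13)
  expect_equal(g$kind, "unknown")
  agp <- hb$agp
  expect_equal(agp$gap_type[agp$component_type == "N"], "overlap13N")
  expect_equal(agp$gap_length[agp$component_type == "N"], 13)
})

test_that("13N junctions are resolved into truth when flanks truly overlap", {
  sc <- scaffoldScenario(53, c(0, 310000), c(300000, 600000))
  hb <- hybridScaffold(sc$contigs, sc$maps, sc$alignments, sc$digests)
  rs <- resolve13NOverlaps(hb)
  expect_equal(rs$resolved, 1)
  expect_equal(seqString(rs$scaffolds[[1]]), sc$truth)  # exact restoration
  expect_false(any(rs$agp$component_type == "N"))
})

test_that("diverged or flagged junctions keep their 13N gap", {
  sc <- scaffoldScenario(54, c(0, 310000), c(300000, 600000), mutate2 = 0.2)
  hb <- hybridScaffold(sc$contigs, sc$maps, sc$alignments, sc$digests)
  if (length(hb$scaffolds) == 1 && nrow(findNGaps(hb$scaffolds[[1]], 0))) {
    rs <- resolve13NOverlaps(hb)
    expect_equal(rs$resolved, 0)
    expect_equal(rs$retained13N, 1)
  }
  sc2 <- scaffoldScenario(55, c(0, 310000), c(300000, 600000))
  hb2 <- hybridScaffold(sc2$contigs, sc2$maps, sc2$alignments, sc2$digests)
  rs2 <- resolve13NOverlaps(hb2, skipContigs = "c1")   # flagged unmergeable
  expect_equal(rs2$resolved, 0)
  expect_equal(rs2$retained13N, 1)
})

test_that("contigs without a placement become leftovers", {
  sc <- scaffoldScenario(56, c(0, 295000), c(305000, 600000))
  set.seed(57)
  stray <- seqRecord("stray", randomDNA(50000))
  contigs <- c(sc$contigs, list(stray = stray))
  digests <- c(sc$digests, list(stray = insilicoDigest(stray)))
  hb <- hybridScaffold(contigs, sc$maps, sc$alignments, digests)
  expect_true("stray" %in% names(hb$leftover))
  expect_false("stray" %in% hb$agp$component_id)
})

test_that("map-guided adjacency estimates gaps and flags large overlaps", {
  sc <- scaffoldScenario(58, c(0, 295000), c(305000, 600000))
  pl <- contigPlacements(sc$alignments, sc$digests, sc$maps)
  adj <- mapGuidedAdjacency(pl$placements, minDetectableOverlap = 200000)
  expect_equal(nrow(adj), 1)
  expect_equal(adj$estimated_gap_bp, 10000, tolerance = 0.01)
  expect_equal(adj$action, "gap")
  # 250 kb placement overlap triggers a merge action
  sc2 <- scaffoldScenario(59, c(0, 400000), c(150000, 600000))
  pl2 <- contigPlacements(sc2$alignments, sc2$digests, sc2$maps)
  adj2 <- mapGuidedAdjacency(pl2$placements, minDetectableOverlap = 200000)
  expect_equal(adj2$action, "merge")
  # contigs on different maps yield no adjacency
  one <- pl$placements[1, ]; one$map_id <- "other"
  adj3 <- mapGuidedAdjacency(rbind(pl$placements[2, ], one))
  expect_equal(nrow(adj3), 0)
})

test_that("AGP derived from provenance reconstructs the scaffold sequence", {
  sc <- scaffoldScenario(60, c(0, 295000), c(305000, 600000))
  hb <- hybridScaffold(sc$contigs, sc$maps, sc$alignments, sc$digests)
  rebuilt <- sequenceFromAGP(hb$agp, sc$contigs)
  expect_equal(seqString(rebuilt[[1]]), seqString(hb$scaffolds[[1]]))
})
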