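# Conflict detection, junction support scoring and contig cutting.

# Build a chimera scenario: truth sequences for two unrelated loci, an
# optical map per locus, and a chimeric contig joining them.
chimeraScenario <- function(seed = 21, lociBp = 2e5) {
  set.seed(seed)
  t1 <- randomDNA(2 * lociBp); t2 <- randomDNA(2 * lociBp)
  m1 <- insilicoDigest(seqRecord("m1", t1)); m1@source <- "optical"
  m2 <- insilicoDigest(seqRecord("m2", t2)); m2@source <- "optical"
  # join the first half of locus 1 to the second half of locus 2, so both
  # the contig and the map continue well past the junction
  chim <- seqRecord("chim", paste0(substr(t1, 1, lociBp),
                                   substr(t2, lociBp + 1, 2 * lociBp)))
  dg <- insilicoDigest(chim)
  list(maps = list(m1 = m1, m2 = m2), contig = chim,
       digests = list(chim = dg), junction = lociBp)
}

test_that("a chimeric junction is detected near the planted join", {
  sc <- chimeraScenario()
  p <- alignParams()
  al <- c(alignLabelMaps(sc$digests$chim, sc$maps$m1, p),
          alignLabelMaps(sc$digests$chim, sc$maps$m2, p))
  cf <- detectConflicts(al, sc$digests, sc$maps,
                        minOverhangLabels = 5, minOverhangBp = 50000)
  expect_gte(nrow(cf), 1)
  # every reported junction sits within 2 label intervals of the join
  lab <- mapLabels(sc$digests$chim)
  for (j in cf$junction_bp) {
    lo <- min(j, sc$junction); hi <- max(j, sc$junction)
    expect_lte(sum(lab > lo & lab < hi), 2)
  }
})

test_that("contained alignments and short overhangs yield no conflict", {
  set.seed(22)
  t1 <- randomDNA(3e5)
  mp <- insilicoDigest(seqRecord("m", t1)); mp@source <- "optical"
  inner <- seqRecord("in", substr(t1, 100001, 200000))
  dg <- list(`in` = insilicoDigest(inner))
  al <- alignLabelMaps(dg$`in`, mp, alignParams())
  cf <- detectConflicts(al, dg, list(m = mp))
  expect_equal(nrow(cf), 0)
  # a 10 kb foreign tail is below the 50 kb overhang floor
  tail10 <- seqRecord("t10", paste0(substr(t1, 1, 150000), randomDNA(10000)))
  dg2 <- list(t10 = insilicoDigest(tail10))
  al2 <- alignLabelMaps(dg2$t10, mp, alignParams())
  cf2 <- detectConflicts(al2, dg2, list(m = mp))
  expect_equal(nrow(cf2), 0)
})

test_that("junction support is the contiguous fraction of spanning maps", {
  dg <- list(c1 = labelMap("c1", 110000, seq(10000, 100000, by = 10000)))
  mkAln <- function(ref, qIdx, rIdx) {
    new("MapAlignment", queryId = "c1", refId = ref, orientation = "+",
        pairs = cbind(query = as.integer(qIdx), ref = as.integer(rIdx)),
        score = 50, confidence = 20,
        querySpan = range(dg$c1@labels[qIdx]), refSpan = c(1, 2))
  }
  conflict <- data.frame(contig_id = "c1", junction_bp = 50000,
                         junction_label_idx = 5L, stringsAsFactors = FALSE)
  spanning <- lapply(1:5, function(i) mkAln(paste0("m", i), 1:10, 1:10))
  expect_equal(scoreJunctionSupport(conflict, spanning, dg), 100)
  broken <- lapply(1:4, function(i) mkAln(paste0("b", i), c(1:4, 6:10),
                                          c(1:4, 6:10)))
  expect_equal(scoreJunctionSupport(conflict, broken, dg), 0)
  expect_equal(scoreJunctionSupport(conflict, c(spanning[1], broken[1:3]), dg), 25)
  expect_equal(scoreJunctionSupport(conflict, list(), dg), 0)
})

test_that("cutting splits at junctions, keeps provenance and conserves bases", {
  set.seed(23)
  ctg <- seqRecord("c1", randomDNA(400000))
  cf <- data.frame(contig_id = "c1", junction_bp = 150000, side = "end",
                   support_score = 10, stringsAsFactors = FALSE)
  cut <- cutContigs(list(c1 = ctg), cf)
  expect_equal(vapply(cut$contigs, seqLen, 0), c(c1.1 = 150000, c1.2 = 250000))
  expect_equal(provenance(cut$contigs$c1.1)$src_end, 150000)
  expect_equal(provenance(cut$contigs$c1.2)$src_start, 150000)
  expect_equal(paste0(seqString(cut$contigs$c1.1), seqString(cut$contigs$c1.2)),
               seqString(ctg))
  # two junctions -> three fragments in coordinate order
  cf2 <- data.frame(contig_id = "c1", junction_bp = c(250000, 100000),
                    side = c("end", "end"), support_score = c(0, 0),
                    stringsAsFactors = FALSE)
  cut2 <- cutContigs(list(c1 = ctg), cf2)
  expect_equal(unname(vapply(cut2$contigs, seqLen, 0)), c(1e5, 15e4, 15e4))
  # supported junctions are not cut
  cf3 <- data.frame(contig_id = "c1", junction_bp = 150000, side = "end",
                    support_score = 80, stringsAsFactors = FALSE)
  expect_length(cutContigs(list(c1 = ctg), cf3)$contigs, 1)
  # short fragments are kept but flagged
  cf4 <- data.frame(contig_id = "c1", junction_bp = 5000, side = "end",
                    support_score = 0, stringsAsFactors = FALSE)
  led <- cutContigs(list(c1 = ctg), cf4)$ledger
  expect_true(led$flagged_short[led$fragment_id == "c1.1"])
  expect_error(cutContigs(list(c1 = ctg),
                          data.frame(contig_id = "c1", junction_bp = 5e5,
                                     side = "end", support_score = 0)),
               "outside")
})

test_that("no conflict is called at a true locus covered by concordant maps", {
  sc <- chimeraScenario(seed = 24)
  # three honest (non-chimeric) contigs over locus 1
  p <- alignParams()
  honest <- seqRecord("h", substr(seqString(sc$contig), 1, sc$junction))
  dg <- list(h = insilicoDigest(honest))
  al <- alignLabelMaps(dg$h, sc$maps$m1, p)
  cf <- detectConflicts(al, dg, sc$maps["m1"])
  expect_equal(nrow(cf), 0)
})
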