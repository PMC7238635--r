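# Repeat monomer scanning, array calling, composition, mappability,
# coverage and enrichment ratios.

test_that("monomer scanning counts tandem units and tolerates divergence", {
  set.seed(71)
  mono <- randomDNA(156)
  g <- list(seqRecord("c1", paste0(randomDNA(20000), strrep(mono, 10),
                                   randomDNA(20000))))
  hits <- scanRepeatMonomers(g, mono, family = "CentC")
  expect_equal(length(hits), 1)
  expect_equal(S4Vectors::mcols(hits)$units, 10)
  expect_equal(GenomicRanges::width(hits), 1560, tolerance = 0.01)
  # 20 percent per-base divergence is still detected at the 0.7 floor
  div <- paste(vapply(1:10, function(i) mutateSequence(mono, 0.2), ""),
               collapse = "")
  g2 <- list(seqRecord("c2", paste0(randomDNA(20000), div, randomDNA(20000))))
  hits2 <- scanRepeatMonomers(g2, mono, family = "CentC")
  expect_equal(sum(S4Vectors::mcols(hits2)$units), 10, tolerance = 0.11)
  # uniform random sequence has no hits
  g3 <- list(seqRecord("c3", randomDNA(100000)))
  expect_length(scanRepeatMonomers(g3, mono, family = "CentC"), 0)
  # minus-strand copies are found too
  g4 <- list(seqRecord("c4", paste0(randomDNA(20000), strrep(revComp(mono), 8),
                                    randomDNA(20000))))
  expect_equal(sum(S4Vectors::mcols(scanRepeatMonomers(g4, mono))$units), 8)
  expect_error(scanRepeatMonomers(g, randomDNA(30)), "50")
})

# Construct hit blocks directly (units scaled to widths).
mkHits <- function(chrom, starts, widths, family = "knob180") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = starts,
                                                       width = widths))
  S4Vectors::mcols(gr)$family <- family
  S4Vectors::mcols(gr)$units <- pmax(1L, round(widths / 180))
  gr
}

test_that("knob and CentC array rules are threshold-sharp", {
  # span exactly 500 kb (blocks within the spacing rule) passes
  starts <- seq(1, by = 95000, length.out = 6)
  pass <- mkHits("c", starts, rep(25000, 6))
  expect_length(callRepeatArrays(pass, "knob"), 1)
  # one bp less span fails the knob class
  below <- mkHits("c", starts, c(rep(25000, 5), 24999))
  expect_length(callRepeatArrays(below, "knob"), 0)
  # density exactly 10 percent passes, one bp of repeat less fails
  dOk <- mkHits("c", starts, c(rep(5000, 5), 25000))     # 50 kb / 500 kb
  expect_length(callRepeatArrays(dOk, "knob"), 1)
  dNo <- mkHits("c", starts, c(rep(5000, 4), 4999, 25000))
  expect_length(callRepeatArrays(dNo, "knob"), 0)
  # 600 kb at 15 percent is a knob
  knob <- mkHits("c", seq(1, 600000, by = 100000), rep(15000, 6))
  expect_length(callRepeatArrays(knob, "knob"), 1)
  # 400 kb at 40 percent is not a knob but is a valid CentC-class span
  mid <- mkHits("c", seq(1, 400000, by = 100000), rep(40000, 4))
  expect_length(callRepeatArrays(mid, "knob"), 0)
  midc <- mid; S4Vectors::mcols(midc)$family <- "CentC"
  expect_length(callRepeatArrays(midc, "centc"), 1)
  # CentC span sharpness at 100 kb
  cOk <- mkHits("c", c(1, 90001), c(10000, 10000), family = "CentC")
  expect_length(callRepeatArrays(cOk, "centc"), 1)
  cNo <- mkHits("c", c(1, 90001), c(10000, 9999), family = "CentC")
  expect_length(callRepeatArrays(cNo, "centc"), 0)
})

test_that("spacing above 100 kb splits clusters", {
  near <- mkHits("c", c(1, 400001), c(300000, 300000))   # 100 kb gap: one cluster
  expect_length(callRepeatArrays(near, "knob"), 1)
  far <- mkHits("c", c(1, 450001), c(300000, 300000))    # 150 kb gap: two, each < 500 kb
  expect_length(callRepeatArrays(far, "knob"), 0)
})

test_that("subtelomeric knob clusters are excluded", {
  sub <- mkHits("c", 1, 600000)                           # at the chromosome start
  expect_length(callRepeatArrays(sub, "knob"), 1)         # no windows: kept
  expect_length(callRepeatArrays(sub, "knob", seqLengths = c(c = 5e6)), 0)
  interior <- mkHits("c", 2000001, 600000)
  expect_length(callRepeatArrays(interior, "knob", seqLengths = c(c = 5e6)), 1)
})

test_that("repeat composition flattens overlapping annotations per family", {
  arrays <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 100000))
  te <- GenomicRanges::GRanges("c", IRanges::IRanges(c(1, 1), c(50000, 50000)))
  S4Vectors::mcols(te)$family <- "Cinful-Zeon-like"
  comp <- repeatComposition(arrays, te)
  expect_equal(comp$fraction, 0.5)  # two identical nested TEs count once
  one <- repeatComposition(arrays, te[1])
  expect_equal(one$fraction, 0.5)
})

test_that("mappability classes follow the depth bounds and 1 kb merging", {
  d <- rep(30L, 10000)
  mc <- mappabilityClasses(list(s = d))
  expect_length(mc$non_unique, 0)
  expect_equal(sum(GenomicRanges::width(mc$unique)), 10000)
  d1 <- rep(1L, 5000)
  mc1 <- mappabilityClasses(list(s = d1))
  expect_equal(sum(GenomicRanges::width(mc1$non_unique)), 5000)
  # boundary: depth 2 is non-unique, 3 unique; 101 non-unique, 100 unique
  db <- c(rep(2L, 100), rep(3L, 100), rep(101L, 100), rep(100L, 2000))
  mcb <- mappabilityClasses(list(s = db), mergeGap = 0)
  nu <- mcb$non_unique
  expect_equal(GenomicRanges::start(nu), c(1, 201))
  expect_equal(GenomicRanges::end(nu), c(100, 300))
  # two non-unique runs 800 bp apart merge into one island
  dm <- rep(50L, 5000); dm[1:100] <- 1L; dm[901:1000] <- 1L
  mcm <- mappabilityClasses(list(s = dm))
  expect_equal(length(mcm$non_unique), 1)
  expect_equal(GenomicRanges::width(mcm$non_unique), 1000)
  # 1001 bp apart stays two islands
  dm2 <- rep(50L, 5000); dm2[1:100] <- 1L; dm2[1102:1200] <- 1L
  expect_equal(length(mappabilityClasses(list(s = dm2))$non_unique), 2)
})

test_that("low-coverage regions are maximal runs below the cutoff", {
  expect_equal(sum(GenomicRanges::width(
    lowCoverageRegions(list(s = rep(0L, 500)), 3))), 500)
  d <- rep(10L, 100); d[50] <- 2L
  lc <- lowCoverageRegions(list(s = d), 3)
  expect_equal(GenomicRanges::start(lc), 50)
  expect_equal(GenomicRanges::width(lc), 1)
  # monotonicity: the min-2 set is nested within the min-3 set
  set.seed(72)
  dr <- sample(0:5, 2000, replace = TRUE)
  l2 <- lowCoverageRegions(list(s = dr), 2)
  l3 <- lowCoverageRegions(list(s = dr), 3)
  ov <- GenomicRanges::intersect(l2, l3)
  expect_equal(sum(GenomicRanges::width(ov)), sum(GenomicRanges::width(l2)))
})

test_that("RPKM ratios are depth-normalization exact", {
  set.seed(73)
  feat <- GenomicRanges::GRanges("s", IRanges::IRanges(c(1, 50001), c(20000, 80000)))
  pos <- sort(sample.int(100000, 5000, replace = TRUE))
  r1 <- rpkmEnrichment(list(s = pos), list(s = pos), feat)
  expect_equal(S4Vectors::mcols(r1)$ratio, c(1, 1))
  r2 <- rpkmEnrichment(list(s = rep(pos, 2)), list(s = pos), feat)
  expect_equal(S4Vectors::mcols(r2)$ratio, c(1, 1))   # doubling depth: unchanged
  # planted 5x enrichment in feature 1
  chip <- sort(c(sample(1:20000, 5000, replace = TRUE),
                 sample(20001:100000, 8000, replace = TRUE)))
  input <- sort(c(sample(1:20000, 1000, replace = TRUE),
                  sample(20001:100000, 8000, replace = TRUE)))
  r3 <- rpkmEnrichment(list(s = chip), list(s = input), feat)
  expect_equal(S4Vectors::mcols(r3)$ratio[1] / S4Vectors::mcols(r3)$ratio[2],
               5, tolerance = 0.15)
  # zero input reads: absent, never infinite
  far <- GenomicRanges::GRanges("s", IRanges::IRanges(99990, 99999))
  r4 <- rpkmEnrichment(list(s = 1:100), list(s = 1:100 * 0 + 1), far)
  expect_true(is.na(S4Vectors::mcols(r4)$ratio))
})
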