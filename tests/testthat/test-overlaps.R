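# K-mer anchored overlap detection and unitig merging.

test_that("planted exact overlaps are classified and measured", {
  set.seed(41)
  g <- randomDNA(100000)
  a <- seqRecord("a", substr(g, 1, 60000))
  b <- seqRecord("b", substr(g, 30001, 100000))   # 30 kb suffix/prefix overlap
  ov <- findSequenceOverlaps(list(a = a), list(b = b))
  expect_equal(nrow(ov), 1)
  expect_equal(ov$kind, "dovetail")
  expect_equal(ov$orientation, "+")
  expect_gte(ov$identity, 0.99)
  expect_equal(ov$a_start, 30000, tolerance = 100)
  # containment
  inner <- seqRecord("i", substr(g, 20001, 50000))
  ovc <- findSequenceOverlaps(list(a = a), list(i = inner))
  expect_equal(ovc$kind, "containment")
  # below the overlap floor nothing is emitted
  short <- seqRecord("s", substr(g, 52001, 100000))  # 8 kb overlap with a
  ovs <- findSequenceOverlaps(list(a = a), list(s = short), minOverlap = 25000)
  expect_equal(nrow(ovs), 0)
})

test_that("overlaps are symmetric and orientation-aware", {
  set.seed(42)
  g <- randomDNA(80000)
  a <- seqRecord("a", substr(g, 1, 50000))
  b <- seqRecord("b", revComp(substr(g, 30001, 80000)))
  ov <- findSequenceOverlaps(list(a = a), list(b = b))
  expect_equal(ov$orientation, "-")
  expect_equal(ov$kind, "dovetail")
  sym <- findSequenceOverlaps(list(b = b), list(a = a))
  expect_equal(sym$orientation, "-")
  expect_equal(sym$a_start, ov$b_start, tolerance = 200)
  expect_equal(sym$b_start, ov$a_start, tolerance = 200)
})

test_that("identity estimation inverts the k-mer survival model", {
  set.seed(43)
  g <- randomDNA(100000)
  a <- seqRecord("a", substr(g, 1, 60000))
  noisy <- seqRecord("n", mutateSequence(substr(g, 30001, 100000), 0.01))
  ov <- findSequenceOverlaps(list(a = a), list(n = noisy), minIdentity = 0.9)
  expect_equal(nrow(ov), 1)
  expect_equal(ov$identity, 0.99, tolerance = 0.008)
  # 20 percent divergence is rejected by the identity floor
  far <- seqRecord("f", mutateSequence(substr(g, 30001, 100000), 0.2))
  expect_equal(nrow(findSequenceOverlaps(list(a = a), list(f = far))), 0)
})

test_that("dovetail chains merge into unitigs that restore the source", {
  set.seed(44)
  g <- randomDNA(150000)
  a <- seqRecord("a", substr(g, 1, 100000))
  b <- seqRecord("b", substr(g, 70001, 150000))
  contigs <- list(a = a, b = b)
  ov <- findSequenceOverlaps(contigs, contigs)
  mg <- mergeOverlapping(contigs, ov, primaryIds = "a")
  expect_equal(length(mg$records), 1)
  expect_equal(seqLen(mg$records[[1]]), 150000)
  expect_equal(seqString(mg$records[[1]]), g)  # exact overlap: exact merge
  # three-contig chain
  g2 <- randomDNA(250000)
  chain <- list(x = seqRecord("x", substr(g2, 1, 100000)),
                y = seqRecord("y", substr(g2, 80001, 180000)),
                z = seqRecord("z", substr(g2, 160001, 250000)))
  ovc <- findSequenceOverlaps(chain, chain)
  mgc <- mergeOverlapping(chain, ovc, primaryIds = c("x", "z"))
  expect_equal(length(mgc$records), 1)
  expect_equal(seqString(mgc$records[[1]]), g2)
})

test_that("merging never changes bases outside overlap spans", {
  set.seed(45)
  g <- randomDNA(120000)
  a <- seqRecord("a", substr(g, 1, 80000))
  b <- seqRecord("b", mutateSequence(substr(g, 60001, 120000), 0.01))
  contigs <- list(a = a, b = b)
  ov <- findSequenceOverlaps(contigs, contigs)
  mg <- mergeOverlapping(contigs, ov, primaryIds = "a")
  u <- seqString(mg$records[[1]])
  expect_equal(substr(u, 1, 60000), substr(g, 1, 60000))        # a's exclusive part
  expect_equal(substr(u, seqLen(mg$records[[1]]) - 30000 + 1, seqLen(mg$records[[1]])),
               substr(seqString(b), seqLen(b) - 30000 + 1, seqLen(b)))
})

test_that("branching ends merge nothing and order does not matter", {
  set.seed(46)
  g <- randomDNA(100000)
  a <- seqRecord("a", substr(g, 1, 60000))
  b <- seqRecord("b", substr(g, 40001, 100000))
  # c shares a's 3' end too (same overlap): a's right end is ambiguous
  cc <- seqRecord("c", paste0(substr(g, 40001, 70000), randomDNA(40000)))
  contigs <- list(a = a, b = b, c = cc)
  ov <- findSequenceOverlaps(contigs, contigs)
  mg <- mergeOverlapping(contigs, ov)
  expect_gte(length(mg$branches), 1)
  expect_equal(sort(names(mg$records)), c("a", "b", "c"))  # nothing merged
  # unitig construction is invariant to contig order
  c2 <- list(b = b, a = a)
  ov2 <- findSequenceOverlaps(c2, c2)
  mg2 <- mergeOverlapping(c2, ov2, primaryIds = "a")
  ovf <- findSequenceOverlaps(list(a = a, b = b), list(a = a, b = b))
  mgf <- mergeOverlapping(list(a = a, b = b), ovf, primaryIds = "a")
  expect_equal(seqString(mg2$records[[1]]), seqString(mgf$records[[1]]))
})

test_that("contained contigs are dropped with tolerance for short tails", {
  set.seed(47)
  g <- randomDNA(100000)
  a <- seqRecord("a", g)
  tailRec <- seqRecord("t", paste0(substr(g, 20001, 60000), randomDNA(1500)))
  contigs <- list(a = a, t = tailRec)
  ov <- findSequenceOverlaps(contigs, contigs)
  dc <- dropContained(contigs, ov, maxTail = 3000)
  expect_equal(dc$dropped, "t")
  dc2 <- dropContained(contigs, ov, maxTail = 500)
  expect_length(dc2$dropped, 0)
})
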