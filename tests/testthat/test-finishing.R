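# Gap filling, telomere extension, marker filtering, ordering and
# pseudomolecule emission.

test_that("a spanning read closes a gap; absent or oversized reads do not", {
  set.seed(61)
  g <- randomDNA(60000)
  scf <- list(s1 = seqRecord("s1", paste0(substr(g, 1, 30000), strrep("N", 200),
                                          substr(g, 30201, 60000))))
  reads <- vapply(1:12, function(i) {
    st <- sample(20000:28000, 1)
    mutateSequence(substr(g, st, min(st + sample(8000:12000, 1), 60000)), 0.02, 0.005)
  }, "")
  names(reads) <- paste0("r", 1:12)
  fg <- fillGaps(scf, reads)
  expect_equal(fg$report$action[1], "closed")
  expect_equal(nrow(findNGaps(fg$scaffolds$s1, 0)), 0)
  expect_equal(seqLen(fg$scaffolds$s1), 60000, tolerance = 0.01)
  # the patched interior matches truth within read error (alignment-based:
  # indels in the read shift coordinates)
  mid <- substr(seqString(fg$scaffolds$s1), 29001, 31000)
  pa <- Biostrings::pairwiseAlignment(mid, substr(g, 29001, 31000))
  expect_gte(Biostrings::pid(pa), 93)
  # no reads touching the gap: unchanged through all iterations
  far <- reads; names(far) <- paste0("f", 1:12)
  fg2 <- fillGaps(list(s2 = seqRecord("s2", paste0(randomDNA(20000), strrep("N", 100),
                                                   randomDNA(20000)))), far)
  expect_true(all(fg2$report$action == "none"))
  expect_equal(max(fg2$report$iteration), 3)    # iteration count respected
})

test_that("reads implying a wildly different span are rejected", {
  set.seed(62)
  g <- randomDNA(80000)
  # true content between flanks is 30 kb but the gap is annotated as 3 kb
  scf <- list(s1 = seqRecord("s1", paste0(substr(g, 1, 20000), strrep("N", 3000),
                                          substr(g, 50001, 80000))))
  reads <- vapply(1:8, function(i) {
    st <- sample(12000:16000, 1)
    substr(g, st, st + 45000)
  }, "")
  names(reads) <- paste0("r", 1:8)
  fg <- fillGaps(scf, reads)
  expect_false(any(fg$report$action == "closed"))
})

test_that("gap filling never increases total gap length", {
  set.seed(63)
  g <- randomDNA(50000)
  scf <- list(s1 = seqRecord("s1", paste0(substr(g, 1, 20000), strrep("N", 5000),
                                          substr(g, 26001, 50000))))
  reads <- vapply(1:10, function(i) {
    st <- sample(10000:19000, 1)
    substr(g, st, st + 15000)
  }, "")
  names(reads) <- paste0("r", 1:10)
  before <- sum(findNGaps(scf$s1, 0)$end - findNGaps(scf$s1, 0)$start)
  fg <- fillGaps(scf, reads)
  gAfter <- findNGaps(fg$scaffolds$s1, 0)
  expect_lte(sum(gAfter$end - gAfter$start), before)
})

test_that("telomere extension takes the longest uniquely anchored tract read", {
  set.seed(64)
  core <- randomDNA(40000)
  chromEnd <- paste0(core, tandemFill("TTTAGGG", 3000))   # truth 3' end
  scf <- list(s1 = seqRecord("s1", substr(chromEnd, 1, 40500)))
  mkRead <- function(from, tract) paste0(substr(core, from, 40000),
                                         tandemFill("TTTAGGG", tract))
  reads <- c(r1 = mkRead(32000, 1200), r2 = mkRead(25000, 2500),
             r3 = mkRead(33000, 900))
  tl <- extendTelomeres(scf, reads, minTract = 1000)
  expect_equal(nrow(tl$report), 1)
  expect_equal(tl$report$read_id, "r2")        # longest qualifying read
  newSeq <- seqString(tl$scaffolds$s1)
  expect_gte(nchar(newSeq), 40000 + 2400)
  # interior untouched
  expect_equal(substr(newSeq, 1, 40000), substr(chromEnd, 1, 40000))
  # a 0.9 kb tract alone is not a candidate
  tl2 <- extendTelomeres(scf, reads["r3"], minTract = 1000)
  expect_equal(nrow(tl2$report), 0)
})

test_that("reads anchoring at two loci are excluded as non-unique", {
  set.seed(65)
  anchor <- randomDNA(12000)
  # the same terminal anchor on two scaffolds makes the read ambiguous
  scf <- list(s1 = seqRecord("s1", paste0(randomDNA(30000), anchor)),
              s2 = seqRecord("s2", paste0(randomDNA(25000), anchor)))
  reads <- c(rt = paste0(anchor, tandemFill("TTTAGGG", 1500)))
  tl <- extendTelomeres(scf, reads, minTract = 1000)
  expect_equal(nrow(tl$report), 0)
  # with a single locus the same read extends
  tl2 <- extendTelomeres(scf["s1"], reads, minTract = 1000)
  expect_equal(nrow(tl2$report), 1)
})

test_that("marker filters follow the strict >20, mapq>30 and cap-100 rules", {
  mk <- function(n, sid, mapq = 60, unique = TRUE) {
    data.frame(marker_id = paste0(sid, "_", seq_len(n)), scaffold_id = sid,
               physical_bp = sort(sample.int(1e6, n)), linkage_group = "lg1",
               genetic_pos = seq_len(n), mapq = mapq, unique = unique,
               stringsAsFactors = FALSE)
  }
  set.seed(66)
  m <- rbind(mk(20, "s20"), mk(21, "s21"), mk(250, "s250"))
  f <- filterMarkers(m)
  expect_false("s20" %in% f$scaffold_id)        # exactly 20 is excluded
  expect_equal(sum(f$scaffold_id == "s21"), 21)
  expect_equal(sum(f$scaffold_id == "s250"), 100)
  s250 <- m[m$scaffold_id == "s250", ]
  kept <- f[f$scaffold_id == "s250", ]
  expect_true(min(s250$physical_bp) %in% kept$physical_bp)  # ends survive
  expect_true(max(s250$physical_bp) %in% kept$physical_bp)
  # mapq 30 dropped, 31 kept; non-unique dropped
  m2 <- rbind(mk(30, "q30", mapq = 30), mk(30, "q31", mapq = 31),
              mk(30, "nu", unique = FALSE))
  f2 <- filterMarkers(m2)
  expect_equal(unique(f2$scaffold_id), "q31")
})

test_that("ordering recovers monotone marker order and orientation", {
  set.seed(67)
  mkScf <- function(sid, gstart, flip = FALSE) {
    n <- 10
    phys <- sort(sample.int(2e5, n))
    gen <- gstart + (if (flip) rev(phys) else phys) / 2e5 * 10
    data.frame(marker_id = paste0(sid, seq_len(n)), scaffold_id = sid,
               physical_bp = phys, linkage_group = "lg1", genetic_pos = gen,
               mapq = 60L, unique = TRUE, stringsAsFactors = FALSE)
  }
  m <- rbind(mkScf("sA", 0), mkScf("sB", 10, flip = TRUE), mkScf("sC", 20))
  oo <- orderOrient(m)
  od <- oo$orders$lg1
  expect_equal(od$scaffold_id, c("sA", "sB", "sC"))
  expect_equal(od$orientation, c("+", "-", "+"))
  expect_equal(oo$method[["lg1"]], "exhaustive")
  # single scaffolds: ascending -> "+", descending -> "-"
  up <- orderOrient(mkScf("solo", 0))
  expect_equal(up$orders$lg1$orientation, "+")
  dn <- orderOrient(mkScf("solo", 0, flip = TRUE))
  expect_equal(dn$orders$lg1$orientation, "-")
  expect_error(orderOrient(m[0, ]), "empty")
})

test_that("pseudomolecule emission concatenates with 100 N and round-trips", {
  set.seed(68)
  scf <- list(s1 = seqRecord("s1", randomDNA(10000)),
              s2 = seqRecord("s2", randomDNA(5000)))
  ord <- list(lg1 = data.frame(scaffold_id = c("s1", "s2"),
                               orientation = c("+", "-"),
                               stringsAsFactors = FALSE))
  pm <- emitPseudomolecules(ord, scf)
  expect_equal(seqLen(pm$records$lg1), 15100)
  expect_equal(pm$agp$gap_type[pm$agp$component_type == "N"], "scaffold")
  rebuilt <- sequenceFromAGP(pm$agp, scf)
  expect_equal(seqString(rebuilt$lg1), seqString(pm$records$lg1))
  expect_error(emitPseudomolecules(list(), scf), "empty")
})
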