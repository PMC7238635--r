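# Readers/writers: round-trip identity, coordinate conventions, and
# precondition errors.

test_that("FASTA round-trips, folds case and rejects duplicates", {
  tmp <- tempfile(fileext = ".fa")
  recs <- list(a = seqRecord("a", "ACGT"), b = seqRecord("b", "acgtn"))
  expect_equal(seqString(recs$b), "ACGTN")      # case folded at construction
  writeSequences(recs, tmp)
  back <- readSequences(tmp)
  expect_equal(vapply(back, seqString, ""), c(a = "ACGT", b = "ACGTN"))
  writeSequences(back, tmp)                     # second round trip
  expect_equal(vapply(readSequences(tmp), seqString, ""),
               c(a = "ACGT", b = "ACGTN"))
  writeLines(c(">c1", "ACGT", ">c1", "GGGG"), tmp)
  expect_error(readSequences(tmp), "duplicate")
  writeLines(c(">e1", "", ">e2", "ACGT"), tmp)
  expect_error(readSequences(tmp), "empty")
  expect_error(seqRecord("x", "ACGRT"), "non-ACGTN")
  expect_equal(seqString(seqRecord("x", "ACGRT", coerceAmbiguous = TRUE)),
               "ACGNT")
})

test_that("label maps round-trip within float tolerance and check monotonicity", {
  tmp <- tempfile(fileext = ".cmap")
  maps <- list(m1 = labelMap("m1", 3000, c(100, 2500), source = "optical"),
               m2 = labelMap("m2", 5000, numeric(0), source = "optical"))
  writeLabelMaps(maps, tmp)
  back <- readLabelMaps(tmp)
  expect_equal(mapLabels(back$m1), c(100, 2500), tolerance = 1e-6)
  expect_equal(mapLength(back$m2), 5000)
  expect_length(mapLabels(back$m2), 0)          # zero labels is a valid map
  expect_error(labelMap("bad", 3000, c(200, 100)), "increasing")
})

test_that("AGP tiles objects, converts coordinates and round-trips", {
  agp <- data.frame(
    object = "s1", object_beg = c(1, 10001, 10101),
    object_end = c(10000, 10100, 15100), part_number = 1:3,
    component_type = c("W", "N", "W"),
    component_id = c("c1", NA, "c2"), component_beg = c(1, NA, 1),
    component_end = c(10000, NA, 5000), orientation = c("+", NA, "+"),
    gap_length = c(NA, 100, NA), gap_type = c(NA, "estimated", NA),
    stringsAsFactors = FALSE)
  expect_equal(max(agp$object_end), 15100)      # 10 kb + 100 N + 5 kb
  tmp <- tempfile(fileext = ".agp")
  writeAGP(agp, tmp)
  back <- readAGP(tmp)
  expect_equal(nrow(back), 3)
  expect_equal(back$object_end, agp$object_end)
  bad <- agp; bad$object_beg[3] <- 10102        # part 3 starts at wrong offset
  expect_error(writeAGP(bad, tmp), "expected")
  one <- agp[1, ]
  writeAGP(one, tmp)                            # single-component object
  expect_equal(readAGP(tmp)$object_end, 10000)
})

test_that("BED round-trips 0-based half-open and sorts output", {
  gr <- GenomicRanges::GRanges(c("c2", "c1"),
                               IRanges::IRanges(start = c(51, 101), end = c(150, 200)))
  S4Vectors::mcols(gr)$label <- c("x", "y")
  S4Vectors::mcols(gr)$score <- c(1, 2)
  tmp <- tempfile(fileext = ".bed")
  writeBed(gr, tmp)
  d <- read.delim(tmp, header = FALSE)
  expect_equal(d[[1]], c("c1", "c2"))           # sorted by seq then start
  expect_equal(d[[2]], c(100, 50))              # 0-based starts
  back <- readBed(tmp)
  expect_equal(GenomicRanges::start(back), c(101, 51))
  writeLines("c1\t100\t100\tz", tmp)
  expect_error(readBed(tmp), "end <= start")
})

test_that("marker and alignment tables round-trip", {
  mk <- data.frame(marker_id = "m1", scaffold_id = "s1", physical_bp = 100L,
                   linkage_group = "lg1", genetic_pos = 1.5, mapq = 60L,
                   unique = TRUE, stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".csv")
  writeMarkers(mk, tmp)
  expect_equal(readMarkers(tmp)$unique, TRUE)
  al <- new("MapAlignment", queryId = "q", refId = "r", orientation = "-",
            pairs = cbind(query = c(5L, 3L, 1L), ref = c(1L, 2L, 3L)),
            score = 12.5, confidence = 5.4, querySpan = c(100, 900),
            refSpan = c(50, 800))
  tmp2 <- tempfile(fileext = ".tsv")
  writeAlignments(list(al), tmp2)
  back <- readAlignments(tmp2)[[1]]
  expect_equal(alignmentPairs(back), alignmentPairs(al))
  expect_equal(back@orientation, "-")
})

test_that("readers and writers are bijections on random valid records", {
  set.seed(11)
  for (i in 1:5) {
    recs <- lapply(1:3, function(j)
      seqRecord(sprintf("r%d", j), randomDNA(sample(50:500, 1))))
    names(recs) <- vapply(recs, seqId, "")
    tmp <- tempfile(fileext = ".fa")
    writeSequences(recs, tmp, wrap = sample(c(20, 60, 1000), 1))
    expect_equal(vapply(readSequences(tmp), seqString, ""),
                 vapply(recs, seqString, ""))
    mp <- randomLabelMap(sprintf("m%d", i), sample(3:30, 1))
    tmp2 <- tempfile(fileext = ".cmap")
    writeLabelMaps(list(mp), tmp2)
    expect_equal(mapLabels(readLabelMaps(tmp2)[[1]]), mapLabels(mp),
                 tolerance = 1e-6)
  }
})
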