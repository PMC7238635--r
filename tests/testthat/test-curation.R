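# Discrepancy calling between contigs and maps, and cross-assembly patching.

# Truth locus with an optical map; the primary contig carries a planted
# deletion (a collapsed segment), the donor is clean.
curationScenario <- function(seed = 31, delBp = 5000, at = 150000) {
  set.seed(seed)
  truth <- randomDNA(3e5)
  mp <- insilicoDigest(seqRecord("map", truth)); mp@source <- "optical"
  collapsed <- paste0(substr(truth, 1, at), substr(truth, at + delBp + 1, nchar(truth)))
  primary <- seqRecord("prim", collapsed)
  donor <- seqRecord("don", truth)
  list(truth = truth, maps = list(map = mp), primary = primary, donor = donor,
       digests = list(prim = insilicoDigest(primary), don = insilicoDigest(donor)))
}

test_that("a planted collapse is called as a deletion of the right size", {
  sc <- curationScenario()
  p <- alignParams()
  al <- alignLabelMaps(sc$digests$prim, sc$maps$map, p)[[1]]
  calls <- callDiscrepancies(al, sc$digests$prim, sc$maps$map, params = p)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "deletion")
  expect_equal(calls$size, 5000)          # noise-free maps: exact
  expect_gte(calls$confidence, 0.1)
})

test_that("perfect alignments and sub-threshold differences yield no call", {
  sc <- curationScenario(seed = 32, delBp = 800)
  p <- alignParams()
  alClean <- alignLabelMaps(sc$digests$don, sc$maps$map, p)[[1]]
  expect_equal(nrow(callDiscrepancies(alClean, sc$digests$don, sc$maps$map,
                                      params = p)), 0)
  al800 <- alignLabelMaps(sc$digests$prim, sc$maps$map, p)[[1]]
  expect_equal(nrow(callDiscrepancies(al800, sc$digests$prim, sc$maps$map,
                                      params = p)), 0)  # 800 bp < 1 kb rule
})

test_that("a concordant donor patch restores the sequence exactly", {
  sc <- curationScenario(seed = 33)
  p <- alignParams()
  alP <- alignLabelMaps(sc$digests$prim, sc$maps$map, p)[[1]]
  alD <- alignLabelMaps(sc$digests$don, sc$maps$map, p)
  call <- callDiscrepancies(alP, sc$digests$prim, sc$maps$map, params = p)
  call$zygosity <- "homozygous"
  res <- patchWithAlternate(sc$primary, call[1, ], list(don = sc$donor),
                            alD, sc$digests["don"], sc$maps, params = p)
  expect_true(res$patched)
  expect_equal(res$donor_id, "don")
  expect_equal(seqString(res$record), sc$truth)   # error-free: exact restore
  # idempotence: re-calling on the patched contig finds nothing
  dg2 <- insilicoDigest(res$record)
  al2 <- alignLabelMaps(dg2, sc$maps$map, p)[[1]]
  expect_equal(nrow(callDiscrepancies(al2, dg2, sc$maps$map, params = p)), 0)
  # provenance points into the donor across the patched window
  expect_true("don" %in% provenance(res$record)$source_id)
})

test_that("discrepant donors and heterozygous calls are never patched", {
  sc <- curationScenario(seed = 34)
  p <- alignParams()
  alP <- alignLabelMaps(sc$digests$prim, sc$maps$map, p)[[1]]
  call <- callDiscrepancies(alP, sc$digests$prim, sc$maps$map, params = p)[1, ]
  call$zygosity <- "homozygous"
  # donor with the same collapse is not concordant
  badDonor <- seqRecord("bad", seqString(sc$primary))
  bd <- list(bad = insilicoDigest(badDonor))
  alBad <- alignLabelMaps(bd$bad, sc$maps$map, p)
  res <- patchWithAlternate(sc$primary, call, list(bad = badDonor), alBad,
                            bd, sc$maps, params = p)
  expect_false(res$patched)
  expect_equal(res$note, "no concordant donor")
  expect_equal(seqString(res$record), seqString(sc$primary))
  het <- call; het$zygosity <- "heterozygous"
  alD <- alignLabelMaps(sc$digests$don, sc$maps$map, p)
  res2 <- patchWithAlternate(sc$primary, het, list(don = sc$donor), alD,
                             sc$digests["don"], sc$maps, params = p)
  expect_false(res2$patched)
  expect_equal(res2$note, "not homozygous")
})

test_that("zygosity adjudication needs two agreeing covering maps", {
  sc <- curationScenario(seed = 35)
  p <- alignParams()
  # second, identical map of the same locus
  m2 <- sc$maps$map; m2@id <- "map2"
  maps <- list(map = sc$maps$map, map2 = m2)
  al1 <- alignLabelMaps(sc$digests$prim, maps$map, p)[[1]]
  al2 <- alignLabelMaps(sc$digests$prim, maps$map2, p)[[1]]
  calls <- rbind(callDiscrepancies(al1, sc$digests$prim, maps$map, params = p),
                 callDiscrepancies(al2, sc$digests$prim, maps$map2, params = p))
  merged <- mergeDiscrepancies(calls, list(al1, al2), sc$digests["prim"])
  expect_equal(nrow(merged), 1)
  expect_equal(merged$zygosity, "homozygous")
  expect_equal(merged$n_maps_covering, 2)
  # with a single covering map the locus stays unknown
  m1only <- mergeDiscrepancies(
    callDiscrepancies(al1, sc$digests$prim, maps$map, params = p),
    list(al1), sc$digests["prim"])
  expect_equal(m1only$zygosity, "unknown")
})
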