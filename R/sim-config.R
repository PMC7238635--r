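# Simulation configuration: the study conditions for the synthetic
# genome/assembly/optical-map bundle.
#
# The default is a desk-scale analogue of a repeat-rich plant genome:
# 3 chromosomes x 5 Mb with array spans scaled down ~100x from their
# megabase-scale counterparts while preserving the threshold topology that
# drives the pipeline: chr1 and chr2 are solvable (no array exceeds the
# long-noisy break threshold), chr3 carries one knob array exceeding both
# break thresholds and the read lengths (designed unsolvable, and motif
# free so the optical map splits there too).  Two chimeric joins and one
# tandem-array collapse are planted in the accurate profile, and one
# heterozygous region (1 percent divergence plus a 20 kb indel) sits on
# chr2 where the accurate profile breaks.  The `scale` field multiplies
# every length-like quantity so that the whole topology shrinks coherently.

#' Simulation configuration
#'
#' @param seed integer seed propagated to every simulator component
#' @param scale multiplies all length-like defaults (1 = desk scale:
#'   3 x 5 Mb)
#' @param nChromosomes number of chromosomes
#' @param ... named overrides of any default field
#' @return list of class \code{SimConfig}
#' @export
simConfig <- function(seed = 1L, scale = 1, nChromosomes = 3L, ...) {
  s <- function(x) round(x * scale)
  arrays <- data.frame(
    chrom  = c("chr1", "chr1", "chr1", "chr2", "chr2", "chr3", "chr3"),
    family = c("knob180", "CentC", "rDNA-5S", "TR-1", "CentC", "knob180", "CentC"),
    start  = s(c(1.20e6, 2.45e6, 3.50e6, 1.00e6, 2.50e6, 1.50e6, 2.50e6)),
    span   = s(c(4.0e4, 6.0e4, 1.5e4, 2.0e4, 6.0e4, 1.5e5, 6.0e4)),
    divergence = c(0.10, 0.08, 0.03, 0.10, 0.08, 0.10, 0.08),
    teRate = c(0.10, 0.15, 0.00, 0.00, 0.15, 0.10, 0.15),
    stringsAsFactors = FALSE)
  arrays <- arrays[arrays$chrom %in% paste0("chr", seq_len(nChromosomes)), , drop = FALSE]
  cfg <- list(
    seed = as.integer(seed), scale = scale, nChromosomes = as.integer(nChromosomes),
    chromosomeLength = s(5e6),
    telomereLen = s(3000), telomereUnit = "TTTAGGG",
    subtelomere = list(offset = s(5e4), span = s(1e4), divergence = 0.05),
    arrays = arrays, teLen = s(3000),
    monomerLens = c(CentC = 156, knob180 = 180, `rDNA-5S` = 341, `rDNA-45S` = 9349),
    het = list(chrom = "chr2", start = s(3.6e6), end = s(3.7e6),
               divergence = 0.01, indelLen = s(2e4)),
    profiles = list(
      accurate = list(breakArraySpan = s(3e4), subRate = 0.001, indelRate = 0,
                      nRandomBreaks = 4L, breakAtHet = TRUE, tipTrim = s(2500),
                      arrayEdgeKeep = s(5000), readN50 = s(22300),
                      readSubRate = 0.005, readIndelRate = 0.001, useAltHap = FALSE),
      long = list(breakArraySpan = s(8e4), subRate = 0.01, indelRate = 0.001,
                  nRandomBreaks = 3L, breakAtHet = FALSE, tipTrim = s(2500),
                  arrayEdgeKeep = s(5000), readN50 = s(29311),
                  readSubRate = 0.02, readIndelRate = 0.005, useAltHap = TRUE)),
    chimeras = 2L,
    collapse = list(chrom = "chr2", arrayStart = s(1.00e6), fraction = 0.5),
    maps = list(replicates = 3L, sdCoeff = 2.0, missRate = 0.05,
                falsePer100kb = 0.5, splitUnlabeled = s(1e5),
                minMapLen = s(1.5e5), pad = s(1e4), altHapReplicate = 2L),
    digestion = list(motif = "CTTAAG", minLabelSpacing = 800L),
    reads = list(depthLong = 10, minReadLen = s(1000), sdlog = 0.55),
    chip = list(fold = 10, depth = 30, readLen = 150L),
    markers = list(perGroup = 120L, noiseSd = 1.0, fracNonUnique = 0.05,
                   fracLowMapq = 0.05, flank = 50L, cmLength = 100))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "SimConfig")
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Family monomer sequences: fixed references independent of the run seed.
# The TR-1 consensus is the published 358 bp monomer bundled in extdata;
# the others are fixed synthetic monomers kept free of the labeling motif
# so satellite arrays are unlabeled stretches on optical maps.
simMonomers <- function(config) {
  motif <- config$digestion$motif
  mons <- withSeed(8675309, {
    list(CentC = randomDNA(config$monomerLens[["CentC"]], exclude = motif),
         knob180 = randomDNA(config$monomerLens[["knob180"]], exclude = motif),
         `rDNA-5S` = randomDNA(config$monomerLens[["rDNA-5S"]], exclude = motif),
         `rDNA-45S` = randomDNA(config$monomerLens[["rDNA-45S"]], exclude = motif))
  })
  tr1 <- system.file("extdata", "TR1_consensus.fa", package = "gapless")
  mons[["TR-1"]] <- seqString(readSequences(tr1)[[1]])
  mons
}
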