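# gapless

Merging two independent long-read genome assemblies into gapless
chromosome-scale pseudomolecules, anchored on optical maps.

## The problem

Long-read assemblies of repeat-rich genomes fail in complementary ways.
An accurate-read assembly (the polished backbone) breaks inside long
tandem repeat arrays, collapses some of them, and occasionally joins two
unrelated loci across a shared repeat (a chimeric contig).  A
longer-read, noisier assembly walks through many of those arrays and
through heterozygous regions, but carries more sequence error.  Optical
maps — ordered patterns of fluorescent labels at the genomic positions of
a short motif (here CTTAAG, the direct-label enzyme recognition site) —
span megabases and are independent of base-level sequence, which makes
them the natural referee between the two assemblies.

`gapless` implements the reconciliation pipeline as reusable,
provenance-tracking operations:

1. **Conflict resolution** — contig digests are aligned to the maps by a
   banded local dynamic programme over label index pairs; an alignment
   terminating with substantial unaligned labels and base pairs on *both*
   the contig and the map marks a chimeric junction.  Junctions are
   scored by the fraction of spanning maps that align contiguously
   through them (0–100) and cut when support falls below 35.  The map is
   always trusted over the sequence.
2. **Error curation** — for each adjacent matched label pair, a contig
   span differing from the (rescaled) map span by more than 1 kb is an
   insertion/deletion call.  Calls confirmed homozygous by every covering
   map (at least two) are patched with the alternate assembly's segment,
   provided the donor itself is clean across the locus; boundaries snap
   to matched labels and then to an exact shared 20-mer.
3. **Overlap merging** — exact k-mer anchors chained on the dominant
   diagonal find dovetail/containment overlaps between the assemblies
   (identity estimated as the anchor survival fraction raised to 1/k);
   maximal unbranched dovetail paths merge into unitigs, keeping
   primary-assembly bases where both cover.
4. **Hybrid scaffolding** — contigs are ordered and oriented along the
   maps; positive inter-contig gaps become N runs of the map-estimated
   size (minimum 100 N); junctions whose placements overlap get exactly
   13 N (kind `overlap13N` in the AGP) and are then resolved by
   sequence-level merging where the flanks truly overlap.
5. **Finishing** — three iterations of long-read gap filling (reads
   anchored to both flanks by chained exact k-mers patch the gap when the
   implied span matches the estimate within a factor of two), telomere
   extension with the longest uniquely anchored read carrying a
   TTTAGGG/CCCTAAA tract of at least 1 kb, and pseudomolecule
   construction: markers filtered (uniquely mapped, mapq > 30, more than
   20 per scaffold, capped at 100 evenly spaced), scaffolds ordered and
   oriented per linkage group by maximizing the weighted absolute
   Spearman rank correlation between genetic and physical order
   (exhaustively for up to 8 scaffolds), and concatenated with 100 N
   inter-scaffold gaps into an AGP-documented FASTA.

Around the pipeline sit the repeat/centromere analyses: satellite
monomer scanning (seed-and-extend), rule-based array calling (knobs:
clusters ≥ 500 kb at ≥ 10 % repeat density with ≤ 100 kb spacing,
excluding subtelomeric windows; CentC arrays: ≥ 100 kb), the unique
150-mer fraction (effective genome size), mappability islands (depth ≤ 2
or ≥ 101, merged within 1 kb), CENH3 ChIP island calling (5 kb bins, gap
0, summed −log10 Poisson p > 250 and fold change > 4), RPKM enrichment
ratios, low-coverage regions, and two-sided Fisher interval
co-occurrence with 500 kb flanks.

Everything is validated end-to-end on a bundled truth-annotated
simulator: a repeat-rich 3 × 5 Mb genome (telomeres, subtelomeric
blocks, CentC centromeres with retroelement-like interruptions, knob180
and TR-1 arrays, one heterozygous region), two assembly profiles with
planted chimeras/collapses/breaks, noisy optical maps, two long-read
length profiles, CENH3 ChIP tracks, and genetic markers.

## Worked example

```r
library(gapless)
cfg <- simConfig(seed = 1)          # the default 3 x 5 Mb study
res <- runPipeline(cfg)             # simulates the bundle, then steps 1-5
```

The driver prints one line per step:

```
step 0: 66 + 41 alignments on 10 maps
step 1: 8 conflicts, contigs now 22 + 14
step 2: 1 loci (1 hom, 0 het), 1 patched
step 3: 68 overlaps, 19 contained dropped, 4 unitigs, 4 contigs remain
step 4: 3 scaffolds, 0 x 13N (0 resolved), 0 leftover contigs
finishing: 0 gaps closed, 3 shrunk, 5 telomeres extended
AGP: 300/359 markers kept, 3 pseudomolecules, 0 unplaced pieces
```

Both planted chimeras were cut (8 conflicts across replicate maps
collapse to the two junctions plus their map-side mirrors), the planted
tandem-array collapse was confirmed homozygous against three covering
maps and patched from the long-read assembly, and the two assemblies
merged into one unitig per solvable chromosome.  Validation against the
simulator truth:

```r
v <- validateAgainstTruth(res$pseudomolecules, res$bundle, res$report)
v$n_gaps                        # chr1 0, chr2 0, chr3 1
v$chimera_cut_distance_labels   # 0 0  (labels between cut and junction)
v$collapse_restored             # TRUE
v$identity_outside_repeats      # ~0.994
```

chr1 and chr2 assemble into single gapless pseudomolecules; chr3 keeps
exactly one residual gap at its 150 kb knob array, which exceeds both
assemblies' repeat thresholds and every read length — by design
unresolvable, mirroring how real knob arrays behave.

A thin command-line wrapper with `simulate`, `run-all`, `digest`,
`align`, `annotate` and `validate` subcommands is installed at
`inst/scripts/gapless-cli.R`.

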