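---
title: "Optical-map-anchored assembly reconciliation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical-map-anchored assembly reconciliation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and numerical choices behind
`gapless`: what each pipeline stage assumes, which parameters matter and
why they default to their values, what the bundled simulator does and
does not emulate, and where the design was genuinely open.

## The data model

Sequences travel as `SeqRecord` objects: an uppercase ACGTN string plus
*provenance blocks* that tile the record and point back to intervals on
the objects it was derived from.  Every operation that cuts, patches,
merges or scaffolds produces records whose provenance bottoms out at the
original coordinate systems, so an AGP can be derived mechanically from
any record (`agpFromRecords`) and intervals can be lifted between any
two assembly versions through the shared frame (`liftoverIntervals`).
Internal coordinates are 0-based half-open; AGP rows are 1-based
inclusive and label positions 1-based bp, converted only at the format
boundary.  Optical maps are `LabelMap` objects (length plus strictly
increasing label positions); alignments are monotone label-index
pairings (`MapAlignment`).

## The label-map aligner

Optical map alignment is a banded local dynamic programme over label
index pairs.  Matching a pair earns a fixed bonus (`pairBonus`, default
5); the transition between consecutive matched pairs costs

* a sizing penalty `min(delta^2 / (sdCoeff^2 * meanInterval), svCap)`,
  where `delta` is the difference of the bounded interval lengths and
  the expected sizing error of an interval is `sdCoeff * sqrt(interval)`
  (`sdCoeff` default 2, i.e. about 200 bp on a 10 kb interval — the
  scale of single-molecule sizing noise), and
* `missPenalty` (default 3) per skipped label on either side.

Two choices deserve comment.

**The penalty cap** (`svCap`, default 12).  With a pure quadratic
penalty, a single large insertion/deletion between two labels would
always split the alignment in two, and the error-curation stage could
never observe the discrepancy between adjacent matched pairs.  Capping
the per-pair penalty lets one grossly mis-sized interval be bridged
whenever it is flanked by agreeing pairs (net cost `svCap - pairBonus`
is repaid by two further matches), while a chimeric junction — where
*every* subsequent interval disagrees — still terminates the local
alignment, because each additional pair loses `svCap - pairBonus`.

**Confidence** is `score / ln 10`, a monotone rescaling chosen so a
perfect 10-pair alignment of 10 kb intervals scores at least 20.
Reported alignments need `minPairs >= 6` pairs and confidence `>= 12`
by default; these floors are what keeps spurious cross-chromosome label
chains (a handful of accidentally agreeing intervals) out of the
conflict caller.  The DP first runs unconstrained; if the optimum chain
is shorter than `minPairs` it re-runs with the pair count as a
saturating DP dimension, so the reported optimum is exactly the best
alignment satisfying the reporting rule (the property the enumeration
oracle in the test suite checks).

Maps are rescaled once against the backbone digests (least-squares
interval slope through the origin, `fitStretch`); further rounds are
config-selectable but one round suffices at the bundled noise level.

## Conflicts, support and cutting

A conflict needs at least 5 unaligned labels *and* 50 kb of unaligned
sequence beyond the alignment terminus on both the contig and the map:
overhang on one side only means the molecule or the contig simply ends.
Junction support is the fraction of spanning maps (window of ±3 contig
labels) that align contiguously through the junction; no spanning map
means support 0.  Support below 35 cuts the *sequence* at the terminal
paired label — only label positions are evidence-bearing, so cut
accuracy is intrinsically one label interval, and near unlabeled repeat
arrays that interval is large.  Conflicts are only called from
alignments scoring at least half the contig's best alignment; weaker
alignments still contribute support evidence.  Note the direction: low
support leads to a cut.  The convention for chimeric quality scores in
map-based pipelines is low-for-chimeric, and the sequence (never the
map) is what gets cut.

## Error curation

Discrepancy calls compare adjacent matched-interval lengths; the 1 kb
size floor and the 0.1 confidence floor are the field's standard
cutoffs for map-based structural error calls, and the confidence here
is the mean flanking-pair transition quality normalized to [0, 1] (the
commercial caller's confidence is opaque; ours is calibrated only to be
monotone in flank quality).  Calls from different maps whose contig
intervals overlap within two median label intervals are merged into one
locus; a locus is homozygous when at least two covering maps agree on
kind and size (within max(2 kb, half the size)), heterozygous when
covering maps disagree — which is exactly what happens over the
simulated heterozygous region, where one map replicate derives from the
alternate haplotype — and unknown with a single covering map (no patch:
conservative).  Patch boundaries snap to matched labels, then to the
nearest exact shared 20-mer within 500 bp, which avoids junction
artifacts at the few-bp scale.

## Overlap detection and merging

Overlaps use exact k-mer anchors (k = 21, sampled every 10 bp, k-mers
occurring more than 8 times in the index are masked as repeats),
chained on the dominant diagonal.  Identity is estimated by inverting
the k-mer survival model: if a fraction `s` of sampled positions carries
a chained anchor, identity ≈ `s^(1/k)`.  Raw anchor coverage would
underestimate identity badly at 1 % read error (0.99^21 ≈ 0.81 coverage)
and make the 0.9 identity floor unusable.  The desk-scale defaults
(minimum overlap 5 kb, identity 0.9, overhang 500 bp) scale with the
simulated genome; the full-scale preset mirrors megabase-genome
practice (25 kb overlap floor).  Containment dropping tolerates short
unmatched tails (15 kb at full scale) because a cut chimera retains up
to one label interval of foreign sequence at the cut end.  Unitig
merging only follows unambiguous dovetail edges (a contig end with two
partners is a branch and merges nothing), splices at an exact shared
20-mer, and keeps primary-assembly bases where both assemblies cover —
the backbone is the accurate profile, mirroring the polishing asymmetry
of the two sequencing chemistries.

## Scaffolding and the 13N convention

Each contig is placed on its best map (restricted to alignments within
half its global best score, so a weak off-target alignment cannot steal
a contig whose true map was not selected); exact ties are left unplaced
rather than broken arbitrarily.  With replicate maps, a greedy set
cover picks anchor maps and redundant placements (contained within an
accepted placement) are dropped.  Positive gaps become N runs of the
estimated size, floored at 100 N; overlapping placements get exactly
13 N, kind `overlap13N`, and are afterwards resolved by sequence-level
merging of the flanking windows — junctions flagged unmergeable (the
rDNA/NOR analogue) and junctions whose flanks share only diverged
repeats keep their 13 N.

## Finishing

Gap filling anchors reads to both flank windows by chained exact
k-mers (≥ 300 bp chained per flank, chains must be dense — at least 30 %
of sampled positions — so sparse chains of conserved repeat k-mers
cannot fake an anchor) and accepts a spanning read only when the
implied interior lies within a factor of `maxGapDelta = 2` of the
estimated gap either way (plus 1 kb slack).  The symmetric window is
what keeps the designed-unresolvable array gap open: a read whose
anchors happen to touch both repeat edges would imply an interior far
below the 140 kb estimate and is rejected.  Single-flank anchors shrink
a gap but never close it (a 13 N residual remains) — junctions are only
closed by reads that span them.  Telomere extension requires a terminal
unit tract of at least 1 kb at ≥ 90 % per-base unit identity (unit
coverage inverted through the 7-mer survival model, since one error
voids a whole unit; the tract is the terminal run of unit matches
without holes above 15 units), a unique anchoring locus across all
scaffold ends, and picks the longest qualifying read per end, with
CCCTAAA tracts at 5' ends and TTTAGGG at 3' ends.

## Pseudomolecule construction

Marker sequences (50 bp flanks) are re-anchored by seed k-mers with a
single-locus uniqueness rule — exact full-length matching would lose a
third of markers over segments derived from the noisier assembly.  The
filters are the standard ones: uniquely mapped, mapq > 30 (strict),
scaffolds need more than 20 surviving markers, and scaffolds above 100
markers keep 100 chosen evenly spaced by physical position (even
spacing, rather than the first 100, preserves ordering signal along the
whole scaffold; the selection rule is our choice).  Each scaffold joins
its majority linkage group only.  Ordering maximizes the weighted sum
of absolute Spearman rank correlations between genetic and assembled
physical order, exhaustively for groups of up to 8 scaffolds and by
greedy construction plus single-flip/adjacent-swap/2-opt passes above
that; marker sources get equal weights by default, and the group
direction is canonicalized so genetic positions ascend.  Scaffolds are
concatenated with 100 N (a common pseudomolecule convention;
config-exposed) and the AGP plus components reconstructs the FASTA
exactly.

## Annotation rules

Repeat arrays are called from monomer hit blocks (seed-and-extend with
12-mer seeds, candidate placements verified by global pairwise alignment
at ≥ 0.7 identity — satellite monomers diverge far beyond read error —
then merged into blocks) by single-linkage clustering with ≤ 100 kb
spacing: knob-class clusters need ≥ 500 kb span, CentC-class ≥ 100 kb,
both ≥ 10 % repeat density, and knob calls drop clusters overlapping the
outermost 200 kb of a sequence (the subtelomeric exclusion window is
stated, its width is our default).  CENH3 islands are runs of 5 kb bins
whose ChIP counts are Poisson-improbable (p < 0.01) against the
input-scaled background (lambda floored at the effective-genome-fraction
multiple of the mean input), scored as summed −log10 p; islands need
score > 250 and depth-normalized fold change > 4.  The absolute score
depends on this construction, which follows the broad-island caller
family.  The unique 150-mer fraction folds strands by taking the
minimum of forward and reverse-complement rolling 64-bit hashes; at
desk-to-genome scales the probability of any hash collision is far
below 1e-6, and the test suite pins the count to a literal string
dictionary on small genomes.  Two-sided Fisher p values sum the full
hypergeometric support (probability ≤ observed, with the standard
1 + 1e-7 tolerance).

## The simulator: what it emulates

The default configuration *is* the study condition: 3 chromosomes of
5 Mb with array spans scaled down about 100-fold from their
megabase-scale counterparts, preserving the threshold topology.
Monomers are 156 bp (CentC-like), 180 bp (knob180-like), the published
358 bp TR-1 consensus (bundled in `extdata`), 341 bp and 9349 bp rDNA
units; all synthetic monomers are kept free of the labeling motif so
satellite arrays are unlabeled stretches on the maps, as real AT-rich
satellites typically are.  Chromosomes 1 and 2 carry no array above the
long-noisy break threshold (80 kb) and are designed solvable; chromosome
3 carries a 150 kb knob that exceeds both break thresholds (accurate:
30 kb), every read length, and the 100 kb unlabeled-stretch limit that
splits maps — so exactly one residual gap must survive there.  Two
chimeras join repeat-adjacent loci of different chromosomes, one TR-1
array is collapsed by half, and one 100 kb heterozygous region (1 %
divergence plus a 20 kb deletion on the alternate haplotype) breaks the
accurate profile while the long profile and one of three map replicates
follow the alternate haplotype — giving the zygosity logic real
disagreement to adjudicate.  Read length presets keep the published
corrected/filtered N50 anchors (22.3 kb and 29,311 bp) because read
lengths are physical, not genome-scaled; map noise uses sd =
2·sqrt(interval), 5 % label miss rate, 0.5 false labels per 100 kb,
3 replicates.  Genetic markers are monotone in physical position with
1 cM Gaussian noise, 120 per chromosome, with 5 % flagged non-unique
and 5 % low-mapq to exercise the filters.

What the simulator does **not** emulate: realistic polymerase/pore
error profiles (errors are i.i.d. substitutions and short indels),
segmental duplications and nested TE insertions (interruptions are
labeled synthetic blocks, which is what makes composition truth exact),
optical-map assembly from raw molecules, and recombination beyond
monotone-plus-noise markers.  Passing the end-to-end test therefore
demonstrates that the pipeline's logic is correct under controlled
failure modes, not that it would resolve every structure in a real
2 Gb genome.

## Problem sizes and determinism

The default end-to-end study (15 Mb genome, ~10× long reads, 3 map
replicates) runs in a few minutes on one CPU; module tests use 1/5-scale
configurations (1 Mb chromosomes) and the oracle comparisons use maps of
at most 8 labels, where exhaustive enumeration is exact.  Every
simulator component seeds the RNG from the single config seed plus a
fixed per-component offset, so each output is byte-reproducible from
(config, seed) and components can be re-simulated independently.

## Known limitations

Cut placement is limited to label resolution; inside long unlabeled
arrays that can be tens of kilobases.  Provenance through
indel-carrying sequence is nominal (block-level, drifting by up to the
net indel length).  Discrepancies wider than the DP band's skip window
or spanning map ends are not called.  The heuristic ordering fallback
for large linkage groups is a local optimum, not exact.  The support
score direction (low support cuts) is our reading of an ambiguous
convention; it is config-exposed (`supportCut`).
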