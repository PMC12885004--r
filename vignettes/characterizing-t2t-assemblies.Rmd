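---
title: "Characterizing telomeres, centromeres and LTR domains in T2T assemblies"
author: "TeloCentR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing telomeres, centromeres and LTR domains in T2T assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

Telomere-to-telomere (T2T) assemblies resolve the two classes of
repeat-dominated chromosomal landmarks that short-read assemblies
collapse: terminal telomeric arrays and centromeric satellite regions.
TeloCentR implements the post-assembly characterization of such
assemblies as a reusable, tested pipeline with four analytical layers:

1. **Telomere scanning** — chromosome ends are searched for high-copy
   tandem repeats of short period, repeat units are counted exactly, and
   each motif is classified as canonical (the plant telomeric repeat
   CCCTAAA/TTTAGGG) or noncanonical (e.g. ACGCAGC or TGCGTCG, as
   reported at single chromosome ends of the liverwort *Apopellia
   endiviifolia*).
2. **Centromere calling** — genome-wide detection of satellite-scale
   tandem arrays, single-linkage clustering of nearby arrays, and one
   monocentric call per chromosome, corroborated by the windowed density
   trend of Gypsy-superfamily LTR retrotransposons.
3. **LTR domain mapping** — elements are sliced from the assembly by
   their GFF3 annotation, translated in six frames, and scanned against
   a labelled library of domain-consensus peptides (REXdb-style family
   labels such as Athila, Tat, Phygy, Selgy, Bryco, SIRE).
4. **Centromeric enrichment** — for every domain family, one-tailed
   Fisher exact tests compare occupied length and distinct-element
   counts between the centromeric and noncentromeric partitions of the
   genome, yielding the occupancy-proportion report of the top enriched
   families.

A fifth, first-class component is the **synthetic-assembly simulator**:
it generates desk-scale genomes with planted telomeres, satellite-filled
centromeres, domain-bearing LTR elements and genes, together with exact
truth tables, so every scanner can be validated against known ground
truth.

# Coordinate convention

All intervals are `GRanges` in 1-based closed coordinates, the
Bioconductor convention, both internally and in every report
(`length = end - start + 1`). BED input is converted on import by
`rtracklayer`. We deliberately use a single convention end to end
rather than a 0-based internal representation: every interval operation
in the package is delegated to `IRanges`/`GenomicRanges`, so a second
convention would add translation points without simplifying any
arithmetic. The conservation contracts (complement tiling, base-exact
partition occupancy) are convention-independent and are tested
exactly.

# Telomere scanning

## Canonicalization

A tandem motif is reported in the phase and strand actually observed at
the array start, but compared through its *canonical form*: the
lexicographically smallest string among all rotations of the motif and
all rotations of its reverse complement. CCCTAAA and TTTAGGG — the two
strand readings of the same biological repeat — share the canonical
form AAACCCT; a call is flagged canonical when its canonical form
equals that of CCCTAAA. Canonicalization is idempotent and
strand-invariant, so both chromosome ends are handled by one forward
scan rather than double scanning. Note that ACGCAGC and TGCGTCG are
base-wise complements but *not* reverse complements; they canonicalize
to different classes and the package reports them as two distinct
noncanonical motifs without asserting any pairing convention.

## Period discovery and counting

`discoverTerminalMotif()` scans a terminal window (default 10 kb;
printed telomeric arrays span at most ~3.4 kb, so the window leaves
margin for subterminal degeneracy) for each candidate period
p in 4–12: positions with `seq[i] == seq[i+p]` are marked, maximal
match runs at least one period long are seeded, runs separated by gaps
of at most 2p are merged (one substitution in an array breaks the match
vector in two places at most p apart), and the candidate maximizing
`copies * p` wins, subject to `copies >= 20` and `purity >= 0.9`. Ties
resolve to the smaller period, so a perfect period-7 array is not
reported as period 14. The copy-number and purity defaults are
configurable; published counts run 115–481 copies, far above the
floor, and random terminal windows produce at most isolated short runs
whose purity after merging collapses toward the background match rate
(~0.26 at GC 0.39), which the purity gate rejects.

`countRepeats()` then refines the discovery: whole units of the
discovered motif are extended in both directions from the anchor. At
the default `tolerance = 0` only perfect units count, which makes
planted-copy recovery exact. With `tolerance > 0`, a unit is accepted
when its per-unit mismatch fraction is at most the tolerance, and up to
two consecutive over-tolerance units are bridged when an acceptable
unit follows — so isolated substitutions inside a long array do not
truncate the count, while the array boundary (where background units
essentially never pass) still stops the extension. Whether published
copy counts include degenerate units is not stated anywhere we know of;
the default therefore counts perfect units only and the tolerance is an
explicit knob.

One boundary subtlety: if the background base immediately flanking an
array happens to extend the period-p match run, the reported phase
rotates by up to one motif length and the array span shifts
accordingly. Copy counts are unaffected (they are floors of span over
period); tests assert terminal anchoring to within one motif length.

# Centromere calling

## Array detection

`findTandemArrays()` slides a 10-kb window (step 5 kb) along each
chromosome. Within a window, candidate periods in 50–2,000 bp are
seeded from the distances between reoccurring 13-mers — the classic
trick that avoids scoring every period — and each candidate is scored
by the fraction of positions matching at that lag; the best candidate
is kept when the fraction reaches 0.5. Overlapping window hits are
merged, and each merged region is refined at base resolution: the
rolling match density (half a monomer each side) must stay at or above
0.5, which recovers planted array spans to within about one monomer.
Exactness is claimed for span recovery, not for the period itself
(a 200-bp monomer may be reported at 199–202 if the seeding distances
wobble); tests assert period within ±2 and span within ±1 monomer.

## Clustering and calling

Arrays on the same chromosome whose gaps are at most 100 kb are merged
by single linkage (`clusterArrays()`), reflecting the structure of
satellite-based centromeres in which tandem arrays are interrupted by
retroelement insertions. Per chromosome, `callCentromeres()` takes the
cluster maximizing `span * coverage` — rewarding both extent and
density, since the underlying description ("extensive dense arrays")
names no score — subject to a 20-kb minimum extent, and makes at most
one call (monocentric by construction; polycentric reporting is out of
scope). Contact-map corroboration is replaced by a retroelement flag:
`addRetroSupport()` computes the windowed coverage density of
Gypsy-superfamily elements with a centered moving-average trend (a
deliberate substitution for a LOESS fit — the moving average is
parameter-light and deterministic) and flags a call supported when the
global trend maximum falls within the call span ± 1 window. At desk
scale the flag is corroborative only: with few hundred elements per
genome the trend is noisy, and the flag does not gate any call.

# LTR domain mapping

Elements are sliced from the forward strand (strand recorded, not
applied — the six-frame translation covers both strands regardless).
Translation uses the standard genetic code without initiator-codon
special-casing, drops trailing partial codons, splits at stops and
discards segments under 30 residues (random stop-free segments of that
length are common enough that shorter ones only add alignment load
without adding sensitivity).

Domain scanning replaces a profile-HMM search against REXdb with local
alignment of every segment against labelled consensus peptides
(match +2, mismatch −1, gap opening −10, gap extension −1), with
per-label score thresholds carried in the library file. This keeps the
module's contract — a map from element IDs to domain-family labels —
without an external binary and database; a precomputed hit table from
an external scanner can be substituted wherever a hit data frame is
accepted. Segments are pre-screened by word seeding (a segment is
aligned only when it shares an exact 4-mer with the consensus), the
standard BLAST-style heuristic; at 10% consensus divergence seed words
remain abundant, and the screen can be disabled. Only the best hit per
(element, label) is kept: enrichment counts distinct elements, so
within-element multiplicity is irrelevant downstream.

The packaged domain library is **synthetic**: ten REXdb-style family
labels with randomly generated 60-residue consensus peptides at
threshold 60 (a perfect match scores 120). It exists so that the
simulator and the scanners share a closed loop with known truth; real
analyses should supply their own library FASTA (`"label threshold"`
headers).

# Centromeric enrichment

For each domain family, `partitionOccupancy()` computes occupied length
by exact base overlap (an element straddling a centromere boundary is
apportioned exactly, so centromeric plus noncentromeric bases equal the
element's bases to the base) and distinct-element counts by majority
rule (an element counts as centromeric when more than half its length
overlaps centromeres — the underlying description does not define
straddlers, and the majority rule keeps each element counted exactly
once). The noncentromeric partition is the genome minus the merged
centromeric spans.

`fisherOneTailed()` computes the upper-tail hypergeometric probability
P(X ≥ a) for the 2×2 table via log-gamma with summation started at the
largest term, exact to at least ten significant digits for margins to
1e7; it is tested against exhaustive enumeration for every table with
N ≤ 60 and against the closed-form tail at large margins. Degenerate
tables (a zero margin) return p = 1 by convention rather than erroring,
so sparse families still appear in reports.

The length test runs on 1-kb blocks rather than raw bases
(`lengthUnit`, configurable down to base resolution): base-resolution
cells treat every base as an independent trial and overstate
significance wildly; kilobase blocks are of the order of the element
size, which is the natural exchangeable unit here. Cells are rounded
half up with a one-block minimum for any nonzero occupancy, so a tiny
but real occupancy is never rounded out of existence. The count test
compares a family's element counts against all elements assigned to
each partition. Significance defaults to raw p < 0.05 per test — the
matching reports in the field state raw thresholds — and
Benjamini–Hochberg correction across families is available by flag.
`topEnriched()` reports the k most significant families with their
occupancy proportions.

# The simulator

`simulateAssembly()` generates, per chromosome: i.i.d. background bases
at a configurable GC (default 0.39, the reported genomic average);
telomeric arrays planted verbatim at both termini (substitution rate
configurable, default 0); a centromere built as satellite monomer
tandem fill (per-chromosome random monomer, default 200 bp, mutated per
copy at 2% divergence) interleaved with the LTR elements assigned to
it; further LTR elements and non-overlapping gene intervals outside.
Every LTR element carries its family's consensus peptide as an in-frame
ORF at a random frame, strand and codon offset, written with a fixed
codon-per-amino-acid reverse translation (determinism over codon-usage
realism). An element lands in the centromeric partition with
probability f·Lc / (f·Lc + Lnc) for enrichment factor f, so the
centromeric/noncentromeric density ratio converges to f. Placement is
rejection sampling with a 10,000-attempt cap; infeasible packings error
before any sequence is emitted. Planted features never overlap, and
truth tables are exact: slicing the emitted FASTA at any truth interval
reproduces the planted sequence (at substitution rate 0).

`simConfigScaled()` mirrors the nine published chromosomes at 1/100
scale (≈1.0–5.3 Mb each, ≈29 Mb total): chromosome lengths and
centromere coordinates are scaled, while telomere copy numbers are kept
at their printed values (425/418 on chromosome 1 down to 446/420 on
chromosome 9, with ACGCAGC × 115 at the left end of chromosome 3 and
TGCGTCG × 176 at the right end of chromosome 6) — copy counts, not
chromosome lengths, are the recovery targets. Scaled centromeres are
floored at 25 kb so that all nine stay above the caller's 20-kb default
minimum extent; at exact 1/100 scale the smallest centromere
(chromosome 5, ~19.8 kb) would otherwise fall below a threshold that is
natural at full scale. The default LTR plan spans nine families across
the Gypsy, Copia and Bel-Pao superfamilies with strong centromeric
enrichment for the Tat lineages (f = 8), Phygy and Selgy (f = 6), and a
moderate factor for Bel-Pao (f = 5), emulating the reported pattern of
Gypsy-lineage concentration near centromeres; gene intervals default to
7 per 500-kb window, inside the reported 5.5–9.8 range.

What the simulator does *not* emulate: sequencing error, assembly gaps,
satellite higher-order repeat structure, monomer libraries of real
centromeres (none is published for this genome), interstitial telomeric
repeats, nested or truncated transposons, and genes as sequence (genes
are intervals only). Passing recovery tests on this generator therefore
demonstrates correctness of the scanning and statistical machinery
under the stated genome architecture, not performance on real
assemblies with degenerate repeats.

# Problem sizes and determinism

The test suite and the acceptance script run the nine-chromosome
fixture at 1% linear scale (≈29 Mb), where the full pipeline —
simulation, telomere scan, genome-wide array detection, domain scan and
enrichment — completes in a few minutes on one core; property suites
(exhaustive Fisher enumeration to N = 60, translation oracles,
clustering oracles, power and null simulations) are sized to the same
budget. All randomness flows through R's RNG from a single integer
seed; identical config and seed reproduce byte-identical FASTA, truth
tables and reports, which the tests assert via checksums.

# Known limitations

- Period detection reports the seeded period, not a minimal rotation
  period; a monomer may be reported at a small offset from its planted
  length.
- The telomere scanner reports at most one array per end; interstitial
  telomeric repeats are out of scope.
- The retroelement-support flag is a density-trend heuristic, not a
  chromatin-contact validation, and is intentionally non-gating.
- The consensus-alignment domain scanner trades profile-HMM sensitivity
  for dependency-freedom; deeply diverged domain instances that an HMM
  would catch can be missed at default thresholds.
- Enrichment p-values assume exchangeable length blocks; spatial
  autocorrelation beyond the block scale is not modelled.
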