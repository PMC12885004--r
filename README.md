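# TeloCentR

Telomere, centromere and retroelement characterization of
telomere-to-telomere (T2T) genome assemblies, in R.

## The problem

A finished T2T assembly resolves the repeat landmarks that define
chromosome architecture, and characterizing them is the first
post-assembly analysis: where are the telomeres and how many repeat
units does each end carry (including noncanonical motifs — the
liverwort *Apopellia endiviifolia*, for instance, carries ACGCAGC and
TGCGTCG arrays in place of the canonical plant repeat at two of its
eighteen chromosome ends); where is each centromere, defined
computationally as the extensive dense satellite-array region of a
chromosome; and which LTR-retrotransposon domain families (Athila,
Tat, Phygy, Selgy, Bryco, SIRE, ...) are statistically enriched in the
centromeric partition of the genome. TeloCentR packages these analyses
for genome assemblers and repeat biologists, together with a
synthetic-assembly simulator that provides exact ground truth for
validating every step.

## What it computes

- **Telomeres** — each terminal window is scanned for the tandem
  period p ∈ [4, 12] maximizing copies × p among match runs of
  `seq[i] = seq[i+p]`; repeat units are then counted exactly
  (`copies = ⌊span/p⌋`, perfect units by default, mismatch tolerance as
  a knob). Motifs are compared by their canonical form — the
  lexicographic minimum over all rotations of the motif and of its
  reverse complement — so CCCTAAA/TTTAGGG is one class (canonical) and
  anything else is flagged noncanonical.
- **Centromeres** — satellite arrays (period 50–2,000 bp) are detected
  genome-wide in sliding windows with 13-mer-seeded period candidates,
  clustered by single linkage (gap ≤ 100 kb), and the cluster
  maximizing span × coverage is called per chromosome (one call,
  monocentric), with a Gypsy-density moving-average trend as
  corroboration.
- **LTR domain map** — annotated elements are six-frame translated and
  locally aligned (match +2, mismatch −1, affine gaps) against a
  labelled consensus-peptide library, yielding element → family-label
  sets.
- **Centromeric enrichment** — per family, one-tailed Fisher exact
  tests on the 2×2 partition tables, by occupied length (in 1-kb
  blocks) and by distinct-element counts:
  p = P(X ≥ a), X ~ Hypergeom(N, K, n), computed via log-gamma with
  stable tail summation; plus the occupancy-proportion report of the
  top enriched families.
- **Assembly summaries** — N50/L50 by the cumulative-half definition,
  windowed GC and gene-density tracks (500-kb default), interval
  complement/partition arithmetic, block-size summaries, category
  shares.

## Worked example

Nine-chromosome synthetic assembly at 1/100 of the published
*A. endiviifolia* chromosome lengths, telomere copy numbers kept at
their printed values:

```r
library(TeloCentR)

assemblyStats(apopelliaChromosomes()$length)
#> AssemblyStats
#>   sequences: 9  total: 2,914,960,273 bp
#>   N50: 468,157,909 bp  (L50 = 3)
#>   longest: 529,742,643  shortest: 100,551,284

sim <- simulateAssembly(simConfigScaled(seed = 1))
sim
#> SimulatedAssembly
#>   9 chromosomes, 29,149,601 bp total (seed 1)
#>   truth: 18 telomeres, 9 centromeres, 377 LTR elements, 407 genes

telomereTable(callTelomeres(simGenome(sim)))
#>   name leftCopies leftMotif rightCopies rightMotif
#> 1  Ch1        425   CCCTAAA         418    TTTAGGG
#> 2  Ch2        352   CCCTAAA         422    TTTAGGG
#> 3  Ch3        115   ACGCAGC         414    TTTAGGG
#> 4  Ch4        408   CCCTAAA         402    TTTAGGG
#> 5  Ch5        481   CCCTAAA         421    TTTAGGG
#> 6  Ch6        419   CCCTAAA         176    TGCGTCG
#> 7  Ch7        393   CCCTAAA         452    TTTAGGG
#> 8  Ch8        428   CCCTAAA         403    TTTAGGG
#> 9  Ch9        446   CCCTAAA         420    GTTTAGG
```

All 18 planted copy numbers are recovered exactly; the two
noncanonical ends surface with their planted motifs (Ch9's right motif
prints in a rotated phase — a background base happens to extend the
period-7 run — but counts and canonical class are unaffected). The
centromere caller then recovers all nine planted satellite regions:

```r
arrays <- findTandemArrays(simGenome(sim))
cen <- callCentromeres(simGenome(sim), clusterArrays(arrays))
head(as.data.frame(granges(cen))[, 1:5], 3)
#>   seqnames   start     end width arrayCoverage
#> 1      Ch1 3593980 3634038 40059     0.8865424
#> 2      Ch2 2327972 2378032 50061     0.9219352
#> 3      Ch3 4463971 4492207 28237     0.8564295
```

and the enrichment layer flags the families planted with high
centromeric enrichment factors:

```r
feats <- simTruth(sim)$ltr
feats$type <- "LTR_retrotransposon"
el   <- extractElements(simGenome(sim), feats)
scan <- scanElements(el, readDomainLibrary())
occ  <- partitionOccupancy(el, scan$map, granges(cen), simGenome(sim))
topEnriched(enrichmentTable(occ))[, c("label","propCen","propNon","pLength","pCount")]
#>    label propCen propNon  pLength pCount
#> 1  Selgy  0.0438 0.00288 1.48e-10 0.0265
#> 2 TatIII  0.0185 0.00293 1.87e-03 0.2267
#> 3  TatII  0.0167 0.00307 2.26e-03 0.2267
#> 4   TatI  0.0148 0.00300 1.20e-02 0.5147
```

`propCen`/`propNon` are the proportions of centromeric and
noncentromeric length occupied by elements carrying each domain;
`pLength`/`pCount` are the one-tailed Fisher p-values of the length
and element-count tests. `runPipeline()` composes all of the above and
writes TSV reports, call BEDs and a JSON manifest.

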