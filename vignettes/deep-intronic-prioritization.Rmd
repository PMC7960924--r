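---
title: "Prioritizing deep-intronic splice variants: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing deep-intronic splice variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crypticSplice)
```

## The problem

A third of patients with a clinical diagnosis of inherited retinal disease
(IRD) leave panel or exome testing without a molecular diagnosis. Part of
the gap comes from deep-intronic variants — positions far from any
exon-intron junction — that create or activate cryptic splice sites,
splicing a pseudo-exon into the mature mRNA or stretching a canonical exon
into its intron. Whole-genome sequencing sees these variants; the
bottleneck is interpretation. `crypticSplice` implements a desk-side
version of the prioritization strategy used in cohort studies of this
problem: consume SpliceAI-annotated VCFs, select rare, high-scoring,
panel-gene, deep-intronic candidates, pair alleles under each gene's
inheritance model, reconstruct the predicted aberrant transcript, and
design the minigene construct an assay lab would clone to validate the
prediction.

The package never computes SpliceAI scores, alignments or variant calls;
those are upstream tools whose outputs it consumes.

## The candidate cascade

For each proband VCF, every ALT allele becomes one record carrying its
population allele frequency, genotype, pass-through coding-consequence
class, and (when present) the SpliceAI annotation
`ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`, four
delta scores in [0, 1] for acceptor gain/loss and donor gain/loss with
their positions relative to the variant. The cascade applies:

1. **Frequency** — keep alleles with AF < 0.5% *or absent* from the
   population database (an unobserved allele is by definition rare).
2. **Splice score** — keep alleles whose *maximum* delta score is >= 0.5.
   The max-of-four is the community convention for a single per-variant
   score; both the statistic and the cutoff are arguments.
3. **Panel** — keep alleles in genes of the disease panel
   (gene, inheritance mode AD/AR/XL, canonical transcript id). Symbols
   match case-sensitively.
4. **Inheritance pairing** — a dominant gene or an X-linked hemizygous
   genotype is solved by one qualifying splice allele; a recessive gene
   needs a second allele: homozygosity, a second qualifying splice
   allele, or a rare coding hit in the same gene. Compound heterozygotes
   with unknown phase are assumed in trans and flagged
   `phase_unconfirmed`. Heterozygous females under XL are held as
   `needs_second_allele`.
5. **Junction distance** — keep intronic positions strictly more than
   10 bases from the nearest junction. Distances follow the HGVS offset
   convention (the first intronic base has distance 1), so the filter
   excludes offsets +-1..10; coding and near-junction alleles stay
   eligible as second alleles, not as splice candidates.

All filters are pure set operations, so their order changes only which
removal reason a multiply-failing variant is tagged with; this is tested
as a commutation property. Relaxing the AF or score threshold can only
grow the candidate set (tested as a superset property).

## Event classification and transcript reconstruction

The SpliceAI delta positions are reference-strand offsets from the
variant; adding them to the variant position gives candidate genomic
sites, interpreted in transcript sense:

* acceptor gain + donor gain, acceptor 5' of donor, both inside one
  intron → **pseudo-exon**; the inserted length counts both boundary
  bases (donor − acceptor + 1 in transcript sense). An acceptor 3' of
  the donor cannot form an exon and is classified `none` with a warning.
* donor gain alone (with or without donor loss) → **exon elongation** of
  the upstream exon out to the new donor.
* acceptor gain + acceptor loss → **acceptor shift** of the downstream
  exon's 5' edge.
* When several patterns pass, the most specific wins:
  pseudo-exon > acceptor shift > elongation.

Applying the event to the exon chain, the package splices the mutant mRNA
against the genome (applying the variant's own substitution, since a
gained site often sits on the variant base), classifies the reading frame
(`in_frame` iff the inserted length is a multiple of 3), scans codons from
the CDS start for the first stop ending strictly before the point where
the wild-type stop lands in the mutant transcript, and applies the
standard 50-nt rule for nonsense-mediated decay: NMD is predicted when
the premature stop ends more than 50 nt (strictly) upstream of the last
exon-exon junction. The source studies only say a premature stop
"presumably" triggers NMD; the 50-nt heuristic is the package's explicit,
configurable operationalization. Each consequence report also carries the
*minimum* delta score over the event's gained sites, because validation
assays tend to show partial splicing (both wild-type and aberrant bands)
exactly when one gained site is weakly predicted.

## Minigene design

A splicing-reporter construct clones, between two vector exons, the test
exon (the canonical exon nearest the event), the predicted cryptic exon
with the intervening intron when there is one, and a symmetric intronic
flank of 150 bases per side (published protocols say "approximately
150 bp" without per-side values; a single symmetric parameter is the
simplest faithful reading). Predicted RT-PCR products add 92 bases per
vector exon — reported protocols prime inside both vector exons at that
offset; whether the two contributions are really identical is not stated,
so 92-per-side is a configurable convention. The wild-type product is
`2 x 92 + test exon`; the aberrant product exceeds it by exactly the
inserted length, and the wild-type-sized band is always listed for the
variant construct because partial splicing is always possible while any
gained-site score is below 1. An in-silico splice of the construct
(`spliceConstructInSilico`) checks the arithmetic for every design.
Multi-variant amplicons are edited in coordinate-descending order so
earlier edits cannot invalidate later coordinates.

## Synthetic worlds and the bundled cohort

Real cohort genomes for this problem are not distributable, so the package
carries two generators, both deterministic under an explicit seed:

* `simulateGenomeAndModels()` / `plantCohort()` build toy genomes (one
  gene per contig, ATG-initiated CDS free of internal stops, canonical
  GT...AG introns, both strands) and plant per-proband configurations —
  dominant single-hit, recessive splice+coding, recessive homozygous,
  X-linked hemizygous, unsolved — alongside decoys that must fail exactly
  one filter (common, low-score, near-junction). Planted SpliceAI scores
  are drawn uniformly from [cutoff, 1]: real per-variant scores are
  unpublished, and only pass/fail behaviour is testable. Recovery tests
  demand 100% recall of planted configurations and zero decoy leakage.
* `exampleCohort()` encodes a published eight-proband case series: six
  distinct deep-intronic splice variants (five novel) in six IRD genes,
  with the reported coding second alleles, zygosities and novelty flags.
  Gene models are synthetic stand-ins constructed so the printed cDNA
  anchors are literally realizable (the first exon ends at the printed
  donor anchor, the intron hosts the printed offset, and intron lengths
  keep each offset on its anchored side of the midpoint so formatted
  labels round-trip). Cryptic-exon inserts carry or omit in-frame stops
  exactly as the reported consequences require. What the generators do
  *not* emulate: realistic allele-frequency spectra, sequencing noise,
  multi-transcript genes, or genes with many exons — so a passing suite
  shows the logic is right, not that real-cohort yield is reproduced.

```{r}
fx <- exampleCohort(file.path(tempdir(), "cohort"))
pri <- prioritizeCohort(fx$manifest, fx$panel, fx$models)
pri$summary
```

One honest artifact of two-exon analogs: the 84-base pseudo-exon analog
places its reported premature stop 33 nt upstream of the cryptic-donor
junction, which is the *last* junction of a two-exon gene, so the 50-nt
rule reports no NMD there — in the real multi-exon gene the same stop is
followed by dozens of junctions and NMD is expected.

## Numerical and edge-case choices

* Coordinates are 1-based inclusive throughout (`IRanges`), the native
  convention of GFF3/GTF/VCF and of the Bioconductor containers used;
  readers and writers therefore never shift coordinates.
* Junction-distance ties at an intron midpoint resolve to the donor
  (+) side, so HGVS formatting is deterministic.
* Cutoff comparisons: score >= cutoff passes; AF strictly < threshold
  passes; junction distance strictly > threshold passes; the NMD rule is
  strictly >. Each is the most literal reading of the stated rule.
* Multi-allelic records are decomposed per ALT allele, never dropped;
  alleles the genotype does not carry are skipped.
* Missing AF means "not observed", which passes the frequency filter;
  the AF INFO key is configurable because cohorts differ in which
  population database supplies it.
* One canonical transcript per gene (a panel column) is evaluated;
  multi-transcript aggregation is out of scope.
* A minigene region running off its contig is clipped with a warning.

## Problem sizes used in the shipped checks

The test suite and acceptance script run entirely on generated data: the
eight-proband example cohort (~53 kb of genome across six contigs),
brute-force junction-distance scans on transcripts with up to five exons,
200 random transcripts for the premature-stop oracle, exhaustive frame
checks for insert lengths 1–300, and twenty seeded five-proband cohorts
for recovery properties. These sizes were chosen as the smallest worlds
that exercise every code path including both strands and every planted
configuration.

## Known limitations

* Only substitution HGVS labels (plus del/dup anchors) are parsed; full
  HGVS grammar and protein-level notation are out of scope.
* Structural variants and genotype likelihoods are not handled.
* The pipeline predicts splicing outcomes qualitatively; it does not
  predict isoform ratios, which published assays quantify by gel
  densitometry — the reported minimum gained-site score is the hook for
  correlating prediction strength with assay completeness, not a ratio
  model.
* SpliceAI occasionally disagrees with assays on the exact cryptic
  junction (a reported 84-base prediction validated as 119 bases); the
  package reports the prediction only.
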