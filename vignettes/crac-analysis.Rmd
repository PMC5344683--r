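---
title: "CRAC analysis with cracr: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CRAC analysis with cracr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cracr)
library(GenomicRanges)
```

## The measurement and its signatures

CRAC libraries sequence RNA fragments crosslinked to a tagged bait protein.
Each read is laid out as `[3-nt random trimer][sample barcode][insert][3'
adaptor]`. Three properties of the insert carry the biology:

* its genomic position (where the protein was bound),
* an occasional single-nucleotide deletion, introduced by reverse
  transcriptase at the crosslinked base, which localizes the protein-RNA
  contact to nucleotide resolution,
* an occasional non-genome-encoded oligo(A) suffix, the mark left by the
  TRAMP poly(A) polymerase on nuclear decay substrates.

`cracr` models the analysis of a three-factor experiment - RNA Pol II
(transcription), Nab3 (NNS termination complex) and Mtr4 (TRAMP/exosome) -
across a nutrient-downshift time course, where the scientific readout is
how surveillance-factor binding redistributes when transcription is
reprogrammed.

## Preprocessing model

`prepReads()` chains adaptor clipping, 3' quality trimming (trailing run
below Q20), read-level quality filtering (>= 70% of bases at Q20), a
homopolymer-artifact filter (>= 95% one nucleotide), barcode
demultiplexing, and PCR-duplicate collapsing keyed on *(random trimer,
full insert sequence)* - the strictest reading of "identical reads", since
the trimer exists precisely to separate independent cDNAs with identical
inserts. Quality thresholds default to Q20/70% because the upstream tools
this stage emulates are conventionally run near those values; all are
configurable. Demultiplexing precedes collapsing by default (the reverse
order is available via `collapseFirst`), and every stage reports counts so
that input = kept + dropped + unassigned is checkable from logs.

The random trimer gives only 64 distinguishable labels per insert, so two
independent molecules can occasionally collide; the generator's truth
tables record the trimer so tests compare against *distinguishable*
molecules, which is what any collapsing scheme can recover.

## Alignment model

`alignReads()` is a deliberately transparent aligner for the toy genome:
an exact 18-nt 5' seed proposes loci; extension is 5'-anchored and maximal,
allowing at most one single-nucleotide genomic deletion. Two numerical
choices matter:

* A deletion is accepted only when followed by at least 7 matching bases
  (`delAnchor`). Without this, a read whose oligo(A) tail happens to echo
  nearby genomic sequence would be "explained" as a deletion and the tail
  silently absorbed; 7 bases put that misclassification below ~1e-4 per
  tailed read on random sequence.
* Within a homopolymer run the deleted base is ambiguous; the 5'-most
  position is reported (the leftmost-alignment convention). The read
  simulator additionally plants crosslinked bases that differ from both
  neighbours, so on synthetic data the recovered position is exact rather
  than merely equivalent.

Because the seed is the first 18 nt, a deletion closer than 18 nt to the
read start is not discoverable; the generator therefore only plants
deletions with >= 18 nt of 5' context and >= 8 nt of 3' anchor. Reads
failing that geometry still sample the site - they simply carry no
deletion, exactly as reads that escaped crosslink-induced misincorporation
do in a real library.

The maximal-extension rule means a tail that the genome could extend is
absorbed into the match. This undercounts tails at genomic A-runs - a bias
shared with homology-search based tail detection - and is surfaced per
read rather than hidden: `importSam()` applies the same check to
soft-clipped bases of externally aligned reads, so real data enter the
pipeline under identical semantics.

Multi-mapping reads take a uniform random locus among equal scorers
(`assignMultimappers()`), enumerated in genome order first so the draw is
reproducible under a seed.

## Oligo(A) classification

A non-templated addition qualifies as an oligo(A) tail when it has at
least two A's and at most one non-A residue in five (`nonA_frac <= 1/5`,
boundary accepted; evaluated on the read's sense strand). The rule is a
function of the A count and length only - no sliding window - and the
tailed-read frequency uses adaptor-containing reads as denominator, since
only reads sequenced through their 3' end can reveal a tail. Both the
minimum length (2 nt) and the denominator choice are parameters.

## Quantification and clustering

Reads count toward the sense-strand transcript with the largest overlap
(ties uniform under a seed); dubious ORFs can be excluded by biotype.
Counts scale to hits per million over a declared universe, so column sums
over the universe are exactly 1e6. Surveillance binding is normalized as
factor:Pol II HPM ratios with a 1-HPM pseudocount. Pairwise Pearson
correlations use the top transcripts by mean HPM across all samples
(sample-order independent) on log2(HPM + 1).

Fold changes are per-replicate log2 ratios averaged on the log scale.
The eight directional clusters map the (Pol II, Nab3, Mtr4) sign triple
with Pol II as the most significant bit: (+,+,+) is cluster 1 through
(-,-,-) as cluster 8, so cluster 5 = Pol II down, both surveillance
factors up. This ordering is the unique one consistent with the
descriptions of clusters 1, 5-7 and 8 in the experiment this analysis
models; it is configurable. The dead band epsilon defaults to 0 (pure
sign), with in-band values assigned "down". The representation filter
requires 10 time-0 reads per factor by default - the source analyses state
only the resulting gene count, not their threshold, so the value here is a
package choice.

## Crosslink sites and motif scoring

Deletion positions tally into width-1 sites; the top 50 by read support
(coordinate-ordered at ties) are expanded to 13-nt sense-strand windows
and scored for exact substring occurrence of the consensus (default
`TCTTG`, the DNA form of UCUUG). "Conformance" as exact occurrence is a
package definition - the upstream experiment ran a motif-discovery tool
instead, which is out of scope here; the accompanying k-mer enrichment
against an Altschul-Erikson dinucleotide-preserving shuffle provides the
discovery-free counterpart. The transcript scope of the top-50 selection
is a parameter (`topSites(scope =)`) because the experiment's own account
of which cluster's transcripts fed the motif analysis is ambiguous.

## Metagene profiles

Profiles anchor on the TSS, the poly(A) site, or a per-gene site such as
the strongest crosslink (`strongestSitePerGene()`, ties toward the 5'
end). Two weighting modes reproduce the two figure styles such
experiments use: `hpm_sum` keeps additive coverage so strongly bound genes
dominate, and `per_gene_unit` normalizes each row to sum to 1 ("each gene
normalized to 1 and weighted equally") - read as a density rather than
max-scaling, because the equal-weight average of densities is itself a
distribution. Length-normalized profiles split each transcript into 50
near-equal bins, remainder nucleotides going to the 5'-most bins, so bin
totals conserve coverage exactly. Fixed-window TSS profiles default to a
500-2800 nt length filter with exclusion (not truncation) of
out-of-range transcripts.

## Junction ratios

Spliced (exon1|exon2) and unspliced (intron|exon2) junction references are
built from the annotation; a read counts when it matches exactly and
covers the boundary with >= 3 nt on each side. Only the intron-3'-exon
boundary defines the unspliced class. The aggregate
spliced:unspliced ratio over a transcript class is the pooled-count ratio.

## The synthetic-data generator

`simConfig()` defaults encode the study conditions the generator emulates,
chosen once:

| parameter | default | meaning |
|---|---|---|
| `mtr4OffsetMean` | 25 nt | Mtr4 crosslinks peak ~25 nt downstream of Nab3 sites (Poisson offset) |
| `tailModel$bodyMeanLen` | 4 nt | mean gene-body oligo(A) tail length |
| `tailModel$paMeanLen` | 12 nt | poly(A)-site tails markedly longer (value a package choice) |
| `tailModel$tailProb` | PolII 0.03, Nab3 0.05, Mtr4 0.25 | tailed-read frequencies: 20-30% for Mtr4 vs 1-6% for Pol II |
| `nab3DownstreamWeight` | 0.1 / 0.5 / 0.8 at 0/4/8 min | 5'-proximal binding in glucose shifting downstream after withdrawal |
| `deletionProb` | 0.2 | crosslink-deletion frequency per covering read |
| `pcrDupMean` | 1 | expected extra PCR copies per molecule |
| `readsPerSample` | 2000 | molecules per library (desk-scale depth) |
| `nTranscripts` | 60 | transcription units on two toy chromosomes |

Tail lengths are drawn as 2 + geometric with the stated mean: the floor of
2 nt makes every planted tail an oligo(A) tail by the classification rule,
so planted and callable quantities coincide; the mean is preserved.
Planted tails are forced non-templated (the insert is shortened until the
genome does not continue with A), mirroring the aligner's
maximal-extension convention. After nutrient shift, a designated quarter
of mRNAs ("targets") have their sampling weights multiplied by 0.25 for
Pol II and 4 for Nab3/Mtr4, which propagates through HPM renormalization
to place targets in cluster 5 and non-targets in cluster 4 with wide
margins at the default depth.

What the generator does **not** emulate: sequencing substitution errors,
rRNA/tRNA background, replicate-level biological variability, multiple
introns per gene, and overlapping transcription units. Passing tests
therefore demonstrate the correctness of the analysis logic under clean
conditions - recovery of every planted signal - not robustness to every
artifact of real libraries; real data enter via `importSam()` and face the
same downstream code.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full 3 x 3 x 2
experiment at 2000 molecules per library on a ~90 kb genome of 60
transcripts - enough for every per-gene margin the planted effects need,
while a complete end-to-end run stays around a minute. Every stochastic
step (genome layout, read sampling, multi-mapper and tie assignment,
shuffle backgrounds) derives from an explicit seed, and `runPipeline()`
writes an MD5-checksummed manifest so whole-run determinism is a testable
byte-level property.

## Known limitations

* The toy aligner is for the synthetic genome; real libraries should be
  aligned externally and imported as SAM.
* One deletion per read; multi-nucleotide or substitution signatures of
  crosslinking are not modelled.
* Oligo(U) tails and mechanistic attribution of tails (TRAMP vs canonical
  poly(A) polymerase) are out of scope; position relative to the poly(A)
  site is the only discriminator offered.
* Junction matching is exact; a sequencing error in a junction read drops
  it rather than soft-matching.
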