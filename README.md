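# cracr — analysis of CRAC protein–RNA crosslinking sequencing data

CRAC (UV crosslinking and analysis of cDNAs) maps where an RNA-binding
protein touches the transcriptome: RNA fragments copurified with a tagged
bait protein are reverse transcribed and sequenced. Two sequence-level
signatures carry the information the method exists for:

* **Microdeletions.** Reverse transcriptase frequently drops the
  crosslinked nucleotide, leaving a single-nucleotide deletion in the cDNA
  that pinpoints the protein–RNA contact.
* **Non-genome-encoded oligo(A) tails.** Nuclear surveillance substrates
  carry short 3′ adenosine runs added by the TRAMP poly(A) polymerase;
  these appear as read suffixes that cannot be aligned to the genome.

`cracr` implements the full desk-scale analysis chain for experiments that
profile RNA polymerase II together with the yeast surveillance factors Nab3
(NNS complex, recognizing UCUUG on nascent RNA) and Mtr4 (TRAMP helicase):
linker-aware FASTQ preprocessing with random-trimer PCR-duplicate
collapsing, 5′-anchored alignment that captures deletions and non-templated
tails, oligo(A) classification, per-transcript quantification, directional
clustering, crosslink-site and motif analysis, metagene profiles, and
spliced:unspliced junction ratios — plus a synthetic-data generator that
plants every one of these signals with machine-readable truth tables.

## Core rules and models

* **Oligo(A) call.** A non-templated 3′ addition is an oligo(A) tail when it
  contains ≥ 2 A's and its non-A fraction is ≤ 1/5. The tailed-read
  frequency is computed over reads whose 3′ adaptor was sequenced (only
  those reads reveal their true 3′ end).
* **Tail detection.** Alignment is 5′-anchored and maximal: the longest
  genomic extension wins, and only the remainder becomes the tail. This
  undercounts tails at genomic A-runs — the same bias a homology-search
  based procedure has.
* **Normalization.** Counts are scaled to hits per million (HPM) over a
  stated transcript universe; surveillance binding is expressed as
  factor:Pol II HPM ratios so transcription rate is factored out.
* **Directional clusters.** Each transcript's (Pol II, Nab3, Mtr4) log2
  fold-change sign triple after nutrient shift maps to clusters 1–8 with
  Pol II as the most significant bit; cluster 5 (Pol II down, Nab3 up,
  Mtr4 up) marks specific surveillance targets.
* **Crosslink sites.** Deleted genomic positions are tallied per strand;
  the top sites are expanded to 13-nt windows and scored for exact
  occurrence of the UCUUG (DNA: `TCTTG`) consensus, with k-mer enrichment
  against a dinucleotide-preserving shuffle.

## Worked example

```r
library(cracr)
library(GenomicRanges)

cfg <- simConfig(seed = 1, nTranscripts = 20)
sim <- makeGenome(cfg)

# an Mtr4 library: preprocessing and tail statistics
lib <- simulateCracReads(sim, "Mtr4", time = "0", sample = "Mtr4_0_1",
                         nReads = 2000, seed = 2)
pr  <- prepReads(lib$reads, prepConfig(barcodeTable = makeBarcodeTable("Mtr4_0_1")))
pr$stats
#>  input  dropped_short  dropped_quality  dropped_artifact  unassigned
#>   4035              0                0                 0           0
#>  duplicates_removed  kept
#>                2040  1995
aln   <- assignMultimappers(alignReads(pr$reads, genomeSeq(sim)), seed = 3)
calls <- callTails(aln, pr$reads, txFeatures(sim))
tailFraction(calls)
#> $total_reads_with_adaptor [1] 1995
#> $n_tailed                 [1] 494
#> $fraction_tailed          [1] 0.2476
```

24.8% of this Mtr4 library's reads carry oligo(A) tails — the hallmark of
TRAMP-primed decay intermediates (a Pol II library simulated the same way
sits at ~3%).

```r
# a post-shift Nab3 library: crosslink sites and the consensus motif
libN <- simulateCracReads(sim, "Nab3", time = "4", sample = "Nab3_4_1",
                          nReads = 2000, seed = 4)
prN  <- prepReads(libN$reads, prepConfig(barcodeTable = makeBarcodeTable("Nab3_4_1")))
alnN  <- assignMultimappers(alignReads(prN$reads, genomeSeq(sim)), seed = 5)
sites <- callDeletionSites(alnN, txFeatures(sim))
win   <- extractWindows(topSites(sites, 20), genomeSeq(sim))
cs    <- consensusScore(win, "TCTTG", shuffles = 10, seed = 6)
cs$n_conforming
#> [1] 20
head(cs$kmer_enrichment, 3)
#>       kmer observed expected enrichment
#>  895 TCTTG       20      2.4   7.068966
#> 1005 TTGTA        4      0.3   5.625000
#>  719 GTATG        2      0.0   5.000000
```

All 20 top crosslink-site windows contain the consensus, and `TCTTG` is the
most enriched 5-mer over the shuffled background — the deletion-based site
caller lands exactly on the planted binding motif.

For the full experiment (3 factors × 3 time points × 2 replicates) use
`runPipeline(simConfig(seed = 1), makeSampleSheet(), "run1")`, which writes
counts, HPM, ratios, correlations, fold changes, clusters, sites, tail
statistics, metagene profiles and a checksummed `manifest.json` under the
run directory.

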