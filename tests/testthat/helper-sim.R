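# Shared synthetic fixtures, built once per test run.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(SummarizedExperiment)
})

# small genome used by several files
.tinySim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- makeGenome(simConfig(seed = 11, nTranscripts = 12))
    cache
  }
})

# one prepped + aligned Nab3 library on the tiny genome
.tinyAligned <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- .tinySim()
      lib <- simulateCracReads(sim, "Nab3", sample = "Nab3_0_1",
                               nReads = 300, seed = 21)
      pc <- prepConfig(barcodeTable = makeBarcodeTable("Nab3_0_1"))
      pr <- prepReads(lib$reads, pc)
      aln <- assignMultimappers(alignReads(pr$reads, genomeSeq(sim)),
                                seed = 5)
      cache <<- list(sim = sim, lib = lib, prep = pr, aln = aln)
    }
    cache
  }
})

# number of distinguishable molecules in a truth table: PCR copies collapse,
# but distinct molecules sharing (trimer, insert) are indistinguishable by
# construction of the linker
.truthMolecules <- function(truth) {
  length(unique(paste(truth$sample, truth$umi, truth$chrom,
                      truth$genomic_start, truth$genomic_end, truth$strand,
                      truth$planted_deletion_pos, truth$planted_tail_seq)))
}

# build an alignment GRanges by hand (for unit tests of downstream ops)
.mkAln <- function(chrom, start, end, strand = "+", read_id = NULL,
                   deletion_pos = NA_integer_, tail_seq = "",
                   seqlen = 10000L) {
  n <- max(length(chrom), length(start))
  if (is.null(read_id)) read_id <- sprintf("r%03d", seq_len(n))
  gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end), strand = strand,
    read_id = read_id,
    matched = end - start + 1L,
    score = end - start + 1,
    deletion_pos = as.integer(deletion_pos),
    tail_seq = tail_seq)
  GenomeInfoDb::seqlengths(gr) <-
    stats::setNames(rep(seqlen, length(GenomeInfoDb::seqlevels(gr))),
                    GenomeInfoDb::seqlevels(gr))
  gr
}
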