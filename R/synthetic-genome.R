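#' Synthetic genome with planted CRAC signals
#'
#' Container for a simulated genome: the chromosome sequences, the transcript
#' annotation (GRanges, 1-based closed coordinates), and the planted motif
#' instances with their crosslinked nucleotides.
#'
#' @slot genome [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot features [GenomicRanges::GRanges] of transcription units with
#'   metadata columns `ID`, `biotype` (mRNA/CUT/SUT/snoRNA), `tss`,
#'   `pA_site`, `intron_start`/`intron_end` (NA when intronless),
#'   `mature_start`/`mature_end` (snoRNA mature body), `is_target`.
#' @slot motifSites [GenomicRanges::GRanges] of planted motif instances with
#'   `transcript_id`, `crosslink` (genomic position of the crosslinked
#'   nucleotide immediately 3' of the motif, in transcript sense) and
#'   `is_proximal`.
#' @slot config the [SimConfig-class] used to build the object.
#' @seealso [makeGenome()]
#' @export
setClass("CracGenome", representation(
  genome = "DNAStringSet",
  features = "GRanges",
  motifSites = "GRanges",
  config = "SimConfig"
))

setValidity("CracGenome", function(object) {
  msg <- character(0)
  f <- object@features
  if (!all(c("ID", "biotype", "tss", "pA_site") %in% colnames(mcols(f))))
    msg <- c(msg, "features must carry ID, biotype, tss, pA_site")
  if (anyDuplicated(mcols(f)$ID)) msg <- c(msg, "feature IDs must be unique")
  if (!all(as.character(seqnames(f)) %in% names(object@genome)))
    msg <- c(msg, "feature seqnames absent from genome")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CracGenome", function(object) {
  f <- object@features
  cat("CracGenome:", length(object@genome), "chromosome(s),",
      sum(width(object@genome)), "nt\n")
  print(table(biotype = mcols(f)$biotype))
  cat(length(object@motifSites), "planted motif instances (",
      object@config@motif, ")\n")
})

#' @describeIn CracGenome-class chromosome sequences.
#' @param x a `CracGenome`.
#' @export
genomeSeq <- function(x) x@genome

#' @describeIn CracGenome-class transcript annotation as GRanges.
#' @export
txFeatures <- function(x) x@features

#' @describeIn CracGenome-class planted motif instances as GRanges.
#' @export
motifSites <- function(x) x@motifSites

# Transcript-sense sequence of feature i, as a character scalar.
.senseSeq <- function(sim, id) {
  f <- sim@features[match(id, mcols(sim@features)$ID)]
  s <- as.character(subseq(sim@genome[[as.character(seqnames(f))]],
                           start(f), end(f)))
  if (as.character(strand(f)) == "-") s <- .revcomp(s) else s
}

# Transcript-sense coordinate -> genomic position, vectorized over pos.
.toGenomic <- function(pos, fstart, fend, fstrand) {
  ifelse(fstrand == "+", fstart + pos - 1L, fend - pos + 1L)
}

#' Build a toy genome and annotation with planted signals
#'
#' Generates chromosomes of random sequence in which transcription units are
#' laid out on alternating strands, separated by intergenic spacers.  Each
#' unit receives a biotype (mRNA/CUT/SUT/snoRNA; the noncoding classes drawn
#' shorter than mRNAs), two planted instances of the recognition motif (one
#' 5'-proximal, one downstream), and a designated crosslinked nucleotide
#' immediately 3' of each motif.  A configurable fraction of mRNAs carries
#' exactly one intron.  snoRNA transcribed units extend a fixed margin
#' beyond their mature ends.  A random subset of mRNAs is flagged as
#' surveillance targets for the nutrient-shift effect model.
#'
#' The crosslinked base is planted so that it differs from both neighbouring
#' bases; the diagnostic 1-nt deletion is then recoverable at a unique
#' position (no homopolymer ambiguity), which makes planted-truth
#' comparisons exact.
#'
#' @param cfg a [SimConfig-class].
#' @return A [CracGenome-class].
#' @examples
#' sim <- makeGenome(simConfig(seed = 7, nTranscripts = 10))
#' sim
#' @export
makeGenome <- function(cfg) {
  validObject(cfg)
  if (cfg@transcriptLenRange[1] > cfg@transcriptLenRange[2])
    stop("transcriptLenRange inverted")
  withr::with_seed(cfg@seed, .makeGenomeImpl(cfg))
}

.makeGenomeImpl <- function(cfg) {
  n <- cfg@nTranscripts
  base <- c("A", "C", "G", "T")
  biotype <- sample(names(cfg@biotypeProps), n, replace = TRUE,
                    prob = cfg@biotypeProps)
  lo <- cfg@transcriptLenRange[1]; hi <- cfg@transcriptLenRange[2]
  matureLen <- integer(n)
  for (i in seq_len(n)) {
    matureLen[i] <- switch(biotype[i],
      mRNA = sample(lo:hi, 1L),
      CUT = sample(200:600, 1L),
      SUT = sample(250:700, 1L),
      snoRNA = sample(150:400, 1L))
  }
  hasIntron <- biotype == "mRNA" &
    (stats::runif(n) < cfg@intronFraction) & matureLen >= 300L
  intronLen <- ifelse(hasIntron, sample(80:120, n, replace = TRUE), 0L)
  spanLen <- matureLen + intronLen +
    ifelse(biotype == "snoRNA", 2L * cfg@snoMargin, 0L)
  strand <- rep_len(c("+", "-"), n)

  # Target set for the nutrient-shift effect model.
  mRNAidx <- which(biotype == "mRNA")
  nTarget <- round(cfg@targetFraction * length(mRNAidx))
  targetIdx <- if (nTarget > 0) .resample(mRNAidx, nTarget) else integer(0)
  isTarget <- seq_len(n) %in% targetIdx

  motifLen <- nchar(cfg@motif)
  senseSeqs <- character(n)
  motifOffsets <- vector("list", n)  # sense offset of motif first base
  e1Len <- integer(n)                # sense length of exon 1 (0 = intronless)
  for (i in seq_len(n)) {
    L <- spanLen[i]
    s <- sample(base, L, replace = TRUE)
    prox <- max(40L, round(0.15 * L))
    down <- min(L - 80L, round(0.55 * L))
    offs <- unique(c(prox, if (down > prox + 20L) down))
    for (m in offs) {
      s[m:(m + motifLen - 1L)] <- strsplit(cfg@motif, "")[[1]]
      # crosslinked base just 3' of the motif: distinct from both neighbours
      x <- m + motifLen
      s[x] <- .sample1(setdiff(base, c(s[x - 1L], s[x + 1L])))
    }
    motifOffsets[[i]] <- offs
    if (hasIntron[i]) e1Len[i] <- round(matureLen[i] / 3)
    senseSeqs[i] <- paste(s, collapse = "")
  }

  # Lay transcripts on two chromosomes with random spacers.
  nchrom <- if (n >= 8) 2L else 1L
  chromOf <- rep(seq_len(nchrom), length.out = n)
  chromOf <- sort(chromOf)
  gstart <- integer(n); gend <- integer(n)
  chromSeq <- character(nchrom)
  for (ch in seq_len(nchrom)) {
    idx <- which(chromOf == ch)
    parts <- character(0); pos <- 0L
    for (i in idx) {
      gap <- .randDNA(cfg@intergenicLen)
      seg <- if (strand[i] == "+") senseSeqs[i] else .revcomp(senseSeqs[i])
      parts <- c(parts, gap, seg)
      gstart[i] <- pos + cfg@intergenicLen + 1L
      gend[i] <- gstart[i] + spanLen[i] - 1L
      pos <- gend[i]
    }
    parts <- c(parts, .randDNA(cfg@intergenicLen))
    chromSeq[ch] <- paste(parts, collapse = "")
  }
  genome <- DNAStringSet(chromSeq)
  names(genome) <- paste0("chrSim", seq_len(nchrom))

  chrom <- paste0("chrSim", chromOf)
  ids <- sprintf("TX%04d", seq_len(n))
  tss <- ifelse(strand == "+", gstart, gend)
  # For snoRNAs the poly(A)-site column marks the 3' end of the transcribed
  # unit (they are not polyadenylated in the canonical sense).
  pA <- ifelse(strand == "+", gend, gstart)

  intron_start <- rep(NA_integer_, n); intron_end <- rep(NA_integer_, n)
  for (i in which(hasIntron)) {
    i1 <- e1Len[i] + 1L                      # sense coords of intron
    i2 <- e1Len[i] + intronLen[i]
    g1 <- .toGenomic(i1, gstart[i], gend[i], strand[i])
    g2 <- .toGenomic(i2, gstart[i], gend[i], strand[i])
    intron_start[i] <- min(g1, g2); intron_end[i] <- max(g1, g2)
  }
  mature_start <- rep(NA_integer_, n); mature_end <- rep(NA_integer_, n)
  sno <- biotype == "snoRNA"
  mature_start[sno] <- gstart[sno] + cfg@snoMargin
  mature_end[sno] <- gend[sno] - cfg@snoMargin

  feat <- GRanges(chrom, IRanges(gstart, gend), strand = strand,
                  ID = ids, biotype = biotype, tss = as.integer(tss),
                  pA_site = as.integer(pA),
                  intron_start = intron_start, intron_end = intron_end,
                  mature_start = mature_start, mature_end = mature_end,
                  is_target = isTarget)
  seqlengths(feat) <- stats::setNames(width(genome), names(genome))

  mi <- rep(seq_len(n), lengths(motifOffsets))
  moff <- unlist(motifOffsets)
  if (length(moff)) {
    m1 <- .toGenomic(moff, gstart[mi], gend[mi], strand[mi])
    m2 <- .toGenomic(moff + motifLen - 1L, gstart[mi], gend[mi], strand[mi])
    xs <- .toGenomic(moff + motifLen, gstart[mi], gend[mi], strand[mi])
    motifs <- GRanges(chrom[mi], IRanges(pmin(m1, m2), pmax(m1, m2)),
                      strand = strand[mi],
                      transcript_id = ids[mi],
                      sense_offset = as.integer(moff),
                      crosslink = as.integer(xs),
                      is_proximal = moff == vapply(motifOffsets[mi],
                                                   `[`, numeric(1), 1L))
    seqlengths(motifs) <- seqlengths(feat)
  } else {
    motifs <- GRanges()
  }
  new("CracGenome", genome = genome, features = feat,
      motifSites = motifs, config = cfg)
}

#' Write the synthetic genome, annotation and motif truth to disk
#'
#' Writes `genome.fasta`, `annotation.gff3` (1-based inclusive, attributes
#' `ID`, `biotype`, `pA_site`, ...) and `motif_sites.tsv`.  Output is
#' byte-deterministic for a given [CracGenome-class].
#'
#' @param sim a [CracGenome-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeGenomeFiles <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "annotation.gff3")
  mot <- file.path(dir, "motif_sites.tsv")
  writeXStringSet(sim@genome, fa)
  f <- sim@features
  # exon rows: two for intron-bearing transcripts, one otherwise
  exChrom <- character(0); exStart <- integer(0); exEnd <- integer(0)
  exStrand <- character(0); exParent <- character(0)
  for (i in seq_along(f)) {
    is1 <- mcols(f)$intron_start[i]
    if (is.na(is1)) {
      s <- start(f)[i]; e <- end(f)[i]
    } else {
      ie <- mcols(f)$intron_end[i]
      s <- c(start(f)[i], ie + 1L); e <- c(is1 - 1L, end(f)[i])
    }
    exChrom <- c(exChrom, rep(as.character(seqnames(f))[i], length(s)))
    exStart <- c(exStart, s); exEnd <- c(exEnd, e)
    exStrand <- c(exStrand, rep(as.character(strand(f))[i], length(s)))
    exParent <- c(exParent, rep(mcols(f)$ID[i], length(s)))
  }
  exons <- GRanges(exChrom, IRanges(exStart, exEnd), strand = exStrand)
  seqlengths(exons) <- seqlengths(f)[seqlevels(exons)]
  mtx <- mcols(f)
  mtx$type <- "transcript"; mtx$Parent <- NA_character_
  mex <- mtx[rep(NA_integer_, length(exons)), ]
  mex$type <- "exon"
  mex$Parent <- exParent
  mex$ID <- paste0(exParent, ":exon",
                   stats::ave(seq_along(exParent), exParent,
                              FUN = seq_along))
  all <- c(f, exons)
  mcols(all) <- rbind(mtx, mex)
  rtracklayer::export.gff3(all, gff)
  m <- sim@motifSites
  .write_tsv(data.frame(
    transcript_id = mcols(m)$transcript_id,
    chrom = as.character(seqnames(m)),
    motif_start = start(m), motif_end = end(m),
    strand = as.character(strand(m)),
    crosslink_pos = mcols(m)$crosslink,
    is_proximal = mcols(m)$is_proximal), mot)
  invisible(c(fasta = fa, gff3 = gff, motifs = mot))
}
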