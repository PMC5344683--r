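# Synthetic CRAC read simulation with planted truth.

# Transcript-sense sequence plus `extra` nt of downstream genomic context,
# so that non-templated-tail checks can look past the 3' end.
.senseSeqExt <- function(sim, idx, extra = 40L) {
  f <- sim@features[idx]
  chr <- sim@genome[[as.character(seqnames(f))]]
  if (as.character(strand(f)) == "+") {
    hi <- min(end(f) + extra, length(chr))
    as.character(subseq(chr, start(f), hi))
  } else {
    lo <- max(start(f) - extra, 1L)
    .revcomp(as.character(subseq(chr, lo, end(f))))
  }
}

.lookupByFactor <- function(x, factor) {
  if (is.null(names(x))) x[1] else if (factor %in% names(x)) unname(x[[factor]]) else 0
}

#' Simulate one CRAC library with planted ground truth
#'
#' Draws cDNA molecules from the factor-specific positional model: Pol II
#' uniformly along transcripts, Nab3 centred on planted motif crosslink
#' sites (5'-proximal in glucose, shifting downstream at later time points),
#' and Mtr4 at Nab3 sites displaced downstream by a Poisson offset.  Reads
#' covering a crosslinked nucleotide carry the diagnostic 1-nt deletion with
#' probability `deletionProb`; non-genome-encoded oligo(A) tails are appended
#' with per-factor probability (longer at the poly(A) site than in the gene
#' body); each molecule is emitted as `1 + Poisson(pcrDupMean)` PCR copies.
#' Every emitted read is `[random trimer][barcode][insert][tail][3' adaptor]`
#' and has exactly one row in the returned truth table.
#'
#' Planted tails are guaranteed non-templated: if the genome continues with
#' `A` beyond the insert, the insert is shortened until the junction is
#' unambiguous (mirroring the maximal-extension convention of the aligner).
#'
#' @param sim a [CracGenome-class].
#' @param factor one of `"PolII"`, `"Nab3"`, `"Mtr4"`.
#' @param time time point label (`"0"`, `"mock"`, `"4"`, `"8"`); drives the
#'   downstream-site mixture weight and the target-gene effect multipliers.
#' @param sample sample label used in read names and the barcode table.
#' @param nReads number of cDNA molecules before PCR duplication.
#' @param seed RNG seed for this library.
#' @return A list with `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (one row per emitted read; genomic coordinates 1-based inclusive).
#' @examples
#' sim <- makeGenome(simConfig(seed = 3, nTranscripts = 8))
#' lib <- simulateCracReads(sim, "Nab3", nReads = 50, seed = 11)
#' head(lib$truth)
#' @export
simulateCracReads <- function(sim, factor, time = "0",
                              sample = paste(factor, time, "1", sep = "_"),
                              nReads = sim@config@readsPerSample,
                              seed = sim@config@seed) {
  if (!factor %in% c("PolII", "Nab3", "Mtr4"))
    stop("unknown factor label: ", factor)
  withr::with_seed(seed,
                   .simReadsImpl(sim, factor, as.character(time), sample,
                                 nReads))
}

.simReadsImpl <- function(sim, factor, time, sample, nReads) {
  cfg <- sim@config
  f <- sim@features
  n <- length(f)
  ids <- mcols(f)$ID
  Lg <- width(f)
  str <- as.character(strand(f))
  gs <- start(f); ge <- end(f)
  chrom <- as.character(seqnames(f))
  sense <- vapply(seq_len(n), function(i) .senseSeqExt(sim, i), character(1))

  # crosslink sense offsets per transcript (proximal first)
  ms <- sim@motifSites
  xoff <- mcols(ms)$sense_offset + nchar(cfg@motif)
  xl <- split(xoff[order(!mcols(ms)$is_proximal)],
              mcols(ms)$transcript_id[order(!mcols(ms)$is_proximal)])
  xl <- xl[ids]

  w <- as.numeric(Lg)
  if (time %in% c("4", "8")) {
    eff <- .lookupByFactor(cfg@shiftEffect, factor)
    w[mcols(f)$is_target] <- w[mcols(f)$is_target] * eff
  }

  bc <- if (sample %in% names(cfg@barcodeTable)) {
    unname(cfg@barcodeTable[sample])
  } else if (!length(cfg@barcodeTable)) {
    unname(makeBarcodeTable(sample)[1])
  } else stop("sample '", sample, "' not in barcodeTable")

  tailP <- .lookupByFactor(cfg@tailModel$tailProb, factor)
  paFrac <- .lookupByFactor(cfg@paSiteFrac, factor)
  wD <- if (time %in% names(cfg@nab3DownstreamWeight))
    unname(cfg@nab3DownstreamWeight[[time]]) else 0.1
  ins <- cfg@insertLenRange
  minKeep <- 24L  # inserts never shortened below this by the tail-junction rule

  tid <- sample.int(n, nReads, replace = TRUE, prob = w)
  insLen <- sample(ins[1]:ins[2], nReads, replace = TRUE)

  mol_seq <- character(nReads); mol_tail <- character(nReads)
  mol_del <- rep(NA_integer_, nReads)
  mol_s <- integer(nReads); mol_e <- integer(nReads)
  copies <- 1L + stats::rpois(nReads, cfg@pcrDupMean)
  umi <- .randDNA(rep(cfg@umiLen, nReads))

  for (m in seq_len(nReads)) {
    i <- tid[m]; L <- min(insLen[m], Lg[i] - 2L)
    xlink <- NA_integer_
    if (stats::runif(1) < paFrac) {
      e0 <- Lg[i]; s0 <- e0 - L + 1L
    } else if (factor == "PolII") {
      s0 <- sample.int(Lg[i] - L + 1L, 1L); e0 <- s0 + L - 1L
    } else if (is.null(xl[[i]]) || !length(xl[[i]])) {
      s0 <- sample.int(Lg[i] - L + 1L, 1L); e0 <- s0 + L - 1L
    } else {
      sites <- xl[[i]]
      x <- if (length(sites) > 1L && stats::runif(1) < wD)
        sites[length(sites)] else sites[1L]
      if (factor == "Mtr4") x <- x + stats::rpois(1L, cfg@mtr4OffsetMean)
      x <- min(max(x, 10L), Lg[i] - 10L)
      u <- L %/% 2L + sample(-10:10, 1L)
      u <- min(max(u, 3L), L - 3L)
      s0 <- min(max(x - u + 1L, 1L), Lg[i] - L + 1L)
      e0 <- s0 + L - 1L
      if (x > s0 && x < e0) xlink <- x
    }
    tail <- ""
    if (stats::runif(1) < tailP) {
      nearPa <- (Lg[i] - e0) <= 5L
      mean_len <- if (nearPa) cfg@tailModel$paMeanLen else cfg@tailModel$bodyMeanLen
      tlen <- .rtail_len(1L, mean_len)
      tc <- rep("A", tlen)
      if (cfg@tailModel$nonARate > 0 && tlen > 1L) {
        flip <- which(stats::runif(tlen - 1L) < cfg@tailModel$nonARate) + 1L
        tc[flip] <- sample(c("C", "G", "T"), length(flip), replace = TRUE)
      }
      tail <- paste(tc, collapse = "")
      # enforce a non-templated junction (genome must not continue with A)
      while (e0 - s0 + 1L > minKeep &&
             substr(sense[i], e0 + 1L, e0 + 1L) == "A") {
        e0 <- e0 - 1L
      }
    }
    # Deletions are planted only where the read geometry supports exact
    # recovery: at least 18 matched nt 5' of the deleted base (the seed) and
    # at least 8 nt of 3' anchor.
    if (factor != "PolII" && !is.na(xlink) &&
        xlink - s0 >= 18L && e0 - xlink >= 8L &&
        stats::runif(1) < cfg@deletionProb) {
      mol_del[m] <- xlink
    }
    insert <- substr(sense[i], s0, e0)
    if (!is.na(mol_del[m])) {
      k <- mol_del[m] - s0 + 1L
      insert <- paste0(substr(insert, 1L, k - 1L),
                       substr(insert, k + 1L, nchar(insert)))
    }
    mol_seq[m] <- insert
    mol_tail[m] <- tail
    mol_s[m] <- s0; mol_e[m] <- e0
  }

  # expand molecules into PCR copies
  ridx <- rep(seq_len(nReads), copies)
  copyNo <- sequence(copies)
  read_id <- sprintf("%s_m%06d_c%d", sample, ridx, copyNo)
  i <- tid[ridx]
  gstart <- ifelse(str[i] == "+", gs[i] + mol_s[ridx] - 1L, ge[i] - mol_e[ridx] + 1L)
  gend <- ifelse(str[i] == "+", gs[i] + mol_e[ridx] - 1L, ge[i] - mol_s[ridx] + 1L)
  delg <- ifelse(str[i] == "+", gs[i] + mol_del[ridx] - 1L, ge[i] - mol_del[ridx] + 1L)

  seq <- paste0(umi[ridx], bc, mol_seq[ridx], mol_tail[ridx], cfg@adaptor3)
  reads <- data.frame(
    id = read_id,
    seq = seq,
    qual = strrep("I", nchar(seq)),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = read_id,
    molecule_id = sprintf("%s_m%06d", sample, ridx),
    umi = umi[ridx],
    sample = sample, factor = factor, time = time,
    transcript_id = ids[i],
    chrom = chrom[i],
    genomic_start = as.integer(gstart),
    genomic_end = as.integer(gend),
    strand = str[i],
    planted_deletion_pos = as.integer(delg),
    planted_tail_seq = mol_tail[ridx],
    n_pcr_copies = copies[ridx],
    is_spliced = NA,
    stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Simulate junction-spanning reads
#'
#' Emits reads that span exactly one splice junction of an intron-containing
#' transcript: spliced reads join the exon1/exon2 boundary (no intronic
#' sequence), unspliced reads cross the intron to 3'-exon boundary.  Reads
#' carry the same 5' linker layout and 3' adaptor as [simulateCracReads()].
#'
#' @param sim a [CracGenome-class]; must contain intron-bearing transcripts.
#' @param splicedFraction probability a read is spliced.
#' @param nReads number of reads.
#' @param readLen insert length in nt (must be at least `2 * minOverhang`).
#' @param minOverhang minimum planted overhang on each side of the junction.
#' @param sample sample label.
#' @param seed RNG seed.
#' @return A list with `reads` and `truth` (column `is_spliced` set).
#' @export
simulateJunctionReads <- function(sim, splicedFraction, nReads,
                                  readLen = 40L, minOverhang = 5L,
                                  sample = "JUNC", seed = sim@config@seed) {
  f <- sim@features
  has_intron <- !is.na(mcols(f)$intron_start)
  if (!any(has_intron)) stop("no intron-bearing transcripts in annotation")
  if (readLen < 2L * minOverhang)
    stop("readLen shorter than twice the minimum overhang")
  withr::with_seed(seed, {
    cfg <- sim@config
    idx <- which(has_intron)
    ids <- mcols(f)$ID
    bc <- if (sample %in% names(cfg@barcodeTable)) {
      unname(cfg@barcodeTable[sample])
    } else unname(makeBarcodeTable(sample)[1])
    tid <- .resample(idx, nReads, replace = TRUE)
    spliced <- stats::runif(nReads) < splicedFraction
    k1 <- sample(minOverhang:(readLen - minOverhang), nReads, replace = TRUE)
    sense <- stats::setNames(
      vapply(idx, function(i) .senseSeqExt(sim, i, 0L), character(1)),
      ids[idx])
    out_seq <- character(nReads)
    gstartL <- integer(nReads); gendL <- integer(nReads)
    for (m in seq_len(nReads)) {
      i <- tid[m]
      s <- sense[[ids[i]]]
      # sense coordinates of the intron
      fs <- start(f)[i]; fe <- end(f)[i]; st <- as.character(strand(f))[i]
      ig1 <- mcols(f)$intron_start[i]; ig2 <- mcols(f)$intron_end[i]
      io <- sort(c(.toSense(ig1, fs, fe, st), .toSense(ig2, fs, fe, st)))
      i1 <- io[1]; i2 <- io[2]
      left_end <- if (spliced[m]) i1 - 1L else i2  # exon1 end vs intron end
      left <- substr(s, left_end - k1[m] + 1L, left_end)
      right <- substr(s, i2 + 1L, i2 + (readLen - k1[m]))
      out_seq[m] <- paste0(left, right)
      gstartL[m] <- .toGenomic(left_end - k1[m] + 1L, fs, fe, st)
      gendL[m] <- .toGenomic(left_end, fs, fe, st)
    }
    umi <- .randDNA(rep(cfg@umiLen, nReads))
    seq <- paste0(umi, bc, out_seq, cfg@adaptor3)
    read_id <- sprintf("%s_j%06d", sample, seq_len(nReads))
    list(
      reads = data.frame(id = read_id, seq = seq,
                         qual = strrep("I", nchar(seq)),
                         stringsAsFactors = FALSE),
      truth = data.frame(
        read_id = read_id,
        molecule_id = read_id,
        umi = umi,
        sample = sample, factor = NA_character_, time = NA_character_,
        transcript_id = ids[tid],
        chrom = as.character(seqnames(f))[tid],
        genomic_start = as.integer(pmin(gstartL, gendL)),
        genomic_end = as.integer(pmax(gstartL, gendL)),
        strand = as.character(strand(f))[tid],
        planted_deletion_pos = NA_integer_,
        planted_tail_seq = "",
        n_pcr_copies = 1L,
        is_spliced = spliced,
        stringsAsFactors = FALSE))
  })
}

# genomic position -> transcript-sense coordinate
.toSense <- function(gpos, fstart, fend, fstrand) {
  if (fstrand == "+") gpos - fstart + 1L else fend - gpos + 1L
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path (uncompressed FASTQ).
#' @return Invisibly, `path`.
#' @export
writeReadsFastq <- function(reads, path) {
  if (file.exists(path)) unlink(path)
  fq <- ShortRead::ShortReadQ(
    sread = DNAStringSet(reads$seq),
    quality = ShortRead::FastqQuality(Biostrings::BStringSet(reads$qual)),
    id = Biostrings::BStringSet(reads$id))
  ShortRead::writeFastq(fq, path, mode = "w", compress = FALSE)
  invisible(path)
}

#' Read a FASTQ file into the plain read representation
#'
#' @param path FASTQ path (gzip-transparent).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
readFastqFile <- function(path) {
  fq <- ShortRead::readFastq(path)
  data.frame(
    id = as.character(ShortRead::id(fq)),
    seq = as.character(ShortRead::sread(fq)),
    qual = as.character(Biostrings::quality(Biostrings::quality(fq))),
    stringsAsFactors = FALSE)
}
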