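# FASTQ preprocessing: adaptor clipping, quality trimming/filtering,
# homopolymer-artifact removal, demultiplexing, PCR-duplicate collapsing.

#' Preprocessing configuration
#'
#' @param adaptor3 3' adaptor sequence to clip.
#' @param minOverlap minimum adaptor-suffix overlap for a confident clip (nt).
#' @param minLenAfterClip inserts shorter than this after clipping are dropped.
#' @param qualTrimThreshold Phred threshold for 3' quality trimming.
#' @param qualFilterThreshold,qualFilterFrac a read is kept only if at least
#'   `qualFilterFrac` of its bases reach `qualFilterThreshold`.
#' @param artifactFrac reads whose insert is at least this fraction a single
#'   nucleotide are removed as homopolymer artifacts.
#' @param barcodeTable named character sample -> barcode.
#' @param umiLen length of the 5' random trimer.
#' @param barcodeMismatches allowed barcode mismatches (0 = exact).
#' @param collapseFirst if `TRUE`, duplicates are collapsed before
#'   demultiplexing instead of after.
#' @return A validated list of class `PrepConfig`.
#' @export
prepConfig <- function(adaptor3 = "TGGAATTCTCGGGTGCCAAGG",
                       minOverlap = 7L,
                       minLenAfterClip = 18L,
                       qualTrimThreshold = 20L,
                       qualFilterThreshold = 20L,
                       qualFilterFrac = 0.7,
                       artifactFrac = 0.95,
                       barcodeTable = character(0),
                       umiLen = 3L,
                       barcodeMismatches = 0L,
                       collapseFirst = FALSE) {
  stopifnot(nchar(adaptor3) > 0, qualTrimThreshold >= 0,
            qualFilterThreshold >= 0, qualFilterFrac >= 0,
            qualFilterFrac <= 1, umiLen >= 1)
  if (anyDuplicated(barcodeTable))
    stop("duplicate barcodes in barcode table")
  if (length(barcodeTable) && length(unique(nchar(barcodeTable))) != 1L)
    stop("barcodes must all have the same length")
  structure(list(adaptor3 = adaptor3, minOverlap = as.integer(minOverlap),
                 minLenAfterClip = as.integer(minLenAfterClip),
                 qualTrimThreshold = as.integer(qualTrimThreshold),
                 qualFilterThreshold = as.integer(qualFilterThreshold),
                 qualFilterFrac = qualFilterFrac,
                 artifactFrac = artifactFrac,
                 barcodeTable = barcodeTable,
                 umiLen = as.integer(umiLen),
                 barcodeMismatches = as.integer(barcodeMismatches),
                 collapseFirst = collapseFirst),
            class = "PrepConfig")
}

#' Clip the 3' sequencing adaptor
#'
#' Removes the longest read suffix that matches a prefix of `adaptor3`.  A
#' clip is recorded as confident (`had_adaptor3 = TRUE`) when the matched
#' overlap reaches `minOverlap`; shorter chance overlaps are left in place.
#' If the complete adaptor occurs internally, everything from its first
#' occurrence onward is removed.
#'
#' `had_adaptor3` matters downstream: only reads whose 3' adaptor was seen
#' were sequenced through their true 3' end, so only they are candidates for
#' oligo(A) tail calling.
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param adaptor3 adaptor sequence.
#' @param minOverlap minimum confident overlap (nt).
#' @return `reads` with clipped `seq`/`qual` and logical `had_adaptor3`.
#' @export
clipAdaptor <- function(reads, adaptor3, minOverlap = 7L) {
  stopifnot(nchar(adaptor3) > 0)
  seq <- reads$seq
  n <- length(seq)
  cut_at <- rep(NA_integer_, n)  # first base of the adaptor match
  # full internal occurrence
  hit <- regexpr(adaptor3, seq, fixed = TRUE)
  full <- hit > 0L
  cut_at[full] <- hit[full]
  # partial adaptor prefix at the read end, longest first
  maxL <- min(nchar(adaptor3) - 1L, max(nchar(seq)))
  for (L in seq(maxL, minOverlap, by = -1L)) {
    todo <- is.na(cut_at) & nchar(seq) >= L
    if (!any(todo)) next
    m <- endsWith(seq[todo], substr(adaptor3, 1L, L))
    cut_at[todo][m] <- nchar(seq[todo][m]) - L + 1L
  }
  had <- !is.na(cut_at)
  keep_len <- ifelse(had, cut_at - 1L, nchar(seq))
  reads$seq <- substr(seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads$had_adaptor3 <- had
  reads
}

#' Quality-trim and quality-filter reads
#'
#' Trims 3' bases whose Phred score falls below `trimThreshold` (trailing run
#' only, as `fastq_quality_trimmer` does), then drops reads in which fewer
#' than `filterFrac` of the remaining bases reach `filterThreshold`.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (Phred+33).
#' @param trimThreshold,filterThreshold,filterFrac thresholds.
#' @return List with `reads` (kept, trimmed) and `dropped` (count).
#' @export
qualityFilter <- function(reads, trimThreshold = 20L,
                          filterThreshold = 20L, filterFrac = 0.7) {
  n <- nrow(reads)
  if (n == 0L) return(list(reads = reads, dropped = 0L))
  keep_len <- integer(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    q <- .phred(reads$qual[i])
    k <- length(q)
    while (k > 0L && q[k] < trimThreshold) k <- k - 1L
    keep_len[i] <- k
    ok[i] <- k > 0L && mean(q[seq_len(k)] >= filterThreshold) >= filterFrac
  }
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  list(reads = reads[ok, , drop = FALSE], dropped = sum(!ok))
}

#' Remove homopolymer sequencing artifacts
#'
#' Drops reads whose sequence is at least `artifactFrac` a single nucleotide.
#'
#' @param reads data.frame with `seq`.
#' @param artifactFrac homopolymer fraction threshold.
#' @return List with `reads` and `dropped`.
#' @export
artifactFilter <- function(reads, artifactFrac = 0.95) {
  if (nrow(reads) == 0L) return(list(reads = reads, dropped = 0L))
  freq <- Biostrings::letterFrequency(DNAStringSet(reads$seq),
                                      c("A", "C", "G", "T"))
  maxfrac <- apply(freq, 1L, max) / pmax(nchar(reads$seq), 1L)
  ok <- maxfrac < artifactFrac & nchar(reads$seq) > 0L
  list(reads = reads[ok, , drop = FALSE], dropped = sum(!ok))
}

#' Demultiplex reads by 5' linker barcode
#'
#' The linker layout is `[random trimer][barcode][insert]`.  The trimer is
#' stored as `umi`, the barcode matched (exactly by default) against the
#' table, and both are removed from the sequence.
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param barcodeTable named character sample -> barcode (unique, equal
#'   length).
#' @param umiLen random-trimer length.
#' @param mismatches allowed barcode mismatches.
#' @return `reads` with added `sample` (or `"unassigned"`) and `umi`, and the
#'   linker stripped from `seq`/`qual`.
#' @export
demultiplex <- function(reads, barcodeTable, umiLen = 3L, mismatches = 0L) {
  if (!length(barcodeTable)) stop("empty barcode table")
  if (anyDuplicated(barcodeTable)) stop("duplicate barcodes in barcode table")
  bcLen <- unique(nchar(barcodeTable))
  if (length(bcLen) != 1L) stop("barcodes must all have the same length")
  reads$umi <- substr(reads$seq, 1L, umiLen)
  bc <- substr(reads$seq, umiLen + 1L, umiLen + bcLen)
  idx <- match(bc, barcodeTable)
  if (mismatches > 0L && anyNA(idx)) {
    una <- which(is.na(idx))
    for (i in una) {
      d <- vapply(barcodeTable, function(b) {
        sum(utf8ToInt(bc[i]) != utf8ToInt(b))
      }, numeric(1))
      if (min(d) <= mismatches && sum(d == min(d)) == 1L)
        idx[i] <- which.min(d)
    }
  }
  reads$sample <- ifelse(is.na(idx), "unassigned", names(barcodeTable)[idx])
  reads$seq <- substr(reads$seq, umiLen + bcLen + 1L, nchar(reads$seq))
  reads$qual <- substr(reads$qual, umiLen + bcLen + 1L, nchar(reads$qual))
  reads
}

#' Collapse putative PCR duplicates
#'
#' Reads identical in (sample, random trimer, insert sequence) are collapsed
#' to one representative (the first seen).  The random trimer exists
#' precisely so that independent cDNAs with identical inserts are not
#' collapsed.
#'
#' @param reads data.frame with `sample`, `umi`, `seq`.
#' @return List with `reads` (unique) and `histogram` (table: copies-per-
#'   molecule -> number of molecules).
#' @export
collapseDuplicates <- function(reads) {
  if (nrow(reads) == 0L)
    return(list(reads = reads, histogram = table(integer(0))))
  key <- paste(reads$sample, reads$umi, reads$seq, sep = "\r")
  keep <- !duplicated(key)
  list(reads = reads[keep, , drop = FALSE],
       histogram = table(copies = as.vector(table(key))))
}

#' Run the full preprocessing chain on one FASTQ's worth of reads
#'
#' Applies, in order: adaptor clipping, minimum-length filtering, 3' quality
#' trimming and read-level quality filtering, homopolymer-artifact removal,
#' demultiplexing, and PCR-duplicate collapsing (order of the last two
#' configurable via `collapseFirst`).  Read-count conservation is recorded
#' per stage: input = kept + dropped + unassigned.
#'
#' @param reads data.frame with `id`, `seq`, `qual` (e.g. [readFastqFile()]).
#' @param cfg a [prepConfig()].
#' @return List with `reads` (columns `id`, `sample`, `umi`, `seq`, `qual`,
#'   `had_adaptor3`), `stats` (named integer vector of per-stage counts) and
#'   `histogram` (duplicate copy-number table).
#' @examples
#' sim <- makeGenome(simConfig(seed = 5, nTranscripts = 6))
#' lib <- simulateCracReads(sim, "PolII", nReads = 40, seed = 2)
#' pc <- prepConfig(barcodeTable = makeBarcodeTable("PolII_0_1"))
#' pr <- prepReads(lib$reads, pc)
#' pr$stats
#' @export
prepReads <- function(reads, cfg = prepConfig()) {
  stats <- c(input = nrow(reads))
  reads <- clipAdaptor(reads, cfg$adaptor3, cfg$minOverlap)
  tooShort <- nchar(reads$seq) <
    (cfg$minLenAfterClip + cfg$umiLen +
       if (length(cfg$barcodeTable)) unique(nchar(cfg$barcodeTable))[1] else 0L)
  stats["dropped_short"] <- sum(tooShort)
  reads <- reads[!tooShort, , drop = FALSE]
  qf <- qualityFilter(reads, cfg$qualTrimThreshold,
                      cfg$qualFilterThreshold, cfg$qualFilterFrac)
  stats["dropped_quality"] <- qf$dropped
  af <- artifactFilter(qf$reads, cfg$artifactFrac)
  stats["dropped_artifact"] <- af$dropped
  if (cfg$collapseFirst) {
    pre <- af$reads
    pre$sample <- ""
    pre$umi <- substr(pre$seq, 1L, cfg$umiLen)
    cd0 <- collapseDuplicates(pre)
    stats["duplicates_removed"] <- nrow(pre) - nrow(cd0$reads)
    reads <- demultiplex(cd0$reads[setdiff(colnames(cd0$reads),
                                           c("sample", "umi"))],
                         cfg$barcodeTable, cfg$umiLen,
                         cfg$barcodeMismatches)
    stats["unassigned"] <- sum(reads$sample == "unassigned")
    reads <- reads[reads$sample != "unassigned", , drop = FALSE]
    stats["kept"] <- nrow(reads)
    return(list(reads = reads, stats = stats, histogram = cd0$histogram))
  }
  reads <- demultiplex(af$reads, cfg$barcodeTable, cfg$umiLen,
                       cfg$barcodeMismatches)
  stats["unassigned"] <- sum(reads$sample == "unassigned")
  reads <- reads[reads$sample != "unassigned", , drop = FALSE]
  cd <- collapseDuplicates(reads)
  stats["duplicates_removed"] <- nrow(reads) - nrow(cd$reads)
  stats["kept"] <- nrow(cd$reads)
  list(reads = cd$reads, stats = stats, histogram = cd$histogram)
}
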