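# Spliced vs unspliced junction quantification.

#' Spliced:unspliced junction ratios
#'
#' Matches reads against annotated junction reference sequences: the
#' exon-exon junction (spliced form) and the intron to 3'-exon boundary
#' (unspliced form; the 5' boundary is not used).  A read counts for a
#' junction when it matches the reference exactly and covers the boundary
#' with at least `minOverhang` nucleotides on each side.
#'
#' @param seqs character vector of read insert sequences (linker removed),
#'   e.g. `prepReads()$reads$seq`.
#' @param sim a [CracGenome-class] (for transcript sense sequences and
#'   intron coordinates); intronless transcripts are skipped.
#' @param minOverhang minimum matched nt on each side of the boundary.
#' @return List with `perTranscript` (data.frame `transcript_id`,
#'   `n_spliced`, `n_unspliced`, `ratio` - NA and flagged `undefined` when
#'   `n_unspliced` is 0) and `aggregate` (pooled counts and ratio).
#' @examples
#' sim <- makeGenome(simConfig(seed = 2, nTranscripts = 10,
#'                             intronFraction = 1))
#' jr <- simulateJunctionReads(sim, 0.8, 200, seed = 4)
#' pc <- prepConfig(barcodeTable = makeBarcodeTable("JUNC"))
#' pr <- prepReads(jr$reads, pc)
#' junctionRatio(pr$reads$seq, sim)$aggregate
#' @export
junctionRatio <- function(seqs, sim, minOverhang = 3L) {
  f <- sim@features
  withIntron <- which(!is.na(mcols(f)$intron_start))
  if (!length(withIntron)) stop("annotation contains no introns")
  maxLen <- max(nchar(seqs), 60L)
  ids <- mcols(f)$ID

  refs <- vector("list", length(withIntron))
  names(refs) <- ids[withIntron]
  for (j in seq_along(withIntron)) {
    i <- withIntron[j]
    s <- .senseSeqExt(sim, i, 0L)
    fs <- start(f)[i]; fe <- end(f)[i]; st <- as.character(strand(f))[i]
    io <- sort(c(.toSense(mcols(f)$intron_start[i], fs, fe, st),
                 .toSense(mcols(f)$intron_end[i], fs, fe, st)))
    i1 <- io[1]; i2 <- io[2]
    K <- maxLen
    ex1 <- substr(s, max(1L, i1 - K), i1 - 1L)           # exon1 suffix
    intr <- substr(s, max(i1, i2 - K + 1L), i2)           # intron suffix
    ex2 <- substr(s, i2 + 1L, min(nchar(s), i2 + K))      # exon2 prefix
    refs[[j]] <- list(
      spliced = paste0(ex1, ex2), sb = nchar(ex1),
      unspliced = paste0(intr, ex2), ub = nchar(intr))
  }

  nS <- stats::setNames(integer(length(refs)), names(refs))
  nU <- nS
  refSpl <- DNAStringSet(vapply(refs, `[[`, character(1), "spliced"))
  refUns <- DNAStringSet(vapply(refs, `[[`, character(1), "unspliced"))
  sb <- vapply(refs, `[[`, numeric(1), "sb")
  ub <- vapply(refs, `[[`, numeric(1), "ub")
  for (r in seqs) {
    L <- nchar(r)
    if (L < 2L * minOverhang) next
    hitS <- which(vcountPattern(r, refSpl) > 0L)
    for (j in hitS) {
      st0 <- start(matchPattern(r, refSpl[[j]]))[1]
      if (st0 <= sb[j] - minOverhang + 1L && st0 + L - 1L >= sb[j] + minOverhang)
        nS[j] <- nS[j] + 1L
    }
    hitU <- which(vcountPattern(r, refUns) > 0L)
    for (j in hitU) {
      st0 <- start(matchPattern(r, refUns[[j]]))[1]
      if (st0 <= ub[j] - minOverhang + 1L && st0 + L - 1L >= ub[j] + minOverhang)
        nU[j] <- nU[j] + 1L
    }
  }
  per <- data.frame(
    transcript_id = names(refs),
    n_spliced = as.integer(nS), n_unspliced = as.integer(nU),
    ratio = ifelse(nU > 0L, nS / nU, NA_real_),
    undefined = nU == 0L, row.names = NULL)
  agg <- list(n_spliced = sum(nS), n_unspliced = sum(nU),
              ratio = if (sum(nU) > 0L) sum(nS) / sum(nU) else NA_real_)
  list(perTranscript = per, aggregate = agg)
}
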