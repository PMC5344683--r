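# Oligo(A) tail classification of non-templated 3' additions.

#' Classify non-templated 3' additions as oligo(A) tails
#'
#' Applies the classification rule to each alignment's non-genome-encoded 3'
#' portion, in read-sense orientation: a tail is an oligo(A) tail when it
#' contains two or more `A`s and no more than one in five non-A residues
#' (non-A fraction <= 1/5).  Only reads whose 3' adaptor was observed are
#' candidates - without the adaptor the true 3' end of the cDNA was not
#' sequenced - so reads with `had_adaptor3 = FALSE` get `NA` calls.
#'
#' @param aln assigned alignments ([assignMultimappers()]).
#' @param hadAdaptor3 logical vector parallel to `aln` (or a data.frame with
#'   `id`/`had_adaptor3` columns to join by read id).
#' @param features optional annotation [GenomicRanges::GRanges] with `ID`;
#'   used to attach the sense-overlapping transcript.
#' @return [S4Vectors::DataFrame] with one row per alignment: `read_id`,
#'   `tail_seq`, `tail_len`, `n_A`, `nonA_frac`, `is_oligoA` (NA when no
#'   adaptor), `anchor_pos` (genomic position of the last templated
#'   nucleotide, strand-aware), `strand`, `chrom`, `transcript_id`.
#' @examples
#' oligoARule(c("AA", "A", "AAAAG", "AAG", ""))
#' @export
callTails <- function(aln, hadAdaptor3, features = NULL) {
  if (is.data.frame(hadAdaptor3)) {
    hadAdaptor3 <- hadAdaptor3$had_adaptor3[
      match(mcols(aln)$read_id, hadAdaptor3$id)]
  }
  stopifnot(length(hadAdaptor3) == length(aln))
  tail_seq <- mcols(aln)$tail_seq
  rule <- oligoARule(tail_seq)
  std <- as.character(strand(aln))
  anchor <- ifelse(std == "+", end(aln), start(aln))
  tx <- rep(NA_character_, length(aln))
  if (!is.null(features)) {
    ov <- findOverlaps(aln, features)
    same <- std[S4Vectors::queryHits(ov)] ==
      as.character(strand(features))[S4Vectors::subjectHits(ov)]
    ov <- ov[same]
    tx[S4Vectors::queryHits(ov)] <-
      mcols(features)$ID[S4Vectors::subjectHits(ov)]
  }
  DataFrame(
    read_id = mcols(aln)$read_id,
    tail_seq = tail_seq,
    tail_len = rule$tail_len,
    n_A = rule$n_A,
    nonA_frac = rule$nonA_frac,
    is_oligoA = ifelse(hadAdaptor3, rule$is_oligoA, NA),
    had_adaptor3 = hadAdaptor3,
    anchor_pos = as.integer(anchor),
    chrom = as.character(seqnames(aln)),
    strand = std,
    transcript_id = tx)
}

#' Oligo(A) classification rule
#'
#' Vectorized over tail sequences; depends only on the A count and tail
#' length.  A tail qualifies when it has at least two `A`s and its non-A
#' fraction is at most 1/5 (the boundary case, one non-A in five, qualifies).
#'
#' @param tail_seq character vector of tail sequences (read sense).
#' @return data.frame with `tail_len`, `n_A`, `nonA_frac`, `is_oligoA`.
#' @export
oligoARule <- function(tail_seq) {
  tail_len <- nchar(tail_seq)
  n_A <- tail_len - nchar(gsub("A", "", tail_seq, fixed = TRUE))
  nonA_frac <- ifelse(tail_len > 0L, (tail_len - n_A) / tail_len, 0)
  data.frame(tail_len = tail_len, n_A = n_A, nonA_frac = nonA_frac,
             is_oligoA = n_A >= 2L & nonA_frac <= 1 / 5 + 1e-12)
}

#' Fraction of adaptor-containing reads carrying oligo(A) tails
#'
#' The headline tailed-read frequency: among reads whose 3' adaptor was
#' observed, the fraction whose oligo(A) tail is at least `minLen` nt.
#'
#' @param calls output of [callTails()].
#' @param minLen minimum qualifying tail length (nt).
#' @return List with `total_reads_with_adaptor`, `n_tailed`,
#'   `fraction_tailed` (NA when the denominator is zero).
#' @export
tailFraction <- function(calls, minLen = 2L) {
  withAd <- calls[calls$had_adaptor3, , drop = FALSE]
  n <- nrow(withAd)
  nt <- sum(withAd$is_oligoA & withAd$tail_len >= minLen, na.rm = TRUE)
  list(total_reads_with_adaptor = n, n_tailed = nt,
       fraction_tailed = if (n > 0L) nt / n else NA_real_)
}

#' Mean oligo(A) tail length along a metagene
#'
#' For each position relative to the chosen anchor, the mean tail length of
#' oligo(A)-classified reads whose last templated nucleotide maps there.
#' Positions with no qualifying reads are reported as `NA`, not zero.
#'
#' @param calls output of [callTails()].
#' @param features annotation [GenomicRanges::GRanges] with `ID`, `tss`,
#'   `pA_site`.
#' @param anchor `"pA"` or `"TSS"`.
#' @param window integer(2), positions relative to the anchor (anchor = 0,
#'   positive downstream in transcript sense).
#' @return Numeric vector over `window[1]:window[2]` of mean tail lengths.
#' @export
tailLengthMetagene <- function(calls, features, anchor = c("pA", "TSS"),
                               window = c(-200L, 20L)) {
  anchor <- match.arg(anchor)
  ok <- !is.na(calls$is_oligoA) & calls$is_oligoA &
    !is.na(calls$transcript_id)
  calls <- calls[ok, , drop = FALSE]
  idx <- match(calls$transcript_id, mcols(features)$ID)
  a <- if (anchor == "pA") mcols(features)$pA_site[idx] else
    mcols(features)$tss[idx]
  fstrand <- as.character(strand(features))[idx]
  rel <- ifelse(fstrand == "+", calls$anchor_pos - a, a - calls$anchor_pos)
  pos <- window[1]:window[2]
  inw <- rel >= window[1] & rel <= window[2]
  means <- tapply(calls$tail_len[inw], factor(rel[inw], levels = pos), mean)
  stats::setNames(as.numeric(means), pos)
}

#' Coverage track restricted to oligo(A)-tailed reads
#'
#' @param aln assigned alignments.
#' @param calls matching [callTails()] output.
#' @param hpm scale to hits per million of all alignments.
#' @return Per-strand track list as from [coverageTracks()].
#' @export
tailedReadTrack <- function(aln, calls, hpm = FALSE) {
  tailed <- !is.na(calls$is_oligoA) & calls$is_oligoA
  coverageTracks(aln, mode = "tailed_reads", tailed = tailed, hpm = hpm)
}
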