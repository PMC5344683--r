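# Alignment of prepped CRAC reads to the toy genome, capturing
# crosslink-induced single-nucleotide deletions and non-templated 3' tails.

# One strand-space: a chromosome viewed 5'->3' on one strand, so reads are
# always aligned left-to-right regardless of strand.
.strandSpaces <- function(genome) {
  out <- list()
  for (ch in names(genome)) {
    p <- as.character(genome[[ch]])
    m <- .revcomp(p)
    out[[paste0(ch, "+")]] <- list(chrom = ch, strand = "+",
                                   str = p, raw = charToRaw(p),
                                   len = nchar(p))
    out[[paste0(ch, "-")]] <- list(chrom = ch, strand = "-",
                                   str = m, raw = charToRaw(m),
                                   len = nchar(m))
  }
  out
}

# 5'-anchored maximal extension of a read against a strand-space at start s.
# Allows at most `maxDel` single-nucleotide genomic deletions; a deletion is
# accepted only when supported by at least `delAnchor` matching bases after
# it (otherwise the 3' remainder is left as a tail candidate).  Returns
# matched read length, deletion offset (strand-space, NA if none) and the
# genomic length consumed.
.extend <- function(rraw, graw, s, maxDel = 1L, delAnchor = 7L) {
  len <- length(rraw); glen <- length(graw)
  n <- min(len, glen - s + 1L)
  if (n <= 0L) return(NULL)
  cmp <- rraw[seq_len(n)] != graw[s:(s + n - 1L)]
  i <- which.max(cmp)
  if (!cmp[i]) {  # no mismatch within n bases
    return(list(matched = n, del = NA_integer_, glen = n))
  }
  # contiguous match is i-1; try skipping one genomic base (deletion)
  best <- list(matched = i - 1L, del = NA_integer_, glen = i - 1L)
  if (maxDel >= 1L && i <= len) {
    g2 <- s + i  # genome index aligned to read position i after the skip
    n2 <- min(len - i + 1L, glen - g2 + 1L)
    if (n2 > 0L) {
      cmp2 <- rraw[i:(i + n2 - 1L)] != graw[g2:(g2 + n2 - 1L)]
      j <- which.max(cmp2)
      m2 <- if (!cmp2[j]) n2 else j - 1L
      if (m2 >= delAnchor) {
        d <- s + i - 1L  # the skipped genomic base
        # left-align the deletion within a homopolymer run
        while (d > s && graw[d - 1L] == graw[d]) d <- d - 1L
        best <- list(matched = i - 1L + m2, del = d,
                     glen = i - 1L + m2 + 1L)
      }
    }
  }
  best
}

#' Align reads 5'-anchored against the genome
#'
#' Finds, for each read, all loci where the read matches the genome
#' contiguously from its 5' end, or with exactly one internal 1-nt genomic
#' deletion (the crosslink signature).  The genomic match is maximal: any 3'
#' read bases that cannot be extended into the genome become the
#' non-templated `tail_seq`.  Both strands are searched.  Candidate loci are
#' discovered via an exact seed of the first `seedLen` nucleotides, so a
#' deletion must lie at least `seedLen` bases into the read to be
#' recoverable; a deletion is called only when followed by at least
#' `delAnchor` matching bases, otherwise the remainder is treated as a tail
#' candidate.  This maximal-extension convention undercounts tails at
#' genomic A-runs, the same bias a homology-search-based procedure has.
#'
#' @param reads data.frame with `id` and `seq` (insert only, linker removed).
#' @param genome [Biostrings::DNAStringSet].
#' @param seedLen exact-match seed length (reads shorter are unmapped).
#' @param maxDel maximum genomic deletions per read (0 or 1).
#' @param delAnchor minimum matched bases required 3' of a deletion.
#' @return [GenomicRanges::GRanges] of candidate alignments (possibly several
#'   per read) with metadata `read_id`, `matched`, `score`, `deletion_pos`
#'   (genomic, NA if none), `tail_seq`, ordered by genome position within
#'   read.  Attribute `unmapped` holds the ids of unmapped reads.
#' @seealso [assignMultimappers()] to resolve multi-mapping reads.
#' @export
alignReads <- function(reads, genome, seedLen = 18L, maxDel = 1L,
                       delAnchor = 7L) {
  seqs <- reads$seq; ids <- reads$id
  mappable <- nchar(seqs) >= seedLen & !grepl("[^ACGT]", seqs)
  spaces <- .strandSpaces(genome)
  seeds <- substr(seqs, 1L, seedLen)
  uq <- unique(seeds[mappable])

  acc <- vector("list", 2048L); nacc <- 0L
  if (length(uq)) {
    pd <- Biostrings::PDict(DNAStringSet(uq))
    bySeed <- split(which(mappable), seeds[mappable])
    for (sp in spaces) {
      mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(sp$str))
      si <- Biostrings::startIndex(mi)
      for (k in seq_along(uq)) {
        starts <- si[[k]]
        if (is.null(starts) || !length(starts)) next
        for (r in bySeed[[uq[k]]]) {
          rraw <- charToRaw(seqs[r])
          for (s in sort(starts)) {
            e <- .extend(rraw, sp$raw, s, maxDel, delAnchor)
            if (is.null(e) || e$matched < seedLen) next
            nacc <- nacc + 1L
            if (nacc > length(acc)) acc <- c(acc, vector("list", length(acc)))
            acc[[nacc]] <- list(r = r, sp = sp$chrom, strand = sp$strand,
                                slen = sp$len, s = s, e = e)
          }
        }
      }
    }
  }
  if (nacc == 0L) {
    gr <- GRanges()
    attr(gr, "unmapped") <- ids
    return(gr)
  }
  acc <- acc[seq_len(nacc)]
  r <- vapply(acc, `[[`, integer(1), "r")
  chrom <- vapply(acc, `[[`, character(1), "sp")
  std <- vapply(acc, `[[`, character(1), "strand")
  slen <- vapply(acc, `[[`, integer(1), "slen")
  s <- vapply(acc, function(a) a$s, integer(1))
  matched <- vapply(acc, function(a) a$e$matched, integer(1))
  glen <- vapply(acc, function(a) a$e$glen, integer(1))
  del_ss <- vapply(acc, function(a) a$e$del, integer(1))
  ndel <- !is.na(del_ss)

  gstart <- ifelse(std == "+", s, slen - (s + glen - 1L) + 1L)
  gend <- ifelse(std == "+", s + glen - 1L, slen - s + 1L)
  delpos <- ifelse(std == "+", del_ss, slen - del_ss + 1L)
  tail_seq <- substr(seqs[r], matched + 1L, nchar(seqs[r]))
  score <- matched - 0.25 * ndel

  gr <- GRanges(chrom, IRanges(gstart, gend), strand = std,
                read_id = ids[r], matched = matched, score = score,
                deletion_pos = as.integer(delpos), tail_seq = tail_seq)
  seqlengths(gr) <- stats::setNames(width(genome), names(genome))[seqlevels(gr)]
  gr <- gr[order(mcols(gr)$read_id, as.integer(seqnames(gr)), start(gr),
                 as.integer(strand(gr)))]
  attr(gr, "unmapped") <- setdiff(ids, mcols(gr)$read_id)
  gr
}

#' Resolve multi-mapping reads by uniform random assignment
#'
#' Among each read's equally best-scoring candidate loci (ties enumerated in
#' genome order), one is chosen uniformly at random; the choice is
#' deterministic under `seed`.
#'
#' @param cand candidate [GenomicRanges::GRanges] from [alignReads()] or
#'   [importSam()].
#' @param seed RNG seed.
#' @return GRanges with exactly one alignment per read and an added `n_loci`
#'   column (number of equally best loci).
#' @export
assignMultimappers <- function(cand, seed = 1L) {
  if (!length(cand)) return(cand)
  um <- attr(cand, "unmapped")
  rid <- mcols(cand)$read_id
  sc <- mcols(cand)$score
  best <- stats::ave(sc, rid, FUN = max)
  keep <- sc >= best - 1e-9
  cand <- cand[keep]; rid <- rid[keep]
  nl <- stats::ave(rep(1L, length(cand)), rid, FUN = length)
  mcols(cand)$n_loci <- as.integer(nl)
  u <- withr::with_seed(seed, stats::runif(length(cand)))
  ord <- order(rid, u)
  sel <- ord[!duplicated(rid[ord])]
  out <- cand[sort(sel)]
  attr(out, "unmapped") <- um
  out
}

#' Export assigned alignments as SAM
#'
#' Minimal SAM 1.6 with `@SQ` lines from the genome; deletions become `D`
#' CIGAR operations and non-templated tails 3' soft clips (read-sense, i.e.
#' leading soft clips for minus-strand records).
#'
#' @param aln assigned alignments ([assignMultimappers()]).
#' @param genome the genome [Biostrings::DNAStringSet].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
exportSam <- function(aln, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ch in names(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, length(genome[[ch]])), con)
  if (!length(aln)) return(invisible(path))
  chrom <- as.character(seqnames(aln))
  std <- as.character(strand(aln))
  st <- start(aln); en <- end(aln)
  del <- mcols(aln)$deletion_pos
  tails <- mcols(aln)$tail_seq
  chromChar <- vapply(genome, as.character, character(1))
  gseq <- substring(chromChar[chrom], st, en)
  hasDel <- !is.na(del)
  k <- del - st + 1L
  gseq[hasDel] <- paste0(substr(gseq[hasDel], 1L, k[hasDel] - 1L),
                         substring(gseq[hasDel], k[hasDel] + 1L))
  cig <- ifelse(hasDel,
                sprintf("%dM1D%dM", del - st, en - del),
                sprintf("%dM", en - st + 1L))
  tl <- nchar(tails)
  sClip <- tl > 0L
  plus <- std == "+"
  cig[sClip & plus] <- paste0(cig[sClip & plus], tl[sClip & plus], "S")
  cig[sClip & !plus] <- paste0(tl[sClip & !plus], "S", cig[sClip & !plus])
  seqout <- paste0(gseq, tails)
  seqout[!plus] <- .revcomp(seqout[!plus])
  lines <- paste(mcols(aln)$read_id, ifelse(plus, 0L, 16L), chrom, st, 255L,
                 cig, "*", 0L, 0L, seqout, strrep("I", nchar(seqout)),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Import alignments from SAM
#'
#' Real-data entry point.  `D` CIGAR operations become deletion positions,
#' read-sense 3' soft clips become tail candidates subject to the
#' maximal-extension check against the genome (clipped bases that do extend
#' into the genome are absorbed into the span).  `N` operations are kept and
#' flagged as junction reads.  Secondary alignments are grouped per read so
#' [assignMultimappers()] applies.
#'
#' @param path SAM file path.
#' @param genome the genome [Biostrings::DNAStringSet]; required for the
#'   tail extension check.
#' @return Candidate [GenomicRanges::GRanges] as from [alignReads()], plus a
#'   `junction` logical column.
#' @export
importSam <- function(path, genome) {
  if (missing(genome) || is.null(genome))
    stop("genome required for the tail extension check")
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  ln <- ln[nzchar(ln)]
  if (!length(ln)) return(GRanges())
  fields <- strsplit(ln, "\t", fixed = TRUE)
  out <- vector("list", length(fields))
  chromChars <- lapply(genome, as.character)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) next  # unmapped
    chrom <- f[3]; pos <- as.integer(f[4]); cig <- f[6]; sq <- f[10]
    minus <- bitwAnd(flag, 16L) > 0L
    ops <- regmatches(cig, gregexpr("\\d+[MIDNSHP=X]", cig))[[1]]
    opn <- as.integer(sub("[A-Z=]$", "", ops))
    opc <- sub("^\\d+", "", ops)
    refConsume <- opc %in% c("M", "D", "N", "=", "X")
    span <- sum(opn[refConsume])
    gstart <- pos; gend <- pos + span - 1L
    # deletion positions (each deleted base)
    delpos <- integer(0)
    cur <- pos
    for (k in seq_along(opc)) {
      if (opc[k] == "D") delpos <- c(delpos, cur:(cur + opn[k] - 1L))
      if (refConsume[k]) cur <- cur + opn[k]
    }
    junction <- any(opc == "N")
    lead <- if (opc[1] == "S") opn[1] else 0L
    trail <- if (opc[length(opc)] == "S") opn[length(opc)] else 0L
    matched <- sum(opn[opc %in% c("M", "=", "X")])
    # read-sense 3' tail candidate
    gch <- chromChars[[chrom]]
    if (!minus) {
      tail <- if (trail > 0L) substr(sq, nchar(sq) - trail + 1L, nchar(sq)) else ""
      while (nchar(tail) > 0L && gend < nchar(gch) &&
             substr(tail, 1L, 1L) == substr(gch, gend + 1L, gend + 1L)) {
        gend <- gend + 1L; matched <- matched + 1L
        tail <- substr(tail, 2L, nchar(tail))
      }
    } else {
      tail <- if (lead > 0L) .revcomp(substr(sq, 1L, lead)) else ""
      while (nchar(tail) > 0L && gstart > 1L &&
             substr(tail, 1L, 1L) ==
               chartr("ACGT", "TGCA", substr(gch, gstart - 1L, gstart - 1L))) {
        gstart <- gstart - 1L; matched <- matched + 1L
        tail <- substr(tail, 2L, nchar(tail))
      }
    }
    out[[i]] <- data.frame(
      read_id = f[1], chrom = chrom, start = gstart, end = gend,
      strand = if (minus) "-" else "+",
      matched = matched,
      deletion_pos = if (length(delpos)) delpos[1] else NA_integer_,
      tail_seq = tail, junction = junction,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(GRanges())
  gr <- GRanges(out$chrom, IRanges(out$start, out$end), strand = out$strand,
                read_id = out$read_id, matched = out$matched,
                score = out$matched - 0.25 * !is.na(out$deletion_pos),
                deletion_pos = out$deletion_pos, tail_seq = out$tail_seq,
                junction = out$junction)
  seqlengths(gr) <- vapply(genome, length, integer(1))[seqlevels(gr)]
  gr[order(mcols(gr)$read_id, as.integer(seqnames(gr)), start(gr))]
}

#' Per-strand coverage-style tracks
#'
#' @param aln assigned alignments.
#' @param mode `"coverage"` (read spans), `"deletions"` (1-nt intervals at
#'   deletion positions) or `"tailed_reads"` (spans of reads flagged in
#'   `tailed`).
#' @param tailed logical vector parallel to `aln` selecting oligo(A)-tailed
#'   reads (required for `mode = "tailed_reads"`).
#' @param hpm if `TRUE`, scale values by 1e6 / number of alignments in `aln`.
#' @return List with elements `plus` and `minus`, each an
#'   [IRanges::RleList] over chromosomes.
#' @export
coverageTracks <- function(aln, mode = c("coverage", "deletions",
                                         "tailed_reads"),
                           tailed = NULL, hpm = FALSE) {
  mode <- match.arg(mode)
  sel <- switch(mode,
    coverage = aln,
    deletions = {
      d <- aln[!is.na(mcols(aln)$deletion_pos)]
      GRanges(seqnames(d), IRanges(mcols(d)$deletion_pos, width = 1L),
              strand = strand(d), seqlengths = seqlengths(aln))
    },
    tailed_reads = {
      if (is.null(tailed)) stop("tailed flags required for tailed_reads mode")
      aln[tailed]
    })
  scale <- if (hpm && length(aln)) 1e6 / length(aln) else 1
  list(plus = coverage(sel[strand(sel) != "-"]) * scale,
       minus = coverage(sel[strand(sel) == "-"]) * scale)
}

#' Write per-strand bedgraph files
#'
#' Intervals are written 0-based half-open as the format requires; zero
#' coverage is omitted.
#'
#' @param tracks output of [coverageTracks()].
#' @param prefix path prefix; writes `<prefix>.plus.bedgraph` and
#'   `<prefix>.minus.bedgraph`.
#' @return Invisibly, the two paths.
#' @export
writeBedgraph <- function(tracks, prefix) {
  paths <- c(plus = paste0(prefix, ".plus.bedgraph"),
             minus = paste0(prefix, ".minus.bedgraph"))
  for (s in c("plus", "minus")) {
    gr <- as(tracks[[s]], "GRanges")
    gr <- gr[gr$score != 0]
    rtracklayer::export(gr, paths[[s]], format = "bedGraph")
  }
  invisible(paths)
}
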