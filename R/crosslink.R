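# Crosslink-site calling from read microdeletions, site ranking, motif
# window extraction and consensus scoring.

#' Call crosslink sites from read microdeletions
#'
#' Reverse transcriptase frequently drops the crosslinked nucleotide, so the
#' genomic positions deleted from reads pinpoint protein-RNA contacts.
#' Tallies deletion positions per strand into width-1 sites with read
#' support counts, annotated to the sense-overlapping transcript.
#'
#' @param aln assigned alignments with `deletion_pos`.
#' @param features annotation [GenomicRanges::GRanges] with `ID`; optional.
#' @param restrictTo optional character vector of transcript ids; sites on
#'   other transcripts (or outside any) are dropped.
#' @return [GenomicRanges::GRanges] of width-1 sites with `deletion_count`
#'   and `transcript_id`, sorted by position.
#' @export
callDeletionSites <- function(aln, features = NULL, restrictTo = NULL) {
  d <- aln[!is.na(mcols(aln)$deletion_pos)]
  if (!length(d)) return(GRanges())
  key <- paste(seqnames(d), mcols(d)$deletion_pos,
               strand(d), sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  sites <- GRanges(
    vapply(parts, `[`, character(1), 1L),
    IRanges(as.integer(vapply(parts, `[`, character(1), 2L)), width = 1L),
    strand = vapply(parts, `[`, character(1), 3L),
    deletion_count = as.integer(tab))
  if (!is.null(seqlengths(aln)) && !anyNA(seqlengths(aln)))
    seqlengths(sites) <- seqlengths(aln)[seqlevels(sites)]
  mcols(sites)$transcript_id <- NA_character_
  if (!is.null(features)) {
    ov <- findOverlaps(sites, features)
    same <- as.character(strand(sites))[S4Vectors::queryHits(ov)] ==
      as.character(strand(features))[S4Vectors::subjectHits(ov)]
    ov <- ov[same]
    mcols(sites)$transcript_id[S4Vectors::queryHits(ov)] <-
      mcols(features)$ID[S4Vectors::subjectHits(ov)]
  }
  if (!is.null(restrictTo))
    sites <- sites[!is.na(mcols(sites)$transcript_id) &
                     mcols(sites)$transcript_id %in% restrictTo]
  sort(sites)
}

#' Top crosslink sites by deletion support
#'
#' Ranks sites by `deletion_count` within an optional transcript scope; ties
#' at the cutoff are broken by (chromosome, position) ascending so the
#' selection is deterministic.
#'
#' @param sites output of [callDeletionSites()].
#' @param n number of sites to keep.
#' @param scope optional transcript ids restricting the ranking.
#' @return The top `n` sites with a `rank` column; if fewer are available,
#'   all are returned with a warning.
#' @export
topSites <- function(sites, n = 50L, scope = NULL) {
  if (!is.null(scope))
    sites <- sites[!is.na(mcols(sites)$transcript_id) &
                     mcols(sites)$transcript_id %in% scope]
  if (length(sites) < n) {
    warning("only ", length(sites), " sites available (requested ", n, ")")
    n <- length(sites)
  }
  ord <- order(-mcols(sites)$deletion_count,
               as.integer(seqnames(sites)), start(sites))
  out <- sites[ord[seq_len(n)]]
  mcols(out)$rank <- seq_len(n)
  out
}

#' Extract fixed-width sequence windows around sites
#'
#' Sense-strand window of `2*flank + 1` nt centred on each site
#' (minus-strand windows are reverse complemented).  Windows running off a
#' contig end are padded with `N` and flagged.
#'
#' @param sites [GenomicRanges::GRanges] of width-1 sites.
#' @param genome [Biostrings::DNAStringSet].
#' @param flank half-width in nt (default 6, i.e. 13-nt windows).
#' @return [Biostrings::DNAStringSet] of windows with metadata column
#'   `clipped` marking padded windows.
#' @export
extractWindows <- function(sites, genome, flank = 6L) {
  n <- length(sites)
  out <- character(n); clipped <- logical(n)
  chrom <- as.character(seqnames(sites))
  pos <- start(sites)
  std <- as.character(strand(sites))
  for (i in seq_len(n)) {
    chr <- genome[[chrom[i]]]
    lo <- pos[i] - flank; hi <- pos[i] + flank
    padL <- max(0L, 1L - lo); padR <- max(0L, hi - length(chr))
    s <- as.character(subseq(chr, max(lo, 1L), min(hi, length(chr))))
    s <- paste0(strrep("N", padL), s, strrep("N", padR))
    if (std[i] == "-") s <- .revcomp(s)
    out[i] <- s
    clipped[i] <- padL > 0L || padR > 0L
  }
  ws <- DNAStringSet(out)
  names(ws) <- sprintf("%s:%d:%s", chrom, pos, std)
  mcols(ws)$clipped <- clipped
  ws
}

#' Score windows for consensus-motif conformance
#'
#' A window conforms when the consensus occurs in it as an exact substring.
#' Additionally reports k-mer enrichment against a dinucleotide-preserving
#' shuffle background.
#'
#' @param windows [Biostrings::DNAStringSet] from [extractWindows()].
#' @param consensus consensus motif (DNA alphabet; the classic Nab3 motif
#'   UCUUG is `"TCTTG"` in DNA).
#' @param k k-mer size for the enrichment table.
#' @param shuffles number of shuffled background replicates.
#' @param seed RNG seed for the shuffle.
#' @return List with `n_windows`, `n_conforming`, `fraction` (NA for an
#'   empty window set), and `kmer_enrichment` (data.frame `kmer`, `observed`,
#'   `expected`, `enrichment`, most enriched first).
#' @export
consensusScore <- function(windows, consensus = "TCTTG", k = 5L,
                           shuffles = 50L, seed = 1L) {
  nW <- length(windows)
  if (nW == 0L) {
    return(list(n_windows = 0L, n_conforming = 0L, fraction = NA_real_,
                kmer_enrichment = data.frame()))
  }
  conf <- vcountPattern(consensus, windows, fixed = TRUE) > 0L
  obs <- colSums(oligonucleotideFrequency(windows, k))
  seqs <- as.character(windows)
  exp <- withr::with_seed(seed, {
    tot <- numeric(length(obs)); names(tot) <- names(obs)
    for (r in seq_len(shuffles)) {
      sh <- DNAStringSet(vapply(seqs, shuffleDinucleotides, character(1)))
      tot <- tot + colSums(oligonucleotideFrequency(sh, k))
    }
    tot / shuffles
  })
  enr <- data.frame(kmer = names(obs), observed = as.numeric(obs),
                    expected = as.numeric(exp),
                    enrichment = (obs + 0.5) / (exp + 0.5),
                    row.names = NULL)
  enr <- enr[obs + exp > 0, ]
  enr <- enr[order(-enr$enrichment), ]
  list(n_windows = nW, n_conforming = sum(conf),
       fraction = mean(conf),
       kmer_enrichment = enr)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: returns a random sequence with exactly the same
#' dinucleotide (and hence mononucleotide) composition as the input, and the
#' same first and last characters.  Non-ACGTN inputs are returned unchanged.
#'
#' @param s a single sequence (character scalar).
#' @return A shuffled sequence of the same length.
#' @export
shuffleDinucleotides <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3L) return(s)
  verts <- unique(ch)
  last <- ch[n]
  # edge multiset: from ch[i] to ch[i+1]
  edges <- split(ch[-1L], factor(ch[-n], levels = verts))
  for (attempt in seq_len(100L)) {
    # pick a trailing edge for every vertex except the terminal one
    lastEdge <- vapply(verts, function(v) {
      if (v == last && !length(edges[[v]])) return(NA_character_)
      e <- edges[[v]]
      if (!length(e)) NA_character_ else .sample1(e)
    }, character(1))
    # connectivity: following trailing edges from each vertex must reach
    # the terminal vertex
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.na(lastEdge[[v]])) next
      cur <- v; seen <- character(0)
      while (cur != last && !cur %in% seen && !is.na(lastEdge[[cur]])) {
        seen <- c(seen, cur)
        cur <- lastEdge[[cur]]
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(s)
  # shuffle remaining edges, append the trailing edge per vertex
  pool <- edges
  for (v in verts) {
    e <- pool[[v]]
    if (!is.na(lastEdge[[v]]) && v != last) {
      drop <- match(lastEdge[[v]], e)
      e <- e[-drop]
    }
    pool[[v]] <- if (length(e)) sample(e) else character(0)
  }
  out <- character(n); out[1L] <- ch[1L]
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  for (i in 2L:n) {
    v <- out[i - 1L]
    e <- pool[[v]]
    if (ptr[[v]] <= length(e)) {
      out[i] <- e[ptr[[v]]]
      ptr[[v]] <- ptr[[v]] + 1L
    } else {
      out[i] <- lastEdge[[v]]
    }
  }
  paste(out, collapse = "")
}

#' Strongest crosslink site per transcript
#'
#' Per transcript, the site with the highest deletion count; ties go to the
#' 5'-most site in transcript sense (deterministic).
#'
#' @param sites output of [callDeletionSites()] (annotated to transcripts).
#' @return GRanges with one anchor site per transcript; transcripts without
#'   sites are simply absent (their count is in attribute `n_without`).
#' @export
strongestSitePerGene <- function(sites) {
  s <- sites[!is.na(mcols(sites)$transcript_id)]
  if (!length(s)) return(s)
  tx <- mcols(s)$transcript_id
  std <- as.character(strand(s))
  # 5'-most in transcript sense: smallest start on +, largest on -
  fiveprime <- ifelse(std == "+", start(s), -start(s))
  ord <- order(tx, -mcols(s)$deletion_count, fiveprime)
  sel <- ord[!duplicated(tx[ord])]
  out <- s[sort(sel)]
  attr(out, "n_without") <- NA_integer_
  out
}

#' Motif frequency in transcript regions
#'
#' Counts occurrences (overlaps allowed) of a short motif in a TSS-proximal
#' window of each transcript, reported per kilobase.
#'
#' @param features annotation [GenomicRanges::GRanges] with `ID`, `tss`.
#' @param genome [Biostrings::DNAStringSet].
#' @param motif DNA motif (default `"CTT"`, the core Nab3 recognition).
#' @param regionLen length of the TSS-proximal window (nt).
#' @return data.frame with `transcript_id`, `n_hits`, `per_kb`.
#' @export
motifScan <- function(features, genome, motif = "CTT", regionLen = 300L) {
  n <- length(features)
  hits <- integer(n)
  std <- as.character(strand(features))
  for (i in seq_len(n)) {
    chr <- genome[[as.character(seqnames(features))[i]]]
    tss <- mcols(features)$tss[i]
    if (std[i] == "+") {
      lo <- tss; hi <- min(tss + regionLen - 1L, length(chr))
      s <- as.character(subseq(chr, lo, hi))
    } else {
      lo <- max(tss - regionLen + 1L, 1L); hi <- tss
      s <- .revcomp(as.character(subseq(chr, lo, hi)))
    }
    hits[i] <- countPattern(motif, DNAString(s))
  }
  data.frame(transcript_id = mcols(features)$ID, n_hits = hits,
             per_kb = hits / (regionLen / 1000))
}
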